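test_that("reverse_complement matches hand derivation and is an involution", {
  expect_equal(reverse_complement("ACGTTCGAACG"), "CGTTCGAACGT")
  expect_equal(reverse_complement("ACGT"), "ACGT")  # palindrome
  expect_equal(reverse_complement("N"), "N")
  expect_equal(reverse_complement("ARG"), "CNT")    # ambiguity collapses to N

  set.seed(101)
  for (i in 1:25) {
    s <- random_dna(sample(1:80, 1))
    expect_equal(reverse_complement(reverse_complement(s)), s)
    expect_equal(reverse_complement(s), oracle_revcomp(s))
  }
  expect_error(reverse_complement(""), "non-empty")
})

test_that("encode_boh realises the published letter map", {
  expect_equal(encode_boh("A"), matrix(c(0, 0, 0, 1, 1, 0, 0, 0),
                                       nrow = 2, byrow = TRUE))
  m <- encode_boh("ACGT")
  expect_equal(m[1, ], c(0, 0, 0, 1))  # A
  expect_equal(m[2, ], c(0, 0, 1, 0))  # C
  expect_equal(m[3, ], c(0, 1, 0, 0))  # G
  expect_equal(m[4, ], c(1, 0, 0, 0))  # T
  expect_equal(encode_boh("N"), matrix(0, 2, 4))
})

test_that("letter map is strand-symmetric: complement vector = reversed vector", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (b in names(comp)) {
    v <- encode_boh(b)[1, ]
    vc <- encode_boh(comp[[b]])[1, ]
    expect_equal(vc, rev(v))
  }
})

test_that("encode_boh row count and row sums against brute force", {
  set.seed(102)
  for (L in sample(3:200, 30)) {
    s <- random_dna(L, alphabet = c("A", "C", "G", "T", "N"))
    m <- encode_boh(s)
    expect_identical(dim(m), c(2L * L, 4L))
    expect_equal(m, oracle_boh(s), ignore_attr = TRUE)
    n_amb <- sum(strsplit(s, "")[[1]] == "N")
    expect_equal(sum(m), 2 * L - 2 * n_amb)
    expect_true(all(rowSums(m) %in% c(0, 1)))
  }
})

test_that("expand_codon_frames follows the offset rule", {
  fr <- expand_codon_frames("ACGTTCGAACG")
  expect_equal(fr[[1]], c("ACG", "TTC", "GAA"))
  expect_equal(fr[[2]], c("CGT", "TCG", "AAC"))
  expect_equal(fr[[3]], c("GTT", "CGA", "ACG"))
  # reverse complement is CGTTCGAACGT
  expect_equal(fr[[4]], c("CGT", "TCG", "AAC"))
  expect_equal(fr[[5]], c("GTT", "CGA", "ACG"))
  expect_equal(fr[[6]], c("TTC", "GAA", "CGT"))
  expect_equal(length(unlist(fr)), 18L)  # 2*(11-2)

  fr3 <- expand_codon_frames("ACG")
  expect_equal(fr3, list("ACG", character(0), character(0),
                         "CGT", character(0), character(0)))
  expect_error(expand_codon_frames("AC"), "shorter than 3")
})

test_that("total codon count equals 2*(L-2) for L = 3..100", {
  set.seed(103)
  for (L in 3:100) {
    s <- random_dna(L)
    codons <- unlist(expand_codon_frames(s))
    expect_equal(length(codons), 2L * (L - 2L))
    expect_equal(sort(codons), sort(oracle_codon_list(s)))
  }
})

test_that("encode_coh uses the lexicographic codon index", {
  m <- encode_coh("AAA")
  expect_equal(which(m[1, ] == 1), 1L)      # AAA -> column 1
  expect_equal(codon_index("TTT"), 64L)
  expect_equal(codon_index("ACG"), 7L)       # 16*0 + 4*1 + 2 + 1
  expect_equal(codon_index("NNA"), NA_integer_)

  m2 <- encode_coh("ACGTTCGAACG")
  expect_identical(dim(m2), c(18L, 64L))
  expect_true(all(rowSums(m2) == 1))

  # codon containing N -> all-zero row
  m3 <- encode_coh("ANA")   # both frames' codons contain N
  expect_true(all(rowSums(m3) == 0))
})

test_that("pad_for_group appends zero rows to the group shape", {
  s <- random_dna(100)
  p <- pad_for_group(encode_boh(s), encode_coh(s), "A")
  expect_equal(nrow(p$boh), 800L)
  expect_equal(nrow(p$coh), 800L)
  expect_equal(p$original_length, 100)
  expect_equal(p$boh[1:200, ], encode_boh(s), ignore_attr = TRUE)
  expect_equal(p$coh[1:196, ], encode_coh(s), ignore_attr = TRUE)
  expect_true(all(p$boh[201:800, ] == 0))
  expect_true(all(p$coh[197:800, ] == 0))

  s400 <- random_dna(400)
  p400 <- pad_for_group(encode_boh(s400), encode_coh(s400), "A")
  expect_equal(nrow(p400$boh), 800L)   # exactly full, no padding
  expect_true(all(p400$coh[797:800, ] == 0))

  s401 <- random_dna(401)
  expect_error(pad_for_group(encode_boh(s401), encode_coh(s401), "A"),
               "exceeds")
})

test_that("network index encoding reconstructs the reference one-hot matrices", {
  # cross-check between the C++ index encoder feeding the network and the
  # R reference encoders
  set.seed(104)
  for (i in 1:10) {
    L <- sample(3:120, 1)
    s <- random_dna(L, alphabet = c("A", "C", "G", "T", "N"))
    enc <- mgeclass:::encode_indices_cpp(s, 200L)
    boh <- matrix(0, 400, 4)
    for (r in seq_len(400)) {
      id <- enc$boh[r, 1]
      if (id >= 0) boh[r, id + 1] <- 1
    }
    coh <- matrix(0, 400, 64)
    for (r in seq_len(400)) {
      id <- enc$coh[r, 1]
      if (id >= 0) coh[r, id + 1] <- 1
    }
    ref <- pad_for_group(encode_boh(s), encode_coh(s), "A")
    expect_equal(boh[1:(2 * L), ], encode_boh(s), ignore_attr = TRUE)
    expect_equal(coh[1:(2 * (L - 2)), ], encode_coh(s), ignore_attr = TRUE)
    expect_true(all(boh[(2 * L + 1):400, ] == 0))
  }
})

test_that("encoding is deterministic", {
  s <- random_dna(50)
  expect_identical(encode_boh(s), encode_boh(s))
  expect_identical(encode_coh(s), encode_coh(s))
})
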