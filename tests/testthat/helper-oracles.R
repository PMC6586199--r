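# Independent oracles and small utilities shared across the suite.
# Every oracle here is deliberately naive (loops, enumeration, O(n^2)) and
# independent of the package's production code paths.

CLS <- c("phage", "chromosome", "plasmid")

random_dna <- function(L, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# base-by-base complement + reversal, via Biostrings (independent of the
# package's C++ implementation)
oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# naive per-row one-hot builder under the published letter map
oracle_boh <- function(s) {
  map <- list(A = c(0, 0, 0, 1), C = c(0, 0, 1, 0),
              G = c(0, 1, 0, 0), T = c(1, 0, 0, 0))
  rc <- oracle_revcomp(s)
  chars <- c(strsplit(s, "")[[1]], strsplit(rc, "")[[1]])
  t(vapply(chars, function(ch) {
    if (ch %in% names(map)) map[[ch]] else rep(0, 4)
  }, numeric(4)))
}

# enumerate full codons in all six frames by explicit loops
oracle_codon_list <- function(s) {
  rc <- oracle_revcomp(s)
  out <- character(0)
  for (strand in c(s, rc)) {
    for (off in 0:2) {
      p <- off + 1
      while (p + 2 <= nchar(strand)) {
        out <- c(out, substr(strand, p, p + 2))
        p <- p + 3
      }
    }
  }
  out
}

# O(n^2) Mann-Whitney AUC with 0.5 tie credit
oracle_auc_pairwise <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# random valid score triples (rows sum to 1)
random_triples <- function(n) {
  m <- matrix(rexp(3 * n), ncol = 3)
  m / rowSums(m)
}

# shared small simulated dataset + trained model, built once per test run
.fixture_env <- new.env(parent = emptyenv())

small_trained_model <- function() {
  if (is.null(.fixture_env$model)) {
    sim <- simulate_fragment_set(400, "A", seed = 42)
    idx <- unlist(lapply(CLS, function(cl) which(sim$fragments$label == cl)[1:300]))
    train <- sim$fragments[idx, ]
    test <- sim$fragments[-idx, ]
    class(train) <- class(test) <- c("dna_fragments", "data.frame")
    model <- build_architecture("A", seed = 7)
    model <- train_model(model, train, epochs = 3, seed = 11)
    .fixture_env$model <- model
    .fixture_env$train <- train
    .fixture_env$test <- test
  }
  list(model = .fixture_env$model, train = .fixture_env$train,
       test = .fixture_env$test)
}
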