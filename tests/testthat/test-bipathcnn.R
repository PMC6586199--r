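audit_architecture <- function(group) {
  model <- build_architecture(group, seed = 5)
  layers <- architecture_layers(model)
  for (p in c("b", "c")) {
    pl <- layers[layers$path == p, ]
    expect_equal(pl$units[pl$layer == "conv1"], 64)
    expect_equal(pl$kernel_length[pl$layer == "conv1"], 6)
    expect_equal(pl$units[pl$layer == "conv2"], 128)
    expect_equal(pl$kernel_length[pl$layer == "conv2"], 3)
    expect_equal(pl$units[pl$layer == "conv3"], 256)
    expect_equal(pl$kernel_length[pl$layer == "conv3"], 3)
    expect_equal(pl$kernel_length[pl$layer == "pool1"], 3)
    expect_equal(pl$kernel_length[pl$layer == "pool2"], 3)
    expect_equal(sum(pl$type == "batchnorm+dropout"), 2)
    expect_equal(sum(pl$type == "gap"), 1)
  }
  hd <- layers[layers$path == "head", ]
  expect_equal(hd$units[hd$layer == "concatenate"], 512)  # 256 + 256
  expect_equal(hd$units[hd$layer == "dense"], 512)        # same as its input
  expect_equal(hd$units[hd$layer == "softmax"], 3)
  invisible(layers)
}

test_that("built architecture matches the declared hyperparameters", {
  for (g in c("A", "B", "C")) audit_architecture(g)
  # input shapes follow the group maximum: 2 * L_max rows
  mA <- build_architecture("A")
  expect_equal(2L * mA$spec$L_max, 800L)
  expect_equal(2L * build_architecture("B")$spec$L_max, 1600L)
  expect_equal(2L * build_architecture("C")$spec$L_max, 2400L)
  # conv1 weight widths encode the input channel counts (4 and 64)
  expect_equal(dim(mA$weights$b_W1), c(64L, 4L * 6L))
  expect_equal(dim(mA$weights$c_W1), c(64L, 64L * 6L))
  expect_error(build_architecture("E"), "should be one of")
})

test_that("single-path ablations shrink the head to the path width", {
  for (p in c("base", "codon")) {
    m <- build_architecture("A", paths = p, seed = 2)
    layers <- architecture_layers(m)
    hd <- layers[layers$path == "head", ]
    expect_equal(hd$units[hd$layer == "concatenate"], 256)
    expect_equal(hd$units[hd$layer == "dense"], 256)
    expect_equal(nrow(layers[layers$path %in% c("b", "c"), ]), 8)
  }
})

test_that("prediction produces valid, deterministic, seed-reproducible scores", {
  sim <- simulate_fragment_set(10, "A", seed = 5)
  frags <- sim$fragments

  m1 <- build_architecture("A", seed = 99)
  s1 <- predict_batch(m1, frags)
  expect_equal(dim(s1), c(30L, 3L))
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_true(all(abs(rowSums(s1) - 1) < 1e-6))

  # determinism with fixed weights
  expect_identical(s1, predict_batch(m1, frags))
  # same init seed -> same untrained scores; different seed -> different
  s1b <- predict_batch(build_architecture("A", seed = 99), frags)
  expect_identical(s1, s1b)
  s2 <- predict_batch(build_architecture("A", seed = 100), frags)
  expect_false(identical(s1, s2))
})

test_that("training input validation names the offending record", {
  sim <- simulate_fragment_set(5, "A", seed = 6)
  frags <- sim$fragments
  model <- build_architecture("A")

  two_cls <- frags[frags$label != "plasmid", ]
  class(two_cls) <- c("dna_fragments", "data.frame")
  expect_error(train_model(model, two_cls), "plasmid")

  long <- dna_fragments(c(frags$id, "too_long"),
                        c(frags$seq, random_dna(500)),
                        c(frags$label, "phage"))
  expect_error(train_model(model, long), "too_long")
  expect_error(predict_batch(model, dna_fragments("x", random_dna(401))),
               "above the group A maximum")
})

test_that("model learns separable data and its loss decreases", {
  fx <- small_trained_model()
  lh <- fx$model$metadata$loss_history
  expect_length(lh, 3)
  expect_lt(lh[length(lh)], lh[1])

  s <- predict_batch(fx$model, fx$test)
  acc <- mean(CLS[max.col(s)] == fx$test$label)
  expect_gt(acc, 0.7)   # scaled-down sanity bound; full bound in acceptance
})

test_that("save/load round-trips weights, manifest and predictions", {
  fx <- small_trained_model()
  dir <- withr::local_tempdir()
  save_model(fx$model, dir)
  expect_true(file.exists(file.path(dir, "manifest.txt")))
  man <- readLines(file.path(dir, "manifest.txt"))
  expect_true(any(grepl("^group\tA$", man)))
  expect_true(any(grepl("class_order\tphage,chromosome,plasmid", man)))

  re <- load_model(dir)
  expect_identical(predict_batch(re, fx$test[1:10, ]),
                   predict_batch(fx$model, fx$test[1:10, ]))
})

test_that("dual-path model is not beaten by single-path ablations (with slack)", {
  sim <- simulate_fragment_set(1000, "A", seed = 21)
  idx <- unlist(lapply(CLS, function(cl) which(sim$fragments$label == cl)[1:800]))
  train <- sim$fragments[idx, ]
  test <- sim$fragments[-idx, ]
  class(train) <- class(test) <- c("dna_fragments", "data.frame")

  accs <- vapply(c("both", "base", "codon"), function(p) {
    m <- build_architecture("A", paths = p, seed = 31)
    m <- train_model(m, train, epochs = 5, seed = 41)
    s <- predict_batch(m, test)
    mean(CLS[max.col(s)] == test$label)
  }, numeric(1))
  expect_lte(accs[["base"]], accs[["both"]] + 0.05)
  expect_lte(accs[["codon"]], accs[["both"]] + 0.05)
})
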