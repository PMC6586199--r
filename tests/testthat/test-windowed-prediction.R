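test_that("length routing follows the group boundaries", {
  expect_equal(select_group_for_length(100), "A")
  expect_equal(select_group_for_length(1000), "C")
  expect_equal(select_group_for_length(400), "A")   # boundary -> lower group
  expect_equal(select_group_for_length(401), "B")
  expect_equal(select_group_for_length(800), "B")
  expect_equal(select_group_for_length(801), "C")
  expect_equal(select_group_for_length(1200), "C")
  expect_equal(select_group_for_length(50), "A")    # sub-100 bp windows
  expect_error(select_group_for_length(1201), "window first")
})

test_that("the 2,500 bp worked example and other plans are exact", {
  p <- plan_windows(2500)
  expect_equal(p$start, c(0, 1200, 2400))
  expect_equal(p$end, c(1200, 2400, 2500))
  expect_equal(p$group, c("C", "C", "A"))
  expect_equal(p$weight, c(1200, 1200, 100) / 2500)

  p1 <- plan_windows(1000)
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$group, "C")
  expect_equal(p1$weight, 1)

  p13 <- plan_windows(1300)
  expect_equal(p13$window_length, c(1200, 100))
  expect_equal(p13$group, c("C", "A"))
  expect_equal(p13$weight, c(12, 1) / 13)
})

test_that("window plans tile the sequence and conserve weight", {
  set.seed(301)
  for (L in c(1, 99, 100, 1199, 1200, 1201, 2400, 2401,
              sample(1:20000, 40))) {
    p <- plan_windows(L)
    expect_equal(p$start[1], 0)
    expect_equal(p$end[nrow(p)], L)
    if (nrow(p) > 1) {
      expect_equal(p$start[-1], p$end[-nrow(p)])  # contiguous, no overlap
      expect_true(all(p$window_length[-nrow(p)] == 1200))
    }
    expect_equal(sum(p$window_length), L)
    expect_equal(sum(p$weight), 1, tolerance = 1e-12)
    expect_equal(nrow(p), ceiling(L / 1200))
  }
})

test_that("aggregate_scores is the convex combination of window triples", {
  expect_equal(aggregate_scores(rbind(c(1, 0, 0), c(0, 1, 0)), c(0.5, 0.5)),
               c(0.5, 0.5, 0), ignore_attr = TRUE)
  set.seed(302)
  for (i in 1:20) {
    k <- sample(1:6, 1)
    sc <- random_triples(k)
    w <- diff(c(0, sort(runif(k - 1)), 1))
    agg <- aggregate_scores(sc, w)
    expect_equal(sum(agg), 1, tolerance = 1e-12)
    expect_true(all(agg >= 0))
  }
})

test_that("threshold labelling follows the argmax + uncertainty rule", {
  expect_equal(label_with_threshold(c(0.7, 0.2, 0.1), 0.5), "phage")
  expect_equal(label_with_threshold(c(0.4, 0.35, 0.25), 0.5),
               "uncertain phage")
  expect_equal(label_with_threshold(c(0.1, 0.2, 0.7), 0.5), "plasmid")
  expect_equal(label_with_threshold(c(0.2, 0.5, 0.3), 0.6),
               "uncertain chromosome")
  # argmax ties break in the fixed class order
  expect_equal(label_with_threshold(c(0.4, 0.4, 0.2)), "phage")
  expect_equal(label_with_threshold(c(0.2, 0.4, 0.4)), "chromosome")

  set.seed(303)
  sc <- random_triples(50)
  expect_false(any(startsWith(label_with_threshold(sc, 0), "uncertain")))
  expect_error(label_with_threshold(c(0.5, 0.3, 0.2), 1.5), "\\[0, 1\\]")
})

test_that("windowed prediction equals direct prediction for short sequences", {
  models <- list(A = build_architecture("A", seed = 1),
                 B = build_architecture("B", seed = 2),
                 C = build_architecture("C", seed = 3))
  sim <- simulate_fragment_set(4, "B", seed = 9)
  res <- predict_sequences(models, sim$fragments)
  direct <- predict_batch(models$B, sim$fragments)
  expect_equal(as.matrix(res[, c("phage_score", "chromosome_score",
                                 "plasmid_score")]),
               direct, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("long sequences aggregate their windows by length weighting", {
  models <- list(A = build_architecture("A", seed = 1),
                 C = build_architecture("C", seed = 3))
  gm <- class_genome_model("phage", seed = 15)
  long_seq <- synth_genome(gm, 2500, seed = 16)
  frags <- dna_fragments("long1", long_seq)
  res <- predict_sequences(models, frags)

  p <- plan_windows(2500)
  wf <- dna_fragments(paste0("w", 1:3),
                      substring(long_seq, p$start + 1, p$end))
  manual <- aggregate_scores(
    rbind(predict_batch(models$C, wf[1:2, ]),
          predict_batch(models$A, wf[3, ])),
    p$weight)
  expect_equal(unlist(res[1, c("phage_score", "chromosome_score",
                               "plasmid_score")]),
               manual, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sum(res[1, c("phage_score", "chromosome_score",
                            "plasmid_score")]), 1, tolerance = 1e-6)
})

test_that("fragments under 100 bp are skipped with a warning", {
  models <- list(A = build_architecture("A", seed = 1))
  frags <- dna_fragments(c("ok", "short"),
                         c(random_dna(150), random_dna(60)))
  expect_warning(res <- predict_sequences(models, frags), "short")
  expect_equal(res$id, "ok")
})

test_that("raising the threshold only grows the uncertain set", {
  set.seed(304)
  sc <- random_triples(200)
  prev <- rep(FALSE, 200)
  for (th in seq(0, 1, by = 0.05)) {
    unc <- startsWith(label_with_threshold(sc, th), "uncertain")
    expect_true(all(unc[prev]))  # once uncertain, stays uncertain
    # the certain class never changes, only the prefix
    expect_equal(sub("^uncertain ", "", label_with_threshold(sc, th)),
                 label_with_threshold(sc, 0))
    prev <- unc
  }
})
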