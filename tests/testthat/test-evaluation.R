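test_that("fold assignment is stratified and distinct across repetitions", {
  y <- factor(rep(c("joy", "fear", "sadness", "relaxation"), each = 50))
  clf <- classifier_spec(repetitions = 5, folds = 10, seed = 2)
  folds <- eegsel:::make_folds(y, clf)
  expect_length(folds, 5)
  for (f in folds) {
    expect_setequal(unique(f), 1:10)
    # each fold holds 5 samples of every class (50 / 10), within +/- 1
    counts <- table(f, y)
    expect_true(all(abs(counts - 5) <= 1))
  }
  # repetitions produce different partitions
  expect_gt(length(unique(vapply(folds, paste, character(1),
                                 collapse = ","))), 1L)
  # same spec -> identical partitions
  folds2 <- eegsel:::make_folds(y, clf)
  expect_identical(folds, folds2)
  tiny <- factor(rep(c("joy", "fear"), c(30, 5)))
  expect_error(eegsel:::make_folds(tiny, clf), "stratify")
})

test_that("trial-grouped folds keep sibling segments together", {
  trial <- rep(1:20, each = 5)
  y <- factor(rep(rep(c("joy", "fear", "sadness", "relaxation"), each = 5),
                  each = 5))
  clf <- classifier_spec(repetitions = 2, folds = 5, seed = 4,
                         group_by_trial = TRUE)
  folds <- eegsel:::make_folds(y, clf, trial = trial)
  for (f in folds) {
    expect_true(all(tapply(f, trial, function(v) length(unique(v))) == 1))
  }
})

test_that("validation demands trial-disjoint tables and scores channel prefixes", {
  tb <- make_separable_table(n_per_class = 20, n_channels = 3, seed = 5)
  clf <- classifier_spec(repetitions = 2, seed = 6)
  sel_half <- tb
  curve <- validate_selection(1:3, tb, clf, cutoffs = c(1, 3))
  expect_equal(curve$n_selected, c(1L, 3L))
  expect_gt(curve$mean[1], 0.9)               # single separable channel
  expect_equal(dim(curve$folds), c(20L, 2L))
  expect_error(validate_selection(1:3, tb, clf, selection_table = sel_half),
               "leakage")
  # feature-prefix mode consumes a feature ranking
  fw <- fscore(tb)
  cf <- validate_selection(fw, tb, clf, cutoffs = c(2, 4), unit = "feature")
  expect_gt(cf$mean[2], 0.9)
})

test_that("band proportions are exact fractions that sum to one", {
  tb <- make_table(matrix(rnorm(20 * 8), 20), rep(c("joy", "fear"), 10))
  w <- c(8, 7, 6, 5, 4, 3, 2, 1)  # ranking = feature order
  fw <- eegsel:::new_feature_weights(stats::setNames(w, colnames(tb$x)),
                                     method = "manual", table = tb)
  bp <- band_proportions(fw, cutoffs = c(4, 8))
  expect_equal(unlist(bp[1, c("theta", "alpha", "beta", "gamma")]),
               c(theta = 0.25, alpha = 0.25, beta = 0.25, gamma = 0.25))
  expect_equal(unname(rowSums(bp[, -1])), rep(1, 2))
  # both alpha features on top -> the alpha fraction is 1 at cutoff 2
  w2 <- c(1, 10, 1, 2, 1, 9, 1, 2)            # f2, f6 (alpha) on top
  fw2 <- eegsel:::new_feature_weights(stats::setNames(w2, colnames(tb$x)),
                                      method = "manual", table = tb)
  bp2 <- band_proportions(fw2, cutoffs = 2)   # top 2 = the two alpha features
  expect_equal(bp2$alpha, 1)
  expect_equal(bp2$theta + bp2$beta + bp2$gamma, 0)
  # averaging across subjects keeps rows summing to one
  bpm <- band_proportions(list(fw, fw2), cutoffs = c(2, 4))
  expect_equal(unname(rowSums(bpm[, -1])), rep(1, 2))
  expect_error(band_proportions(fw, cutoffs = 9), "exceeds")
})

test_that("paired comparisons flag degenerate cases and detect real shifts", {
  a <- matrix(runif(16 * 3, 0.4, 0.6), 16)
  res <- paired_comparison(a, a)
  expect_equal(res$p, rep(1, 3))
  expect_equal(res$t, rep(0, 3))
  # constant offset with zero within-pair variance is degenerate
  expect_warning(res2 <- paired_comparison(a + 0.05, a), "zero within-pair")
  expect_true(all(res2$degenerate))
  expect_true(all(is.na(res2$p)))
  expect_error(paired_comparison(a[1, , drop = FALSE], a[1, , drop = FALSE]),
               "2 subjects")
  # power against a known shift matches a Monte-Carlo paired-t oracle
  n_sub <- 16
  delta <- 0.05
  sd_w <- 0.05
  set.seed(8)
  sims <- 200
  rej <- matrix(NA, sims, 2)
  for (s in seq_len(sims)) {
    base <- matrix(runif(n_sub, 0.4, 0.6), n_sub, 1)
    b <- base + matrix(rnorm(n_sub, 0, sd_w), n_sub)
    aa <- base + delta + matrix(rnorm(n_sub, 0, sd_w), n_sub)
    rej[s, 1] <- paired_comparison(aa, b)$p < 0.05
    # oracle: direct t statistic on the paired differences
    d <- aa - b
    tstat <- mean(d) / (sd(d) / sqrt(n_sub))
    rej[s, 2] <- 2 * stats::pt(-abs(tstat), n_sub - 1) < 0.05
  }
  expect_equal(mean(rej[, 1]), mean(rej[, 2]), tolerance = 1e-12)
  expect_gt(mean(rej[, 1]), 0.5)              # shifted pairs are detected
})
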