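test_that("the range-scaled feature difference behaves per its definition", {
  expect_equal(feature_diff(0.3, 0.7, 0, 1), 0.4)
  expect_equal(feature_diff(0.5, 0.5, 0, 1), 0)
  expect_equal(feature_diff(0, 1, 0, 1), 1)          # global extremes
  expect_equal(feature_diff(5, 5, 5, 5), 0)          # constant feature
  expect_equal(feature_diff(c(0.3, 0), c(0.7, 2), c(0, 0), c(1, 4)),
               c(0.4, 0.5))
})

test_that("relieff reproduces the frozen brute-force toy values", {
  # 2-class, 2-feature, 6-sample set with k = 1; expected weights computed
  # with the literal straight-line oracle and frozen
  x <- matrix(c(0.10, 0.20,
                0.90, 0.80,
                0.15, 0.30,
                0.85, 0.70,
                0.05, 0.25,
                0.95, 0.75), ncol = 2, byrow = TRUE)
  y <- c("joy", "fear", "joy", "fear", "joy", "fear")
  tb <- make_table(x, y, bands_per_channel = 2)
  w <- unname(coef(relieff(tb, k = 1)))
  expect_equal(w, c(0.76851851851851849, 0.65277777777777757),
               tolerance = 1e-12)
  expect_equal(w, brute_relieff(x, y, 1), tolerance = 1e-14)
})

test_that("relieff matches the O(n^2) literal oracle on random instances", {
  for (seed in 1:3) {
    tb <- make_random_table(n = 80L, p = 8L, seed = seed)
    for (k in c(1L, 5L, 10L)) {
      w <- unname(coef(relieff(tb, k = k)))
      expect_equal(w, brute_relieff(tb$x, tb$labels, k), tolerance = 1e-12)
    }
  }
})

test_that("relieff weights are bounded, zero for constant features, and order-invariant", {
  tb <- make_random_table(n = 100L, p = 8L, seed = 4)
  tb$x[, 6] <- 3.14                       # constant feature
  fw <- relieff(tb, k = 5)
  expect_true(all(coef(fw) >= -1 & coef(fw) <= 1))
  expect_equal(unname(coef(fw)[6]), 0)
  expect_setequal(fw$ranking, seq_len(8))
  expect_equal(sum(fw$class_priors), 1)
  # permuting the samples leaves the weights unchanged (deterministic ties)
  set.seed(9)
  perm <- sample(nrow(tb$x))
  tb2 <- tb
  tb2$x <- tb$x[perm, ]
  tb2$labels <- tb$labels[perm]
  tb2$trial <- tb$trial[perm]
  expect_equal(unname(coef(relieff(tb2, k = 5))), unname(coef(fw)),
               tolerance = 1e-12)
})

test_that("relieff rejects classes that are too small and missing values", {
  tb <- make_random_table(n = 20L, p = 4L, seed = 2)
  expect_error(relieff(tb, k = 10), "class '\\w+' has 5 samples")
  tb$x[1, 1] <- NA
  expect_error(relieff(tb, k = 2), "missing")
})

test_that("relieff ranks a planted discriminative feature first", {
  hits <- 0L
  for (seed in 1:10) {
    tb <- make_random_table(n = 200L, p = 20L, shift = 1.5,
                            shifted_feature = 7L, seed = seed)
    fw <- relieff(tb, k = 10)
    hits <- hits + (fw$ranking[1] == 7L)
  }
  expect_gte(hits, 9L)
})

test_that("fscore matches the literal formula and flags degenerate scatter", {
  eps <- 0.01
  x1 <- c(0, eps, 1, 1 + eps)
  y <- c("joy", "joy", "fear", "fear")
  tb <- make_table(cbind(x1, rnorm(4)), y, bands_per_channel = 2)
  fw <- fscore(tb)
  expect_equal(unname(coef(fw)[1]), brute_fscore(x1, y), tolerance = 1e-12)
  expect_gt(coef(fw)[1], 1e3)
  # identical-in-all-samples feature scores 0
  tb2 <- make_table(cbind(c(1, 1, 1, 1), x1), y, bands_per_channel = 2)
  expect_equal(unname(coef(fscore(tb2))[1]), 0)
  # zero within-class scatter with positive between -> Inf, ranked first
  tb3 <- make_table(cbind(c(0, 0, 1, 1), rnorm(4)), y,
                    bands_per_channel = 2)
  expect_warning(fw3 <- fscore(tb3), "Inf")
  expect_equal(unname(coef(fw3)[1]), Inf)
  expect_equal(fw3$ranking[1], 1L)
})

test_that("fscore is unchanged by duplicating every sample and shrinks under label permutation", {
  tb <- make_random_table(n = 60L, p = 8L, shift = 2, shifted_feature = 2L,
                          seed = 11)
  f1 <- unname(coef(fscore(tb)))
  dup <- tb
  dup$x <- rbind(tb$x, tb$x)
  dup$labels <- factor(c(as.character(tb$labels), as.character(tb$labels)))
  dup$trial <- c(tb$trial, tb$trial + 60L)
  expect_equal(unname(coef(fscore(dup))), f1, tolerance = 1e-12)
  # permuting labels destroys the planted feature's F-score on average
  set.seed(13)
  perms <- replicate(20, {
    pt <- tb
    pt$labels <- sample(tb$labels)
    unname(coef(fscore(pt))[2])
  })
  expect_lt(mean(perms), f1[2] / 5)
})
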