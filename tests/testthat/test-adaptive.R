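test_that("contributions are the relative accuracy increments with C(1) = 0", {
  expect_equal(contribution(c(0.50, 0.55)), c(0, 0.1))
  expect_equal(contribution(c(0.60, 0.54)), c(0, -0.1))
  expect_equal(contribution(rep(0.4, 5)), rep(0, 5))      # flat curve
  expect_error(contribution(c(0, 0.5)), "S\\(n-1\\)")
})

test_that("the weight update is multiplicative in the slot contribution", {
  w <- c(a = 0.20, b = 0.25)
  upd <- update_weights(w, contributions = c(0, -0.10), ranking = c(1L, 2L))
  expect_equal(unname(upd), c(0.20, 0.225))
  # a +0.5 contribution lets a 0.2 channel overtake a 0.25 channel
  upd2 <- update_weights(c(a = 0.25, b = 0.20),
                         contributions = c(0, 0.5), ranking = c(1L, 2L))
  expect_equal(unname(upd2), c(0.25, 0.30))
  expect_equal(eegsel:::order_desc(upd2), c(2L, 1L))
  # zero contributions everywhere -> fixed point
  expect_equal(update_weights(w, c(0, 0), c(1L, 2L)), w)
  expect_warning(update_weights(c(a = -0.1, b = 0.2), c(0, 0.1), c(2L, 1L)),
                 "negative")
})

test_that("the accuracy curve reaches ceiling on separable data and is reproducible", {
  tb <- make_separable_table(n_per_class = 25, n_channels = 3, seed = 2)
  clf <- classifier_spec(repetitions = 2, seed = 5)
  cv <- accuracy_curve(tb, ranking = 1:3, clf = clf)
  expect_true(all(cv$mean >= 0 & cv$mean <= 1))
  expect_gt(cv$mean[1], 0.95)                 # channel 1 separates alone
  expect_gt(min(cv$mean), 0.9)
  cv2 <- accuracy_curve(tb, ranking = 1:3, clf = clf)
  expect_identical(cv$mean, cv2$mean)         # fixed seed -> identical curve
  expect_error(accuracy_curve(tb, ranking = c(1, 1, 2), clf = clf),
               "permutation")
})

test_that("xmrcs stops immediately when no contribution is negative enough", {
  tb <- make_separable_table(n_per_class = 25, n_channels = 3, seed = 3)
  clf <- classifier_spec(repetitions = 2, seed = 7)
  init <- channel_weights(stats::setNames(c(0.5, 0.3, 0.2),
                                          tb$channel_names))
  # epsilon = 1 dominates every possible negative contribution
  fit <- xmrcs(tb, init, clf, epsilon = 1)
  expect_equal(fit$iterations, 0L)
  expect_true(fit$converged)
  expect_equal(fit$weights, init$weights)     # weights untouched
  expect_length(fit$trace, 1L)
})

test_that("xmrcs honors the iteration cap, preserves the channel set and keeps a reproducible trace", {
  tb <- make_random_table(n = 80L, p = 16L, shift = 2, shifted_feature = 1L,
                          seed = 4)
  clf <- classifier_spec(repetitions = 2, seed = 9)
  init <- channel_weights(stats::setNames(c(0.4, 0.3, 0.2, 0.1),
                                          tb$channel_names))
  fit <- suppressWarnings(
    xmrcs(tb, init, clf, epsilon = 0.5e-6, max_iterations = 2))
  expect_lte(fit$iterations, 2L)
  if (!fit$converged) expect_equal(fit$iterations, 2L)
  expect_setequal(fit$ranking, 1:4)
  fit2 <- suppressWarnings(
    xmrcs(tb, init, clf, epsilon = 0.5e-6, max_iterations = 2))
  expect_identical(lapply(fit$trace, `[[`, "curve"),
                   lapply(fit2$trace, `[[`, "curve"))
  expect_identical(fit$weights, fit2$weights)
  # the trace records one curve per evaluated iteration, each in [0, 1]
  for (st in fit$trace) {
    expect_true(all(st$curve >= 0 & st$curve <= 1))
    expect_equal(st$contributions[1], 0)
  }
})

test_that("xmrcs demotes an over-ranked noise channel on planted data", {
  sp <- planted_generator_spec(informative = c(2, 5), strength = 2,
                               n_channels = 8, n_trials = 16,
                               trial_duration = 40, seed = 31)
  ft <- zscore_features(extract_features(generate_subject(sp)))
  halves <- split_dataset(ft, seed = 32)
  init <- mrcs(relieff(halves$selection, k = 10))
  w <- init$weights
  w[8] <- max(w) * 1.05                       # noise channel forced to rank 1
  fit <- suppressWarnings(
    xmrcs(halves$selection, channel_weights(w),
          classifier_spec(repetitions = 2, seed = 33),
          epsilon = 0.01, max_iterations = 6))
  expect_gt(match(8L, fit$ranking), 1L)       # demoted from the top slot
  # the informative channels end above the noise channel
  expect_lt(max(match(c(2L, 5L), fit$ranking)), match(8L, fit$ranking))
})
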