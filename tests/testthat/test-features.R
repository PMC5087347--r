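test_that("quadrant labeling follows the rating rule with inclusive 5", {
  expect_equal(as.character(label_trial(5, 5)), "joy")
  expect_equal(as.character(label_trial(4.9, 5)), "fear")
  expect_equal(as.character(label_trial(1, 1)), "sadness")
  expect_equal(as.character(label_trial(9, 1)), "relaxation")
  expect_equal(as.character(label_trial(c(5, 4.9), c(5, 4.9))),
               c("joy", "sadness"))
  expect_error(label_trial(0.5, 5), "\\[1, 9\\]")
  expect_error(label_trial(5, 9.5), "\\[1, 9\\]")
})

test_that("segmentation produces the expected number of windows and partitions the trial", {
  spec <- generator_spec(n_channels = 3, n_trials = 4, trial_duration = 60,
                         seed = 1)
  ts <- generate_subject(spec)
  seg <- segment_trials(ts, window = 4, overlap = 0)
  expect_equal(dim(seg$segments), c(4 * 15, 3, 512))
  expect_equal(seg$trial, rep(1:4, each = 15))
  # partition: concatenated segments reproduce the trial exactly
  strip <- do.call(c, lapply(1:15, function(s) seg$segments[s, 2, ]))
  expect_identical(strip, ts$signals[1, 2, ])
  # window equal to trial length -> exactly one segment
  ts2 <- generate_subject(generator_spec(n_channels = 2, n_trials = 4,
                                         trial_duration = 4, seed = 2))
  expect_equal(dim(segment_trials(ts2, window = 4)$segments)[1], 4)
  expect_error(segment_trials(ts2, window = 8), "longer")
})

test_that("a full default-shaped subject yields 600 samples of 128 features", {
  spec <- generator_spec(seed = 3)
  ft <- extract_features(generate_subject(spec))
  expect_equal(nrow(ft$x), 600)   # 40 trials x 15 segments
  expect_equal(ncol(ft$x), 128)   # 32 channels x 4 bands
  expect_equal(colnames(ft$x)[1:4],
               c("Fp1_theta", "Fp1_alpha", "Fp1_beta", "Fp1_gamma"))
  expect_true(all(ft$x >= 0))
  # all samples of a trial share its label
  expect_true(all(tapply(as.character(ft$labels), ft$trial,
                         function(l) length(unique(l))) == 1))
})

test_that("band power matches the direct-DFT oracle for tones and is band-selective", {
  t <- (0:511) / 128
  tone <- sin(2 * pi * 10 * t)
  oracle <- dft_power(tone)             # literal (1/N) sum |X(k)|^2 = 256
  expect_equal(oracle, 256, tolerance = 1e-12)
  bp <- band_power(tone, "alpha", 128)
  expect_lt(abs(bp - oracle) / oracle, 0.01)
  expect_lt(band_power(tone, "gamma", 128), 0.01)  # stopband floor
  expect_equal(band_power(rep(0, 512), "alpha", 128), 0)
  expect_error(band_power(tone, "alpha", 128, n_fft = 256), "FFT length")
  expect_error(band_power(tone, c(30, 70), 128), "Nyquist")
})

test_that("band powers of a 4-45 Hz band-limited signal approximately partition its power", {
  # the four zero-phase band filters have |H|^4 = 1/4 at each crossover, so
  # the band sum under-counts by roughly 10%; tolerance documented
  for (s in 1:3) {
    set.seed(s)
    x <- zerophase_filter(rnorm(2048), bandpass_coefficients(4, 45, 128))
    seg <- x[1025:1536]
    parts <- vapply(c("theta", "alpha", "beta", "gamma"),
                    function(b) band_power(seg, b, 128), numeric(1))
    ratio <- sum(parts) / sum(seg^2)
    expect_gt(ratio, 0.85)
    expect_lt(ratio, 1.02)
  }
})

test_that("extract_features agrees with band_power on every segment when filtering per segment", {
  spec <- generator_spec(n_channels = 2, n_trials = 4, trial_duration = 8,
                         seed = 6)
  ts <- generate_subject(spec)
  ft <- extract_features(ts, filter_scope = "segment")
  seg <- segment_trials(ts, window = 4)
  for (i in c(1, 5, 8)) {
    for (ch in 1:2) {
      for (b in c("theta", "gamma")) {
        col <- which(ft$feature_map$channel == ch & ft$feature_map$band == b)
        expect_equal(unname(ft$x[i, col]),
                     band_power(seg$segments[i, ch, ], b, 128),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("z-scoring uses the population convention and handles degenerate columns", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 1, 0))
  tb <- make_table(cbind(x, x[, 1]), c("joy", "fear", "joy"),
                   bands_per_channel = 2, normalized = FALSE)
  expect_warning(z <- zscore_features(tb), "constant")
  sd_pop <- sqrt(2 / 3)   # population sd of (1, 2, 3)
  expect_equal(unname(z$x[, 1]), c(-1, 0, 1) / sd_pop, tolerance = 1e-12)
  expect_equal(unname(z$x[, 2]), c(0, 0, 0))
  expect_equal(unname(colMeans(z$x)), rep(0, 4))
  # idempotence up to floating error
  z2 <- suppressWarnings(zscore_features(z))
  expect_equal(z2$x[, c(1, 3, 4)], z$x[, c(1, 3, 4)], tolerance = 1e-12)
  # held-out transform reuses the fitted statistics
  tb2 <- tb
  tb2$x <- tb2$x + 1
  h <- apply_zscore(tb2, z$norm_stats)
  expect_equal(h$x[, 1], (tb2$x[, 1] - 2) / sd_pop, ignore_attr = TRUE)
  expect_error(zscore_features(make_table(x[1, , drop = FALSE], "joy",
                                          bands_per_channel = 3,
                                          normalized = FALSE)),
               "2 samples")
})

test_that("the trial-level split is stratified, leak-free and deterministic", {
  # 10 trials per class, 3 segments each
  y_trial <- rep(c("joy", "fear", "sadness", "relaxation"), each = 10)
  trial <- rep(seq_len(40), each = 3)
  set.seed(1)
  x <- matrix(rnorm(120 * 4), 120)
  tb <- make_table(x, y_trial[trial], trial = trial)
  sp <- split_dataset(tb, seed = 7)
  expect_equal(length(intersect(unique(sp$selection$trial),
                                unique(sp$validation$trial))), 0)
  expect_equal(as.vector(table(sp$selection$labels)), rep(15L, 4))
  expect_equal(as.vector(table(sp$validation$labels)), rep(15L, 4))
  sp2 <- split_dataset(tb, seed = 7)
  expect_identical(sp$selection$trial, sp2$selection$trial)
  sp3 <- split_dataset(tb, seed = 8)
  expect_false(identical(sp$selection$trial, sp3$selection$trial))
  # a class with fewer than 2 trials cannot be split
  tb_small <- make_table(x[1:9, ], rep(c("joy", "fear", "sadness"), 3),
                         trial = rep(1:3, 3))
  expect_error(split_dataset(tb_small), "joy")
})
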