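# Fixture builders: feature tables constructed in code (no stored data).

# Build a feature_table directly from a matrix, bypassing signal
# extraction; features are laid out channel-major over `bands_per_channel`
# bands.
make_table <- function(x, labels, bands_per_channel = 4L, trial = NULL,
                       normalized = TRUE) {
  stopifnot(ncol(x) %% bands_per_channel == 0L)
  n_ch <- ncol(x) %/% bands_per_channel
  band_names <- band_definitions()$name[seq_len(bands_per_channel)]
  ch_names <- sprintf("Ch%02d", seq_len(n_ch))
  fm <- data.frame(channel = rep(seq_len(n_ch), each = bands_per_channel),
                   channel_name = rep(ch_names, each = bands_per_channel),
                   band = rep(band_names, n_ch))
  colnames(x) <- paste(fm$channel_name, fm$band, sep = "_")
  structure(list(
    x = x,
    labels = factor(labels, levels = levels(factor(labels))),
    trial = if (is.null(trial)) seq_len(nrow(x)) else trial,
    feature_map = fm, channel_names = ch_names,
    bands = band_definitions()[seq_len(bands_per_channel), ],
    sampling_rate = 128, window = 4,
    normalized = normalized, norm_stats = NULL
  ), class = "feature_table")
}

# Near-separable 4-class table: the four features of channel 1 encode the
# class mean pattern; remaining channels are standard-normal noise.
make_separable_table <- function(n_per_class = 30L, n_channels = 4L,
                                 noise = 0.05, seed = 1L) {
  set.seed(seed)
  y <- rep(c("joy", "fear", "sadness", "relaxation"), each = n_per_class)
  n <- length(y)
  x <- matrix(rnorm(n * n_channels * 4L), n)
  mu <- 2 * diag(4)
  x[, 1:4] <- mu[match(y, c("joy", "fear", "sadness", "relaxation")), ] +
    noise * matrix(rnorm(n * 4L), n)
  make_table(x, y)
}

# Random 4-class table with one shifted (discriminative) feature.
make_random_table <- function(n = 120L, p = 16L, shift = 1.5,
                              shifted_feature = 3L, seed = 1L) {
  set.seed(seed)
  y <- rep(c("joy", "fear", "sadness", "relaxation"), length.out = n)
  x <- matrix(rnorm(n * p), n)
  if (shift != 0) {
    x[, shifted_feature] <- x[, shifted_feature] + shift * (y == "joy")
  }
  make_table(x, y)
}

# Small planted-effect generator spec shared by recovery tests.
recovery_spec <- function(seed, n_channels = 16L, informative = c(4L, 11L),
                          n_trials = 16L, trial_duration = 60) {
  planted_generator_spec(informative = informative, strength = 2,
                         n_channels = n_channels, n_trials = n_trials,
                         trial_duration = trial_duration, seed = seed)
}
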