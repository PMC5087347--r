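# Band-power feature extraction: quadrant labeling, trial segmentation,
# band filtering, FFT band power, z-score normalization, trial-level split.

#' Canonical EEG frequency bands
#'
#' Default band definitions: theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz,
#' gamma 30-45 Hz.
#'
#' @return Data frame with columns `name`, `low`, `high` (Hz).
#' @export
band_definitions <- function() {
  data.frame(name = c("theta", "alpha", "beta", "gamma"),
             low  = c(4, 8, 13, 30),
             high = c(8, 13, 30, 45))
}

#' Quadrant emotion label from valence/arousal ratings
#'
#' Maps 1-9 ratings to one of four classes: joy (valence >= 5,
#' arousal >= 5), fear (valence < 5, arousal >= 5), sadness (both < 5),
#' relaxation (valence >= 5, arousal < 5). The boundary 5 is inclusive on
#' the >= side.
#'
#' @param valence,arousal Numeric ratings in `[1, 9]` (vectorised).
#' @return Factor with levels joy, fear, sadness, relaxation.
#' @examples
#' label_trial(c(5, 4.9, 1), c(5, 5, 1))
#' @export
label_trial <- function(valence, arousal) {
  if (length(valence) != length(arousal)) {
    stop("`valence` and `arousal` must have the same length", call. = FALSE)
  }
  if (any(valence < 1 | valence > 9 | arousal < 1 | arousal > 9)) {
    stop("ratings must lie in [1, 9]", call. = FALSE)
  }
  lab <- ifelse(arousal >= 5,
                ifelse(valence >= 5, "joy", "fear"),
                ifelse(valence >= 5, "relaxation", "sadness"))
  factor(lab, levels = EMOTION_CLASSES)
}

#' Segment trials into fixed windows
#'
#' Cuts every trial into windows of `window` seconds with overlap fraction
#' `overlap` (0 = non-overlapping, the default setting: 60-s trials into
#' fifteen 4-s segments). Any trailing remainder shorter than a window is
#' dropped. Segments are returned in temporal order within each trial.
#'
#' @param trials A `trialset`.
#' @param window Window length in seconds (default 4).
#' @param overlap Overlap fraction in `[0, 1)` (default 0).
#' @return List with `segments` (array: segment x channel x time) and
#'   `trial` (source-trial index per segment).
#' @export
segment_trials <- function(trials, window = 4, overlap = 0) {
  stopifnot(inherits(trials, "trialset"))
  fs <- trials$sampling_rate
  wlen <- window * fs
  if (abs(wlen - round(wlen)) > 1e-9) {
    stop("`window` times the sampling rate must be an integer sample count",
         call. = FALSE)
  }
  wlen <- as.integer(round(wlen))
  ntime <- dim(trials$signals)[3L]
  if (wlen > ntime) stop("window longer than the trial", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)",
                                        call. = FALSE)
  step <- as.integer(round(wlen * (1 - overlap)))
  if (step < 1L) stop("overlap too large", call. = FALSE)
  starts <- seq.int(1L, ntime - wlen + 1L, by = step)
  n_tr <- dim(trials$signals)[1L]
  n_ch <- dim(trials$signals)[2L]
  segs <- array(NA_real_, dim = c(n_tr * length(starts), n_ch, wlen))
  trial_of <- integer(n_tr * length(starts))
  k <- 0L
  for (tr in seq_len(n_tr)) {
    for (s in starts) {
      k <- k + 1L
      segs[k, , ] <- trials$signals[tr, , s:(s + wlen - 1L)]
      trial_of[k] <- tr
    }
  }
  list(segments = segs, trial = trial_of)
}

#' Band power of a single-channel segment
#'
#' The segment is band-pass filtered (zero-phase Butterworth) to the band,
#' then the power is computed as the mean squared magnitude over all N bins
#' of the N-point FFT of the filtered segment:
#' `bp = (1/N) * sum_k |X(k)|^2`, with N the segment length (512 for 4-s
#' windows at 128 Hz).
#'
#' @param x Numeric vector, one channel of one segment.
#' @param band Band name (looked up in `bands`) or numeric `c(low, high)`
#'   in Hz.
#' @param sampling_rate Sampling rate in Hz.
#' @param n_fft FFT length; must equal the segment length (checked when
#'   supplied, defaults to `length(x)`).
#' @param bands Band definition table (see [band_definitions()]).
#' @return Nonnegative scalar power (signal units squared).
#' @examples
#' x <- sin(2 * pi * 10 * (0:511) / 128)
#' band_power(x, "alpha", 128)
#' @export
band_power <- function(x, band, sampling_rate, n_fft = length(x),
                       bands = band_definitions()) {
  if (n_fft != length(x)) {
    stop(sprintf("segment length %d does not match the configured FFT length %d",
                 length(x), n_fft), call. = FALSE)
  }
  edges <- resolve_band(band, bands)
  if (edges[2L] > sampling_rate / 2) {
    stop("band exceeds the Nyquist frequency", call. = FALSE)
  }
  coefs <- bandpass_coefficients(edges[1L], edges[2L], sampling_rate)
  xf <- zerophase_filter(x, coefs)
  sum(Mod(fft(xf))^2) / length(xf)
}

resolve_band <- function(band, bands) {
  if (is.character(band)) {
    i <- match(band, bands$name)
    if (is.na(i)) stop("unknown band: ", band, call. = FALSE)
    c(bands$low[i], bands$high[i])
  } else if (is.numeric(band) && length(band) == 2L) {
    band
  } else stop("`band` must be a band name or c(low, high)", call. = FALSE)
}

#' Extract the band-power feature table from a trial set
#'
#' Labels every trial by the quadrant rule, segments trials, and computes
#' the band power of every (channel, band) pair per segment, yielding
#' `n_channels * n_bands` features per sample (128 for the 32-channel,
#' 4-band default). Features are ordered channel-major (all bands of
#' channel 1, then channel 2, ...) and named `channel_band`
#' (e.g. `Fp1_gamma`).
#'
#' By default each whole trial is filtered once per (channel, band) and then
#' segmented (`filter_scope = "trial"`), which avoids a filter transient in
#' every segment; `filter_scope = "segment"` filters each segment
#' independently, exactly as [band_power()] does.
#'
#' @param trials A `trialset`.
#' @param bands Band definition table.
#' @param window,overlap Segmentation parameters, see [segment_trials()].
#' @param filter_scope `"trial"` (default) or `"segment"`.
#' @return An object of class `feature_table`: `x` (samples x features),
#'   `labels`, `trial` (source trial per sample), `feature_map`
#'   (data frame: channel index, channel name, band), `channel_names`,
#'   plus normalization state.
#' @export
extract_features <- function(trials, bands = band_definitions(), window = 4,
                             overlap = 0,
                             filter_scope = c("trial", "segment")) {
  stopifnot(inherits(trials, "trialset"))
  filter_scope <- match.arg(filter_scope)
  fs <- trials$sampling_rate
  labels_trial <- label_trial(trials$valence, trials$arousal)
  n_tr <- dim(trials$signals)[1L]
  n_ch <- dim(trials$signals)[2L]
  n_b <- nrow(bands)
  ch_names <- trials$channel_names
  feature_map <- data.frame(
    channel = rep(seq_len(n_ch), each = n_b),
    channel_name = rep(ch_names, each = n_b),
    band = rep(bands$name, times = n_ch)
  )
  fnames <- paste(feature_map$channel_name, feature_map$band, sep = "_")

  wlen <- window * fs
  if (abs(wlen - round(wlen)) > 1e-9) {
    stop("`window` times the sampling rate must be an integer sample count",
         call. = FALSE)
  }
  wlen <- as.integer(round(wlen))
  ntime <- dim(trials$signals)[3L]
  if (wlen > ntime) stop("window longer than the trial", call. = FALSE)
  starts <- seq.int(1L, ntime - wlen + 1L,
                    by = as.integer(round(wlen * (1 - overlap))))
  n_per_trial <- length(starts)
  n_samp <- n_tr * n_per_trial
  trial_of <- rep(seq_len(n_tr), each = n_per_trial)
  x <- matrix(NA_real_, n_samp, n_ch * n_b,
              dimnames = list(NULL, fnames))
  coefs <- lapply(seq_len(n_b), function(b) {
    bandpass_coefficients(bands$low[b], bands$high[b], fs)
  })
  seg_rows <- lapply(starts, function(s) s:(s + wlen - 1L))

  for (tr in seq_len(n_tr)) {
    xt <- t(matrix(trials$signals[tr, , ], n_ch))  # time x channels
    row0 <- (tr - 1L) * n_per_trial
    for (b in seq_len(n_b)) {
      cols <- (seq_len(n_ch) - 1L) * n_b + b
      if (filter_scope == "trial") {
        # Filter the whole trial once per band, then cut into windows.
        xf <- zerophase_filter(xt, coefs[[b]])
        for (s in seq_len(n_per_trial)) {
          # Eq. 1 power via Parseval: (1/N) sum_k |X(k)|^2 over all N FFT
          # bins equals the sum of squared filtered samples.
          x[row0 + s, cols] <- colSums(xf[seg_rows[[s]], , drop = FALSE]^2)
        }
      } else {
        for (s in seq_len(n_per_trial)) {
          xf <- zerophase_filter(xt[seg_rows[[s]], , drop = FALSE], coefs[[b]])
          x[row0 + s, cols] <- colSums(xf^2)
        }
      }
    }
  }

  structure(list(
    x = x,
    labels = labels_trial[trial_of],
    trial = trial_of,
    feature_map = feature_map,
    channel_names = ch_names,
    bands = bands,
    sampling_rate = fs,
    window = window,
    normalized = FALSE,
    norm_stats = NULL
  ), class = "feature_table")
}

#' Z-score normalization of a feature table
#'
#' Standardises every feature column to mean 0, standard deviation 1
#' (`(f - mu_f) / sigma_f`), using the population (divide-by-n) standard
#' deviation over all samples of the table. The fitted `(mu_f, sigma_f)`
#' are stored so held-out samples can be transformed with
#' [apply_zscore()]. Constant features (sigma = 0) are set to all zeros
#' with a warning.
#'
#' Fitting on the combined dataset before splitting mirrors the reference
#' procedure (normalisation "over all samples"); fit [zscore_features()] on
#' the selection half and [apply_zscore()] on the validation half for a
#' leakage-free alternative.
#'
#' @param table A `feature_table` with at least 2 samples.
#' @return The normalized `feature_table`, with `norm_stats` set.
#' @export
zscore_features <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$x) < 2L) stop("need at least 2 samples to normalize",
                               call. = FALSE)
  mu <- colMeans(table$x)
  sigma <- sqrt(colMeans(sweep(table$x, 2L, mu)^2))  # population convention
  apply_zscore(table, list(mu = mu, sigma = sigma), warn_constant = TRUE)
}

#' @rdname zscore_features
#' @param stats Normalization statistics (`mu`, `sigma`) fitted by
#'   [zscore_features()].
#' @param warn_constant Warn when a constant feature is zeroed out.
#' @export
apply_zscore <- function(table, stats, warn_constant = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  mu <- stats$mu
  sigma <- stats$sigma
  const <- sigma == 0
  if (any(const) && warn_constant) {
    warning(sum(const), " constant feature(s) set to zero (sigma = 0): ",
            paste(head(colnames(table$x)[const], 5L), collapse = ", "),
            call. = FALSE)
  }
  z <- sweep(sweep(table$x, 2L, mu), 2L, ifelse(const, 1, sigma), "/")
  z[, const] <- 0
  table$x <- z
  table$normalized <- TRUE
  table$norm_stats <- list(mu = mu, sigma = sigma)
  table
}

subset_feature_table <- function(table, idx) {
  table$x <- table$x[idx, , drop = FALSE]
  table$labels <- table$labels[idx]
  table$trial <- table$trial[idx]
  table
}

#' Trial-level stratified split into selection and validation halves
#'
#' Splits a feature table into a channel-selection half and a
#' performance-validation half at the trial level: all segments of a trial
#' land on the same side (leakage guard), stratified by class, about 50/50.
#' Deterministic given the seed.
#'
#' @param table A `feature_table`.
#' @param seed Integer seed.
#' @param fraction Fraction of trials per class assigned to the selection
#'   half (default 0.5; odd counts round up on the selection side).
#' @return List with `selection` and `validation` feature tables.
#' @export
split_dataset <- function(table, seed = 1L, fraction = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  trial_label <- tapply(as.character(table$labels), table$trial,
                        function(l) l[1L])
  trials <- as.integer(names(trial_label))
  sel_trials <- integer(0)
  with_seed(seed, {
    for (cl in EMOTION_CLASSES) {
      cl_trials <- trials[trial_label == cl]
      if (length(cl_trials) < 2L) {
        stop(sprintf("class '%s' has %d trial(s); need at least 2 to split",
                     cl, length(cl_trials)), call. = FALSE)
      }
      k <- ceiling(length(cl_trials) * fraction)
      sel_trials <- c(sel_trials, sample(cl_trials, k))
    }
  })
  in_sel <- table$trial %in% sel_trials
  list(selection = subset_feature_table(table, which(in_sel)),
       validation = subset_feature_table(table, which(!in_sel)))
}
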