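# Synthetic trial generator emulating the layout of preprocessed
# affective-EEG recordings: trials x channels x time, 1-9 valence/arousal
# ratings, four quadrant classes, with class-discriminative band-power
# effects planted in known channels.

#' Specification for the synthetic trial generator
#'
#' Describes one synthetic "subject": recording geometry, class balance,
#' background noise, and an effect map planting narrowband (band-limited
#' Gaussian noise) components of class-dependent amplitude into chosen
#' channels.
#'
#' @param n_channels Number of channels (default 32, the standard montage).
#' @param sampling_rate Sampling rate in Hz (default 128).
#' @param trial_duration Trial length in seconds (default 60).
#' @param n_trials Number of trials (default 40), split across the four
#'   quadrant classes per `class_counts`.
#' @param class_counts Named integer vector of trials per class
#'   (joy, fear, sadness, relaxation); defaults to an even split and must
#'   sum to `n_trials`.
#' @param effect_map Data frame with columns `class`, `channel`, `band`,
#'   `multiplier` (amplitude multiplier >= 0). For each trial of `class`, a
#'   band-limited Gaussian component with standard deviation
#'   `base_amplitude * multiplier` is added to `channel`. An empty data
#'   frame (default) yields exchangeable pure-noise channels.
#' @param noise_sd Standard deviation of the broadband background noise.
#' @param base_amplitude Amplitude unit that `multiplier` scales.
#' @param pink If `TRUE`, background noise has a 1/f amplitude spectrum
#'   instead of white; white keeps analytic band-power expectations simple.
#' @param bands Band definitions used to realise effect components.
#' @param seed Integer seed making [generate_subject()] deterministic.
#' @return An object of class `generator_spec`.
#' @seealso [generate_subject()], [planted_generator_spec()]
#' @export
generator_spec <- function(n_channels = 32L, sampling_rate = 128,
                           trial_duration = 60, n_trials = 40L,
                           class_counts = NULL,
                           effect_map = empty_effect_map(),
                           noise_sd = 1, base_amplitude = 1,
                           pink = FALSE, bands = band_definitions(),
                           seed = NULL) {
  stopifnot_scalar_number(n_channels, "n_channels", 1)
  stopifnot_scalar_number(sampling_rate, "sampling_rate", 1)
  stopifnot_scalar_number(trial_duration, "trial_duration", 1e-9)
  stopifnot_scalar_number(n_trials, "n_trials", 1)
  stopifnot_scalar_number(noise_sd, "noise_sd", 0)
  if (is.null(class_counts)) {
    if (n_trials %% 4L != 0L) {
      stop("`n_trials` must be divisible by 4 unless `class_counts` is given",
           call. = FALSE)
    }
    class_counts <- stats::setNames(rep(n_trials / 4L, 4L), EMOTION_CLASSES)
  }
  if (!setequal(names(class_counts), EMOTION_CLASSES) ||
      sum(class_counts) != n_trials) {
    stop("`class_counts` must name the four classes and sum to `n_trials`",
         call. = FALSE)
  }
  class_counts <- class_counts[EMOTION_CLASSES]
  effect_map <- validate_effect_map(effect_map, n_channels, bands)
  structure(list(
    n_channels = as.integer(n_channels), sampling_rate = sampling_rate,
    trial_duration = trial_duration, n_trials = as.integer(n_trials),
    class_counts = class_counts, effect_map = effect_map,
    noise_sd = noise_sd, base_amplitude = base_amplitude, pink = pink,
    bands = bands, seed = seed,
    informative_channels = sort(unique(effect_map$channel))
  ), class = "generator_spec")
}

#' @rdname generator_spec
#' @export
empty_effect_map <- function() {
  data.frame(class = character(), channel = integer(),
             band = character(), multiplier = numeric())
}

validate_effect_map <- function(effect_map, n_channels, bands) {
  req <- c("class", "channel", "band", "multiplier")
  if (!is.data.frame(effect_map) || !all(req %in% names(effect_map))) {
    stop("`effect_map` needs columns class, channel, band, multiplier",
         call. = FALSE)
  }
  if (nrow(effect_map) == 0L) return(effect_map[req])
  if (!all(effect_map$class %in% EMOTION_CLASSES)) {
    stop("effect_map classes must be one of: ",
         paste(EMOTION_CLASSES, collapse = ", "), call. = FALSE)
  }
  if (any(effect_map$channel < 1L | effect_map$channel > n_channels)) {
    stop("effect_map references a channel outside 1..n_channels", call. = FALSE)
  }
  if (!all(effect_map$band %in% bands$name)) {
    stop("effect_map band not among the defined bands", call. = FALSE)
  }
  if (any(!is.finite(effect_map$multiplier) | effect_map$multiplier < 0)) {
    stop("effect multipliers must be finite and >= 0", call. = FALSE)
  }
  effect_map[req]
}

#' Generator spec with planted discriminative channels
#'
#' Convenience constructor for the planted-effect study design used in
#' tests: two (or more) informative channels carry band-limited components
#' whose amplitudes follow a 2x2 class design over two bands, so that all
#' four quadrant classes are separable from the informative channels and
#' every other channel is exchangeable noise.
#'
#' The amplitude design, per informative channel pair (gamma on the first
#' channel, beta on the second): joy = (strong, base), fear = (base, strong),
#' sadness = (strong, strong), relaxation = (base, base).
#'
#' @param informative Integer vector of informative channel indices
#'   (default channels 4 and 18).
#' @param strength Amplitude multiplier of the "strong" condition
#'   (default 2); the "base" condition has multiplier 1.
#' @param ... Passed on to [generator_spec()].
#' @return A `generator_spec`.
#' @export
planted_generator_spec <- function(informative = c(4L, 18L), strength = 2,
                                   ...) {
  if (length(informative) < 1L) stop("need at least one informative channel")
  chA <- informative[1L]
  chB <- if (length(informative) >= 2L) informative[2L] else informative[1L]
  strong <- strength
  base <- 1
  em <- rbind(
    data.frame(class = EMOTION_CLASSES, channel = chA, band = "gamma",
               multiplier = c(strong, base, strong, base)),
    data.frame(class = EMOTION_CLASSES, channel = chB, band = "beta",
               multiplier = c(base, strong, strong, base))
  )
  generator_spec(effect_map = em, ...)
}

rating_quadrant <- function(class, n) {
  # Ratings uniform within the quadrant implied by the class; the label rule
  # only uses the quadrant, not the value.
  switch(class,
    joy        = cbind(runif(n, 5, 9), runif(n, 5, 9)),
    fear       = cbind(runif(n, 1, 5), runif(n, 5, 9)),
    sadness    = cbind(runif(n, 1, 5), runif(n, 1, 5)),
    relaxation = cbind(runif(n, 5, 9), runif(n, 1, 5))
  )
}

pink_noise <- function(n) {
  # White noise shaped to a 1/f amplitude spectrum (DC bin left at scale 1).
  X <- fft(rnorm(n))
  k <- seq_len(n) - 1L               # FFT bin index
  fbin <- pmin(k, n - k)             # distance to DC, symmetric spectrum
  scale <- 1 / sqrt(pmax(fbin, 1))
  y <- Re(fft(X * scale, inverse = TRUE)) / n
  y / sd(y)
}

#' Generate one synthetic subject
#'
#' Draws trial-structured multi-channel signals per the generator spec:
#' broadband background noise plus, for each effect-map entry matching the
#' trial's class, a band-limited Gaussian noise component of standard
#' deviation `base_amplitude * multiplier`. Trial classes are assigned with
#' the spec's per-class counts in a seeded random order, and valence/arousal
#' ratings are drawn uniformly inside the class's quadrant. Deterministic
#' given the seed.
#'
#' @param spec A [generator_spec()].
#' @param seed Optional integer seed overriding `spec$seed`.
#' @return An object of class `trialset`: list with `signals` (array
#'   trials x channels x time), `valence`, `arousal` (ratings in 1-9),
#'   `sampling_rate`, `channel_names`, and the true `class` per trial.
#' @examples
#' ts <- generate_subject(generator_spec(n_channels = 4, n_trials = 8,
#'                                       trial_duration = 4, seed = 1))
#' dim(ts$signals)
#' @export
generate_subject <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "generator_spec"))
  nt <- round(spec$trial_duration * spec$sampling_rate)
  with_seed(seed, {
    classes <- sample(rep(EMOTION_CLASSES, times = spec$class_counts))
    valence <- numeric(spec$n_trials)
    arousal <- numeric(spec$n_trials)
    for (cl in EMOTION_CLASSES) {
      idx <- which(classes == cl)
      if (length(idx)) {
        va <- rating_quadrant(cl, length(idx))
        valence[idx] <- va[, 1L]
        arousal[idx] <- va[, 2L]
      }
    }
    signals <- array(
      if (spec$pink) {
        spec$noise_sd * replicate(spec$n_trials * spec$n_channels,
                                  pink_noise(nt))
      } else {
        rnorm(spec$n_trials * spec$n_channels * nt, sd = spec$noise_sd)
      },
      dim = c(nt, spec$n_channels, spec$n_trials)
    )
    if (nrow(spec$effect_map)) {
      coefs <- lapply(seq_len(nrow(spec$bands)), function(i) {
        bandpass_coefficients(spec$bands$low[i], spec$bands$high[i],
                              spec$sampling_rate)
      })
      names(coefs) <- spec$bands$name
      for (tr in seq_len(spec$n_trials)) {
        em <- spec$effect_map[spec$effect_map$class == classes[tr], ,
                              drop = FALSE]
        for (r in seq_len(nrow(em))) {
          amp <- spec$base_amplitude * em$multiplier[r]
          if (amp <= 0) next
          comp <- zerophase_filter(rnorm(nt), coefs[[em$band[r]]])
          comp <- comp / sd(comp) * amp
          signals[, em$channel[r], tr] <- signals[, em$channel[r], tr] + comp
        }
      }
    }
    # store as trials x channels x time
    signals <- aperm(signals, c(3L, 2L, 1L))
    structure(list(
      signals = signals, valence = valence, arousal = arousal,
      class = factor(classes, levels = EMOTION_CLASSES),
      sampling_rate = spec$sampling_rate,
      channel_names = montage_labels(spec$n_channels),
      spec = spec
    ), class = "trialset")
  })
}

#' Number of trials per quadrant class in a trial set
#'
#' @param trials A `trialset`.
#' @return Named integer vector of trial counts for joy, fear, sadness,
#'   relaxation, derived from the ratings by the quadrant rule.
#' @export
class_trial_counts <- function(trials) {
  table(label_trial(trials$valence, trials$arousal))
}

#' Does a subject have enough trials in every class?
#'
#' Subjects are retained only when every quadrant class holds at least
#' `min_trials` trials, so both halves of the trial-level split keep
#' enough data per class.
#'
#' @param trials A `trialset`.
#' @param min_trials Minimum trials per class (default 5).
#' @return Logical scalar.
#' @export
subject_eligible <- function(trials, min_trials = 5L) {
  all(class_trial_counts(trials) >= min_trials)
}
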