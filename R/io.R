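# Plain-text container and tabular artifact readers/writers.
#
# Trial-set container (format "eegsel-trialset", version 1): a single
# tab-separated text file. Header lines start with '#' and carry the
# format tag, sampling rate, dimensions, channel names and per-trial
# ratings; the body holds one line per (trial, channel) with the time
# samples, written with 17 significant digits for exact double round-trip.

#' Write / read a trial set container
#'
#' @param trials A `trialset`.
#' @param path File path.
#' @return `read_trialset()` returns a `trialset`; `write_trialset()`
#'   returns `path` invisibly.
#' @export
write_trialset <- function(trials, path) {
  stopifnot(inherits(trials, "trialset"))
  d <- dim(trials$signals)
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) paste(sprintf("%.17g", x), collapse = "\t")
  writeLines(c(
    "#eegsel-trialset\tv1",
    sprintf("#sampling_rate\t%.17g", trials$sampling_rate),
    sprintf("#dims\t%d\t%d\t%d", d[1L], d[2L], d[3L]),
    paste0("#channels\t", paste(trials$channel_names, collapse = "\t")),
    paste0("#valence\t", num(trials$valence)),
    paste0("#arousal\t", num(trials$arousal))
  ), con)
  for (tr in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      writeLines(num(trials$signals[tr, ch, ]), con)
    }
  }
  invisible(path)
}

#' @rdname write_trialset
#' @export
read_trialset <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "#eegsel-trialset")) {
    stop("not an eegsel trial-set container: ", path, call. = FALSE)
  }
  hdr <- strsplit(lines[1:6], "\t", fixed = TRUE)
  key <- vapply(hdr, `[[`, character(1), 1L)
  get_line <- function(k) hdr[[match(k, key)]][-1L]
  fs <- as.numeric(get_line("#sampling_rate"))
  d <- as.integer(get_line("#dims"))
  channels <- get_line("#channels")
  valence <- as.numeric(get_line("#valence"))
  arousal <- as.numeric(get_line("#arousal"))
  body <- lines[-(1:6)]
  if (length(body) != d[1L] * d[2L]) {
    stop("corrupt container: expected ", d[1L] * d[2L], " signal rows",
         call. = FALSE)
  }
  signals <- array(NA_real_, dim = d)
  i <- 0L
  for (tr in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      i <- i + 1L
      signals[tr, ch, ] <- as.numeric(strsplit(body[i], "\t",
                                               fixed = TRUE)[[1L]])
    }
  }
  structure(list(signals = signals, valence = valence, arousal = arousal,
                 class = label_trial(valence, arousal),
                 sampling_rate = fs, channel_names = channels),
            class = "trialset")
}

#' Wrap a preprocessed-DEAP-style array as a trial set
#'
#' Adapter for arrays following the preprocessed affective-EEG layout:
#' `data` shaped trials x channels x time at 128 Hz where the first 32
#' channels are EEG and each trial carries a leading 3-s pre-trial
#' baseline, and `ratings` with valence and arousal in the first two
#' columns. The baseline is trimmed (trials become exactly 60 s) and only
#' the EEG channels are kept. Load the `.mat`/`.dat` source with any
#' external tool and pass the arrays here.
#'
#' @param data Numeric array, trials x channels x time.
#' @param ratings Matrix with columns valence, arousal (1-9).
#' @param sampling_rate Sampling rate in Hz (default 128).
#' @param n_eeg_channels EEG channels to keep (default 32).
#' @param baseline_seconds Leading baseline to trim (default 3).
#' @return A `trialset`.
#' @export
as_trialset <- function(data, ratings, sampling_rate = 128,
                        n_eeg_channels = 32L, baseline_seconds = 3) {
  stopifnot(length(dim(data)) == 3L)
  skip <- round(baseline_seconds * sampling_rate)
  keep_t <- (skip + 1L):dim(data)[3L]
  keep_c <- seq_len(min(n_eeg_channels, dim(data)[2L]))
  signals <- data[, keep_c, keep_t, drop = FALSE]
  valence <- ratings[, 1L]
  arousal <- ratings[, 2L]
  structure(list(signals = signals, valence = valence, arousal = arousal,
                 class = label_trial(valence, arousal),
                 sampling_rate = sampling_rate,
                 channel_names = montage_labels(length(keep_c))),
            class = "trialset")
}

#' Write / read a feature table as tab-separated text
#'
#' One row per sample; feature columns named `channel_band`, plus `label`
#' and `trial` columns.
#'
#' @param table A `feature_table`.
#' @param path File path.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table$x)
  df$label <- as.character(table$labels)
  df$trial <- table$trial
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param sampling_rate,window Metadata not stored in the flat file.
#' @export
read_feature_table <- function(path, sampling_rate = 128, window = 4) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  labels <- factor(df$label, levels = EMOTION_CLASSES)
  trial <- df$trial
  x <- as.matrix(df[, setdiff(names(df), c("label", "trial")), drop = FALSE])
  parts <- strsplit(colnames(x), "_", fixed = TRUE)
  ch_name <- vapply(parts, `[[`, character(1), 1L)
  band <- vapply(parts, function(p) p[length(p)], character(1))
  channel_names <- unique(ch_name)
  # the flat file carries no normalization flag; recover it from the data
  mu <- colMeans(x)
  sg <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  looks_normalized <- all(abs(mu) < 1e-6) &&
    all(abs(sg - 1) < 1e-6 | sg < 1e-12)
  structure(list(
    x = x, labels = labels, trial = trial,
    feature_map = data.frame(channel = match(ch_name, channel_names),
                             channel_name = ch_name, band = band),
    channel_names = channel_names,
    bands = band_definitions()[match(unique(band), band_definitions()$name), ],
    sampling_rate = sampling_rate, window = window,
    normalized = looks_normalized, norm_stats = NULL
  ), class = "feature_table")
}

#' Write feature weights as tabular text
#'
#' Columns `feature`, `channel`, `band`, `weight`, sorted by weight
#' descending. Comment header lines (prefixed `#`) may carry provenance.
#'
#' @param fw A `feature_weights` object.
#' @param path File path.
#' @param header Optional character vector of `#`-prefixed comment lines.
#' @export
write_feature_weights <- function(fw, path, header = character()) {
  stopifnot(inherits(fw, "feature_weights"))
  idx <- fw$ranking
  df <- data.frame(feature = names(fw$weights)[idx],
                   channel = fw$feature_map$channel_name[idx],
                   band = fw$feature_map$band[idx],
                   weight = sprintf("%.17g", unname(fw$weights[idx])))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_weights
#' @param method Method label to attach when reading.
#' @export
read_feature_weights <- function(path, method = "unknown") {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  # rows are weight-sorted; restore a deterministic channel-major feature
  # order (channels lexicographic, bands in canonical order)
  channel_names <- sort(unique(df$channel))
  ord <- order(match(df$channel, channel_names),
               match(df$band, band_definitions()$name))
  df <- df[ord, ]
  w <- stats::setNames(df$weight, df$feature)
  structure(list(
    weights = w, ranking = order_desc(w), method = method,
    class_priors = NULL, k = NULL, m = NULL,
    feature_map = data.frame(channel = match(df$channel, channel_names),
                             channel_name = df$channel, band = df$band),
    channel_names = channel_names
  ), class = "feature_weights")
}

#' Write a channel ranking as tabular text
#'
#' Rank / channel / weight / lobe layout (see [channel_report()]).
#'
#' @param cw A `channel_weights` object.
#' @param path File path.
#' @param header Optional `#`-prefixed comment lines.
#' @export
write_channel_weights <- function(cw, path, header = character()) {
  rep_df <- channel_report(cw)
  rep_df$weight <- sprintf("%.17g", rep_df$weight)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  write.table(rep_df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an accuracy curve as tabular text
#'
#' @param curve An `accuracy_curve`.
#' @param path File path.
#' @param header Optional `#`-prefixed comment lines.
#' @export
write_accuracy_curve <- function(curve, path, header = character()) {
  df <- data.frame(n_selected = curve$n_selected,
                   mean_accuracy = curve$mean, sd_accuracy = curve$sd)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an X-MRCS iteration trace as tabular text
#'
#' One row per (iteration, rank position): iteration, channel, weight,
#' rank, S(n), C(n).
#'
#' @param fit An `xmrcs_fit`.
#' @param path File path.
#' @param header Optional `#`-prefixed comment lines.
#' @export
write_xmrcs_trace <- function(fit, path, header = character()) {
  stopifnot(inherits(fit, "xmrcs_fit"))
  rows <- lapply(fit$trace, function(st) {
    data.frame(iteration = st$iteration,
               rank = seq_along(st$ranking),
               channel = fit$channel_names[st$ranking],
               weight = st$weights[st$ranking],
               S = st$curve,
               C = st$contributions)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
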