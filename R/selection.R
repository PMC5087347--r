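# Channel selection from feature weights: top-N-feature channel sets,
# MRCS mean aggregation, cross-subject aggregation.

#' Channels owning the top-N features
#'
#' The feature-selection-based strategy: take the N highest-weighted
#' features and select the distinct channels that own them, ordered by
#' first appearance in the feature ranking (duplicates collapse, so the
#' channel count is at most N).
#'
#' @param fw A `feature_weights` object.
#' @param n Number of top features, `1 <= n <= n_features`.
#' @return An object of class `channel_selection`: `selected` (channel
#'   indices in inclusion order), `channel_names`, `source`,
#'   `n_features_requested`.
#' @export
channels_from_top_features <- function(fw, n) {
  stopifnot(inherits(fw, "feature_weights"))
  if (n < 1L || n > length(fw$weights)) {
    stop(sprintf("`n` must be in 1..%d", length(fw$weights)), call. = FALSE)
  }
  top <- fw$ranking[seq_len(n)]
  sel <- unique(fw$feature_map$channel[top])
  structure(list(
    selected = sel,
    channel_names = fw$channel_names[sel],
    source = "topn_features",
    n_features_requested = as.integer(n)
  ), class = "channel_selection")
}

#' MRCS: mean-ReliefF channel weights
#'
#' Aggregates feature weights to the channel level: a channel's weight is
#' the arithmetic mean of the weights of all features belonging to it
#' (`W(T) = (1/N) sum_i W(f_i)`, N features per channel). Channels are
#' ranked by weight, descending, ties broken by lower channel index.
#'
#' @param fw A `feature_weights` object (typically from [relieff()]; the
#'   same aggregation applies to [fscore()] weights).
#' @return An object of class `channel_weights`: named `weights` per
#'   channel, `ranking` (channel indices descending), `provenance`.
#' @export
mrcs <- function(fw) {
  stopifnot(inherits(fw, "feature_weights"))
  n_ch <- length(fw$channel_names)
  owners <- factor(fw$feature_map$channel, levels = seq_len(n_ch))
  if (any(table(owners) == 0L)) {
    stop("every channel must own at least one feature", call. = FALSE)
  }
  w <- as.numeric(tapply(fw$weights, owners, mean))
  names(w) <- fw$channel_names
  new_channel_weights(w, provenance = paste0("mrcs_", fw$method),
                      channel_names = fw$channel_names)
}

#' Subject-independent channel weights
#'
#' Aggregates per-subject channel weights into one ranking by summing each
#' channel's weight over subjects (`W(T_k) = sum_s W(T_sk)`). All subjects
#' must share the same channel set; per-subject weights are typically MRCS
#' weights.
#'
#' @param per_subject List of `channel_weights`, one per subject.
#' @return A `channel_weights` object with
#'   `provenance = "subject_independent"`.
#' @export
subject_independent <- function(per_subject) {
  if (!length(per_subject) ||
      !all(vapply(per_subject, inherits, logical(1), "channel_weights"))) {
    stop("`per_subject` must be a non-empty list of channel_weights",
         call. = FALSE)
  }
  ref <- names(per_subject[[1L]]$weights)
  for (cw in per_subject[-1L]) {
    if (!identical(names(cw$weights), ref)) {
      stop("subjects have mismatched channel sets", call. = FALSE)
    }
  }
  w <- Reduce(`+`, lapply(per_subject, `[[`, "weights"))
  new_channel_weights(w, provenance = "subject_independent",
                      channel_names = ref)
}

#' Construct a channel weighting
#'
#' Builds a `channel_weights` object from a named numeric vector, ranking
#' channels by descending weight with ties broken by lower channel index.
#' Useful for handcrafted or externally computed weightings (e.g. as the
#' initial state of [xmrcs()]).
#'
#' @param weights Named numeric vector, one weight per channel.
#' @param provenance Strategy label (default `"manual"`).
#' @return A `channel_weights` object.
#' @export
channel_weights <- function(weights, provenance = "manual") {
  if (is.null(names(weights))) {
    names(weights) <- montage_labels(length(weights))
  }
  new_channel_weights(weights, provenance = provenance,
                      channel_names = names(weights))
}

new_channel_weights <- function(w, provenance, channel_names) {
  structure(list(
    weights = w,
    ranking = order_desc(w),
    provenance = provenance,
    channel_names = channel_names
  ), class = "channel_weights")
}

#' Ranked-channel report
#'
#' Tabulates a channel weighting as rank / electrode / weight / brain lobe,
#' the layout used for reporting subject-independent selections.
#'
#' @param cw A `channel_weights` object.
#' @param n Number of top channels to report (default all).
#' @return Data frame with columns `rank`, `channel`, `weight`, `lobe`.
#' @export
channel_report <- function(cw, n = length(cw$weights)) {
  stopifnot(inherits(cw, "channel_weights"))
  idx <- cw$ranking[seq_len(n)]
  data.frame(rank = seq_len(n),
             channel = cw$channel_names[idx],
             weight = unname(cw$weights[idx]),
             lobe = electrode_lobe(cw$channel_names[idx]))
}
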