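# X-MRCS: classifier-in-the-loop adjustment of channel weights by their
# marginal contribution to the cross-validated accuracy curve.

#' Accuracy curve over channel prefixes
#'
#' For a channel ranking, computes `S(n)`: the mean cross-validated
#' classification accuracy using all features (all bands) of the top-n
#' channels, for n = 1 .. n_channels. Channels are added one by one in
#' ranking order; at position n exactly `n_bands * n` features are fed to
#' the classifier. Per-fold accuracies are retained for dispersion.
#'
#' @param table A `feature_table` (channel-selection set).
#' @param ranking Integer vector: channel indices in descending-weight
#'   order, covering all channels.
#' @param clf A [classifier_spec()].
#' @param cache Optional environment memoizing identical channel prefixes.
#' @return An `accuracy_curve` object (`n_selected`, `mean`, `sd`,
#'   per-fold matrix).
#' @export
accuracy_curve <- function(table, ranking, clf = classifier_spec(),
                           cache = NULL) {
  stopifnot(inherits(table, "feature_table"))
  n_ch <- length(table$channel_names)
  if (!setequal(ranking, seq_len(n_ch))) {
    stop("`ranking` must be a permutation of all channel indices",
         call. = FALSE)
  }
  feature_sets <- lapply(seq_len(n_ch), function(n) {
    which(table$feature_map$channel %in% ranking[seq_len(n)])
  })
  res <- curve_engine(table, feature_sets, clf, cache)
  new_accuracy_curve(seq_len(n_ch), res$mean, res$sd, res$folds,
                     unit = "channel", channels = ranking)
}

#' Relative accuracy contribution of each ranked channel
#'
#' `C(n) = (S(n) - S(n-1)) / S(n-1)` for n >= 2: the relative change in
#' mean accuracy when the n-th ranked channel is added; may be negative.
#' `C(1)` has no predecessor and is defined as 0, so the top channel's
#' weight is never updated through its own slot.
#'
#' @param s Numeric vector of mean accuracies `S(n)`, n = 1 .. n_channels.
#' @return Numeric vector of contributions, same length as `s`.
#' @export
contribution <- function(s) {
  if (any(s[-length(s)] <= 0)) {
    stop("S(n-1) = 0: contribution undefined (empty-class or degenerate curve)",
         call. = FALSE)
  }
  c(0, diff(s) / s[-length(s)])
}

#' Multiplicative weight update from contributions
#'
#' `W_i(T) = W_{i-1}(T) * (1 + C_{i-1}(n_T))`, where `n_T` is channel T's
#' rank under the weights being updated. A channel's weight grows when its
#' contribution is positive and shrinks when negative. A negative weight
#' entering this update inverts that direction; the formula is applied
#' as stated and a warning is emitted.
#'
#' @param weights Named channel weights `W_{i-1}`.
#' @param contributions `C_{i-1}(n)` per rank position, from
#'   [contribution()].
#' @param ranking Channel indices by descending `weights`.
#' @return Updated weights (same names/order as `weights`).
#' @export
update_weights <- function(weights, contributions, ranking) {
  if (any(weights < 0)) {
    warning("negative channel weight at update time: the multiplicative update inverts the intended direction for such channels",
            call. = FALSE)
  }
  rank_of <- integer(length(weights))
  rank_of[ranking] <- seq_along(ranking)
  weights * (1 + contributions[rank_of])
}

#' X-MRCS: classifier-in-the-loop channel weight adjustment
#'
#' Starting from MRCS weights `W_0`, repeats: rank channels by weight,
#' evaluate the cross-validated accuracy curve `S_i(n)` on the
#' channel-selection set, compute contributions `C_i(n)`, and update every
#' channel's weight multiplicatively by its slot's contribution. The loop
#' stops when the largest negative contribution is smaller than `epsilon`
#' in absolute value (vacuously, when no contribution is negative), or
#' after `max_iterations` weight updates (non-convergence is flagged, not
#' an error).
#'
#' The curve is recomputed under the new ranking each iteration; identical
#' channel prefixes are memoized across iterations, and one fold partition
#' (fixed by `clf$seed`) is used throughout so curve differences reflect
#' the ranking, not fold noise. Only the channel-selection set is touched;
#' validation data never enters the loop.
#'
#' @param table The channel-selection `feature_table`.
#' @param init Initial `channel_weights` (MRCS, from [mrcs()]).
#' @param clf A [classifier_spec()].
#' @param epsilon Convergence threshold on the largest negative
#'   contribution (default 0.01).
#' @param max_iterations Iteration cap (default 50).
#' @return An object of class `xmrcs_fit` (inherits `channel_weights`):
#'   final `weights` and `ranking`, `iterations` (number of updates),
#'   `converged`, and `trace` — one entry per evaluated iteration with
#'   weights, ranking, curve and contributions.
#' @export
xmrcs <- function(table, init, clf = classifier_spec(), epsilon = 0.01,
                  max_iterations = 50L) {
  stopifnot(inherits(table, "feature_table"),
            inherits(init, "channel_weights"))
  stopifnot_scalar_number(epsilon, "epsilon", 0)
  w <- init$weights
  cache <- new.env(parent = emptyenv())
  trace <- list()
  i <- 0L
  converged <- FALSE
  repeat {
    ranking <- order_desc(w)
    curve <- accuracy_curve(table, ranking, clf, cache = cache)
    ctr <- contribution(curve$mean)
    trace[[i + 1L]] <- list(iteration = i, weights = w, ranking = ranking,
                            curve = curve$mean, contributions = ctr)
    neg <- ctr[ctr < 0]
    if (!length(neg) || max(abs(neg)) < epsilon) {
      converged <- TRUE
      break
    }
    if (i >= max_iterations) break
    w <- update_weights(w, ctr, ranking)
    i <- i + 1L
  }
  structure(list(
    weights = w,
    ranking = order_desc(w),
    provenance = "xmrcs",
    channel_names = init$channel_names,
    iterations = i,
    converged = converged,
    epsilon = epsilon,
    max_iterations = as.integer(max_iterations),
    init_weights = init$weights,
    trace = trace
  ), class = c("xmrcs_fit", "channel_weights"))
}
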