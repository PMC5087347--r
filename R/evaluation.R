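# Performance validation: accuracy curves on the held-out set, band
# proportions among top-ranked features, paired comparisons.

#' Validate a selection on the held-out set
#'
#' Evaluates an ordered channel (or feature) ranking on the
#' performance-validation set: for every prefix length, the mean and
#' standard deviation of classification accuracy over
#' `repetitions x folds` cross-validation evaluations (50 by default).
#' For channel prefixes all features of the selected channels are fed to
#' the classifier; for feature prefixes the top-n features themselves.
#'
#' If `selection_table` is supplied, the two tables are checked for
#' trial-level disjointness and any shared trial id is a hard error
#' (leakage guard).
#'
#' @param sel A `channel_weights`/`xmrcs_fit` (channel ranking), a
#'   `channel_selection`, an integer vector of channel indices in rank
#'   order, or — with `unit = "feature"` — a `feature_weights` object or
#'   feature index vector.
#' @param table The validation `feature_table`.
#' @param clf A [classifier_spec()].
#' @param cutoffs Prefix lengths to evaluate (default all).
#' @param unit `"channel"` (default) or `"feature"`.
#' @param selection_table Optional selection-half `feature_table` for the
#'   leakage check.
#' @return An `accuracy_curve` object.
#' @export
validate_selection <- function(sel, table, clf = classifier_spec(),
                               cutoffs = NULL,
                               unit = c("channel", "feature"),
                               selection_table = NULL) {
  stopifnot(inherits(table, "feature_table"))
  unit <- match.arg(unit)
  if (!is.null(selection_table)) {
    shared <- intersect(unique(selection_table$trial), unique(table$trial))
    if (length(shared)) {
      stop("leakage: trials shared between selection and validation sets: ",
           paste(head(shared, 5L), collapse = ", "), call. = FALSE)
    }
  }
  order_idx <- selection_order(sel, unit)
  if (is.null(cutoffs)) cutoffs <- seq_along(order_idx)
  if (any(cutoffs < 1L | cutoffs > length(order_idx))) {
    stop("`cutoffs` out of range", call. = FALSE)
  }
  cutoffs <- sort(unique(as.integer(cutoffs)))
  feature_sets <- lapply(cutoffs, function(n) {
    if (unit == "channel") {
      which(table$feature_map$channel %in% order_idx[seq_len(n)])
    } else {
      order_idx[seq_len(n)]
    }
  })
  res <- curve_engine(table, feature_sets, clf)
  new_accuracy_curve(cutoffs, res$mean, res$sd, res$folds, unit = unit,
                     channels = if (unit == "channel") order_idx else NULL)
}

selection_order <- function(sel, unit) {
  if (unit == "channel") {
    if (inherits(sel, "channel_weights")) return(sel$ranking)
    if (inherits(sel, "channel_selection")) return(sel$selected)
    if (is.numeric(sel)) return(as.integer(sel))
  } else {
    if (inherits(sel, "feature_weights")) return(sel$ranking)
    if (is.numeric(sel)) return(as.integer(sel))
  }
  stop("unsupported selection object for unit = ", unit, call. = FALSE)
}

#' Band proportions among the top-N features
#'
#' For each cutoff N, the fraction of the N highest-weighted features
#' falling in each band (theta, alpha, beta, gamma). Fractions are exact
#' counts over N, so each row sums to 1. When a list of weightings is
#' given (e.g. one per subject), fractions are averaged across them.
#'
#' @param fw A `feature_weights` object, or a list of them.
#' @param cutoffs Top-N cutoffs (default the canonical 4, 8, 16, 32, 64,
#'   96, 128 clipped to the feature count).
#' @return Data frame: `top_n`, then one fraction column per band.
#' @export
band_proportions <- function(fw, cutoffs = NULL) {
  if (inherits(fw, "feature_weights")) fw <- list(fw)
  stopifnot(all(vapply(fw, inherits, logical(1), "feature_weights")))
  p <- length(fw[[1L]]$weights)
  band_names <- unique(fw[[1L]]$feature_map$band)
  if (is.null(cutoffs)) {
    cutoffs <- c(4L, 8L, 16L, 32L, 64L, 96L, 128L)
    cutoffs <- cutoffs[cutoffs <= p]
  }
  if (any(cutoffs > p)) stop("cutoff exceeds the number of features",
                             call. = FALSE)
  rows <- lapply(cutoffs, function(n) {
    fr <- rowMeans(vapply(fw, function(w) {
      top_bands <- w$feature_map$band[w$ranking[seq_len(n)]]
      counts <- table(factor(top_bands, levels = band_names))
      as.numeric(counts) / n
    }, numeric(length(band_names))))
    stats::setNames(as.list(fr), band_names)
  })
  out <- cbind(data.frame(top_n = cutoffs),
               do.call(rbind, lapply(rows, as.data.frame)))
  rownames(out) <- NULL
  out
}

#' Paired comparison of two per-subject accuracy curves
#'
#' Two-sided paired t-test of accuracy between two strategies at each
#' prefix length, across subjects. Identical columns give t = 0, p = 1;
#' a nonzero constant offset with zero within-pair variance is degenerate
#' (the t statistic is unbounded) and is flagged with `p = NA`.
#'
#' @param curve_a,curve_b Matrices of per-subject accuracy
#'   (subjects x prefix lengths), same shape, rows aligned by subject.
#' @param n_selected Optional prefix lengths for labeling rows.
#' @return Data frame: `n_selected`, `mean_diff` (a - b), `t`, `p`,
#'   `degenerate`.
#' @export
paired_comparison <- function(curve_a, curve_b, n_selected = NULL) {
  curve_a <- as.matrix(curve_a)
  curve_b <- as.matrix(curve_b)
  if (!identical(dim(curve_a), dim(curve_b))) {
    stop("curves must have identical dimensions", call. = FALSE)
  }
  if (nrow(curve_a) < 2L) stop("need at least 2 subjects", call. = FALSE)
  if (is.null(n_selected)) n_selected <- seq_len(ncol(curve_a))
  res <- lapply(seq_len(ncol(curve_a)), function(j) {
    d <- curve_a[, j] - curve_b[, j]
    # same near-zero-variance criterion as t.test ("essentially constant")
    constant <- sd(d) == 0 ||
      sd(d) / sqrt(length(d)) < 10 * .Machine$double.eps * abs(mean(d))
    if (constant) {
      if (all(d == 0)) {
        data.frame(mean_diff = 0, t = 0, p = 1, degenerate = FALSE)
      } else {
        data.frame(mean_diff = mean(d), t = NA_real_, p = NA_real_,
                   degenerate = TRUE)
      }
    } else {
      tt <- t.test(curve_a[, j], curve_b[, j], paired = TRUE)
      data.frame(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
                 p = tt$p.value, degenerate = FALSE)
    }
  })
  out <- cbind(data.frame(n_selected = n_selected), do.call(rbind, res))
  if (any(out$degenerate)) {
    warning("zero within-pair variance with nonzero offset at ",
            sum(out$degenerate), " prefix length(s); p set to NA",
            call. = FALSE)
  }
  rownames(out) <- NULL
  out
}
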