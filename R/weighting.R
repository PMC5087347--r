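# Feature weighting: multi-class ReliefF and the F-score filter.

#' Range-scaled feature difference
#'
#' `|value(f, R1) - value(f, R2)| / (max(f) - min(f))`, the per-feature
#' difference used inside the ReliefF update, scaled by the feature's range
#' over the scoring set so that it lies in `[0, 1]`. A constant feature
#' (zero range) is defined to have difference 0.
#'
#' @param v1,v2 Feature values of the two samples (vectorised over
#'   features).
#' @param fmin,fmax Per-feature minimum and maximum over the scoring set.
#' @return Differences in `[0, 1]`.
#' @export
feature_diff <- function(v1, v2, fmin, fmax) {
  rng <- fmax - fmin
  out <- abs(v1 - v2) / ifelse(rng > 0, rng, 1)
  out[rng <= 0] <- 0
  out
}

#' Multi-class ReliefF feature weights
#'
#' Scores every feature by its ability to separate a sample from its
#' nearest neighbors of other classes (misses) relative to its nearest
#' neighbors of the same class (hits). All weights start at zero; for
#' every sample `R_i` the k nearest hits and, per other class `C`, the k
#' nearest misses are found by Euclidean distance over all features, and
#' each feature weight is updated by
#' `- sum_j diff(f, R_i, H_j) / (m k)
#'  + sum_C [P(C) / (1 - P(class(R_i)))] sum_j diff(f, R_i, M_j(C)) / (m k)`,
#' with `m` the number of samples, class priors `P(C)` estimated from the
#' scoring set, and `diff` the range-scaled difference
#' ([feature_diff()]). The loop visits every sample once.
#'
#' A sample is never its own hit; distance ties are broken by lowest sample
#' index, making the output invariant to sample order.
#'
#' @param table A normalized `feature_table` (the channel-selection set).
#' @param k Neighbor count (default 10); must be below every class size.
#' @return An object of class `feature_weights`: `weights` (named,
#'   in `[-1, 1]`), `ranking` (feature indices, descending weight),
#'   `class_priors`, `method = "relieff"`, plus the feature map for
#'   downstream channel aggregation.
#' @references Kononenko's ReliefF extension of Relief to multi-class
#'   problems with k nearest hits/misses.
#' @export
relieff <- function(table, k = 10L) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$x
  y <- droplevels(table$labels)
  n <- nrow(x)
  p <- ncol(x)
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  cls_n <- table(y)
  small <- names(cls_n)[cls_n <= k]
  if (length(small)) {
    stop(sprintf("class '%s' has %d samples; ReliefF with k = %d needs every class to have more than k members",
                 small[1L], cls_n[[small[1L]]], k), call. = FALSE)
  }
  if (!isTRUE(table$normalized)) {
    warning("feature table is not z-scored; ReliefF distances assume comparable feature scales",
            call. = FALSE)
  }
  fmin <- apply(x, 2L, min)
  fmax <- apply(x, 2L, max)
  rng <- fmax - fmin
  div <- ifelse(rng > 0, rng, 1)   # constant features contribute diff = 0
  priors <- as.numeric(cls_n) / n
  names(priors) <- names(cls_n)
  m <- n
  d2 <- as.matrix(stats::dist(x))
  w <- numeric(p)
  classes <- levels(y)
  idx_by_class <- lapply(classes, function(cl) which(y == cl))
  names(idx_by_class) <- classes
  for (i in seq_len(n)) {
    ci <- as.character(y[i])
    di <- d2[i, ]
    for (cl in classes) {
      cand <- idx_by_class[[cl]]
      if (cl == ci) cand <- cand[cand != i]
      # deterministic tie-break: lowest index first among equal distances
      nb <- cand[order(di[cand], cand)][seq_len(k)]
      sdiff <- colSums(abs(x[nb, , drop = FALSE] -
                             matrix(x[i, ], k, p, byrow = TRUE))) / div
      sdiff[rng <= 0] <- 0
      if (cl == ci) {
        w <- w - sdiff / (m * k)
      } else {
        w <- w + (priors[[cl]] / (1 - priors[[ci]])) * sdiff / (m * k)
      }
    }
  }
  names(w) <- colnames(x)
  new_feature_weights(w, method = "relieff", table = table,
                      class_priors = priors, k = k, m = m)
}

#' F-score feature weights
#'
#' Filter ranking by the ratio of between-class to pooled within-class
#' scatter, per feature:
#' `F_i = sum_j n_j (xbar_ij - xbar_i)^2 / sum_j sum_k (x_kij - xbar_ij)^2`,
#' where `xbar_ij` is the class-j mean and `xbar_i` the grand mean of
#' feature i. A feature with zero scatter of both kinds scores 0; zero
#' within-class scatter with positive between-class scatter yields `Inf`
#' (flagged with a warning) and ranks first.
#'
#' @param table A `feature_table` (the channel-selection set).
#' @return A `feature_weights` object with `method = "fscore"`.
#' @export
fscore <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$x
  y <- droplevels(table$labels)
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  grand <- colMeans(x)
  between <- numeric(ncol(x))
  within <- numeric(ncol(x))
  for (cl in levels(y)) {
    xi <- x[y == cl, , drop = FALSE]
    mj <- colMeans(xi)
    between <- between + nrow(xi) * (mj - grand)^2
    within <- within + colSums(sweep(xi, 2L, mj)^2)
  }
  w <- ifelse(within > 0, between / within,
              ifelse(between > 0, Inf, 0))
  if (any(is.infinite(w))) {
    warning(sum(is.infinite(w)),
            " feature(s) have zero within-class scatter; F-score set to Inf",
            call. = FALSE)
  }
  names(w) <- colnames(x)
  priors <- as.numeric(table(y)) / length(y)
  names(priors) <- levels(y)
  new_feature_weights(w, method = "fscore", table = table,
                      class_priors = priors)
}

new_feature_weights <- function(w, method, table, class_priors = NULL,
                                k = NULL, m = NULL) {
  structure(list(
    weights = w,
    ranking = order_desc(w),
    method = method,
    class_priors = class_priors,
    k = k, m = m,
    feature_map = table$feature_map,
    channel_names = table$channel_names
  ), class = "feature_weights")
}
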