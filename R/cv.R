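# Repeated stratified k-fold cross-validation around the wrapped classifier.

#' Classifier specification for selection and validation
#'
#' Describes the wrapped classifier and cross-validation scheme: an RBF
#' support-vector machine (libsvm via e1071) with one-vs-one multi-class
#' strategy and default penalty `cost = 1` and kernel width
#' `gamma = 1/n_features`, evaluated by `repetitions` runs of
#' stratified `folds`-fold cross-validation (default five 10-fold runs).
#'
#' @param kind Classifier kind; only `"svm"` is implemented.
#' @param cost SVM penalty parameter C (libsvm default 1).
#' @param gamma RBF kernel width; `NULL` (default) means `1/n_features`.
#' @param repetitions Cross-validation repetitions (default 5), each with a
#'   distinct fold partition.
#' @param folds Folds per repetition (default 10).
#' @param seed Integer seed fixing all fold partitions.
#' @param group_by_trial If `TRUE`, all segments of a trial are kept in the
#'   same fold (guards against sibling-segment inflation); default `FALSE`,
#'   sample-level folds.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = "svm", cost = 1, gamma = NULL,
                            repetitions = 5L, folds = 10L, seed = 1L,
                            group_by_trial = FALSE) {
  kind <- match.arg(kind, "svm")
  structure(list(kind = kind, cost = cost, gamma = gamma,
                 repetitions = as.integer(repetitions),
                 folds = as.integer(folds), seed = as.integer(seed),
                 group_by_trial = group_by_trial),
            class = "classifier_spec")
}

# Stratified fold assignments: one integer vector per repetition, each a
# partition of the samples with per-fold class counts within +/- 1 of
# proportional. Repetitions use distinct seeded shuffles.
make_folds <- function(labels, clf, trial = NULL) {
  y <- droplevels(labels)
  n <- length(y)
  cls_n <- table(y)
  if (any(cls_n < clf$folds) && !clf$group_by_trial) {
    bad <- names(cls_n)[which.min(cls_n)]
    stop(sprintf("class '%s' has %d samples; cannot stratify into %d folds",
                 bad, min(cls_n), clf$folds), call. = FALSE)
  }
  lapply(seq_len(clf$repetitions), function(rep) {
    with_seed(derive_seed(clf$seed, rep), {
      fold <- integer(n)
      if (clf$group_by_trial) {
        if (is.null(trial)) stop("trial ids required for grouped folds",
                                 call. = FALSE)
        tl <- tapply(as.character(y), trial, function(l) l[1L])
        tid <- as.integer(names(tl))
        for (cl in levels(y)) {
          tcl <- sample(tid[tl == cl])
          tf <- rep_len(seq_len(clf$folds), length(tcl))
          for (j in seq_along(tcl)) fold[trial == tcl[j]] <- tf[j]
        }
      } else {
        for (cl in levels(y)) {
          idx <- sample(which(y == cl))
          fold[idx] <- rep_len(seq_len(clf$folds), length(idx))
        }
      }
      fold
    })
  })
}

fit_predict <- function(xtr, ytr, xte, clf) {
  g <- if (is.null(clf$gamma)) 1 / ncol(xtr) else clf$gamma
  fit <- e1071::svm(x = xtr, y = ytr, kernel = "radial",
                    cost = clf$cost, gamma = g, scale = FALSE)
  predict(fit, xte)
}

# Per-fold accuracies (repetitions x folds values) for one feature subset.
cv_fold_accuracies <- function(x, y, clf, folds_list) {
  unlist(lapply(folds_list, function(fold) {
    vapply(seq_len(clf$folds), function(f) {
      te <- fold == f
      if (!any(te)) return(NA_real_)
      pred <- fit_predict(x[!te, , drop = FALSE], y[!te],
                          x[te, , drop = FALSE], clf)
      mean(pred == y[te])
    }, numeric(1))
  }))
}

# Mean accuracy for each of a list of feature-index sets, with per-fold
# values retained. `cache` (an environment) memoizes identical sets.
curve_engine <- function(table, feature_sets, clf, cache = NULL) {
  y <- droplevels(table$labels)
  folds_list <- make_folds(table$labels, clf, trial = table$trial)
  folds_mat <- vapply(feature_sets, function(fs) {
    key <- paste(fs, collapse = ",")
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    acc <- cv_fold_accuracies(table$x[, fs, drop = FALSE], y, clf, folds_list)
    if (!is.null(cache)) cache[[key]] <- acc
    acc
  }, numeric(clf$repetitions * clf$folds))
  list(mean = colMeans(folds_mat, na.rm = TRUE),
       sd = apply(folds_mat, 2L, sd, na.rm = TRUE),
       folds = folds_mat)
}

new_accuracy_curve <- function(n_selected, mean, sd, folds, unit, channels) {
  structure(list(n_selected = n_selected, mean = mean, sd = sd,
                 folds = folds, unit = unit, channels = channels),
            class = "accuracy_curve")
}
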