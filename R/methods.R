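# print / summary / coef / plot methods for the package's S3 classes.

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf("Synthetic trial generator: %d channels @ %g Hz, %d trials x %g s\n",
              x$n_channels, x$sampling_rate, x$n_trials, x$trial_duration))
  cat(sprintf("  noise sd %g (%s), %d planted effect(s) in channel(s) %s\n",
              x$noise_sd, if (x$pink) "1/f" else "white",
              nrow(x$effect_map),
              if (length(x$informative_channels))
                paste(x$informative_channels, collapse = ", ") else "-"))
  invisible(x)
}

#' @export
print.trialset <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf("Trial set: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$sampling_rate))
  print(table(label_trial(x$valence, x$arousal)))
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d samples x %d features (%d channels x %d bands)%s\n",
              nrow(x$x), ncol(x$x), length(x$channel_names),
              nrow(x$bands),
              if (isTRUE(x$normalized)) ", z-scored" else ""))
  print(table(x$labels))
  invisible(x)
}

#' @export
print.feature_weights <- function(x, ...) {
  cat(sprintf("Feature weights (%s), %d features\n", x$method,
              length(x$weights)))
  top <- x$ranking[seq_len(min(5L, length(x$ranking)))]
  cat("  top:", paste(sprintf("%s=%.4g", names(x$weights)[top],
                              x$weights[top]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.feature_weights <- function(object, ...) object$weights

#' @export
plot.feature_weights <- function(x, n = 20L, ...) {
  idx <- x$ranking[seq_len(min(n, length(x$ranking)))]
  barplot(rev(x$weights[idx]), horiz = TRUE, las = 1,
          cex.names = 0.6, xlab = "weight",
          main = sprintf("Top %d features (%s)", length(idx), x$method), ...)
  invisible(x)
}

#' @export
print.channel_weights <- function(x, ...) {
  cat(sprintf("Channel weights (%s), %d channels\n", x$provenance,
              length(x$weights)))
  top <- x$ranking[seq_len(min(8L, length(x$ranking)))]
  cat("  ranking:", paste(x$channel_names[top], collapse = " > "),
      if (length(x$ranking) > 8L) "..." else "", "\n")
  invisible(x)
}

#' @export
coef.channel_weights <- function(object, ...) object$weights

#' @export
summary.channel_weights <- function(object, ...) {
  channel_report(object)
}

#' @export
plot.channel_weights <- function(x, ...) {
  idx <- x$ranking
  barplot(rev(x$weights[idx]), names.arg = rev(x$channel_names[idx]),
          horiz = TRUE, las = 1, cex.names = 0.6, xlab = "channel weight",
          main = x$provenance, ...)
  invisible(x)
}

#' @export
print.xmrcs_fit <- function(x, ...) {
  cat(sprintf("X-MRCS fit: %d iteration(s), %s (epsilon = %g, cap %d)\n",
              x$iterations,
              if (x$converged) "converged" else "iteration cap reached",
              x$epsilon, x$max_iterations))
  NextMethod()
}

#' @export
summary.xmrcs_fit <- function(object, ...) {
  rep_df <- channel_report(object)
  init_rank <- integer(length(object$init_weights))
  init_rank[order_desc(object$init_weights)] <-
    seq_along(object$init_weights)
  rep_df$initial_rank <- init_rank[object$ranking]
  rep_df
}

#' @export
plot.xmrcs_fit <- function(x, ...) {
  w <- vapply(x$trace, `[[`, numeric(length(x$weights)), "weights")
  w <- cbind(w, x$weights)
  matplot(t(w), type = "l", lty = 1, xlab = "iteration",
          ylab = "channel weight", main = "X-MRCS weight trajectories",
          xaxt = "n", ...)
  axis(1, at = seq_len(ncol(w)), labels = seq_len(ncol(w)) - 1L)
  invisible(x)
}

#' @export
print.channel_selection <- function(x, ...) {
  cat(sprintf("Channel selection (%s, top %d features): %d channel(s)\n",
              x$source, x$n_features_requested, length(x$selected)))
  cat(" ", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.accuracy_curve <- function(x, ...) {
  cat(sprintf("Accuracy curve over %d %s prefix(es): best %.3f at n = %d\n",
              length(x$n_selected), x$unit,
              max(x$mean), x$n_selected[which.max(x$mean)]))
  invisible(x)
}

#' @export
as.data.frame.accuracy_curve <- function(x, ...) {
  data.frame(n_selected = x$n_selected, mean_accuracy = x$mean,
             sd_accuracy = x$sd)
}

#' @export
plot.accuracy_curve <- function(x, add = FALSE, col = 1, ...) {
  if (!add) {
    plot(x$n_selected, x$mean, type = "b", pch = 16, col = col,
         ylim = range(c(x$mean - x$sd, x$mean + x$sd)),
         xlab = sprintf("number of selected %ss", x$unit),
         ylab = "classification accuracy", ...)
  } else {
    lines(x$n_selected, x$mean, type = "b", pch = 16, col = col, ...)
  }
  arrows(x$n_selected, x$mean - x$sd, x$n_selected, x$mean + x$sd,
         length = 0.02, angle = 90, code = 3, col = col)
  invisible(x)
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("Classifier: RBF %s (cost %g, gamma %s, one-vs-one), %d x %d-fold CV%s\n",
              toupper(x$kind), x$cost,
              if (is.null(x$gamma)) "1/n_features" else format(x$gamma),
              x$repetitions, x$folds,
              if (x$group_by_trial) ", trial-grouped folds" else ""))
  invisible(x)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  input: %s\n",
              if (is.null(x$input)) "synthetic (simulate)" else x$input))
  cat(sprintf("  window %gs, overlap %g; method %s (k = %d); strategy %s\n",
              x$window, x$overlap, x$method, x$k, x$strategy))
  cat(sprintf("  epsilon %g, max iterations %d; %d x %d-fold CV\n",
              x$epsilon, x$max_iterations, x$cv_repetitions, x$cv_folds))
  invisible(x)
}
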