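# End-to-end pipeline: simulate/load -> features -> rank -> select ->
# validate, with YAML-serializable configuration and provenance-stamped
# artifacts.

#' Pipeline run configuration
#'
#' Collects every tunable parameter of the pipeline with defaults matching
#' the reference procedure: 4-s non-overlapping windows, the four canonical
#' bands, ReliefF with k = 10, MRCS/X-MRCS selection with epsilon = 0.01
#' and at most 50 iterations, and five 10-fold cross-validations.
#'
#' @param input Path to a trial-set container, or `NULL` to simulate.
#' @param out_dir Directory receiving the artifacts.
#' @param simulate A [generator_spec()] used when `input` is `NULL`.
#' @param window,overlap Segmentation parameters (seconds, fraction).
#' @param method Feature weighting method: `"relieff"` or `"fscore"`.
#' @param k ReliefF neighbor count.
#' @param strategy Channel selection strategy: `"mrcs"`, `"xmrcs"`, or
#'   `"topn_features"`.
#' @param n_features Top-N features for the `topn_features` strategy.
#' @param epsilon,max_iterations X-MRCS convergence parameters.
#' @param cv_repetitions,cv_folds Cross-validation scheme.
#' @param split_seed,cv_seed Seeds for the trial split and fold partitions.
#' @param normalize_scope `"all"` (z-score fit on the combined table before
#'   splitting, the reference procedure) or `"train"` (fit on the selection
#'   half only, applied to the validation half).
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(input = NULL, out_dir = "eegsel-artifacts",
                       simulate = generator_spec(seed = 1L),
                       window = 4, overlap = 0,
                       method = c("relieff", "fscore"), k = 10L,
                       strategy = c("mrcs", "xmrcs", "topn_features"),
                       n_features = 32L,
                       epsilon = 0.01, max_iterations = 50L,
                       cv_repetitions = 5L, cv_folds = 10L,
                       split_seed = 1L, cv_seed = 1L,
                       normalize_scope = c("all", "train")) {
  structure(list(
    input = input, out_dir = out_dir, simulate = simulate,
    window = window, overlap = overlap,
    method = match.arg(method), k = as.integer(k),
    strategy = match.arg(strategy), n_features = as.integer(n_features),
    epsilon = epsilon, max_iterations = as.integer(max_iterations),
    cv_repetitions = as.integer(cv_repetitions),
    cv_folds = as.integer(cv_folds),
    split_seed = as.integer(split_seed), cv_seed = as.integer(cv_seed),
    normalize_scope = match.arg(normalize_scope)
  ), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (inherits(x$simulate, "generator_spec")) {
    x$simulate <- unclass(x$simulate)
    x$simulate$effect_map <- as.list(x$simulate$effect_map)
    x$simulate$bands <- as.list(x$simulate$bands)
    x$simulate$class_counts <- as.list(x$simulate$class_counts)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$simulate)) {
    s <- x$simulate
    em <- if (length(s$effect_map$class)) {
      as.data.frame(s$effect_map, stringsAsFactors = FALSE)
    } else empty_effect_map()
    x$simulate <- generator_spec(
      n_channels = s$n_channels, sampling_rate = s$sampling_rate,
      trial_duration = s$trial_duration, n_trials = s$n_trials,
      class_counts = unlist(s$class_counts),
      effect_map = em,
      noise_sd = s$noise_sd, base_amplitude = s$base_amplitude,
      pink = s$pink, seed = s$seed
    )
  }
  cfg <- do.call(run_config, x[setdiff(names(x), character(0))])
  cfg
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
config_fingerprint <- function(config) {
  # out_dir does not affect the computation, so it is excluded: the same
  # scientific configuration yields the same fingerprint wherever it is run
  config$out_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end channel-selection pipeline
#'
#' Executes simulate/load, feature extraction and normalization, the
#' trial-level split, feature weighting, channel selection, and held-out
#' validation, writing every artifact (feature weights, channel ranking,
#' accuracy curve, X-MRCS trace when applicable) as tab-separated text
#' stamped with the configuration fingerprint and seeds.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the in-memory objects (`features`,
#'   `split`, `feature_weights`, `selection`, `curve`, ...) and the
#'   artifact `paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[eegsel] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- config_fingerprint(config)
  stamp <- c(sprintf("#config_md5\t%s", fp),
             sprintf("#split_seed\t%d\t#cv_seed\t%d",
                     config$split_seed, config$cv_seed))

  say("stage: input")
  trials <- stage("input", {
    if (is.null(config$input)) generate_subject(config$simulate)
    else read_trialset(config$input)
  })

  say("stage: features")
  ft <- stage("features", {
    ft <- extract_features(trials, window = config$window,
                           overlap = config$overlap)
    if (config$normalize_scope == "all") zscore_features(ft) else ft
  })

  say("stage: split")
  halves <- stage("split", {
    halves <- split_dataset(ft, seed = config$split_seed)
    if (config$normalize_scope == "train") {
      sel <- zscore_features(halves$selection)
      halves$selection <- sel
      halves$validation <- apply_zscore(halves$validation, sel$norm_stats)
    }
    halves
  })

  say("stage: rank (", config$method, ")")
  fw <- stage("rank", {
    if (config$method == "relieff") relieff(halves$selection, k = config$k)
    else fscore(halves$selection)
  })

  clf <- classifier_spec(repetitions = config$cv_repetitions,
                         folds = config$cv_folds, seed = config$cv_seed)
  say("stage: select (", config$strategy, ")")
  selection <- stage("select", {
    switch(config$strategy,
      topn_features = channels_from_top_features(fw, config$n_features),
      mrcs = mrcs(fw),
      xmrcs = xmrcs(halves$selection, mrcs(fw), clf,
                    epsilon = config$epsilon,
                    max_iterations = config$max_iterations))
  })

  say("stage: validate")
  curve <- stage("validate", {
    validate_selection(selection, halves$validation, clf,
                       selection_table = halves$selection)
  })

  say("stage: artifacts -> ", config$out_dir)
  paths <- stage("artifacts", {
    p <- list(
      config = file.path(config$out_dir, "config.yaml"),
      feature_weights = file.path(config$out_dir, "feature_weights.tsv"),
      curve = file.path(config$out_dir, "accuracy_curve.tsv")
    )
    write_run_config(config, p$config)
    write_feature_weights(fw, p$feature_weights, header = stamp)
    if (inherits(selection, "channel_weights")) {
      p$channel_weights <- file.path(config$out_dir, "channel_weights.tsv")
      write_channel_weights(selection, p$channel_weights, header = stamp)
    }
    if (inherits(selection, "xmrcs_fit")) {
      p$trace <- file.path(config$out_dir, "xmrcs_trace.tsv")
      write_xmrcs_trace(selection, p$trace, header = stamp)
    }
    write_accuracy_curve(curve, p$curve, header = stamp)
    p
  })

  invisible(list(trials = trials, features = ft, split = halves,
                 feature_weights = fw, selection = selection,
                 curve = curve, config = config, fingerprint = fp,
                 paths = paths))
}
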