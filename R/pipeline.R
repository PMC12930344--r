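# End-to-end orchestration: simulate cohorts, extract features, run the
# statistics, build scalogram datasets, train and evaluate the classifier,
# and write a reproducibility manifest. Two runs with the same config
# produce identical features and reports.

#' Pipeline configuration
#'
#' Every tunable of the full pipeline in one serializable list. The
#' defaults run a reduced-size but complete analysis in well under ten
#' minutes on one CPU.
#'
#' @param seed master seed; every stochastic stage derives its stream from
#'   it.
#' @param presets names of the two cohorts to simulate and compare.
#' @param n_per_group subjects per cohort.
#' @param feature_params arguments for [feature_config()].
#' @param family_alpha family-wise error rate for the feature comparison.
#' @param hl_groups Hosmer-Lemeshow group count.
#' @param scalogram list: `f_min`, `f_max`, `n_scales`, `size`.
#' @param train_cnn logical; train/evaluate the classifier stage.
#' @param cnn list of [train_compact_cnn()] hyperparameters plus `split`.
#' @param out_dir output directory.
#' @return list of class `koro_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, presets = c("young", "older"),
                            n_per_group = 30L, feature_params = list(),
                            family_alpha = 0.05, hl_groups = 10L,
                            scalogram = list(f_min = 5, f_max = 100,
                                             n_scales = 32L, size = 32L),
                            train_cnn = FALSE,
                            cnn = list(epochs = 12L, lr = 1e-3,
                                       batch_size = 16L,
                                       split = c(0.7, 0.15, 0.15)),
                            out_dir = tempfile("koro_run_")) {
  cfg <- as.list(environment())
  class(cfg) <- "koro_pipeline_config"
  cfg
}

#' Read / write a pipeline configuration
#'
#' Plain-text YAML round-trip of [pipeline_config()].
#' @param cfg a config list.
#' @param path file path.
#' @return `read_pipeline_config` returns the config; the writer returns
#'   `path` invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(pipeline_config()), raw)
  class(cfg) <- "koro_pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate the two cohorts; extract the ten-feature
#' table; compare groups (Bonferroni-adjusted); fit the logistic model on
#' all features with Hosmer-Lemeshow calibration; correlate features with
#' baPWV when present (hospital preset) including covariate-adjusted
#' models; optionally build scalogram images and train/evaluate the
#' compact CNN. Writes `features.csv`, `cohort.csv`, `report.json`,
#' `metrics.json` + `history.csv` (classifier stage), and `manifest.json`
#' (config hash, seed, package version). Any stage failure aborts with
#' the stage name.
#'
#' @param config a [pipeline_config()].
#' @return list with the in-memory results and `out_dir`, invisibly the
#'   same as what was written.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fc <- stage("config", do.call(feature_config, config$feature_params))

  cohorts <- stage("simulate", lapply(seq_along(config$presets), function(k) {
    co <- generate_cohort(cohort_preset(config$presets[[k]]),
                          config$n_per_group,
                          seed = .derive_seed(config$seed, k))
    # subject ids must stay unique when the same preset appears twice
    for (i in seq_along(co$recordings)) {
      id <- sprintf("g%d_%s", k, co$recordings[[i]]$subject_id)
      co$recordings[[i]]$subject_id <- id
      co$subjects[[i]]$subject_id <- id
    }
    co
  }))
  recordings <- do.call(c, lapply(cohorts, `[[`, "recordings"))
  subjects <- do.call(c, lapply(cohorts, `[[`, "subjects"))
  grp_labels <- if (anyDuplicated(config$presets))
    paste0(config$presets, c(".1", ".2")) else unlist(config$presets)
  group <- rep(grp_labels, each = config$n_per_group)

  # recordings in which no usable beat train is found are dropped with a
  # warning, as unusable measurements would be in a real cohort
  feats <- stage("features",
                 extract_features_cohort(recordings, config = fc,
                                         on_error = "drop"))
  if (is.null(feats) || nrow(feats) < length(recordings) * 0.8)
    stop("stage features failed: more than 20% of recordings unusable",
         call. = FALSE)
  write.csv(feats, file.path(config$out_dir, "features.csv"),
            row.names = FALSE)
  write_cohort(subjects, file.path(config$out_dir, "cohort.csv"))

  grp_map <- setNames(group, vapply(recordings, `[[`, "", "subject_id"))
  group <- unname(grp_map[feats$subject_id])
  keep_ids <- feats$subject_id
  subjects <- subjects[vapply(subjects, `[[`, "", "subject_id") %in% keep_ids]
  recordings <- recordings[vapply(recordings, `[[`, "", "subject_id") %in%
                             keep_ids]
  fx <- feats[, feature_names()]
  comparison <- stage("compare_groups",
                      compare_groups(fx, group, config$family_alpha))
  # exploratory stage: at small n the synthetic groups can be perfectly
  # separable, in which case the ML logistic fit does not exist; that is
  # recorded in the report instead of aborting the pipeline
  logistic <- tryCatch(
    fit_logistic(fx, as.integer(group == grp_labels[2]),
                 hl_groups = config$hl_groups),
    error = function(e) {
      if (!grepl("separation", conditionMessage(e)))
        stop("stage logistic failed: ", conditionMessage(e), call. = FALSE)
      list(table = NULL, separation = TRUE,
           note = conditionMessage(e))
    })

  bapwv <- vapply(subjects, `[[`, 0, "bapwv")
  correlations <- NULL; adjusted <- NULL
  if (any(!is.na(bapwv))) {
    keep <- !is.na(bapwv)
    correlations <- stage("correlation", do.call(rbind, lapply(
      feature_names(), function(fn) {
        pw <- pearson_with_power(fx[[fn]][keep], bapwv[keep])
        data.frame(feature = fn, r = pw$r, p = pw$p, power = pw$power,
                   n = pw$n)
      })))
    covar <- cohort_to_df(subjects)[keep, ]
    adjusted <- stage("adjusted", lapply(
      correlations$feature[correlations$p < 0.05], function(fn) {
        d <- cbind(covar, setNames(fx[keep, fn, drop = FALSE], fn))
        fit_adjusted(d, "bapwv", fn)
      }))
  }

  report <- list(
    group_comparison = comparison,
    logistic = if (isTRUE(logistic$separation)) logistic["note"]
               else c(logistic["table"], logistic["intercept"],
                      logistic["hosmer_lemeshow"], logistic["accuracy"]),
    correlations = correlations,
    adjusted = lapply(adjusted, function(a)
      list(feature = a$feature, table = a$table, adj_r2 = a$adj_r2)))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)

  metrics <- NULL
  if (isTRUE(config$train_cnn)) {
    sg <- config$scalogram
    ds <- stage("build_dataset",
                build_dataset(recordings,
                              as.integer(group == grp_labels[2]),
                              split = config$cnn$split,
                              seed = .derive_seed(config$seed, 91L),
                              size = sg$size, f_min = sg$f_min,
                              f_max = sg$f_max, n_scales = sg$n_scales,
                              config = fc))
    model <- stage("train",
                   train_compact_cnn(dataset_split(ds, "train"),
                                     dataset_split(ds, "val"),
                                     hyper = config$cnn,
                                     seed = .derive_seed(config$seed, 92L)))
    metrics <- stage("evaluate",
                     evaluate_classifier(model, dataset_split(ds, "test")))
    jsonlite::write_json(unclass(metrics),
                         file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(model$history, file.path(config$out_dir, "history.csv"),
              row.names = FALSE)
  }

  cfg_yaml <- yaml::as.yaml(unclass(config)[setdiff(names(config), "out_dir")])
  manifest <- list(
    config_hash = sprintf("%08x", sum(utf8ToInt(cfg_yaml) *
                                        (seq_along(utf8ToInt(cfg_yaml)) %% 97 + 1))),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("korosound")),
    n_recordings = length(recordings))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(features = feats, comparison = comparison,
                 logistic = logistic, correlations = correlations,
                 adjusted = adjusted, metrics = metrics,
                 manifest = manifest, out_dir = config$out_dir))
}
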