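# End-to-end orchestration: simulate (or read) -> QC -> threshold -> hits ->
# classify -> report, with per-stage logging and provenance.

#' Build and validate a pipeline run configuration
#'
#' Collects every stage's parameters with their defaults, mirroring the
#' JSON schema shipped in `inst/schema/run_config.schema.json`. Omitted
#' fields are filled from the defaults and echoed to the provenance output,
#' so a run directory always records its effective parameters.
#'
#' @param out_dir Output directory for all artifacts.
#' @param simulate Generate the dataset (`TRUE`) or read it from
#'   `data_dir`.
#' @param data_dir Existing dataset directory (when `simulate = FALSE`).
#' @param master_seed Master seed for all stages.
#' @param n_designs,n_rows,n_cols Catalog / grid dimensions.
#' @param resolution_um Raster resolution for design features.
#' @param qc_multiplier IQR multiplier of the QC filter.
#' @param threshold_method `"intersection"` (calibrate from controls) or
#'   `"fixed"` (use `percentile` as given).
#' @param percentile Fallback / fixed calibration percentile.
#' @param alpha Hit-calling significance level.
#' @param adjusted Gate hit classes on BH-adjusted p-values.
#' @param ml_features `"design"`, `"shape"`, or both.
#' @param n_repeats,train_fraction,cv_folds,num_trees Model settings.
#' @param synth A [synth_config()] overriding the defaults (its
#'   `master_seed` is replaced by `master_seed`).
#' @param log_level `"info"` or `"quiet"`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir, simulate = TRUE, data_dir = NULL,
                       master_seed = 1, n_designs = 2176,
                       n_rows = 66, n_cols = 66, resolution_um = 1,
                       qc_multiplier = 1.5,
                       threshold_method = c("intersection", "fixed"),
                       percentile = 93, alpha = 0.05, adjusted = FALSE,
                       ml_features = c("design", "shape"),
                       n_repeats = 100, train_fraction = 0.75, cv_folds = 10,
                       num_trees = 300, synth = NULL,
                       log_level = c("info", "quiet")) {
  threshold_method <- match.arg(threshold_method)
  log_level <- match.arg(log_level)
  ml_features <- match.arg(ml_features, several.ok = TRUE)
  cfg <- list(out_dir = out_dir, simulate = simulate, data_dir = data_dir,
              master_seed = as.integer(master_seed), n_designs = n_designs,
              n_rows = n_rows, n_cols = n_cols,
              resolution_um = resolution_um,
              qc_multiplier = qc_multiplier,
              threshold_method = threshold_method, percentile = percentile,
              alpha = alpha, adjusted = adjusted, ml_features = ml_features,
              n_repeats = n_repeats, train_fraction = train_fraction,
              cv_folds = cv_folds, num_trees = num_trees,
              synth = synth, log_level = log_level)
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' Checks field presence, types and ranges against the published schema;
#' errors name the offending field.
#'
#' @param cfg A configuration list.
#' @return The validated `run_config` (classed), invisibly usable.
#' @export
validate_run_config <- function(cfg) {
  req <- function(field, ok) {
    if (!ok) abort(sprintf("run config field `%s` is invalid.", field),
                   class = "toposcreen_config_error")
  }
  req("out_dir", is.character(cfg$out_dir) && length(cfg$out_dir) == 1)
  req("simulate", is.logical(cfg$simulate))
  if (!isTRUE(cfg$simulate)) {
    req("data_dir", is.character(cfg$data_dir) && dir.exists(cfg$data_dir))
  }
  req("master_seed", is.numeric(cfg$master_seed))
  req("n_designs", is.numeric(cfg$n_designs) && cfg$n_designs >= 1)
  req("grid", is.numeric(cfg$n_rows) && is.numeric(cfg$n_cols) &&
        2 * cfg$n_designs + 4 == cfg$n_rows * cfg$n_cols)
  req("qc_multiplier", is.numeric(cfg$qc_multiplier) && cfg$qc_multiplier > 0)
  req("percentile", is.numeric(cfg$percentile) &&
        cfg$percentile > 0 && cfg$percentile < 100)
  req("alpha", is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1)
  req("train_fraction", is.numeric(cfg$train_fraction) &&
        cfg$train_fraction > 0 && cfg$train_fraction < 1)
  req("threshold_method",
      cfg$threshold_method %in% c("intersection", "fixed"))
  req("ml_features", all(cfg$ml_features %in% c("design", "shape")))
  if (!is.null(cfg$synth)) req("synth", inherits(cfg$synth, "synth_config"))
  class(cfg) <- "run_config"
  cfg
}

pipeline_log <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible(NULL))
  inform(sprintf(paste0("[toposcreen] ", fmt), ...))
}

#' Run the whole screening pipeline
#'
#' Executes (simulate or load) -> QC -> threshold -> hit calling ->
#' classification -> summary, writing each stage's artifact into
#' `cfg$out_dir`: `design_features.csv`, `layout.tsv`, `cells.csv`,
#' `controls.csv`, `qc_report.csv`, `thresholds.json`, `hit_table.csv`,
#' `model_report.json` + `importance.csv` + `accuracies.csv` (per feature
#' set), `summary.json` and `provenance.json`. One log line per stage
#' reports counts in/out. Given the same configuration and master seed the
#' artifacts are byte-identical across runs.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_topochip_pipeline <- function(cfg) {
  cfg <- validate_run_config(unclass(cfg))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  # --- designs, features, layout -------------------------------------------
  catalog <- topo_design_catalog(n_designs = cfg$n_designs,
                                 master_seed = cfg$master_seed)
  feats <- design_features(catalog, resolution_um = cfg$resolution_um)
  layout <- build_chip_layout(catalog,
                              seed = derive_seed(cfg$master_seed, "layout"),
                              n_rows = cfg$n_rows, n_cols = cfg$n_cols)
  readr::write_csv(feats, file.path(cfg$out_dir, "design_features.csv"),
                   progress = FALSE)
  write_layout(layout, file.path(cfg$out_dir, "layout.tsv"))
  pipeline_log(cfg, "designs: %d units, %d features each",
               nrow(catalog), ncol(feats) - 2L)

  # --- dataset --------------------------------------------------------------
  if (isTRUE(cfg$simulate)) {
    synth <- cfg$synth %||% synth_config()
    synth$master_seed <- as.integer(cfg$master_seed)
    ds <- simulate_screen(synth, layout, feats)
    write_screen_dataset(ds, cfg$out_dir)
  } else {
    ds <- read_screen_dataset(cfg$data_dir)
    layout <- ds$layout
  }
  pipeline_log(cfg, "dataset: %d cells on %d chips, %d control cells",
               nrow(ds$cells), length(unique(ds$cells$chip_id)),
               nrow(ds$controls))

  # --- QC -------------------------------------------------------------------
  qc <- qc_filter(ds$cells, multiplier = cfg$qc_multiplier)
  readr::write_csv(qc$bounds, file.path(cfg$out_dir, "qc_report.csv"),
                   progress = FALSE)
  pipeline_log(cfg, "qc: %d cells in, %d excluded", qc$n_in, qc$n_excluded)

  # --- threshold ------------------------------------------------------------
  if (cfg$threshold_method == "intersection") {
    calib <- calibrate_threshold(ds$controls)
    percentile <- calib$calibration_percentile
  } else {
    calib <- NULL
    percentile <- cfg$percentile
  }
  flagged <- apply_threshold(qc$cells, percentile)
  thr <- chip_thresholds(flagged)
  jsonlite::write_json(list(
    method = cfg$threshold_method,
    calibration_percentile = percentile,
    control_crossing = if (!is.null(calib)) calib$threshold else NULL,
    per_chip = thr),
    file.path(cfg$out_dir, "thresholds.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(cfg, "threshold: percentile %.2f, %d chips, %.2f%% positive",
               percentile, nrow(thr), 100 * mean(flagged$icam1_positive))

  # --- hits -----------------------------------------------------------------
  hits <- call_hits(flagged, layout, alpha = cfg$alpha,
                    adjusted = cfg$adjusted)
  write_hit_table(hits, file.path(cfg$out_dir, "hit_table.csv"))
  tab <- table(hits$class)
  pipeline_log(cfg, "hits: %d surfaces -> %d High / %d Low / %d NS",
               nrow(hits), tab[["High"]], tab[["Low"]], tab[["NS"]])

  # --- classification -------------------------------------------------------
  reports <- list()
  n_labeled <- sum(hits$class %in% c("High", "Low"))
  class_counts <- table(factor(hits$class, c("High", "Low")))
  for (fs in cfg$ml_features) {
    if (n_labeled < 20 || any(class_counts < 2)) {
      pipeline_log(cfg,
                   "classify(%s): skipped (%d High / %d Low labeled surfaces)",
                   fs, class_counts[["High"]], class_counts[["Low"]])
      next
    }
    fm <- if (fs == "design") {
      build_feature_matrix(hits, feats)
    } else {
      build_feature_matrix(hits, shape_feature_medians(qc$cells))
    }
    rep_fs <- repeat_split_classify(
      fm, n_repeats = cfg$n_repeats, train_fraction = cfg$train_fraction,
      cv_folds = cfg$cv_folds, num_trees = cfg$num_trees,
      master_seed = derive_seed(cfg$master_seed, paste0("classify:", fs)))
    sub <- file.path(cfg$out_dir, paste0("model_", fs))
    report_model(rep_fs, sub)
    reports[[fs]] <- rep_fs
    pipeline_log(cfg, "classify(%s): mean held-out accuracy %.3f over %d repeats",
                 fs, rep_fs$mean_accuracy, cfg$n_repeats)
  }

  # --- summary & provenance -------------------------------------------------
  summ <- summarize_screen(flagged, hits, layout)
  jsonlite::write_json(summary_as_list(summ),
                       file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  prov <- unclass(cfg)
  prov$synth <- if (isTRUE(cfg$simulate)) unclass(ds$config) else NULL
  prov$package_version <- as.character(utils::packageVersion("toposcreen"))
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(cfg, "done: artifacts in %s", cfg$out_dir)

  invisible(list(catalog = catalog, features = feats, layout = layout,
                 dataset = ds, qc = qc, calibration = calib,
                 cells = flagged, hits = hits, models = reports,
                 summary = summ, config = cfg))
}
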