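# Repeated-split random-forest classification of High vs Low surfaces from
# design descriptors or per-surface cell-shape medians.

#' Build the High/Low feature matrix
#'
#' Restricts a hit table to the High and Low surfaces and joins their
#' features: either design descriptors or per-surface medians of cell-shape
#' features. Features are standardized to zero mean and unit variance over
#' the included rows; zero-variance columns are dropped with a warning.
#'
#' @param hits A `topo_hit_table`.
#' @param features A tibble with `unit_id` and numeric feature columns
#'   (e.g. from [design_features()] or [shape_feature_medians()]).
#' @param feature_cols Character vector of feature columns to use; defaults
#'   to every numeric column except identifiers.
#' @return A `feature_matrix` tibble with `unit_id`, `class` (factor
#'   High/Low) and standardized features; scaling recorded in attributes.
#' @export
build_feature_matrix <- function(hits, features, feature_cols = NULL) {
  check_columns(hits, c("unit_id", "class"), "hit table")
  check_columns(features, "unit_id", "features")
  labelled <- hits[hits$class %in% c("High", "Low"),
                   c("unit_id", "class"), drop = FALSE]
  if (nrow(labelled) == 0) {
    abort("no labeled surfaces: hit table has no High or Low class.",
          class = "toposcreen_config_error")
  }
  missing <- setdiff(labelled$unit_id, features$unit_id)
  if (length(missing) > 0) {
    abort(sprintf("hit surface `%s` lacks features.", missing[[1]]),
          class = "toposcreen_config_error")
  }
  if (is.null(feature_cols)) {
    num <- vapply(features, is.numeric, NA)
    feature_cols <- setdiff(names(features)[num],
                            c("unit_id", "rank", "n_cells", "n_pos"))
  }
  fm <- dplyr::inner_join(labelled, features[c("unit_id", feature_cols)],
                          by = "unit_id")
  X <- as.data.frame(fm[feature_cols])
  sds <- vapply(X, sd, 0)
  zero_var <- names(X)[sds == 0 | is.na(sds)]
  if (length(zero_var) > 0) {
    warn(sprintf("dropping zero-variance feature column(s): %s",
                 paste(zero_var, collapse = ", ")))
    feature_cols <- setdiff(feature_cols, zero_var)
    X <- X[feature_cols]
    sds <- sds[feature_cols]
  }
  mus <- vapply(X, mean, 0)
  X <- as.data.frame(scale(X, center = mus, scale = sds))
  out <- dplyr::bind_cols(
    tibble::tibble(unit_id = fm$unit_id,
                   class = factor(as.character(fm$class),
                                  levels = c("High", "Low"))),
    tibble::as_tibble(X))
  class(out) <- c("feature_matrix", class(out))
  attr(out, "scaling") <- list(center = mus, scale = sds)
  attr(out, "feature_cols") <- feature_cols
  out
}

#' Per-surface medians of cell-shape features
#'
#' @param cells Per-cell table (post QC).
#' @param shape_cols Shape columns to aggregate.
#' @return A tibble with `unit_id` and the per-surface medians.
#' @export
shape_feature_medians <- function(cells,
                                  shape_cols = c("area_um2", "perimeter_um",
                                                 "form_factor", "solidity",
                                                 "eccentricity",
                                                 "median_radius_um")) {
  check_columns(cells, c("unit_id", shape_cols), "cells")
  cells |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(shape_cols), median),
                     .groups = "drop")
}

# stratified split of row indices by class; returns list(train, test)
stratified_split <- function(class, train_fraction) {
  idx <- split(seq_along(class), class)
  train <- unlist(lapply(idx, function(i) {
    sample(i, max(1L, round(train_fraction * length(i))))
  }), use.names = FALSE)
  list(train = sort(train), test = sort(setdiff(seq_along(class), train)))
}

# stratified k-fold assignment
stratified_folds <- function(class, k) {
  fold <- integer(length(class))
  for (lev in levels(class)) {
    i <- sample(which(class == lev))
    fold[i] <- rep_len(seq_len(k), length(i))
  }
  fold
}

# fit + evaluate one repeat on a fixed split; used by repeat_split_classify
# and directly testable for the no-leakage property
fit_one_repeat <- function(fm, split, cv_folds, num_trees, mtry_grid,
                           seed, n_perm = 3) {
  feats <- attr(fm, "feature_cols")
  train <- as.data.frame(fm[split$train, c("class", feats)])
  test <- as.data.frame(fm[split$test, c("class", feats)])
  if (length(unique(train$class)) < 2) {
    return(NULL) # caller resamples
  }
  p <- length(feats)
  mtry_grid <- mtry_grid %||% sort(unique(pmax(1, pmin(p, c(1, floor(sqrt(p)),
                                                            floor(p / 2))))))
  # The tuning grid spans feature subsampling (mtry) and tree depth
  # (min.node.size) up to the intercept-only limit (no splits, majority
  # vote): under absent signal cross-validation selects the null model, so
  # held-out accuracy sits at the majority-class prior instead of the
  # memorised-noise level.
  n_tr <- nrow(train)
  grid <- rbind(
    expand.grid(mtry = mtry_grid,
                min_node = sort(unique(c(1L, max(1L, floor(n_tr / 3)))))),
    data.frame(mtry = mtry_grid[1], min_node = n_tr))
  # hyperparameter tuning by stratified k-fold CV on the training part only
  cv <- withr::with_seed(seed, {
    fold <- stratified_folds(train$class, cv_folds)
    t(vapply(seq_len(nrow(grid)), function(g) {
      accs <- vapply(seq_len(cv_folds), function(f) {
        tr <- train[fold != f, , drop = FALSE]
        te <- train[fold == f, , drop = FALSE]
        if (nrow(te) == 0 || length(unique(tr$class)) < 2) return(NA_real_)
        fit <- ranger::ranger(class ~ ., data = tr, num.trees = num_trees,
                              mtry = grid$mtry[g],
                              min.node.size = grid$min_node[g],
                              seed = seed + f, num.threads = 1)
        mean(predict(fit, data = te)$predictions == te$class)
      }, 0)
      c(mean(accs, na.rm = TRUE),
        sd(accs, na.rm = TRUE) / sqrt(sum(!is.na(accs))))
    }, c(0, 0)))
  })
  # one-standard-error rule: the simplest model (largest node size, then
  # smallest mtry) whose CV accuracy is within one SE of the best
  i_best <- which.max(cv[, 1])
  eligible <- which(cv[, 1] >= cv[i_best, 1] - cv[i_best, 2])
  eligible <- eligible[order(-grid$min_node[eligible],
                             grid$mtry[eligible])]
  best <- grid[eligible[1], ]
  fit <- ranger::ranger(class ~ ., data = train, num.trees = num_trees,
                        mtry = best$mtry, min.node.size = best$min_node,
                        seed = seed, num.threads = 1)
  acc <- mean(predict(fit, data = test)$predictions == test$class)
  # permutation importance on the held-out split
  importance <- withr::with_seed(seed + 7L, {
    vapply(feats, function(f2) {
      drops <- vapply(seq_len(n_perm), function(b) {
        perm <- test
        perm[[f2]] <- sample(perm[[f2]])
        acc - mean(predict(fit, data = perm)$predictions == perm$class)
      }, 0)
      mean(drops)
    }, 0)
  })
  list(accuracy = acc, importance = importance, mtry = best$mtry,
       min_node = best$min_node, fit = fit)
}

#' Repeated-split random-forest classification
#'
#' Runs the repeated random-split protocol: for each repeat, a stratified
#' `train_fraction` / `1 - train_fraction` split; random-forest
#' hyperparameters (`mtry`) tuned by stratified `cv_folds`-fold
#' cross-validation on the training part only; held-out accuracy recorded;
#' permutation importance of each feature measured on the held-out split.
#' Results aggregate to the mean and standard deviation over repeats. The
#' whole procedure is seeded and reproducible from the recorded split seeds.
#'
#' @param fm A `feature_matrix` from [build_feature_matrix()] (at least 20
#'   rows, both classes present).
#' @param n_repeats Number of random splits (default 100).
#' @param train_fraction Training fraction (default 0.75; the held-out
#'   fraction is the complement).
#' @param cv_folds Folds for hyperparameter tuning (default 10).
#' @param num_trees Trees per forest (default 300).
#' @param mtry_grid Optional integer grid for `mtry` tuning.
#' @param master_seed Master seed; each repeat's split seed derives from it.
#' @return A `topo_model_report`: list with `accuracies`, `mean_accuracy`,
#'   `importance` (tibble feature/mean/sd/rank), `importance_raw`,
#'   `split_seeds` and `config`.
#' @export
repeat_split_classify <- function(fm, n_repeats = 100, train_fraction = 0.75,
                                  cv_folds = 10, num_trees = 300,
                                  mtry_grid = NULL, master_seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm) < 20) {
    abort("feature matrix has fewer than 20 rows.",
          class = "toposcreen_config_error")
  }
  if (length(unique(fm$class)) < 2) {
    abort("both classes must be present.", class = "toposcreen_config_error")
  }
  if (cv_folds < 2) {
    abort("`cv_folds` must be at least 2.", class = "toposcreen_config_error")
  }
  feats <- attr(fm, "feature_cols")
  seeds <- vapply(seq_len(n_repeats), function(r) {
    derive_seed(master_seed, paste0("split:", r))
  }, 0L)
  accs <- numeric(n_repeats)
  imp <- matrix(NA_real_, n_repeats, length(feats),
                dimnames = list(NULL, feats))
  for (r in seq_len(n_repeats)) {
    res <- NULL
    seed_r <- seeds[r]
    tries <- 0L
    while (is.null(res)) {
      split <- withr::with_seed(seed_r,
        stratified_split(fm$class, train_fraction))
      res <- fit_one_repeat(fm, split, cv_folds, num_trees, mtry_grid,
                            seed = seed_r)
      if (is.null(res)) {
        tries <- tries + 1L
        inform(sprintf("repeat %d: split lost a class; resampling.", r))
        seed_r <- seed_r + 1000L
        if (tries > 10L) abort("could not produce a two-class split.")
      }
    }
    accs[r] <- res$accuracy
    imp[r, ] <- res$importance
  }
  importance <- tibble::tibble(
    feature = feats,
    importance_mean = colMeans(imp),
    importance_sd = apply(imp, 2, sd)) |>
    dplyr::arrange(dplyr::desc(.data$importance_mean)) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(list(
    accuracies = accs,
    mean_accuracy = mean(accs),
    importance = importance,
    importance_raw = imp,
    split_seeds = seeds,
    config = list(n_repeats = n_repeats, train_fraction = train_fraction,
                  cv_folds = cv_folds, num_trees = num_trees,
                  master_seed = master_seed,
                  n_rows = nrow(fm), features = feats)),
    class = "topo_model_report")
}

#' @export
print.topo_model_report <- function(x, ...) {
  cat(sprintf(
    "<topo_model_report> %d repeats: mean held-out accuracy %.3f (sd %.3f)\n",
    length(x$accuracies), x$mean_accuracy, sd(x$accuracies)))
  cat("top features:",
      paste(head(x$importance$feature, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.topo_model_report <- function(x, ...) x$importance

#' @export
glance.topo_model_report <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean_accuracy,
                 sd_accuracy = sd(x$accuracies),
                 n_repeats = length(x$accuracies),
                 train_fraction = x$config$train_fraction,
                 cv_folds = x$config$cv_folds)
}

#' Write a model report to files
#'
#' Writes `model_report.json` (config, accuracies, importance, split seeds),
#' `importance.csv` and `accuracies.csv`; file content is deterministic
#' given the report.
#'
#' @param report A `topo_model_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
report_model <- function(report, dir) {
  stopifnot(inherits(report, "topo_model_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(json = file.path(dir, "model_report.json"),
             importance = file.path(dir, "importance.csv"),
             accuracies = file.path(dir, "accuracies.csv"))
  jsonlite::write_json(list(
    config = report$config,
    mean_accuracy = report$mean_accuracy,
    accuracies = report$accuracies,
    importance = report$importance,
    split_seeds = report$split_seeds),
    paths[["json"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(report$importance, paths[["importance"]])
  readr::write_csv(tibble::tibble(repeat_id = seq_along(report$accuracies),
                                  split_seed = report$split_seeds,
                                  accuracy = report$accuracies),
                   paths[["accuracies"]])
  invisible(paths)
}

#' Read a model report back from its JSON serialization
#'
#' @param path Path to `model_report.json`.
#' @return A `topo_model_report` (without the raw per-repeat importance).
#' @export
read_model_report <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    accuracies = j$accuracies,
    mean_accuracy = j$mean_accuracy,
    importance = tibble::as_tibble(j$importance),
    importance_raw = NULL,
    split_seeds = j$split_seeds,
    config = j$config),
    class = "topo_model_report")
}
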