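#' Configuration for the synthetic screen generator
#'
#' Encodes the statistical structure the screening analysis assumes: Poisson
#' cell counts per well at the printed seeding density (10,000 cells/cm^2 on
#' 300 um wells gives a mean of 9 cells/well), a two-component lognormal
#' intensity mixture whose components cross at the 93rd percentile of the
#' negative component, a multiplicative per-chip batch factor, planted
#' High/Low hit surfaces acting on the positive-component weight, and
#' class-conditional cell-shape distributions.
#'
#' @param n_chips Number of chip replicas (default 8).
#' @param seeding_density_cells_per_cm2 Seeding density (default 10000).
#' @param cells_per_well_mean Poisson mean of cells per well. Defaults to
#'   seeding density times well area; if both are supplied they must agree
#'   within 1%.
#' @param well_side_um Well side used for the density-to-count conversion.
#' @param meanlog_neg,meanlog_pos,sdlog Lognormal intensity components
#'   (arbitrary fluorescence units). The defaults (4.0, 5.18, 0.4) put the
#'   component crossing at the 93rd percentile of the negative component.
#' @param baseline_positive_weight Baseline mixture weight of the positive
#'   component (default 0.07).
#' @param pos_control_positive_weight Positive-component weight in the
#'   stimulated positive control (default 0.70).
#' @param chip_scale_sd Lognormal sd of the per-chip multiplicative intensity
#'   batch factor (default 0.15).
#' @param n_planted_high,n_planted_low Number of planted High/Low surfaces
#'   when explicit id sets are not given (defaults 112 and 72).
#' @param planted_high_ids,planted_low_ids Optional explicit unit-id sets;
#'   must be disjoint, present in the layout, and non-flat.
#' @param effect_high,effect_low Additive shifts of the positive weight on
#'   planted surfaces (defaults +0.20 and -0.05); shifted weights are floored
#'   at `weight_floor`.
#' @param weight_floor Lower floor for mixture weights (default 0.005).
#' @param actin_rho Correlation between log actin and log marker intensity
#'   (default 0.5).
#' @param n_control_cells Cells per control condition (default 2000).
#' @param master_seed Master seed; all stage streams derive from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_chips = 8,
                         seeding_density_cells_per_cm2 = 10000,
                         cells_per_well_mean = NULL,
                         well_side_um = 300,
                         meanlog_neg = 4.0, meanlog_pos = 5.18, sdlog = 0.4,
                         baseline_positive_weight = 0.07,
                         pos_control_positive_weight = 0.70,
                         chip_scale_sd = 0.15,
                         n_planted_high = 112, n_planted_low = 72,
                         planted_high_ids = NULL, planted_low_ids = NULL,
                         effect_high = 0.20, effect_low = -0.05,
                         weight_floor = 0.005,
                         actin_rho = 0.5,
                         n_control_cells = 2000,
                         master_seed = 1) {
  derived_mean <- seeding_density_cells_per_cm2 * (well_side_um / 1e4)^2
  if (is.null(cells_per_well_mean)) {
    cells_per_well_mean <- derived_mean
  } else if (abs(cells_per_well_mean - derived_mean) / derived_mean > 0.01) {
    # an explicit per-well mean overrides the density; keep them consistent
    seeding_density_cells_per_cm2 <- cells_per_well_mean / (well_side_um / 1e4)^2
  }
  check_positive_scalar(cells_per_well_mean, "cells_per_well_mean")
  check_positive_scalar(sdlog, "sdlog")
  check_probability(baseline_positive_weight, "baseline_positive_weight")
  check_probability(pos_control_positive_weight, "pos_control_positive_weight")
  check_probability(weight_floor, "weight_floor")
  if (chip_scale_sd < 0) {
    abort("`chip_scale_sd` must be non-negative.",
          class = "toposcreen_config_error")
  }
  if (!is.null(planted_high_ids) && !is.null(planted_low_ids) &&
      length(intersect(planted_high_ids, planted_low_ids)) > 0) {
    abort("planted High and Low id sets must be disjoint.",
          class = "toposcreen_config_error")
  }
  if (abs(actin_rho) > 1) {
    abort("`actin_rho` must be in [-1, 1].", class = "toposcreen_config_error")
  }
  structure(
    list(n_chips = as.integer(n_chips),
         seeding_density_cells_per_cm2 = seeding_density_cells_per_cm2,
         cells_per_well_mean = cells_per_well_mean,
         well_side_um = well_side_um,
         meanlog_neg = meanlog_neg, meanlog_pos = meanlog_pos, sdlog = sdlog,
         baseline_positive_weight = baseline_positive_weight,
         pos_control_positive_weight = pos_control_positive_weight,
         chip_scale_sd = chip_scale_sd,
         n_planted_high = n_planted_high, n_planted_low = n_planted_low,
         planted_high_ids = planted_high_ids,
         planted_low_ids = planted_low_ids,
         effect_high = effect_high, effect_low = effect_low,
         weight_floor = weight_floor, actin_rho = actin_rho,
         n_control_cells = n_control_cells,
         master_seed = as.integer(master_seed)),
    class = "synth_config")
}

# Class-conditional shape model. Groups: flat wells vs topography wells
# crossed with marker-positive vs -negative cells. Latent Gaussian over
# (log area, logit solidity, logit form factor, eccentricity,
# log median radius); perimeter is derived from area and form factor so the
# four are mutually consistent. Orderings encoded: cells on flat surfaces are
# large and spread (largest form factor); marker-negative cells on
# topographies are the thinnest and most eccentric.
shape_model_params <- function() {
  groups <- list(
    flat_neg = c(la = 8.0, ls = 1.8, lf = -0.1, ec = 0.70, lr = 2.30),
    flat_pos = c(la = 8.0, ls = 1.8, lf = -0.2, ec = 0.72, lr = 2.30),
    topo_neg = c(la = 7.5, ls = 0.8, lf = -1.6, ec = 0.92, lr = 1.60),
    topo_pos = c(la = 7.6, ls = 1.0, lf = -1.2, ec = 0.85, lr = 1.90)
  )
  sds <- c(la = 0.35, ls = 0.40, lf = 0.50, ec = 0.06, lr = 0.30)
  # correlations capped at |rho| <= 0.7
  cm <- diag(5)
  dimnames(cm) <- list(names(sds), names(sds))
  cm["ec", "lf"] <- cm["lf", "ec"] <- -0.6
  cm["ec", "ls"] <- cm["ls", "ec"] <- -0.3
  cm["la", "lr"] <- cm["lr", "la"] <- 0.6
  list(groups = groups, sds = sds, chol = chol(cm))
}

# draw n correlated latent shape vectors for one group
draw_shapes <- function(n, mu, sds, cholR) {
  z <- matrix(rnorm(n * 5), n, 5) %*% cholR
  sweep(sweep(z, 2, sds, `*`), 2, mu, `+`)
}

shapes_to_features <- function(lat) {
  area <- exp(lat[, "la"])
  ff <- inv_logit(lat[, "lf"])
  ecc <- pmin(pmax(lat[, "ec"], 0), 0.999)
  tibble::tibble(
    area_um2 = area,
    perimeter_um = sqrt(4 * pi * area / ff),
    form_factor = ff,
    solidity = inv_logit(lat[, "ls"]),
    eccentricity = ecc,
    median_radius_um = exp(lat[, "lr"])
  )
}

# choose planted hit surfaces from archetype-classified design features
select_planted_ids <- function(config, features, layout_ids, flat_id) {
  if (!is.null(config$planted_high_ids) && !is.null(config$planted_low_ids)) {
    return(config)
  }
  if (config$n_planted_high == 0 && config$n_planted_low == 0) {
    config$planted_high_ids <- config$planted_high_ids %||% character(0)
    config$planted_low_ids <- config$planted_low_ids %||% character(0)
    return(config)
  }
  if (is.null(features)) {
    abort(paste0("`features` are required to draw planted hit surfaces; ",
                 "pass design features or explicit planted id sets."),
          class = "toposcreen_config_error")
  }
  fa <- classify_design_archetype(features)
  fa <- fa[fa$unit_id %in% layout_ids & fa$unit_id != flat_id, ]
  pick <- function(pool, n, label) {
    if (length(pool) < n) {
      warn(sprintf(
        "only %d %s archetype designs available; planting %d instead of %d.",
        length(pool), label, length(pool), n))
      n <- length(pool)
    }
    sample(pool, n)
  }
  with_stage_seed(config$master_seed, "plant", {
    high <- pick(fa$unit_id[fa$archetype == "high_like"],
                 config$n_planted_high, "high_like")
    low <- pick(setdiff(fa$unit_id[fa$archetype == "low_like"], high),
                config$n_planted_low, "low_like")
    config$planted_high_ids <- high
    config$planted_low_ids <- low
  })
  config
}

#' Simulate a full synthetic screen
#'
#' Generates per-cell records for `n_chips` chip replicas of the given layout:
#' Poisson cell counts per well, latent marker-positive class with weight
#' `baseline + planted effect`, lognormal mixture intensities scaled by a
#' per-chip batch factor, class-conditional shape features, and a correlated
#' actin intensity. Off-chip negative/positive control samples are generated
#' alongside. Fully reproducible from `master_seed`.
#'
#' @param config A [synth_config()].
#' @param layout A [build_chip_layout()] layout shared by all chips.
#' @param features Design features from [design_features()]; required when
#'   planted id sets are not given explicitly (hits are drawn from the
#'   high-like / low-like archetypes).
#' @return A `screen_dataset` list: `cells` (one row per cell), `controls`,
#'   `wells` (per-well index incl. zero-cell wells), `layout`, `planted`
#'   (tibble of planted surfaces), and `config` with planted ids filled in.
#' @export
simulate_screen <- function(config, layout, features = NULL) {
  stopifnot(inherits(config, "synth_config"), inherits(layout, "chip_layout"))
  meta <- attr(layout, "layout_meta")
  layout_ids <- unique(layout$unit_id)
  config <- select_planted_ids(config, features, layout_ids, meta$flat_id)
  planted <- c(config$planted_high_ids, config$planted_low_ids)
  bad <- setdiff(planted, setdiff(layout_ids, meta$flat_id))
  if (length(bad) > 0) {
    abort(sprintf("planted unit id `%s` is not a patterned unit of the layout.",
                  bad[[1]]), class = "toposcreen_config_error")
  }

  effect <- setNames(rep(0, length(layout_ids)), layout_ids)
  effect[config$planted_high_ids] <- config$effect_high
  effect[config$planted_low_ids] <- config$effect_low

  chips <- sprintf("chip%02d", seq_len(config$n_chips))
  wells <- tidyr::expand_grid(chip_id = chips,
                              tibble::as_tibble(layout[c("row", "col", "unit_id")]))
  wells$n_cells <- with_stage_seed(config$master_seed, "counts",
    rpois(nrow(wells), config$cells_per_well_mean))

  chip_scale <- with_stage_seed(config$master_seed, "chips",
    setNames(rlnorm(config$n_chips, 0, config$chip_scale_sd), chips))

  cells <- tidyr::uncount(wells, weight = .data$n_cells)
  w_pos <- pmin(pmax(config$baseline_positive_weight +
                       effect[cells$unit_id], config$weight_floor), 1)
  cells$true_class <- with_stage_seed(config$master_seed, "class",
    ifelse(rbinom(nrow(cells), 1L, w_pos) == 1L, "pos", "neg"))

  meanlog <- ifelse(cells$true_class == "pos",
                    config$meanlog_pos, config$meanlog_neg)
  cells$icam1_median_intensity <- with_stage_seed(config$master_seed, "intensity",
    rlnorm(nrow(cells), meanlog, config$sdlog)) * chip_scale[cells$chip_id]

  # shape features by (flat/topo x neg/pos) group
  smp <- shape_model_params()
  grp <- paste0(ifelse(cells$unit_id == meta$flat_id, "flat_", "topo_"),
                cells$true_class)
  shp <- with_stage_seed(config$master_seed, "shape", {
    out <- vector("list", length(smp$groups))
    names(out) <- names(smp$groups)
    for (g in names(smp$groups)) {
      idx <- which(grp == g)
      if (length(idx) == 0) next
      lat <- draw_shapes(length(idx), smp$groups[[g]], smp$sds, smp$chol)
      colnames(lat) <- names(smp$sds)
      out[[g]] <- cbind(idx = idx, lat)
    }
    do.call(rbind, out)
  })
  ord <- order(shp[, "idx"])
  cells <- dplyr::bind_cols(cells, shapes_to_features(shp[ord, , drop = FALSE]))

  # actin correlated with the marker on the log scale
  zi <- as.numeric(scale(log(cells$icam1_median_intensity)))
  rho <- config$actin_rho
  cells$actin_intensity <- with_stage_seed(config$master_seed, "actin",
    exp(5 + 0.4 * (rho * zi + sqrt(1 - rho^2) * rnorm(nrow(cells)))))

  cells$cell_id <- sprintf("%s_r%02dc%02d_%04d", cells$chip_id,
                           cells$row, cells$col,
                           stats::ave(seq_len(nrow(cells)),
                                      cells$chip_id, cells$row, cells$col,
                                      FUN = seq_along))
  cell_cols <- c("chip_id", "row", "col", "unit_id", "cell_id", "area_um2",
                 "perimeter_um", "form_factor", "solidity", "eccentricity",
                 "median_radius_um", "icam1_median_intensity",
                 "actin_intensity", "true_class")
  cells <- cells[cell_cols]

  controls <- simulate_controls(config, n_cells = config$n_control_cells)

  planted_tbl <- tibble::tibble(
    unit_id = c(config$planted_high_ids, config$planted_low_ids),
    planted_class = rep(c("High", "Low"),
                        c(length(config$planted_high_ids),
                          length(config$planted_low_ids))))

  structure(
    list(cells = tibble::as_tibble(cells), controls = controls,
         wells = wells, layout = layout, planted = planted_tbl,
         chip_scale = chip_scale, config = config),
    class = "screen_dataset")
}

#' Simulate off-chip control samples
#'
#' The negative control is unstimulated cells on flat polystyrene (positive
#' weight = baseline); the positive control is cytokine-stimulated cells
#' (positive weight = `pos_control_positive_weight`). Both share the screen's
#' intensity components; no chip batch factor applies (the controls are
#' off-chip cultures).
#'
#' @param config A [synth_config()].
#' @param n_cells Cells per condition (at least 100; calibration is unstable
#'   below that).
#' @param seed Optional seed override; defaults to a stream derived from the
#'   config's master seed.
#' @return A tibble with columns `condition` (`"neg"`/`"pos"`), `cell_id`,
#'   `icam1_median_intensity`.
#' @export
simulate_controls <- function(config, n_cells = config$n_control_cells,
                              seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (n_cells < 100) {
    abort("`n_cells` must be at least 100 per condition (calibration unstable).",
          class = "toposcreen_config_error")
  }
  seed <- seed %||% derive_seed(config$master_seed, "controls")
  withr::with_seed(seed, {
    draw <- function(n, w) {
      pos <- rbinom(n, 1L, w) == 1L
      rlnorm(n, ifelse(pos, config$meanlog_pos, config$meanlog_neg),
             config$sdlog)
    }
    tibble::tibble(
      condition = rep(c("neg", "pos"), each = n_cells),
      cell_id = sprintf("%s_%05d", rep(c("neg", "pos"), each = n_cells),
                        rep(seq_len(n_cells), 2)),
      icam1_median_intensity = c(
        draw(n_cells, config$baseline_positive_weight),
        draw(n_cells, config$pos_control_positive_weight)))
  })
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf(
    "<screen_dataset> %d cells on %d chips (%d wells/chip), %d planted hits\n",
    nrow(x$cells), x$config$n_chips,
    nrow(x$layout), nrow(x$planted)))
  invisible(x)
}
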