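# Chi-square hit calling of High/Low surfaces against pooled flat controls.

# 2x2 chi-square without continuity correction, from the closed-form
# statistic; falls back to Fisher's exact test when any expected count is
# below `fisher_threshold`.
test_2x2 <- function(pos1, neg1, pos2, neg2, fisher_threshold = 5) {
  pos1 <- as.numeric(pos1); neg1 <- as.numeric(neg1)
  pos2 <- as.numeric(pos2); neg2 <- as.numeric(neg2)
  n <- pos1 + neg1 + pos2 + neg2
  r1 <- pos1 + neg1; r2 <- pos2 + neg2
  c1 <- pos1 + pos2; c2 <- neg1 + neg2
  if (r1 == 0 || n == 0) {
    return(list(stat = 0, p = 1, method = "none"))
  }
  expected <- c(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / n
  if (any(expected < fisher_threshold)) {
    p <- fisher.test(matrix(c(pos1, pos2, neg1, neg2), 2))$p.value
    return(list(stat = NA_real_, p = p, method = "fisher"))
  }
  stat <- n * (pos1 * neg2 - neg1 * pos2)^2 / (r1 * r2 * c1 * c2)
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE),
       method = "chisq")
}

#' Call High/Low hit surfaces by chi-square against flat controls
#'
#' Pools each unique patterned surface's positive/negative cell counts over
#' all its replica wells and tests them in a 2x2 chi-square (no continuity
#' correction) against the pooled counts of the on-chip flat control wells.
#' A surface is `High` when its positive fraction exceeds the flat reference
#' fraction with `p < alpha`, `Low` when below with `p < alpha`, otherwise
#' `NS`. Benjamini-Hochberg adjusted p-values are reported alongside; by
#' default classes are gated on the raw p-value, with `adjusted = TRUE`
#' switching the gate to the adjusted one. When any expected count is below
#' 5 the surface is tested with Fisher's exact test instead (recorded in the
#' `method` column). Surfaces present in the layout but without any cells
#' are classed `NS` with `p = 1` and ranked last.
#'
#' @param cells Flagged cell table from [apply_threshold()] (needs `unit_id`
#'   and `icam1_positive`).
#' @param layout The [build_chip_layout()] layout (defines the surface set
#'   and the flat control id).
#' @param alpha Significance level (default 0.05, the raw gate).
#' @param adjusted Gate classes on the BH-adjusted p-value instead.
#' @param pooling `"pooled"` (default) ranks surfaces by the pooled positive
#'   fraction; `"replica_mean"` ranks by the mean of per-replica-well
#'   fractions (the chi-square is always computed on pooled counts).
#' @param min_reference_cells Minimum pooled flat-well cell count.
#' @return A `topo_hit_table` tibble sorted by decreasing positive fraction
#'   with columns `unit_id`, `n_cells`, `n_pos`, `pos_fraction`,
#'   `chi2_stat`, `p_value`, `p_adj`, `class`, `rank`, `method`. Reference
#'   counts and the settings are attached as attributes.
#' @export
call_hits <- function(cells, layout, alpha = 0.05, adjusted = FALSE,
                      pooling = c("pooled", "replica_mean"),
                      min_reference_cells = 30) {
  pooling <- match.arg(pooling)
  check_columns(cells, c("unit_id", "icam1_positive"), "cells")
  meta <- attr(layout, "layout_meta")
  flat_id <- meta$flat_id

  flat <- cells[cells$unit_id == flat_id, ]
  ref_pos <- sum(flat$icam1_positive)
  ref_neg <- sum(!flat$icam1_positive)
  if (ref_pos + ref_neg < min_reference_cells) {
    abort(sprintf(
      "reference flat wells pool only %d cells (need >= %d).",
      ref_pos + ref_neg, min_reference_cells),
      class = "toposcreen_config_error")
  }
  ref_fraction <- ref_pos / (ref_pos + ref_neg)

  surfaces <- setdiff(unique(layout$unit_id), flat_id)
  counts <- cells[cells$unit_id != flat_id, ] |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_pos = sum(.data$icam1_positive), .groups = "drop")
  counts <- dplyr::left_join(tibble::tibble(unit_id = surfaces), counts,
                             by = "unit_id") |>
    dplyr::mutate(n_cells = dplyr::coalesce(.data$n_cells, 0L),
                  n_pos = dplyr::coalesce(.data$n_pos, 0L),
                  pos_fraction = ifelse(.data$n_cells > 0,
                                        .data$n_pos / .data$n_cells, NA_real_))

  tests <- purrr::pmap(list(counts$n_pos, counts$n_cells - counts$n_pos),
                       function(p1, n1) {
                         test_2x2(p1, n1, ref_pos, ref_neg)
                       })
  counts$chi2_stat <- vapply(tests, function(t) t$stat, 0)
  counts$p_value <- vapply(tests, function(t) t$p, 0)
  counts$method <- vapply(tests, function(t) t$method, "")
  counts$p_adj <- p.adjust(counts$p_value, method = "BH")

  gate_p <- if (adjusted) counts$p_adj else counts$p_value
  counts$class <- factor(ifelse(
    counts$n_cells == 0 | gate_p >= alpha, "NS",
    ifelse(counts$pos_fraction > ref_fraction, "High",
           ifelse(counts$pos_fraction < ref_fraction, "Low", "NS"))),
    levels = c("High", "Low", "NS"))

  if (pooling == "replica_mean") {
    rep_frac <- cells[cells$unit_id != flat_id, ] |>
      dplyr::group_by(.data$unit_id, .data$chip_id, .data$row, .data$col) |>
      dplyr::summarise(f = mean(.data$icam1_positive), .groups = "drop") |>
      dplyr::group_by(.data$unit_id) |>
      dplyr::summarise(pos_fraction_rep = mean(.data$f), .groups = "drop")
    counts <- dplyr::left_join(counts, rep_frac, by = "unit_id")
    rank_key <- counts$pos_fraction_rep
  } else {
    rank_key <- counts$pos_fraction
  }
  # zero-cell surfaces rank last; ties broken by unit id
  ord <- order(-replace(rank_key, is.na(rank_key), -Inf), counts$unit_id)
  counts <- counts[ord, ]
  counts$rank <- seq_len(nrow(counts))

  counts <- counts[c("unit_id", "n_cells", "n_pos", "pos_fraction",
                     "chi2_stat", "p_value", "p_adj", "class", "rank",
                     "method",
                     intersect("pos_fraction_rep", names(counts)))]
  class(counts) <- c("topo_hit_table", class(counts))
  attr(counts, "hit_meta") <- list(
    alpha = alpha, adjusted = adjusted, pooling = pooling,
    reference = "on_chip_flat",
    ref_pos = ref_pos, ref_neg = ref_neg, ref_fraction = ref_fraction)
  counts
}

#' @export
print.topo_hit_table <- function(x, ...) {
  meta <- attr(x, "hit_meta")
  tab <- table(x$class)
  cat(sprintf(
    "<topo_hit_table> %d surfaces: %d High, %d Low, %d NS (alpha = %g%s, reference fraction %.4f)\n",
    nrow(x), tab[["High"]], tab[["Low"]], tab[["NS"]], meta$alpha,
    if (meta$adjusted) ", BH-adjusted" else "", meta$ref_fraction))
  NextMethod()
}

#' @export
glance.topo_hit_table <- function(x, ...) {
  meta <- attr(x, "hit_meta")
  tibble::tibble(
    n_surfaces = nrow(x),
    n_high = sum(x$class == "High"),
    n_low = sum(x$class == "Low"),
    n_ns = sum(x$class == "NS"),
    alpha = meta$alpha,
    adjusted = meta$adjusted,
    reference_fraction = meta$ref_fraction)
}
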