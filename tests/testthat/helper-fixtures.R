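# Shared fixtures, memoised so expensive objects build once per test run.

.ts_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.ts_cache[[key]])) .ts_cache[[key]] <- force(expr)
  .ts_cache[[key]]
}

# --- small objects for module tests ----------------------------------------

ts_catalog16 <- function() memo("catalog16",
  topo_design_catalog(n_designs = 16, master_seed = 11))

ts_layout6 <- function() memo("layout6",
  build_chip_layout(ts_catalog16(), seed = 2, n_rows = 6, n_cols = 6))

ts_features16 <- function() memo("features16",
  design_features(ts_catalog16(), resolution_um = 1))

# a small planted screen: 16 designs, 6x6 grid, 4 high + 3 low planted
ts_small_screen <- function() memo("small_screen", {
  fa <- classify_design_archetype(ts_features16())
  nonflat <- fa$unit_id[!fa$is_flat]
  cfg <- synth_config(
    planted_high_ids = head(nonflat, 4),
    planted_low_ids = nonflat[5:7],
    n_planted_high = 4, n_planted_low = 3,
    cells_per_well_mean = 30, # denser wells keep per-chip counts stable
    master_seed = 21)
  simulate_screen(cfg, ts_layout6(), ts_features16())
})

# --- full-scale objects for the acceptance suite ---------------------------

ts_full_catalog <- function() memo("full_catalog",
  topo_design_catalog(n_designs = 2176, master_seed = 101))

ts_full_features <- function() memo("full_features",
  design_features(ts_full_catalog(), resolution_um = 1))

ts_full_layout <- function() memo("full_layout",
  build_chip_layout(ts_full_catalog(), seed = 101))

# the default planted screen under the study conditions
ts_default_screen <- function() memo("default_screen",
  simulate_screen(synth_config(master_seed = 101), ts_full_layout(),
                  ts_full_features()))

# default screen carried through QC and thresholding at the calibrated 93
ts_default_flagged <- function() memo("default_flagged", {
  ds <- ts_default_screen()
  qc <- qc_filter(ds$cells)
  apply_threshold(qc$cells, 93)
})
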