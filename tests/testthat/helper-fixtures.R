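# Shared fixtures, built in code at test time.

# Independent 5PL arithmetic used to generate truth curves for recovery
# tests (kept separate from the package's eval_5pl on purpose).
ref_5pl <- function(x, b, cc, d, e, f) {
  cc + (d - cc) / (1 + exp(b * (log(x) - log(e))))^f
}

# Tiny long-format melt export written to a temp file.
write_toy_export <- function(df, path = tempfile(fileext = ".txt"),
                             delim = "\t") {
  readr::write_delim(df, path, delim = delim)
  path
}

toy_export_df <- function() {
  grid <- expand.grid(well = c("A1", "A2", "B1"),
                      temperature = seq(40, 44, 1),
                      stringsAsFactors = FALSE)
  grid$fluorescence <- seq_len(nrow(grid)) * 1.5
  grid[order(grid$well, grid$temperature), ]
}

# 4-record toy plate map (2 compounds, 2 DMSO) as a tibble ready for the
# package's own SDF/CSV writers.
toy_map <- function(plate_id = "10001") {
  map <- tibble::tibble(
    compound_id = c("CMPD-1", "CMPD-2", "DMSO", "DMSO"),
    plate_id = plate_id,
    row = c(1L, 2L, 3L, 4L),
    column = c(1L, 2L, 3L, 4L),
    well = c("A1", "B2", "C3", "D4"),
    smiles = c("c1ccccc1", "CCO", NA, NA),
    Batch = c("B-7", "B-8", NA, NA))
  meltshift:::finish_platemap(map, "DMSO", source = "test")
}

# Small clean simulated plate shared across tests (96-well keeps fits fast).
small_sim <- function(seed = 101, ...) {
  spec <- sim_spec(geometry = "96", n_controls = 8, n_hits = 4,
                   noise_sd = 2, seed = seed, ...)
  simulate_plate(spec)
}
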