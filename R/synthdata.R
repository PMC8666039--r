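#' Specification for a simulated thermal shift plate
#'
#' Describes a ground-truth-labelled differential scanning fluorimetry
#' plate: geometry, temperature ramp, the true 5PL melting model, control
#' layout, hit compounds and injected anomalies. Each well's raw
#' fluorescence is
#' `baseline + amplitude * 5PL(t; e_well) - decline_slope * max(0, t - t_peak) + noise`,
#' emulating the canonical melt-curve anatomy: a flat pretransition region,
#' a steep sigmoidal unfolding region, and (when `decline_slope > 0`) a
#' post-peak aggregation decline. Wells are parameterized by their target
#' midpoint Tm: since the 5PL midpoint is `e` times a factor depending only
#' on (b, f), the generator back-solves `e_well = Tm_well / k(b, f)` so that
#' configured shifts are exact midpoint-Tm shifts.
#'
#' Control wells receive Gaussian per-well Tm jitter of SD
#' `tm_sigma_control` (assay-level variability as measured on the DMSO
#' wells); sample wells apply their configured shift exactly unless
#' `tm_sigma_sample > 0`.
#'
#' @param geometry Plate geometry, `"384"` (default) or `"96"`.
#' @param t_start,t_end,t_step Temperature ramp in degrees C (default
#'   25-95 at 0.5, a common qPCR melt program; 141 points).
#' @param plate_id Plate identifier written to the plate map.
#' @param n_controls Number of DMSO control wells (default 32), placed in
#'   the first and last plate columns unless `control_wells` is given.
#' @param control_wells Optional explicit control well labels.
#' @param n_hits Number of hit compounds (default 16).
#' @param hit_shift True midpoint-Tm shift of hit compounds in degrees C
#'   (default +2).
#' @param tm_base True control midpoint Tm, degrees C (default 50).
#' @param b,c5,d5,f True 5PL slope, asymptotes and asymmetry factor of the
#'   normalized melt (defaults b = -12, c5 = 0, d5 = 1, f = 1.3).
#' @param baseline,amplitude Raw fluorescence offset and amplitude
#'   (defaults 50 and 1000 arbitrary units).
#' @param noise_sd Additive i.i.d. Gaussian fluorescence noise SD
#'   (default 2, i.e. 0.2% of amplitude).
#' @param tm_sigma_control,tm_sigma_sample Per-well Tm jitter SD for
#'   control / sample wells (defaults 0.2 and 0).
#' @param decline_slope Post-peak aggregation decline, fluorescence units
#'   per degree C (default 0 = no decline).
#' @param peak_offset Degrees C above the inflection point where the
#'   aggregation decline starts (default 8).
#' @param anomalies List of injected pathologies, each a list with `well`
#'   and `kind` in `"flat"`, `"inverted"`, `"spike"`; spikes take `position`
#'   (index, default mid-ramp) and either `magnitude` (fluorescence units)
#'   or `spike_factor` (multiple of the well's mean absolute step,
#'   default 100).
#' @param seed Mandatory RNG seed; all outputs are deterministic given it.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(geometry = "384",
                     t_start = 25, t_end = 95, t_step = 0.5,
                     plate_id = "10001",
                     n_controls = 32, control_wells = NULL,
                     n_hits = 16, hit_shift = 2,
                     tm_base = 50,
                     b = -12, c5 = 0, d5 = 1, f = 1.3,
                     baseline = 50, amplitude = 1000,
                     noise_sd = 2,
                     tm_sigma_control = 0.2, tm_sigma_sample = 0,
                     decline_slope = 0, peak_offset = 8,
                     anomalies = list(),
                     seed) {
  if (missing(seed)) stop("a seed is mandatory for the simulator", call. = FALSE)
  ramp <- seq(t_start, t_end, by = t_step)
  stopifnot(length(ramp) >= 20, n_controls >= 2)
  geo <- plate_geometry(geometry)
  all_wells <- as.vector(t(outer(seq_len(geo$rows), seq_len(geo$columns),
                                 well_label)))
  if (is.null(control_wells)) {
    edge <- c(well_label(seq_len(geo$rows), 1L),
              well_label(seq_len(geo$rows), geo$columns))
    control_wells <- edge[seq_len(min(n_controls, length(edge)))]
    if (length(control_wells) < n_controls) {
      more <- setdiff(all_wells, control_wells)
      control_wells <- c(control_wells,
                         more[seq_len(n_controls - length(control_wells))])
    }
  }
  structure(list(geometry = as.character(geometry), ramp = ramp,
                 plate_id = plate_id,
                 control_wells = control_wells, n_hits = n_hits,
                 hit_shift = hit_shift, tm_base = tm_base,
                 b = b, c5 = c5, d5 = d5, f = f,
                 baseline = baseline, amplitude = amplitude,
                 noise_sd = noise_sd,
                 tm_sigma_control = tm_sigma_control,
                 tm_sigma_sample = tm_sigma_sample,
                 decline_slope = decline_slope, peak_offset = peak_offset,
                 anomalies = anomalies, seed = as.integer(seed),
                 all_wells = all_wells),
            class = "sim_spec")
}

# midpoint Tm of the 5PL equals e * tm_factor(b, f)
tm_factor <- function(b, f) {
  1 / exp(-(1 / b) * log(2^(1 / f) - 1))
}

#' Simulate one well's melting curve
#'
#' Draws the raw fluorescence trace for a single well under a [sim_spec()],
#' applying the configured Tm shift, per-well jitter, aggregation decline,
#' noise and optional anomaly. Uses the current RNG state; seed via
#' [simulate_plate()] or `set.seed()` for reproducibility.
#'
#' @param spec A `sim_spec`.
#' @param well Well label.
#' @param shift True Tm shift in degrees C (0 for controls/inactives).
#' @param role `"sample"` or `"control"` (selects the Tm jitter SD).
#' @param anomaly Optional anomaly descriptor (see [sim_spec()]).
#' @return A list with `curve` (tibble `well`, `row`, `column`,
#'   `temperature`, `fluorescence`) and `truth` (one-row tibble with the
#'   exact generating parameters and true midpoint Tm).
#' @export
simulate_curve <- function(spec, well, shift = 0, role = "sample",
                           anomaly = NULL) {
  t <- spec$ramp
  addr <- parse_well_label(well, spec$geometry)
  jitter_sd <- if (role == "control") spec$tm_sigma_control else spec$tm_sigma_sample
  tm_true <- spec$tm_base + shift +
    if (jitter_sd > 0) stats::rnorm(1, 0, jitter_sd) else 0
  kind <- if (is.null(anomaly)) "none" else anomaly$kind

  if (kind == "flat") {
    signal <- rep(0, length(t))
    tm_true <- NA_real_
  } else if (kind == "inverted") {
    # high initial fluorescence decaying with temperature: mirrored sigmoid
    p_inv <- c(b = -spec$b, c = spec$c5, d = spec$d5,
               e = tm_true / tm_factor(-spec$b, spec$f), f = spec$f)
    signal <- spec$amplitude * eval_5pl(t, p_inv)
    tm_true <- NA_real_
  } else {
    e_well <- tm_true / tm_factor(spec$b, spec$f)
    p <- c(b = spec$b, c = spec$c5, d = spec$d5, e = e_well, f = spec$f)
    signal <- spec$amplitude * eval_5pl(t, p)
    if (spec$decline_slope > 0) {
      t_peak <- e_well + spec$peak_offset
      signal <- signal - spec$decline_slope * pmax(0, t - t_peak)
    }
  }

  fluor <- spec$baseline + signal +
    if (spec$noise_sd > 0) stats::rnorm(length(t), 0, spec$noise_sd) else 0

  spike_mag <- NA_real_
  if (kind == "spike") {
    pos <- if (!is.null(anomaly$position)) anomaly$position
           else floor(length(t) / 2)
    spike_mag <- if (!is.null(anomaly$magnitude)) {
      anomaly$magnitude
    } else {
      factor <- if (!is.null(anomaly$spike_factor)) anomaly$spike_factor else 100
      factor * mean(abs(diff(fluor)))
    }
    fluor[pos] <- fluor[pos] + spike_mag
  }

  curve <- tibble::tibble(well = addr$well, row = addr$row,
                          column = addr$column, temperature = t,
                          fluorescence = fluor)
  truth <- tibble::tibble(well = addr$well, role = role, shift = shift,
                          true_tm = tm_true, anomaly = kind,
                          spike_magnitude = spike_mag)
  list(curve = curve, truth = truth)
}

#' Simulate a full plate and write its files
#'
#' Generates every well of the plate under the spec, assigns compound
#' identifiers (`DMSO` for controls, `CMPD-0001`... for samples, hit
#' compounds drawn reproducibly from the sample wells) and writes the raw
#' melt export in the instrument dialect, the plate map as both SDF and
#' CSV, and a ground-truth table. All randomness is governed by
#' `spec$seed`; outputs are byte-identical across runs.
#'
#' @param spec A `sim_spec`.
#' @param dir Output directory (created if needed); `NULL` skips writing.
#' @return A list with tibbles `curves`, `map`, `truth` and (when `dir` is
#'   given) file paths `raw_path`, `sdf_path`, `csv_path`, `truth_path`.
#' @export
simulate_plate <- function(spec, dir = NULL) {
  set.seed(spec$seed)
  geo <- plate_geometry(spec$geometry)
  wells <- spec$all_wells
  roles <- ifelse(wells %in% spec$control_wells, "control", "sample")
  sample_wells <- wells[roles == "sample"]
  hit_wells <- sort(sample(sample_wells, spec$n_hits))
  anomaly_by_well <- stats::setNames(
    lapply(spec$anomalies, identity),
    vapply(spec$anomalies, function(a) a$well, character(1)))

  compound_ids <- character(length(wells))
  compound_ids[roles == "control"] <- "DMSO"
  compound_ids[roles == "sample"] <-
    sprintf("CMPD-%04d", seq_along(sample_wells))

  out <- vector("list", length(wells))
  for (i in seq_along(wells)) {
    w <- wells[i]
    shift <- if (roles[i] == "sample" && w %in% hit_wells) spec$hit_shift else 0
    out[[i]] <- simulate_curve(spec, w, shift = shift, role = roles[i],
                               anomaly = anomaly_by_well[[w]])
  }
  curves <- dplyr::bind_rows(lapply(out, `[[`, "curve"))
  class(curves) <- c("melt_curves", class(curves))
  attr(curves, "geometry") <- spec$geometry
  truth <- dplyr::bind_rows(lapply(out, `[[`, "truth"))
  truth$compound_id <- compound_ids

  addr <- parse_well_label(wells, spec$geometry)
  smiles_pool <- c("c1ccccc1", "CCO", "CC(=O)Oc1ccccc1C(=O)O", "CCN(CC)CC",
                   "c1ccncc1", "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "OCC(O)CO",
                   "Clc1ccc(Cl)cc1")
  smiles <- rep(NA_character_, length(wells))
  smiles[roles == "sample"] <-
    smiles_pool[(seq_along(sample_wells) - 1L) %% length(smiles_pool) + 1L]
  map <- tibble::tibble(compound_id = compound_ids,
                        plate_id = spec$plate_id,
                        row = addr$row, column = addr$column,
                        well = wells, smiles = smiles)
  map <- finish_platemap(map, "DMSO", source = "simulated")

  result <- list(curves = curves, map = map, truth = truth,
                 hit_wells = hit_wells)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    result$raw_path <- file.path(dir, paste0("plate_", spec$plate_id, ".txt"))
    write_melt_export(curves, result$raw_path)
    result$sdf_path <- file.path(dir, paste0("platemap_", spec$plate_id, ".sdf"))
    write_platemap_sdf(map, result$sdf_path, control_smiles = "CS(C)=O")
    result$csv_path <- file.path(dir, paste0("platemap_", spec$plate_id, ".csv"))
    write_platemap_csv(map, result$csv_path)
    result$truth_path <- file.path(dir, paste0("truth_", spec$plate_id, ".csv"))
    readr::write_csv(truth, result$truth_path, progress = FALSE)
  }
  result
}
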