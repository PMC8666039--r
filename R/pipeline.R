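#' Process one plate end to end
#'
#' The full analysis chain: parse the raw melt export, join the plate map,
#' crop to the fitting window, QC-flag pathological wells, smooth /
#' normalize / trim each accepted well, fit the 5-parameter log-logistic
#' model, derive midpoint melting temperatures, call hits against the DMSO
#' control variability, and write the annotated SDF/CSV results, the
#' multi-sheet XLSX report, the plate heatmap and the diagnostic overlay
#' plots. Per-stage well counts are logged via `message()`.
#'
#' @param data_path Raw melt export (delimited text, long format).
#' @param map_path Plate map path (`.sdf` or `.csv`).
#' @param plate_id Plate identifier to join on.
#' @param window Numeric `c(t_low, t_high)` fitting window in degrees C.
#' @param signal_threshold Minimum fluorescence range for a well to be
#'   fittable.
#' @param map_format `"auto"` (by extension), `"sdf"` or `"csv"`.
#' @param column_map,delim,skip,geometry Passed to [read_melt_export()].
#' @param spike_multiplier Discontinuity threshold (default 25).
#' @param smoothing_points Moving-average window (default 21, odd).
#' @param control_id Control compound token (default `"DMSO"`).
#' @param hit_multiplier Hit threshold multiplier (default 3).
#' @param two_sided Two-sided |delta Tm| hit rule (default `TRUE`).
#' @param out_dir Output directory; `NULL` disables all file output.
#' @param plots Write diagnostic and per-well PNGs (default `TRUE` when
#'   `out_dir` is set).
#' @param strict Promote plate-map orphans to errors.
#' @return A `plate_result` (invisibly when writing files), with attribute
#'   `counts` recording wells in, flagged, fitted, converged and hits.
#' @export
run_process <- function(data_path, map_path, plate_id, window,
                        signal_threshold,
                        map_format = c("auto", "sdf", "csv"),
                        column_map = c(well = "well",
                                       temperature = "temperature",
                                       fluorescence = "fluorescence"),
                        delim = "\t", skip = 0, geometry = "384",
                        spike_multiplier = 25, smoothing_points = 21,
                        control_id = "DMSO", hit_multiplier = 3,
                        two_sided = TRUE,
                        out_dir = NULL, plots = !is.null(out_dir),
                        strict = FALSE) {
  map_format <- match.arg(map_format)
  if (map_format == "auto") {
    map_format <- if (grepl("\\.sdf$", map_path, ignore.case = TRUE))
      "sdf" else "csv"
  }
  stopifnot(length(window) == 2, window[1] < window[2],
            signal_threshold >= 0, spike_multiplier > 0,
            smoothing_points %% 2 == 1, hit_multiplier >= 0)

  curves <- read_melt_export(data_path, column_map = column_map,
                             delim = delim, skip = skip, geometry = geometry)
  map <- if (map_format == "sdf") {
    read_sdf_platemap(map_path, control_id = control_id, geometry = geometry)
  } else {
    read_csv_platemap(map_path, control_id = control_id, geometry = geometry)
  }
  joined <- join_platemap(curves, map, plate_id, strict = strict)
  ann <- joined$annotated
  message("wells in: ", length(unique(ann$well)),
          " (orphan wells: ", length(joined$orphan_wells),
          ", orphan entries: ", length(joined$orphan_entries), ")")

  cropped <- crop_window(ann, window[1], window[2])
  qc <- qc_plate(cropped, signal_threshold = signal_threshold,
                 spike_multiplier = spike_multiplier)
  message("QC-flagged: ", sum(!qc$report$accepted))

  processed <- preprocess_plate(qc$accepted,
                                smoothing_points = smoothing_points)
  fits <- fit_plate(processed)
  message("fitted: ", nrow(fits), "; converged: ", sum(fits$converged))

  entries <- map[map$plate_id == as.character(plate_id), ]
  fits_ann <- dplyr::left_join(
    fits, entries[, c("well", "compound_id", "role")], by = "well")
  controls <- control_stats(fits_ann, control_id = control_id,
                            multiplier = hit_multiplier)
  compounds <- aggregate_replicates(
    fits_ann[fits_ann$role == "sample", , drop = FALSE])
  hits <- call_hits(compounds, controls, two_sided = two_sided)
  message("hit compounds: ", sum(hits$hit))

  result <- plate_result(plate_id, map, qc$report, fits, hits, controls)
  attr(result, "counts") <- c(wells_in = length(unique(ann$well)),
                              flagged = sum(!qc$report$accepted),
                              fitted = nrow(fits),
                              converged = sum(fits$converged),
                              hits = sum(hits$hit))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stem <- tools::file_path_sans_ext(basename(data_path))
    out <- function(ext) file.path(out_dir, paste0(stem, ext))
    if (map_format == "sdf") write_results_sdf(result, out(".sdf"))
    write_results_csv(result, out(".csv"))
    write_qc_report(qc$report, out("_qc.csv"))

    fit_plot_paths <- NULL
    overlay_paths <- NULL
    if (plots) {
      plot_dir <- file.path(out_dir, paste0(stem, "_plots"))
      dir.create(plot_dir, showWarnings = FALSE)
      low <- qc$report$well[grepl("LOW_SIGNAL", qc$report$flags)]
      anom <- qc$report$well[!qc$report$accepted &
                               !grepl("LOW_SIGNAL", qc$report$flags)]
      overlay_paths <- c(
        raw = plot_stage(ann, "raw", plot_dir),
        cropped = plot_stage(cropped, "cropped", plot_dir),
        accepted = plot_stage(qc$accepted, "accepted", plot_dir),
        anomalies = plot_stage(cropped[cropped$well %in% anom, ],
                               "anomalies", plot_dir),
        low_signal = plot_stage(cropped[cropped$well %in% low, ],
                                "low_signal", plot_dir),
        processed = plot_stage(processed, "processed", plot_dir,
                               value = "norm_fluorescence"))
      fit_plot_paths <- write_fit_plots(processed, fits, plot_dir)
      render_heatmap(result, "plate",
                     file = file.path(out_dir, paste0(stem, "_heatmap.png")))
    }
    write_workbook(result, out(".xlsx"), fit_plot_paths = fit_plot_paths,
                   overlay_paths = overlay_paths)
    manifest <- list(data_path = data_path, map_path = map_path,
                     map_format = map_format, plate_id = as.character(plate_id),
                     geometry = as.character(geometry),
                     window = window, signal_threshold = signal_threshold,
                     spike_multiplier = spike_multiplier,
                     smoothing_points = smoothing_points,
                     control_id = control_id,
                     hit_multiplier = hit_multiplier, two_sided = two_sided,
                     counts = as.list(attr(result, "counts")))
    jsonlite::write_json(manifest, out("_manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    return(invisible(result))
  }
  result
}

plot_stage <- function(curves, name, dir, value = "fluorescence") {
  path <- file.path(dir, paste0("curves_", name, ".png"))
  if (nrow(curves) == 0L) {
    return(stats::setNames(NA_character_, name))
  }
  plot_overlay(curves, value = value, title = paste(name, "melting curves"),
               file = path)
  path
}

write_fit_plots <- function(processed, fits, dir) {
  wells <- fits$well[fits$converged]
  paths <- stats::setNames(character(length(wells)), wells)
  for (w in wells) {
    pw <- processed[processed$well == w, ]
    ft <- fit_5pl(pw$temperature, pw$norm_fluorescence)
    paths[[w]] <- file.path(dir, paste0("fit_", w, ".png"))
    plot_fit(ft, well = w, file = paths[[w]])
  }
  paths
}

#' Consolidate result files from a results folder
#'
#' Thin wrapper over [consolidate()] for scripted use.
#'
#' @inheritParams consolidate
#' @return See [consolidate()].
#' @export
run_consolidate <- function(results_dir, format = c("auto", "sdf", "csv"),
                            out_dir = NULL) {
  combined <- consolidate(results_dir, format = format, out_dir = out_dir)
  message("consolidated ", nrow(combined), " records from ",
          length(unique(combined$source_file)), " file(s)")
  invisible(combined)
}

#' Simulate a plate and write its files
#'
#' Thin wrapper over [sim_spec()] + [simulate_plate()].
#'
#' @param out_dir Output directory.
#' @param seed RNG seed (mandatory).
#' @param ... Passed to [sim_spec()].
#' @return The [simulate_plate()] result, invisibly.
#' @export
run_simulate <- function(out_dir, seed, ...) {
  spec <- sim_spec(seed = seed, ...)
  sim <- simulate_plate(spec, dir = out_dir)
  message("simulated plate ", spec$plate_id, ": ",
          length(unique(sim$curves$well)), " wells, ",
          length(spec$control_wells), " controls, ",
          length(sim$hit_wells), " hit wells")
  invisible(sim)
}

#' Inspect a single well of a processed plate
#'
#' The well-level drill-down: prints the well's map entry, QC flags and fit
#' record.
#'
#' @param result A `plate_result`.
#' @param well Well label.
#' @return The well's one-row record, invisibly.
#' @export
inspect_well <- function(result, well) {
  addr <- parse_well_label(well)
  rec <- result$wells[result$wells$well == addr$well, ]
  if (nrow(rec) == 0L) stop("well ", addr$well, " is not in this plate",
                            call. = FALSE)
  print(as.data.frame(rec))
  invisible(rec)
}
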