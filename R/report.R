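#' Assemble the per-plate result object
#'
#' Joins the plate map, QC report, fits and hit calls into one per-well
#' table in which every mapped well appears exactly once: fitted wells
#' carry their melting temperature and hit annotation, QC-flagged wells
#' carry their flags with empty fit fields.
#'
#' @param plate_id Plate identifier.
#' @param map `plate_map` entries of this plate.
#' @param qc_report QC report tibble from [qc_plate()].
#' @param fits Fit table from [fit_plate()].
#' @param compounds Hit table from [call_hits()].
#' @param controls A `control_stats` object.
#' @return An object of class `plate_result`.
#' @export
plate_result <- function(plate_id, map, qc_report, fits, compounds,
                         controls) {
  entries <- map[map$plate_id == as.character(plate_id), ]
  wells <- dplyr::left_join(
    entries,
    qc_report[, c("well", "flags", "accepted")], by = "well")
  wells <- dplyr::left_join(
    wells, fits[, c("well", "tm", "rse", "converged")], by = "well")
  wells <- dplyr::left_join(
    wells,
    compounds[, c("compound_id", "delta_tm", "abs_delta_tm", "hit")],
    by = "compound_id")
  # wells that never reached (or failed) the fit carry no Tm or hit call
  no_fit <- is.na(wells$converged) | !wells$converged
  wells$tm[no_fit] <- NA_real_
  wells$rse[no_fit] <- NA_real_
  wells$delta_tm[no_fit] <- NA_real_
  wells$abs_delta_tm[no_fit] <- NA_real_
  wells$hit[no_fit] <- NA
  structure(list(plate_id = as.character(plate_id), wells = wells,
                 map = entries, qc_report = qc_report, fits = fits,
                 compounds = compounds, controls = controls),
            class = "plate_result")
}

#' @export
print.plate_result <- function(x, ...) {
  cat("Plate ", x$plate_id, ": ", nrow(x$wells), " mapped wells, ",
      sum(!x$wells$accepted, na.rm = TRUE), " QC-flagged, ",
      sum(x$wells$converged, na.rm = TRUE), " fitted, ",
      sum(x$compounds$hit), " hit compound(s)\n", sep = "")
  print(x$controls)
  invisible(x)
}

results_well_table <- function(result) {
  w <- result$wells
  tibble::tibble(compound_id = w$compound_id,
                 well = w$well,
                 row = row_index_to_letters(w$row),
                 column = w$column,
                 plate_id = w$plate_id,
                 tm = w$tm, rse = w$rse,
                 delta_tm = w$delta_tm, abs_delta_tm = w$abs_delta_tm,
                 hit = w$hit, qc_flags = w$flags,
                 smiles = w$smiles)
}

#' Write the annotated results SD file
#'
#' One record per mapped well: the original structure and every original
#' plate-map property, plus the added properties `Tm`, `RSE`, `dTm`,
#' `abs_dTm`, `hit` and `QC_flags`. Flagged wells are present with empty
#' fit fields.
#'
#' @param result A `plate_result`.
#' @param path Output `.sdf` path.
#' @param control_smiles Structure for structure-less control rows.
#' @return `path`, invisibly.
#' @export
write_results_sdf <- function(result, path, control_smiles = "CS(C)=O") {
  map <- result$map
  props <- platemap_props(map)
  w <- result$wells
  num <- function(x) ifelse(is.na(x), NA_character_,
                            format(x, digits = 15, trim = TRUE,
                                   scientific = FALSE))
  props$Tm <- num(w$tm)
  props$RSE <- num(w$rse)
  props$dTm <- num(w$delta_tm)
  props$abs_dTm <- num(w$abs_delta_tm)
  props$hit <- ifelse(is.na(w$hit), NA_character_,
                      ifelse(w$hit, "true", "false"))
  props$QC_flags <- w$flags
  write_sdf_records(props, platemap_structures(map, control_smiles), path)
  invisible(path)
}

#' Write the annotated results CSV (SMILES twin of the SD file)
#'
#' @inheritParams write_results_sdf
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(result, path) {
  tab <- results_well_table(result)
  names(tab) <- c("Compound_ID", "Well", "Row", "Column", "Plate_ID",
                  "Tm", "RSE", "dTm", "abs_dTm", "hit", "QC_flags", "SMILES")
  extras <- setdiff(names(result$map),
                    c("compound_id", "plate_id", "row", "column", "well",
                      "smiles", "role"))
  for (nm in extras) tab[[nm]] <- result$map[[nm]]
  readr::write_csv(tab, path, na = "", progress = FALSE)
  invisible(path)
}

tm_grid <- function(result) {
  geo_rows <- max(result$wells$row)
  geo_cols <- max(result$wells$column)
  grid <- matrix(NA_real_, nrow = geo_rows, ncol = geo_cols)
  grid[cbind(result$wells$row, result$wells$column)] <- result$wells$tm
  df <- data.frame(row = row_index_to_letters(seq_len(geo_rows)),
                   stringsAsFactors = FALSE)
  for (j in seq_len(geo_cols)) df[[as.character(j)]] <- grid[, j]
  df
}

#' Write the multi-sheet XLSX report
#'
#' Five sheets: *Plate Heatmap* (row-by-column midpoint-Tm grid with a
#' color scale), *Fit Results with hits annotated* (compound ID, well
#' position, plate row/column/ID, Tm, residual standard error, delta Tm,
#' |delta Tm|, hit status, SMILES), *DMSO mean and SD* (control mean, SD
#' and both hit-threshold variants), *Fitted Melting Curves* and *Melting
#' Curves* (per-well fit plots and the overlay-plot inventory; each row
#' names the saved PNG rather than embedding it). Numeric cells store the
#' exact pipeline values.
#'
#' @param result A `plate_result`.
#' @param path Output `.xlsx` path.
#' @param fit_plot_paths Optional named character vector (well -> PNG path)
#'   for the *Fitted Melting Curves* sheet.
#' @param overlay_paths Optional named character vector (inventory name ->
#'   PNG path) for the *Melting Curves* sheet.
#' @return `path`, invisibly.
#' @export
write_workbook <- function(result, path, fit_plot_paths = NULL,
                           overlay_paths = NULL) {
  heat <- tm_grid(result)
  fitres <- results_well_table(result)
  ctl <- result$controls
  dmso <- data.frame(molecule_id = ctl$control_id,
                     control_tm = ctl$mean_tm,
                     sd_control_tm = ctl$sd_tm,
                     hit_threshold_3sd = ctl$threshold,
                     hit_threshold_abs = ctl$threshold_abs)
  fitted_wells <- result$fits$well[result$fits$converged]
  fitted_sheet <- data.frame(
    well = fitted_wells,
    plot = if (is.null(fit_plot_paths)) NA_character_
           else unname(fit_plot_paths[fitted_wells]),
    stringsAsFactors = FALSE)
  inventory <- c("raw", "cropped", "accepted", "anomalies", "low_signal",
                 "processed")
  curves_sheet <- data.frame(
    curves = inventory,
    plot = if (is.null(overlay_paths)) NA_character_
           else unname(overlay_paths[inventory]),
    stringsAsFactors = FALSE)
  range <- paste0("B2:", col_ref(ncol(heat)), nrow(heat) + 1L)
  write_xlsx_workbook(
    list("Plate Heatmap" = heat,
         "Fit Results with hits annotated" = fitres,
         "DMSO mean and SD" = dmso,
         "Fitted Melting Curves" = fitted_sheet,
         "Melting Curves" = curves_sheet),
    path, color_scale = list(sheet = "Plate Heatmap", range = range))
  invisible(path)
}

#' Render plate / screen melting-temperature heatmaps
#'
#' Plate level: a single row-by-column grid colored by midpoint Tm, hit
#' wells overlaid with a cross marker, flagged or missing wells drawn in
#' the missing style. Screen level: a trellis of per-plate grids for
#' spotting row/column artifacts and comparing plates across a campaign.
#'
#' @param results A `plate_result` or list of them.
#' @param level `"plate"` (single result) or `"screen"` (trellis).
#' @param file Optional PNG path; when given the plot is saved.
#' @return The ggplot object, invisibly if `file` is given.
#' @export
render_heatmap <- function(results, level = c("plate", "screen"),
                           file = NULL) {
  level <- match.arg(level)
  if (inherits(results, "plate_result")) results <- list(results)
  df <- dplyr::bind_rows(lapply(results, function(r) {
    w <- r$wells
    tibble::tibble(plate_id = r$plate_id, row = w$row, column = w$column,
                   tm = w$tm, hit = !is.na(w$hit) & w$hit)
  }))
  n_rows <- max(df$row)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$row,
                                        fill = .data$tm)) +
    ggplot2::geom_tile(color = "grey60") +
    ggplot2::geom_point(data = df[df$hit, ], shape = 4, size = 2,
                        stroke = 1.1, color = "black") +
    ggplot2::scale_y_reverse(breaks = seq_len(n_rows),
                             labels = row_index_to_letters(seq_len(n_rows))) +
    ggplot2::scale_x_continuous(breaks = unique(df$column)) +
    ggplot2::scale_fill_viridis_c(na.value = "grey85",
                                  name = "midpoint Tm (°C)") +
    ggplot2::labs(x = "column", y = "row") +
    ggplot2::theme_minimal(base_size = 9)
  if (level == "screen") {
    p <- p + ggplot2::facet_wrap(~plate_id)
  } else {
    p <- p + ggplot2::ggtitle(paste("Plate", df$plate_id[1]))
  }
  if (!is.null(file)) {
    save_png(p, file, width = 9, height = 5)
    return(invisible(p))
  }
  p
}

save_png <- function(plot, file, width = 7, height = 5) {
  grDevices::png(file, width = width, height = height, units = "in",
                 res = 120)
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(file)
}

#' Overlay plot of melting curves
#'
#' All wells of a stage drawn as one overlay, the diagnostic view used to
#' review raw, cropped, accepted, anomalous, low-signal and processed
#' curves.
#'
#' @param curves Tibble with `well`, `temperature` and a value column.
#' @param value Name of the value column (default `"fluorescence"`).
#' @param title Plot title.
#' @param file Optional PNG path.
#' @return The ggplot object.
#' @export
plot_overlay <- function(curves, value = "fluorescence", title = "",
                         file = NULL) {
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$temperature,
                                    y = .data[[value]],
                                    group = .data$well)) +
    ggplot2::geom_line(alpha = 0.35, linewidth = 0.3) +
    ggplot2::labs(x = "temperature (°C)", y = value, title = title) +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(file)) {
    save_png(p, file)
    return(invisible(p))
  }
  p
}

#' Per-well fitted-curve plot
#'
#' Processed data points with the fitted 5PL overlay and a parameter
#' annotation.
#'
#' @param fit A `fivepl_fit` from [fit_5pl()].
#' @param well Well label used in the title.
#' @param file Optional PNG path.
#' @return The ggplot object.
#' @export
plot_fit <- function(fit, well = "", file = NULL) {
  df <- tibble::tibble(temperature = fit$temperature, value = fit$values)
  grid <- tibble::tibble(
    temperature = seq(min(df$temperature), max(df$temperature),
                      length.out = 200))
  grid$value <- eval_5pl(grid$temperature, fit$params)
  lab <- paste0("b=", signif(fit$params[["b"]], 4),
                " c=", signif(fit$params[["c"]], 3),
                " d=", signif(fit$params[["d"]], 3),
                " e=", signif(fit$params[["e"]], 4),
                " f=", signif(fit$params[["f"]], 3),
                "\nmidpoint Tm=", signif(fit$midpoint_tm, 4),
                " °C, RSE=", signif(fit$rse, 3))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$temperature, .data$value)) +
    ggplot2::geom_point(size = 0.8, color = "firebrick") +
    ggplot2::geom_line(data = grid, color = "black") +
    ggplot2::labs(title = paste("Well", well), subtitle = lab,
                  x = "temperature (°C)", y = "normalized fluorescence") +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(file)) {
    save_png(p, file, width = 5, height = 4)
    return(invisible(p))
  }
  p
}

read_result_file <- function(path, format) {
  if (format == "sdf") {
    sdf <- ChemmineR::read.SDFset(path)
    blocks <- ChemmineR::datablock(sdf)
    cols <- unique(unlist(lapply(blocks, names)))
    tab <- tibble::as_tibble(lapply(stats::setNames(cols, cols), function(nm) {
      vapply(blocks, function(db)
        if (nm %in% names(db)) unname(db[[nm]]) else NA_character_,
        character(1))
    }))
    attr(tab, "sdfset") <- sdf
    tab
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE)
  }
}

#' Consolidate per-plate result files
#'
#' Reads every result file of one format in `results_dir`, unites their
#' (possibly heterogeneous) columns with explicit missing values, records
#' the source file in a provenance column, and writes the combined table --
#' as SDF or CSV plus an XLSX -- into a sibling `Consolidated` directory so
#' that re-running the consolidation never re-reads its own output.
#'
#' @param results_dir Directory holding the per-plate result files.
#' @param format `"sdf"`, `"csv"`, or `"auto"` (error if both are present).
#' @param out_dir Output directory; default `Consolidated` next to
#'   `results_dir`.
#' @return The combined tibble, invisibly, with attribute `paths`.
#' @export
consolidate <- function(results_dir, format = c("auto", "sdf", "csv"),
                        out_dir = NULL) {
  format <- match.arg(format)
  sdf_files <- list.files(results_dir, pattern = "\\.sdf$", full.names = TRUE)
  csv_files <- list.files(results_dir, pattern = "\\.csv$", full.names = TRUE)
  if (format == "auto") {
    if (length(sdf_files) > 0L && length(csv_files) > 0L) {
      stop("results folder mixes SDF and CSV files; pass format explicitly",
           call. = FALSE)
    }
    format <- if (length(sdf_files) > 0L) "sdf" else "csv"
  }
  files <- if (format == "sdf") sdf_files else csv_files
  if (length(files) == 0L) {
    stop("no .", format, " result files found in ", results_dir,
         call. = FALSE)
  }
  pieces <- lapply(files, function(f) {
    tab <- read_result_file(f, format)
    tab$source_file <- basename(f)
    tab
  })
  combined <- dplyr::bind_rows(pieces)
  if (is.null(out_dir)) {
    out_dir <- file.path(dirname(normalizePath(results_dir)), "Consolidated")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (format == "sdf") {
    structures <- unlist(lapply(pieces, function(tab) {
      sdf <- attr(tab, "sdfset")
      lapply(seq_len(nrow(tab)), function(i)
        molblock_lines(sdf[[i]], sdf[[i]]@header[["Molecule_Name"]]))
    }), recursive = FALSE)
    p <- file.path(out_dir, "consolidated.sdf")
    write_sdf_records(as.data.frame(combined), structures, p)
    paths <- c(paths, p)
  } else {
    p <- file.path(out_dir, "consolidated.csv")
    readr::write_csv(combined, p, na = "", progress = FALSE)
    paths <- c(paths, p)
  }
  px <- file.path(out_dir, "consolidated.xlsx")
  write_xlsx_workbook(list("Consolidated Results" = as.data.frame(combined)),
                      px)
  paths <- c(paths, px)
  attr(combined, "paths") <- paths
  invisible(combined)
}
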