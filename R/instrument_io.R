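#' Read a raw qPCR melt-curve export
#'
#' Parses the delimited long-format export written by qPCR instruments into a
#' tidy table of melting curves: one row per (well, temperature) reading. The
#' three required fields -- well position, temperature and fluorescence -- are
#' located by `column_map`, so any instrument's long export can be ingested by
#' renaming. A built-in `format = "wide"` preset accepts a pre-pivoted sheet
#' (one temperature column, one fluorescence column per well), as produced by
#' some instrument software.
#'
#' Readings are sorted by temperature within each well. Duplicate
#' (well, temperature) rows are collapsed to their mean with a warning
#' (instrument re-reads). Decimal commas are not auto-detected; pass
#' `decimal_mark = ","` explicitly for such locales.
#'
#' @param path Path to the delimited text file.
#' @param column_map Named character vector mapping the canonical fields
#'   `well`, `temperature`, `fluorescence` to the file's column names
#'   (long format only).
#' @param delim Field delimiter; tab by default.
#' @param skip Number of preamble lines to skip before the header.
#' @param geometry Plate geometry (`"384"` or `"96"`).
#' @param format `"long"` (default) or `"wide"`.
#' @param decimal_mark Decimal mark; must be set to `","` explicitly for
#'   decimal-comma exports.
#' @return A tibble of class `melt_curves` with columns
#'   `well`, `row`, `column`, `temperature`, `fluorescence`, sorted by well
#'   then temperature.
#' @export
read_melt_export <- function(path,
                             column_map = c(well = "well",
                                            temperature = "temperature",
                                            fluorescence = "fluorescence"),
                             delim = "\t",
                             skip = 0,
                             geometry = "384",
                             format = c("long", "wide"),
                             decimal_mark = ".") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  loc <- readr::locale(decimal_mark = decimal_mark)
  raw <- readr::read_delim(path, delim = delim, skip = skip,
                           col_types = readr::cols(.default = readr::col_character()),
                           locale = loc, progress = FALSE,
                           show_col_types = FALSE)
  if (nrow(raw) == 0L) stop("empty melt export: ", path, call. = FALSE)

  if (format == "wide") {
    long <- tidyr::pivot_longer(raw, -1, names_to = "well",
                                values_to = "fluorescence")
    names(long)[1] <- "temperature"
    long <- long[!is.na(long$fluorescence) & long$fluorescence != "", ]
  } else {
    needed <- c("well", "temperature", "fluorescence")
    if (!all(needed %in% names(column_map))) {
      stop("column_map must name the fields: ",
           paste(needed, collapse = ", "), call. = FALSE)
    }
    missing_cols <- setdiff(unname(column_map[needed]), names(raw))
    if (length(missing_cols) > 0L) {
      stop("column(s) ", paste(sQuote(missing_cols), collapse = ", "),
           " not found; available headers: ",
           paste(sQuote(names(raw)), collapse = ", "), call. = FALSE)
    }
    long <- tibble::tibble(well = raw[[column_map[["well"]]]],
                           temperature = raw[[column_map[["temperature"]]]],
                           fluorescence = raw[[column_map[["fluorescence"]]]])
  }

  num <- function(x, what) {
    v <- suppressWarnings(readr::parse_double(as.character(x), locale = loc))
    bad <- which(is.na(v) & !is.na(x) & x != "")
    if (length(bad) > 0L) {
      stop("non-numeric ", what, " value(s) at data line(s) ",
           paste(utils::head(bad, 5L), collapse = ", "),
           " (e.g. ", sQuote(x[bad[1]]), ")", call. = FALSE)
    }
    v
  }
  temperature <- num(long$temperature, "temperature")
  fluorescence <- num(long$fluorescence, "fluorescence")
  addr <- parse_well_label(long$well, geometry = geometry)

  curves <- tibble::tibble(well = addr$well, row = addr$row,
                           column = addr$column,
                           temperature = temperature,
                           fluorescence = fluorescence)
  if (anyNA(curves$temperature) || anyNA(curves$fluorescence)) {
    stop("missing temperature/fluorescence values in ", path, call. = FALSE)
  }

  dup <- duplicated(curves[, c("well", "temperature")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (well, temperature) reading(s) averaged",
            call. = FALSE)
    curves <- dplyr::summarise(
      dplyr::group_by(curves, .data$well, .data$row, .data$column,
                      .data$temperature),
      fluorescence = mean(.data$fluorescence), .groups = "drop")
  }
  curves <- dplyr::arrange(curves, .data$row, .data$column, .data$temperature)
  class(curves) <- c("melt_curves", class(curves))
  attr(curves, "geometry") <- as.character(geometry)
  curves
}

#' Write melting curves in the canonical long export dialect
#'
#' Tab-separated long format with a single header row (`well`, `temperature`,
#' `fluorescence`); the dialect read back by [read_melt_export()] with its
#' default `column_map`. Used by the plate simulator and as a debugging
#' export.
#'
#' @param curves A `melt_curves` tibble.
#' @param path Output path.
#' @param delim Field delimiter, tab by default (`","` gives the CSV twin).
#' @return `path`, invisibly.
#' @export
write_melt_export <- function(curves, path, delim = "\t") {
  stopifnot(all(c("well", "temperature", "fluorescence") %in% names(curves)))
  readr::write_delim(curves[, c("well", "temperature", "fluorescence")],
                     path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Pivot melting curves to the wide overlay layout
#'
#' One temperature column plus one fluorescence column per well, the layout
#' used for overlay plotting. All wells must share a common temperature grid
#' within `tol`; readings are never interpolated. Wells missing a grid
#' temperature get an explicit `NA` cell.
#'
#' @param curves A `melt_curves` tibble.
#' @param tol Absolute temperature tolerance for grid matching, in degrees C.
#' @return A tibble with `temperature` plus one column per well.
#' @export
pivot_wide <- function(curves, tol = 1e-6) {
  temps <- sort(unique(curves$temperature))
  # merge grid values closer than tol
  if (length(temps) > 1L) {
    keep <- c(TRUE, diff(temps) > tol)
    grid <- temps[keep]
  } else {
    grid <- temps
  }
  idx <- pmin(findInterval(curves$temperature, grid + tol) + 1L, length(grid))
  dist <- abs(curves$temperature - grid[idx])
  if (any(dist > tol)) {
    bad_wells <- unique(curves$well[dist > tol])
    stop("temperature grid mismatch beyond tolerance for well(s): ",
         paste(bad_wells, collapse = ", "), call. = FALSE)
  }
  # the common grid: clustered temperatures covered by at least half the
  # wells; readings off it mean the well was ramped on a different grid
  n_wells <- length(unique(curves$well))
  wells_at <- tapply(curves$well, idx, function(w) length(unique(w)))
  common <- as.integer(names(wells_at))[wells_at >= n_wells / 2]
  off_grid <- !(idx %in% common)
  if (any(off_grid)) {
    bad_wells <- sort(unique(curves$well[off_grid]))
    stop("temperature grid mismatch beyond tolerance for well(s): ",
         paste(bad_wells, collapse = ", "), call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    tibble::tibble(temperature = grid[idx], well = curves$well,
                   fluorescence = curves$fluorescence),
    names_from = "well", values_from = "fluorescence")
  dplyr::arrange(wide, .data$temperature)
}
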