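default_field_map <- c(compound_id = "Compound_ID", plate_id = "Plate_ID",
                       row = "Row", column = "Column", smiles = "SMILES")

# Row letters or integers -> integer index
parse_row_field <- function(x) {
  x <- trimws(as.character(x))
  is_num <- grepl("^[0-9]+$", x)
  out <- integer(length(x))
  out[is_num] <- as.integer(x[is_num])
  if (any(!is_num)) {
    bad <- !is_num & !grepl("^[A-Za-z]+$", x)
    if (any(bad)) stop("unparseable row value(s): ",
                       paste(sQuote(x[bad]), collapse = ", "), call. = FALSE)
    out[!is_num] <- row_letters_to_index(x[!is_num])
  }
  out
}

finish_platemap <- function(map, control_id, source, sdfset = NULL) {
  dup <- duplicated(map[, c("plate_id", "well")])
  if (any(dup)) {
    stop("plate map integrity: duplicate (plate, well) address(es): ",
         paste(unique(paste(map$plate_id[dup], map$well[dup])), collapse = ", "),
         call. = FALSE)
  }
  map$role <- ifelse(toupper(map$compound_id) == toupper(control_id),
                     "control", "sample")
  class(map) <- c("plate_map", class(map))
  attr(map, "control_id") <- control_id
  attr(map, "source") <- source
  if (!is.null(sdfset)) attr(map, "sdfset") <- sdfset
  map
}

#' Read a plate map from an SD file
#'
#' Each SDF record carries a compound structure plus data fields binding it
#' to a plate address. Field names are located through `field_map`; rows are
#' accepted as letters (`"A"`..`"AF"`) or integers, columns as integers. All
#' unrecognized SD properties are passed through untouched so they can be
#' preserved in result files.
#'
#' @param path Path to the SD file (V2000 molblocks + data items).
#' @param field_map Named character vector mapping `compound_id`, `plate_id`,
#'   `row`, `column` to the SD property names used in the file.
#' @param control_id Compound identifier marking control wells
#'   (case-insensitive); default `"DMSO"`.
#' @param geometry Plate geometry.
#' @return A `plate_map` tibble with columns `compound_id`, `plate_id`,
#'   `well`, `row`, `column`, `role`, `smiles` (NA for SDF input; structures
#'   are kept as an `SDFset` attribute), plus any extra SD properties.
#' @export
read_sdf_platemap <- function(path, field_map = default_field_map,
                              control_id = "DMSO", geometry = "384") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
  # zero-atom molblocks are legal no-structure records (e.g. DMSO rows)
  ok <- ChemmineR::validSDF(sdf) |
    vapply(seq_along(sdf), function(i) {
      cl <- sdf[[i]]@header[["Counts_Line"]]
      is.character(cl) && grepl("^\\s*0\\s+0", cl)
    }, logical(1))
  if (!all(ok)) {
    stop("unparseable SD record(s) at index: ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  }
  blocks <- ChemmineR::datablock(sdf)
  fm <- utils::modifyList(as.list(default_field_map), as.list(field_map))
  need <- c("compound_id", "plate_id", "row", "column")
  rows <- lapply(seq_along(blocks), function(i) {
    db <- blocks[[i]]
    for (f in need) {
      if (!fm[[f]] %in% names(db)) {
        stop("SD record ", i, " is missing property ", sQuote(fm[[f]]),
             call. = FALSE)
      }
    }
    db
  })
  get <- function(f) vapply(rows, function(db) unname(db[[fm[[f]]]]), character(1))
  row_idx <- parse_row_field(get("row"))
  col_idx <- as.integer(get("column"))
  map <- tibble::tibble(compound_id = get("compound_id"),
                        plate_id = get("plate_id"),
                        row = row_idx, column = col_idx,
                        well = well_label(row_idx, col_idx),
                        smiles = NA_character_)
  geo <- plate_geometry(geometry)
  if (any(map$row > geo$rows | map$column > geo$columns | map$row < 1 |
          map$column < 1)) {
    stop("plate map address outside the configured geometry", call. = FALSE)
  }
  # unmapped SD properties pass through as extra columns
  extra_names <- setdiff(unique(unlist(lapply(rows, names))),
                         unlist(fm[need]))
  for (nm in extra_names) {
    map[[nm]] <- vapply(rows, function(db)
      if (nm %in% names(db)) unname(db[[nm]]) else NA_character_, character(1))
  }
  finish_platemap(map, control_id, source = "sdf", sdfset = sdf)
}

#' Read a plate map from a SMILES CSV
#'
#' Same contract as [read_sdf_platemap()] with a SMILES column in place of
#' molblocks. SMILES strings are syntax-checked; invalid strings produce a
#' warning, never a failure, because the identity join onto melt curves must
#' still work. Empty SMILES (e.g. DMSO rows) are allowed.
#'
#' @inheritParams read_sdf_platemap
#' @param field_map Also maps `smiles` to the CSV column holding structures.
#' @return A `plate_map` tibble; see [read_sdf_platemap()].
#' @export
read_csv_platemap <- function(path, field_map = default_field_map,
                              control_id = "DMSO", geometry = "384") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  fm <- utils::modifyList(as.list(default_field_map), as.list(field_map))
  need <- c("compound_id", "plate_id", "row", "column")
  missing_cols <- setdiff(unlist(fm[need]), names(raw))
  if (length(missing_cols) > 0L) {
    stop("plate map column(s) ", paste(sQuote(missing_cols), collapse = ", "),
         " not found; available: ", paste(sQuote(names(raw)), collapse = ", "),
         call. = FALSE)
  }
  row_idx <- parse_row_field(raw[[fm$row]])
  col_idx <- as.integer(raw[[fm$column]])
  smi <- if (fm$smiles %in% names(raw)) raw[[fm$smiles]] else NA_character_
  smi[!is.na(smi) & smi == ""] <- NA_character_
  bad_smi <- !is.na(smi) & !valid_smiles(smi)
  if (any(bad_smi)) {
    warning("syntactically invalid SMILES for compound(s): ",
            paste(raw[[fm$compound_id]][bad_smi], collapse = ", "),
            call. = FALSE)
  }
  map <- tibble::tibble(compound_id = raw[[fm$compound_id]],
                        plate_id = raw[[fm$plate_id]],
                        row = row_idx, column = col_idx,
                        well = well_label(row_idx, col_idx),
                        smiles = smi)
  extra <- setdiff(names(raw), unlist(fm))
  for (nm in extra) map[[nm]] <- raw[[nm]]
  finish_platemap(map, control_id, source = "csv")
}

# light syntactic SMILES screen: allowed characters, balanced () and []
valid_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s)) return(TRUE)
    if (!grepl("^[A-Za-z0-9@+\\-\\[\\]()=#$:/\\\\.%*]+$", s, perl = TRUE)) {
      return(FALSE)
    }
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    all(cumsum((ch == "(") - (ch == ")")) >= 0) &&
      sum(ch == "(") == sum(ch == ")") &&
      all(cumsum((ch == "[") - (ch == "]")) >= 0) &&
      sum(ch == "[") == sum(ch == "]")
  }, logical(1), USE.NAMES = FALSE)
}

#' Join a plate map onto melting curves
#'
#' Inner join on (plate, well). Curves without a map entry and entries
#' without data are reported as orphans -- warnings by default, errors under
#' `strict = TRUE` -- never silently dropped.
#'
#' @param curves A `melt_curves` tibble.
#' @param map A `plate_map` tibble.
#' @param plate_id Plate identifier selecting the map entries to join.
#' @param strict Promote orphans to errors.
#' @return A list with `annotated` (curves with compound columns),
#'   `orphan_wells` (wells with data but no map entry) and `orphan_entries`
#'   (mapped wells with no data).
#' @export
join_platemap <- function(curves, map, plate_id, strict = FALSE) {
  entries <- map[map$plate_id == as.character(plate_id), ]
  data_wells <- unique(curves$well)
  orphan_wells <- setdiff(data_wells, entries$well)
  orphan_entries <- setdiff(entries$well, data_wells)
  joined_wells <- intersect(data_wells, entries$well)
  if (length(joined_wells) == 0L) {
    stop("no wells joined for plate ", sQuote(plate_id),
         "; check the plate_id against the map", call. = FALSE)
  }
  if (length(orphan_wells) > 0L || length(orphan_entries) > 0L) {
    msg <- paste0(length(orphan_wells), " well(s) without map entry; ",
                  length(orphan_entries), " map entr(ies) without data")
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  entry_cols <- entries[, setdiff(names(entries), c("row", "column"))]
  annotated <- dplyr::inner_join(curves, entry_cols, by = "well")
  list(annotated = annotated,
       orphan_wells = orphan_wells,
       orphan_entries = orphan_entries)
}
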