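# SDF (V2000) record assembly.
#
# ChemmineR renders molblocks for records that have structures; records
# without one (e.g. DMSO rows from a CSV map) get a valid zero-atom
# molblock. Data fields are appended as SD properties here because no
# installed writer handles mixed structure/structureless record sets.
# The program line of every molblock is fixed so outputs are byte-identical
# across runs.

PROGRAM_LINE <- "  meltshift          2D"

blank_molblock <- function(title) {
  c(title, PROGRAM_LINE, "",
    "  0  0  0  0  0  0  0  0  0  0999 V2000",
    "M  END")
}

# lines of one molblock (no data items, no $$$$) from a ChemmineR SDF object
molblock_lines <- function(sdf_obj, title) {
  lines <- ChemmineR::sdf2str(sdf_obj)
  end <- which(lines == "M  END")
  if (length(end) == 0L) return(blank_molblock(title))
  lines <- lines[seq_len(end[1])]
  lines[1] <- title
  lines[2] <- PROGRAM_LINE
  lines
}

molblock_from_smiles <- function(smiles, title) {
  if (is.na(smiles) || !nzchar(smiles)) return(blank_molblock(title))
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, title))),
    error = function(e) NULL)
  if (is.null(sdf) || length(sdf) == 0L) return(blank_molblock(title))
  molblock_lines(sdf[[1]], title)
}

# props: data frame of character columns; structures: list of molblock line
# vectors, one per row
write_sdf_records <- function(props, structures, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(props))) {
    writeLines(structures[[i]], con)
    for (nm in names(props)) {
      val <- props[[nm]][i]
      writeLines(c(paste0(">  <", nm, ">"),
                   if (is.na(val)) "" else as.character(val),
                   ""), con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

# Resolve one molblock per map row: prefer retained SDF structures, then the
# SMILES column, then control_smiles for control rows, else a blank block.
platemap_structures <- function(map, control_smiles = NULL) {
  sdfset <- attr(map, "sdfset")
  lapply(seq_len(nrow(map)), function(i) {
    title <- map$compound_id[i]
    if (!is.null(sdfset) && i <= length(sdfset)) {
      return(molblock_lines(sdfset[[i]], title))
    }
    smi <- map$smiles[i]
    if ((is.na(smi) || !nzchar(smi)) && map$role[i] == "control" &&
        !is.null(control_smiles)) {
      smi <- control_smiles
    }
    molblock_from_smiles(smi, title)
  })
}

platemap_props <- function(map) {
  extras <- setdiff(names(map),
                    c("compound_id", "plate_id", "row", "column", "well",
                      "smiles", "role"))
  props <- data.frame(Compound_ID = map$compound_id,
                      Plate_ID = map$plate_id,
                      Row = row_index_to_letters(map$row),
                      Column = as.character(map$column),
                      stringsAsFactors = FALSE)
  for (nm in extras) props[[nm]] <- as.character(map[[nm]])
  props
}

#' Write a plate map as an SD file
#'
#' One V2000 record per entry with `Compound_ID`, `Plate_ID`, `Row`
#' (letters), `Column` data items plus any extra map columns. Structures
#' come from the retained SDF records or the SMILES column; control rows
#' may be given an explicit structure via `control_smiles`.
#'
#' @param map A `plate_map` tibble.
#' @param path Output path.
#' @param control_smiles Optional SMILES assigned to structure-less control
#'   rows (e.g. `"CS(C)=O"` for DMSO).
#' @return `path`, invisibly.
#' @export
write_platemap_sdf <- function(map, path, control_smiles = NULL) {
  write_sdf_records(platemap_props(map),
                    platemap_structures(map, control_smiles), path)
  invisible(path)
}

#' Write a plate map as a SMILES CSV
#'
#' @param map A `plate_map` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_platemap_csv <- function(map, path) {
  extras <- setdiff(names(map),
                    c("compound_id", "plate_id", "row", "column", "well",
                      "smiles", "role"))
  out <- tibble::tibble(Compound_ID = map$compound_id,
                        SMILES = map$smiles,
                        Plate_ID = map$plate_id,
                        Row = row_index_to_letters(map$row),
                        Column = map$column)
  for (nm in extras) out[[nm]] <- map[[nm]]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
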