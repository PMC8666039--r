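# Minimal OOXML spreadsheet writer.
#
# Writes XLSX workbooks containing plain data sheets: numeric cells, boolean
# cells, inline strings, plus an optional color-scale conditional format for
# the plate-heatmap sheet. Stored cell values are the exact numbers passed in
# (no display rounding). Intentionally minimal: no shared strings, no themes,
# no embedded images.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# 1-based column index -> "A", "B", ..., "AA", ...
col_ref <- function(j) row_index_to_letters(j)

cell_xml <- function(ref, value) {
  if (is.na(value)) return("")
  if (is.logical(value)) {
    return(paste0('<c r="', ref, '" t="b"><v>', as.integer(value), "</v></c>"))
  }
  if (is.numeric(value)) {
    return(paste0('<c r="', ref, '"><v>',
                  format(value, digits = 17, trim = TRUE, scientific = FALSE),
                  "</v></c>"))
  }
  paste0('<c r="', ref, '" t="inlineStr"><is><t xml:space="preserve">',
         xml_escape(as.character(value)), "</t></is></c>")
}

sheet_xml <- function(df, color_scale_range = NULL) {
  header <- paste0(
    '<row r="1">',
    paste0(vapply(seq_along(df), function(j)
      cell_xml(paste0(col_ref(j), 1L), names(df)[j]), character(1)),
      collapse = ""),
    "</row>")
  body <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(seq_along(df), function(j) {
      cell_xml(paste0(col_ref(j), i + 1L), df[[j]][i])
    }, character(1))
    paste0('<row r="', i + 1L, '">', paste0(cells, collapse = ""), "</row>")
  }, character(1))
  cf <- if (!is.null(color_scale_range)) {
    paste0('<conditionalFormatting sqref="', color_scale_range, '">',
           '<cfRule type="colorScale" priority="1"><colorScale>',
           '<cfvo type="min"/><cfvo type="percentile" val="50"/>',
           '<cfvo type="max"/>',
           '<color rgb="FF4575B4"/><color rgb="FFFFFFBF"/>',
           '<color rgb="FFD73027"/>',
           "</colorScale></cfRule></conditionalFormatting>")
  } else {
    ""
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         "<sheetData>", header, paste0(body, collapse = ""), "</sheetData>",
         cf, "</worksheet>")
}

#' Write a multi-sheet XLSX workbook
#'
#' A minimal OOXML writer: each element of `sheets` becomes one worksheet
#' holding the data frame with a header row. Numeric values are stored at
#' full precision; character cells are written as inline strings. One sheet
#' may carry a three-color scale over a cell range (used for the plate
#' heatmap).
#'
#' @param sheets Named list of data frames; names become sheet names
#'   (max 31 characters each, per the XLSX format).
#' @param path Output `.xlsx` path.
#' @param color_scale Optional list `list(sheet = <name>, range = "B2:Y17")`
#'   applying a color-scale conditional format to that range.
#' @return `path`, invisibly.
#' @export
write_xlsx_workbook <- function(sheets, path, color_scale = NULL) {
  stopifnot(is.list(sheets), !is.null(names(sheets)),
            all(nzchar(names(sheets))))
  if (any(nchar(names(sheets)) > 31)) {
    stop("sheet name(s) longer than 31 characters", call. = FALSE)
  }
  tmp <- tempfile("xlsx_")
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)

  n <- length(sheets)
  overrides <- paste0(
    '<Override PartName="/xl/worksheets/sheet', seq_len(n),
    '.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    overrides, "</Types>"),
    file.path(tmp, "[Content_Types].xml"))

  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>"),
    file.path(tmp, "_rels", ".rels"))

  sheet_tags <- paste0('<sheet name="', xml_escape(names(sheets)),
                       '" sheetId="', seq_len(n), '" r:id="rId', seq_len(n),
                       '"/>', collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    "<sheets>", sheet_tags, "</sheets></workbook>"),
    file.path(tmp, "xl", "workbook.xml"))

  rels <- paste0('<Relationship Id="rId', seq_len(n),
                 '" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" ',
                 'Target="worksheets/sheet', seq_len(n), '.xml"/>',
                 collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    rels, "</Relationships>"),
    file.path(tmp, "xl", "_rels", "workbook.xml.rels"))

  for (i in seq_len(n)) {
    rng <- if (!is.null(color_scale) && names(sheets)[i] == color_scale$sheet) {
      color_scale$range
    } else {
      NULL
    }
    writeLines(sheet_xml(as.data.frame(sheets[[i]]), rng),
               file.path(tmp, "xl", "worksheets", paste0("sheet", i, ".xml")))
  }

  path <- normalizePath(path, mustWork = FALSE)
  old <- setwd(tmp)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  zip::zip(path, files = list.files(".", recursive = TRUE, all.files = TRUE),
           mode = "mirror")
  invisible(path)
}
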