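#' Plate geometries
#'
#' Microtitre plate geometry lookup. `"384"` is 16 rows (A-P) by 24 columns,
#' `"96"` is 8 rows (A-H) by 12 columns.
#'
#' @param geometry `"384"` or `"96"`.
#' @return A list with elements `rows` and `columns` (integer counts).
#' @export
plate_geometry <- function(geometry = c("384", "96")) {
  geometry <- match.arg(as.character(geometry), c("384", "96"))
  switch(geometry,
    "384" = list(rows = 16L, columns = 24L),
    "96"  = list(rows = 8L,  columns = 12L)
  )
}

# bijective base-26 letters -> integer ("A"=1 ... "Z"=26, "AA"=27, "AF"=32)
row_letters_to_index <- function(letters_part) {
  chars <- strsplit(toupper(letters_part), "", fixed = TRUE)
  vapply(chars, function(ch) {
    as.integer(sum(match(ch, LETTERS) * 26^(rev(seq_along(ch)) - 1)))
  }, integer(1))
}

row_index_to_letters <- function(idx) {
  vapply(as.integer(idx), function(i) {
    out <- character(0)
    while (i > 0L) {
      rem <- (i - 1L) %% 26L + 1L
      out <- c(LETTERS[rem], out)
      i <- (i - rem) %/% 26L
    }
    paste(out, collapse = "")
  }, character(1))
}

#' Parse well labels into row/column addresses
#'
#' Converts labels such as `"A1"`, `"b03"`, `"P24"` into 1-based row and
#' column indices. Zero padding and case are ignored, so `"A1"` and `"A01"`
#' denote the same well.
#'
#' @param labels Character vector of well labels.
#' @param geometry Plate geometry, `"384"` (default) or `"96"`; addresses
#'   outside the geometry raise an error.
#' @return A tibble with columns `well` (canonical label), `row`, `column`.
#' @examples
#' parse_well_label(c("A1", "B03", "P24"))
#' @export
parse_well_label <- function(labels, geometry = "384") {
  geo <- plate_geometry(geometry)
  labels <- as.character(labels)
  m <- regmatches(labels, regexec("^\\s*([A-Za-z]+)0*([0-9]+)\\s*$", labels))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("malformed well label(s): ",
         paste(sQuote(labels[bad]), collapse = ", "), call. = FALSE)
  }
  row <- row_letters_to_index(vapply(m, `[`, character(1), 2L))
  col <- as.integer(vapply(m, `[`, character(1), 3L))
  out_of_range <- row < 1L | row > geo$rows | col < 1L | col > geo$columns
  if (any(out_of_range)) {
    stop("well label(s) outside the ", geo$rows, "x", geo$columns,
         " plate geometry: ",
         paste(sQuote(labels[out_of_range]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(well = well_label(row, col), row = row, column = col)
}

#' Build canonical well labels from row/column indices
#'
#' @param row,column 1-based integer indices (recycled to a common length).
#' @return Character vector of labels such as `"A1"`.
#' @export
well_label <- function(row, column) {
  paste0(row_index_to_letters(row), as.integer(column))
}
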