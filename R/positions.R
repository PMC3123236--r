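#' Well addressing
#'
#' Wells are addressed the way plates are labelled in the lab: rows are
#' letters from the top (`A`, `B`, ..., then `AA`, `AB`, ... for very tall
#' plates), columns are 1-based numbers, so the second row / third column is
#' `"B3"`. Internally rows and columns are 0-based integer indices.
#'
#' @param row,col 0-based integer indices.
#' @param label an A1-style well label such as `"B3"`.
#' @param rows,cols plate geometry used for bounds checking; `NULL` skips
#'   the check.
#' @return `well_label()` returns the label; `parse_well_label()` a list
#'   with elements `row` and `col` (0-based).
#' @examples
#' well_label(1, 2)          # "B3"
#' parse_well_label("B3")    # list(row = 1, col = 2)
#' @export
well_label <- function(row, col) {
  if (any(row < 0) || any(col < 0)) stop_validation("well indices are 0-based and non-negative")
  paste0(vapply(row, row_letter, character(1)), col + 1L)
}

row_letter <- function(row0) {
  n <- row0 + 1L
  chars <- character(0)
  while (n > 0L) {
    r <- (n - 1L) %% 26L
    chars <- c(LETTERS[r + 1L], chars)
    n <- (n - 1L) %/% 26L
  }
  paste(chars, collapse = "")
}

letter_row <- function(s) {
  idx <- match(strsplit(s, "")[[1]], LETTERS)
  val <- 0L
  for (i in idx) val <- val * 26L + i
  val - 1L
}

#' @rdname well_label
#' @export
parse_well_label <- function(label, rows = NULL, cols = NULL) {
  assert_scalar_chr(label, "well label")
  m <- regmatches(label, regexec("^([A-Z]+)([0-9]+)$", label))[[1]]
  if (length(m) != 3L)
    stop_validation(sprintf("malformed well label '%s' (expected e.g. 'B3')", label))
  row <- letter_row(m[2])
  col <- as.integer(m[3]) - 1L
  if (col < 0L)
    stop_validation(sprintf("well label '%s': column numbers are 1-based", label))
  if (!is.null(rows) && row >= rows)
    stop_validation(sprintf("well '%s': row out of range for a %d-row plate", label, rows))
  if (!is.null(cols) && col >= cols)
    stop_validation(sprintf("well '%s': column out of range for a %d-column plate", label, cols))
  list(row = row, col = col)
}

# All labels of a rows x cols plate in row-major order (A1, A2, ..., B1, ...).
all_labels <- function(rows, cols) {
  as.vector(t(outer(seq_len(rows) - 1L, seq_len(cols) - 1L, well_label)))
}

# Sort a character vector of labels row-major; validates against geometry.
sort_labels <- function(labels, rows = NULL, cols = NULL) {
  parsed <- lapply(labels, parse_well_label, rows = rows, cols = cols)
  r <- vapply(parsed, `[[`, integer(1), "row")
  c_ <- vapply(parsed, `[[`, integer(1), "col")
  labels[order(r, c_)]
}
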