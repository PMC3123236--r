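# Raw-data import: reader-log and CSV dialects, barcode matching.
#
# Reader-log dialect (project-defined; the format is documented in
# docs/formats.md of the source repository):
#   blocks separated by blank lines, one block per plate read;
#   optional first line "ID1: <barcode>";
#   then one line per well: "<A1-label><TAB><value>".
# Decimal separator is '.' only; anything else is rejected loudly.

NUMBER_RE <- "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$"

parse_strict_number <- function(s, where) {
  s <- trimws(s)
  if (!grepl(NUMBER_RE, s))
    stop_parse(sprintf("non-numeric value '%s' %s ('.' decimal separator required)", s, where))
  v <- as.numeric(s)
  if (!is.finite(v)) stop_parse(sprintf("non-finite value '%s' %s", s, where))
  v
}

new_raw_read <- function(barcode, values, source) {
  structure(list(barcode = barcode, values = values, source = source),
            class = "pw_raw_read")
}

#' @export
print.pw_raw_read <- function(x, ...) {
  cat(sprintf("<raw read> barcode %s, %d wells (%s)\n",
              if (is.na(x$barcode)) "<none>" else x$barcode, length(x$values),
              paste(unlist(x$source), collapse = " block ")))
  invisible(x)
}

#' Read a plate-reader log file
#'
#' Parses the line-oriented reader-log dialect used for multi-plate runs:
#' blank-line-separated blocks, an optional `ID1: <barcode>` header per
#' block, then one `<well><TAB><value>` line per well. Well labels are
#' validated against the declared plate geometry.
#'
#' @param path file path.
#' @param rows,cols declared plate geometry (default 8 x 12).
#' @return a list of raw reads, each with elements `barcode` (`NA` when the
#'   block has no `ID1` line), `values` (named numeric vector keyed by well
#'   label) and `source`.
#' @export
read_reader_log <- function(path, rows = 8L, cols = 12L) {
  if (!file.exists(path)) stop_io(sprintf("file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  reads <- list()
  block_lines <- integer(0)
  flush_block <- function(block_lines) {
    if (length(block_lines) == 0L) return(invisible(NULL))
    barcode <- NA_character_
    start <- 1L
    first <- lines[block_lines[1L]]
    m <- regmatches(first, regexec("^ID1:[ \t]*(.*)$", first))[[1]]
    if (length(m) == 2L) {
      barcode <- trimws(m[2])
      if (!nzchar(barcode)) barcode <- NA_character_
      start <- 2L
    }
    values <- numeric(0)
    for (ln in block_lines[seq_along(block_lines) >= start]) {
      line <- lines[ln]
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 2L)
        stop_parse(sprintf("line %d: expected '<well>\t<value>', got '%s'", ln, line))
      label <- trimws(parts[1])
      tryCatch(parse_well_label(label, rows, cols),
               pw_validation_error = function(e)
                 stop_parse(sprintf("line %d: %s", ln, conditionMessage(e))))
      if (label %in% names(values))
        stop_parse(sprintf("line %d: duplicate well '%s' in block", ln, label))
      values[[label]] <- parse_strict_number(parts[2], sprintf("on line %d", ln))
    }
    reads[[length(reads) + 1L]] <<-
      new_raw_read(barcode, values, list(file = basename(path), block = length(reads) + 1L))
    invisible(NULL)
  }
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) {
      flush_block(block_lines)
      block_lines <- integer(0)
    } else {
      block_lines <- c(block_lines, i)
    }
  }
  flush_block(block_lines)
  reads
}

#' Read plate raw data from a CSV file
#'
#' Expects a header row and columns `barcode`, `well`, `value`. Rows are
#' grouped into reads by barcode; rows with an empty barcode are grouped by
#' contiguous runs (each run is one barcode-less read, to be matched to a
#' plate during import via the override list).
#'
#' @inheritParams read_reader_log
#' @return a list of raw reads as in [read_reader_log()].
#' @export
read_csv_plate <- function(path, rows = 8L, cols = 12L) {
  if (!file.exists(path)) stop_io(sprintf("file '%s' does not exist", path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        strip.white = TRUE)
  required <- c("barcode", "well", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop_parse(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0L) return(list())
  barcode <- ifelse(is.na(df$barcode) | !nzchar(df$barcode), NA_character_, df$barcode)
  # group id: by barcode value, or per contiguous run of empty barcodes
  gid <- character(nrow(df))
  run <- 0L
  prev_empty <- FALSE
  for (i in seq_len(nrow(df))) {
    if (is.na(barcode[i])) {
      if (!prev_empty) run <- run + 1L
      gid[i] <- sprintf("\r_run%d", run)
      prev_empty <- TRUE
    } else {
      gid[i] <- barcode[i]
      prev_empty <- FALSE
    }
  }
  reads <- list()
  for (g in unique(gid)) {
    sel <- which(gid == g)
    values <- numeric(0)
    for (i in sel) {
      label <- df$well[i]
      tryCatch(parse_well_label(label, rows, cols),
               pw_validation_error = function(e)
                 stop_parse(sprintf("row %d: %s", i, conditionMessage(e))))
      if (label %in% names(values))
        stop_parse(sprintf("row %d: duplicate well '%s' for barcode '%s'", i, label,
                           if (startsWith(g, "\r_run")) "<none>" else g))
      values[[label]] <- parse_strict_number(df$value[i], sprintf("in row %d", i))
    }
    reads[[length(reads) + 1L]] <- new_raw_read(
      if (startsWith(g, "\r_run")) NA_character_ else g,
      values, list(file = basename(path), block = length(reads) + 1L))
  }
  reads
}

#' Attach raw reads to stored plates by barcode
#'
#' Matches each read's barcode against the store's non-deleted plates and
#' writes the values into the matching plate's wells, marking the plate
#' imported. Reads without a barcode (reader barcode failure) consume the
#' `barcode_overrides` list in file order. An already-imported plate is
#' skipped unless `force = TRUE`. Every read ends up in exactly one of
#' `attached`, `missing_in_store` or `skipped`.
#'
#' @param store a [store_open()] store.
#' @param reads list of raw reads from [read_reader_log()] /
#'   [read_csv_plate()].
#' @param user acting username (plate updates are saved to the store).
#' @param barcode_overrides character vector assigned to the barcode-less
#'   reads in order; its length must equal their count.
#' @param force re-import over already-imported plates.
#' @return a list of class `pw_import_report` with `attached`,
#'   `missing_in_store` and `skipped` (list of `barcode`/`reason` pairs).
#' @export
attach_results <- function(store, reads, user, barcode_overrides = character(0),
                           force = FALSE) {
  stopifnot(inherits(store, "pw_store"))
  n_missing <- sum(vapply(reads, function(r) is.na(r$barcode), logical(1)))
  if (n_missing != length(barcode_overrides))
    stop_validation(sprintf(
      "%d read(s) lack a barcode but %d override(s) given (overrides are matched to barcode-less reads in file order)",
      n_missing, length(barcode_overrides)))
  attached <- character(0)
  missing_in_store <- character(0)
  skipped <- list()
  next_override <- 1L
  for (read in reads) {
    barcode <- read$barcode
    if (is.na(barcode)) {
      barcode <- barcode_overrides[[next_override]]
      next_override <- next_override + 1L
    }
    plate <- find_plate_by_barcode(store, barcode)
    if (is.null(plate)) {
      missing_in_store <- c(missing_in_store, barcode)
      next
    }
    if (isTRUE(plate$imported) && !force) {
      skipped[[length(skipped) + 1L]] <- list(barcode = barcode,
                                              reason = "already imported (use force to re-import)")
      next
    }
    bad <- setdiff(names(read$values), plate$wells$label)
    if (length(bad) > 0L) {
      skipped[[length(skipped) + 1L]] <- list(
        barcode = barcode,
        reason = sprintf("wells outside plate geometry: %s", paste(bad, collapse = ", ")))
      next
    }
    plate <- set_raw_values(plate, read$values)
    store_save(store, plate, user, overwrite = TRUE)
    attached <- c(attached, barcode)
  }
  structure(list(attached = attached, missing_in_store = missing_in_store,
                 skipped = skipped),
            class = "pw_import_report")
}

#' @export
print.pw_import_report <- function(x, ...) {
  cat(sprintf("<import> attached: %s | missing in store: %s | skipped: %d\n",
              if (length(x$attached)) paste(x$attached, collapse = ", ") else "-",
              if (length(x$missing_in_store)) paste(x$missing_in_store, collapse = ", ") else "-",
              length(x$skipped)))
  for (s in x$skipped) cat(sprintf("  skipped %s: %s\n", s$barcode, s$reason))
  invisible(x)
}
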