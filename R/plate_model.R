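#' Define a plate type
#'
#' A plate type records the physical geometry of a microplate family: the
#' number of rows and columns, hence the well count. The two formats in
#' everyday manual use are 8 x 12 = 96 wells and 16 x 24 = 384 wells, but
#' any positive geometry is accepted.
#'
#' @param name unique name for the type.
#' @param rows,cols positive integers.
#' @return an object of class `pw_plate_type`.
#' @examples
#' std96 <- plate_type("std96", 8, 12)
#' well_count(std96)  # 96
#' @export
plate_type <- function(name, rows, cols) {
  assert_scalar_chr(name, "plate type name")
  if (!is.numeric(rows) || !is.numeric(cols) || length(rows) != 1L || length(cols) != 1L ||
      is.na(rows) || is.na(cols) || rows < 1 || cols < 1 ||
      rows != as.integer(rows) || cols != as.integer(cols))
    stop_validation("rows and cols must be positive integers")
  structure(
    list(name = name, rows = as.integer(rows), cols = as.integer(cols)),
    class = c("pw_plate_type", "pw_resource")
  )
}

#' @rdname plate_type
#' @param x a plate-carrying object (`pw_plate_type`, `pw_plate_layout`,
#'   `pw_master_plate` or `pw_plate`).
#' @export
well_count <- function(x) {
  pt <- geometry_of(x)
  pt$rows * pt$cols
}

geometry_of <- function(x) {
  if (inherits(x, "pw_plate_type")) return(x)
  if (inherits(x, "pw_plate_layout")) return(x$plate_type)
  if (inherits(x, "pw_master_plate")) return(x$layout$plate_type)
  if (inherits(x, "pw_plate")) return(x$master$layout$plate_type)
  stop_validation("object carries no plate geometry")
}

layout_of <- function(x) {
  if (inherits(x, "pw_plate_layout")) return(x)
  if (inherits(x, "pw_master_plate")) return(x$layout)
  if (inherits(x, "pw_plate")) return(x$master$layout)
  stop_validation("object carries no plate layout")
}

is_deleted <- function(x) isTRUE(x$audit$deleted)

check_live <- function(x, what) {
  if (is.null(x)) stop_reference(sprintf("%s does not exist", what))
  if (is_deleted(x))
    stop_reference(sprintf("%s '%s' is marked deleted and cannot be referenced", what, x$name))
  invisible(x)
}

#' Create an empty plate layout
#'
#' A layout is the reusable template stage of plate design: it names groups
#' of wells (markers for controls, blanks and substance dilution series) on
#' a given plate type and carries the calculation formulas (well functions
#' and plate functions) shared by every plate that will use it.
#'
#' @param name unique layout name.
#' @param type a [plate_type()].
#' @return an object of class `pw_plate_layout` with no markers and no
#'   functions.
#' @export
plate_layout <- function(name, type) {
  assert_scalar_chr(name, "layout name")
  if (!inherits(type, "pw_plate_type")) stop_reference("layout requires a plate type")
  check_live(type, "plate type")
  structure(
    list(name = name, plate_type = type,
         markers = list(), well_functions = list(), plate_functions = list()),
    class = c("pw_plate_layout", "pw_resource")
  )
}

marker_kinds <- c("control", "blank", "substance")

find_marker <- function(layout, name) {
  for (m in layout$markers) if (m$name == name) return(m)
  NULL
}

#' Place a marker on a layout
#'
#' Markers name the roles wells play: `control` (untreated, full signal),
#' `blank` (no cells, background signal) or `substance` (treatment wells
#' that will carry a dilution series). Placing a control or blank marker
#' automatically registers `avg(<name>)` and `sd(<name>)` as named
#' plate-level quantities, mirroring routine screening practice. A well may
#' belong to several control/blank groups (e.g. a pooled super-group) but
#' to at most one substance marker.
#'
#' @param layout a [plate_layout()].
#' @param name marker (group) name, unique within the layout.
#' @param kind one of `"control"`, `"blank"`, `"substance"`.
#' @param positions character vector of A1-style well labels.
#' @return the updated layout.
#' @export
place_marker <- function(layout, name, kind, positions) {
  stopifnot(inherits(layout, "pw_plate_layout"))
  assert_scalar_chr(name, "marker name")
  kind <- match.arg(kind, marker_kinds)
  if (length(positions) == 0L) stop_validation("marker needs at least one well")
  pt <- layout$plate_type
  positions <- unique(as.character(positions))
  positions <- sort_labels(positions, pt$rows, pt$cols)  # also validates range
  if (!is.null(find_marker(layout, name)))
    stop_conflict(sprintf("marker '%s' already exists on layout '%s'", name, layout$name))
  if (kind == "substance") {
    for (m in layout$markers) {
      if (m$kind == "substance" && length(intersect(m$positions, positions)) > 0L)
        stop_conflict(sprintf(
          "substance markers '%s' and '%s' overlap: a well can carry only one substance",
          m$name, name))
    }
  }
  layout$markers[[length(layout$markers) + 1L]] <-
    list(name = name, kind = kind, positions = positions)
  if (kind %in% c("control", "blank")) {
    for (fn in c("avg", "sd")) {
      auto_name <- sprintf("%s(%s)", fn, name)
      layout$plate_functions[[auto_name]] <- list(
        name = auto_name,
        formula = parse_formula(sprintf("%s(%s)", fn, name)),
        auto = TRUE
      )
    }
  }
  layout
}

#' Attach a well function to a layout
#'
#' Well functions are per-well calculation formulas (for example a survival
#' index) attached to a set of target wells. Different target groups may use
#' different formulas, so that, e.g., wells in different plate regions can be
#' normalised against their nearest control group.
#'
#' @param layout a [plate_layout()].
#' @param name function name, unique within the layout.
#' @param formula_text formula source, e.g.
#'   `"(value - avg(BLANK)) / (avg(CTRL) - avg(BLANK)) * 100"`.
#' @param targets character vector of target well labels.
#' @return the updated layout.
#' @export
add_well_function <- function(layout, name, formula_text, targets) {
  stopifnot(inherits(layout, "pw_plate_layout"))
  assert_scalar_chr(name, "well function name")
  if (!is.null(layout$well_functions[[name]]))
    stop_conflict(sprintf("well function '%s' already exists", name))
  pt <- layout$plate_type
  targets <- sort_labels(unique(as.character(targets)), pt$rows, pt$cols)
  if (length(targets) == 0L) stop_validation("well function needs at least one target well")
  f <- parse_formula(formula_text)
  check_formula_refs(f, layout)
  layout$well_functions[[name]] <- list(name = name, formula = f, targets = targets)
  layout
}

#' Attach a plate function to a layout
#'
#' Plate functions compute one scalar per plate (e.g. the standard deviation
#' of all screened wells for Z-scoring). They may not reference the current
#' well's own value.
#'
#' @inheritParams add_well_function
#' @return the updated layout.
#' @export
add_plate_function <- function(layout, name, formula_text) {
  stopifnot(inherits(layout, "pw_plate_layout"))
  assert_scalar_chr(name, "plate function name")
  if (!is.null(layout$plate_functions[[name]]))
    stop_conflict(sprintf("plate function '%s' already exists", name))
  f <- parse_formula(formula_text)
  if (formula_uses_value(f))
    stop_validation("a plate function may not reference the current well's value")
  check_formula_refs(f, layout)
  layout$plate_functions[[name]] <- list(name = name, formula = f, auto = FALSE)
  layout
}

# Structural check: every group an aggregate references must exist as a marker.
check_formula_refs <- function(formula, layout) {
  for (g in formula_groups(formula)) {
    if (is.null(find_marker(layout, g)))
      stop_reference(sprintf("formula references unknown group '%s'", g))
  }
  invisible(TRUE)
}

#' Register a substance
#'
#' @param name substance (compound) name.
#' @param external_id optional identifier in an external registry.
#' @return an object of class `pw_substance`.
#' @export
substance <- function(name, external_id = NA_character_) {
  assert_scalar_chr(name, "substance name")
  structure(list(name = name, external_id = external_id),
            class = c("pw_substance", "pw_resource"))
}

#' Geometric dilution series
#'
#' `dilution_series()` describes a serial dilution: a top concentration
#' divided by a constant factor at each step. `expand_dilution_series()`
#' returns the strictly decreasing concentration vector
#' `top / factor^(0:(n_steps-1))`.
#'
#' @param top top (highest) concentration, positive.
#' @param factor dilution factor, strictly greater than 1.
#' @param n_steps number of concentrations, at least 1.
#' @param unit free-text unit label, default `"uM"`.
#' @return `dilution_series()` an object of class `pw_dilution_series`;
#'   `expand_dilution_series()` a numeric vector.
#' @examples
#' expand_dilution_series(dilution_series(10, 2, 5))  # 10 5 2.5 1.25 0.625
#' @export
dilution_series <- function(top, factor, n_steps, unit = "uM") {
  if (!is.numeric(top) || length(top) != 1L || is.na(top) || top <= 0)
    stop_validation("top concentration must be a positive number")
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) || factor <= 1)
    stop_validation("dilution factor must be > 1")
  if (!is.numeric(n_steps) || length(n_steps) != 1L || is.na(n_steps) ||
      n_steps < 1 || n_steps != as.integer(n_steps))
    stop_validation("n_steps must be a positive integer")
  structure(list(top = top, factor = factor, n_steps = as.integer(n_steps), unit = unit),
            class = "pw_dilution_series")
}

#' @rdname dilution_series
#' @param series a `pw_dilution_series`.
#' @export
expand_dilution_series <- function(series) {
  stopifnot(inherits(series, "pw_dilution_series"))
  series$top / series$factor^(seq_len(series$n_steps) - 1)
}

#' Create a master plate
#'
#' A master plate instantiates a layout with actual substances and per-well
#' concentrations; it is the template for a cryostored batch of identical
#' physical plates. Each assignment maps a substance marker to one substance
#' and one concentration per marker well; marker wells sorted row-major
#' receive the concentrations in the order given (a dilution series is
#' expanded highest-first). Substance markers left out of `assignments` stay
#' explicitly empty.
#'
#' @param name unique master plate name.
#' @param layout a [plate_layout()].
#' @param assignments named list, one entry per substance marker to fill:
#'   each a list with `substance` (a [substance()]) and either
#'   `series` (a [dilution_series()]) or `concentrations` (numeric vector
#'   whose length equals the marker's well count), plus optional `unit`.
#' @return an object of class `pw_master_plate`.
#' @export
master_plate <- function(name, layout, assignments = list()) {
  assert_scalar_chr(name, "master plate name")
  if (!inherits(layout, "pw_plate_layout")) stop_reference("master plate requires a layout")
  check_live(layout, "plate layout")
  out <- list()
  nms <- names(assignments)
  if (length(assignments) > 0 && (is.null(nms) || any(!nzchar(nms))))
    stop_validation("assignments must be a named list keyed by substance-marker name")
  for (marker_name in nms) {
    a <- assignments[[marker_name]]
    m <- find_marker(layout, marker_name)
    if (is.null(m)) stop_reference(sprintf("unknown marker '%s'", marker_name))
    if (m$kind != "substance")
      stop_validation(sprintf("marker '%s' is a %s marker; only substance markers take substances",
                              marker_name, m$kind))
    if (!inherits(a$substance, "pw_substance"))
      stop_validation(sprintf("assignment for '%s' lacks a substance", marker_name))
    check_live(a$substance, "substance")
    conc <- if (!is.null(a$series)) expand_dilution_series(a$series) else a$concentrations
    unit <- if (!is.null(a$series)) a$series$unit else if (!is.null(a$unit)) a$unit else "uM"
    if (!is.numeric(conc) || any(is.na(conc)) || any(conc <= 0))
      stop_validation(sprintf("assignment for '%s': concentrations must be positive numbers", marker_name))
    if (length(conc) != length(m$positions))
      stop_validation(sprintf(
        "assignment for '%s': %d concentrations for %d wells", marker_name,
        length(conc), length(m$positions)))
    out[[marker_name]] <- list(substance = a$substance,
                               concentrations = as.numeric(conc), unit = unit)
  }
  structure(list(name = name, layout = layout, assignments = out),
            class = c("pw_master_plate", "pw_resource"))
}

#' Describe the biological sample seeded on a plate
#'
#' @param kind `"cell_line"` (a cultured cell type) or `"patient_cell"`
#'   (tissue sample from a patient).
#' @param name sample name.
#' @param properties free-form named character list of extra properties.
#' @return an object of class `pw_sample`.
#' @export
assay_sample <- function(kind = c("cell_line", "patient_cell"), name, properties = list()) {
  kind <- match.arg(kind)
  assert_scalar_chr(name, "sample name")
  structure(list(kind = kind, name = name, properties = properties),
            class = c("pw_sample", "pw_resource"))
}

#' Instantiate a physical plate from a master plate
#'
#' The master's layout wells act as templates: substance and concentration
#' are copied into the new plate's wells; raw values start empty and no well
#' is an outlier. The barcode identifies the physical plate when raw reader
#' data is imported.
#'
#' @param master a [master_plate()].
#' @param barcode barcode printed on the physical plate.
#' @param name plate name.
#' @param sample an [assay_sample()] describing the cells seeded.
#' @return an object of class `pw_plate`. Its `wells` element is a
#'   data frame with one row per well (row-major order) and columns
#'   `label`, `row`, `col`, `substance`, `concentration`, `raw_value`,
#'   `outlier`.
#' @export
create_plate <- function(master, barcode, name, sample) {
  if (!inherits(master, "pw_master_plate")) stop_reference("plate requires a master plate")
  check_live(master, "master plate")
  assert_scalar_chr(barcode, "barcode")
  assert_scalar_chr(name, "plate name")
  if (!inherits(sample, "pw_sample")) stop_validation("sample must be an assay_sample()")
  pt <- master$layout$plate_type
  labels <- all_labels(pt$rows, pt$cols)
  wells <- data.frame(
    label = labels,
    row = rep(seq_len(pt$rows) - 1L, each = pt$cols),
    col = rep(seq_len(pt$cols) - 1L, times = pt$rows),
    substance = NA_character_,
    concentration = NA_real_,
    raw_value = NA_real_,
    outlier = FALSE,
    stringsAsFactors = FALSE
  )
  for (marker_name in names(master$assignments)) {
    a <- master$assignments[[marker_name]]
    m <- find_marker(master$layout, marker_name)
    idx <- match(m$positions, wells$label)  # positions are stored row-major
    wells$substance[idx] <- a$substance$name
    wells$concentration[idx] <- a$concentrations
  }
  structure(
    list(name = name, barcode = barcode, master = master, sample = sample,
         wells = wells, imported = FALSE),
    class = c("pw_plate", "pw_resource")
  )
}

#' Set or clear outlier flags on wells
#'
#' Marking a well as an outlier removes it from every subsequent group
#' aggregate, QC statistic and dose-response point. A well can only be
#' flagged once it holds raw data.
#'
#' @param plate a [create_plate()] result with imported data.
#' @param wells character vector of well labels.
#' @param outlier `TRUE` to mark, `FALSE` to unmark.
#' @return the updated plate.
#' @export
mark_outlier <- function(plate, wells, outlier = TRUE) {
  stopifnot(inherits(plate, "pw_plate"))
  idx <- match(wells, plate$wells$label)
  if (anyNA(idx))
    stop_validation(sprintf("unknown well(s): %s", paste(wells[is.na(idx)], collapse = ", ")))
  if (isTRUE(outlier) && anyNA(plate$wells$raw_value[idx]))
    stop_validation("a well can be marked outlier only after raw data exists for it")
  plate$wells$outlier[idx] <- isTRUE(outlier)
  plate
}

#' Attach raw values directly to a plate
#'
#' Low-level helper used by the import machinery and handy in scripts and
#' tests; `values` is a named numeric vector keyed by well label.
#'
#' @param plate a `pw_plate`.
#' @param values named numeric vector (names are well labels).
#' @return the updated plate with `imported = TRUE`.
#' @export
set_raw_values <- function(plate, values) {
  stopifnot(inherits(plate, "pw_plate"))
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop_validation("values must be named by well label")
  idx <- match(names(values), plate$wells$label)
  if (anyNA(idx))
    stop_validation(sprintf("value(s) for wells outside the plate geometry: %s",
                            paste(names(values)[is.na(idx)], collapse = ", ")))
  plate$wells$raw_value[idx] <- as.numeric(values)
  plate$imported <- TRUE
  plate
}

#' @export
print.pw_plate_type <- function(x, ...) {
  cat(sprintf("<plate type> %s: %d x %d = %d wells\n", x$name, x$rows, x$cols, x$rows * x$cols))
  invisible(x)
}

#' @export
print.pw_plate_layout <- function(x, ...) {
  cat(sprintf("<plate layout> %s on %s (%dx%d)\n", x$name, x$plate_type$name,
              x$plate_type$rows, x$plate_type$cols))
  for (m in x$markers)
    cat(sprintf("  marker %-12s %-9s %d wells\n", m$name, m$kind, length(m$positions)))
  for (f in x$well_functions)
    cat(sprintf("  well fn %-12s %s\n", f$name, f$formula$source))
  for (f in x$plate_functions)
    if (!isTRUE(f$auto)) cat(sprintf("  plate fn %-11s %s\n", f$name, f$formula$source))
  invisible(x)
}

#' @export
print.pw_plate <- function(x, ...) {
  cat(sprintf("<plate> %s [%s] from master '%s', sample %s (%s), %s\n",
              x$name, x$barcode, x$master$name, x$sample$name, x$sample$kind,
              if (x$imported) "data imported" else "no data"))
  invisible(x)
}
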