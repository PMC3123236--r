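# Synthetic plate generator: plates with the statistical structure the
# analysis assumes (controls/blanks/dilution series, Gaussian noise,
# optional linear spatial drift and edge-well artifacts), plus ground truth.

#' Configure a simulated assay plate
#'
#' The default configuration emulates a cell-viability run on a 96-well
#' plate as such assays are routinely laid out: the outermost wells are
#' excluded from measurement roles (edge wells are notoriously unreliable),
#' two control columns sit in different plate regions (left and right of
#' the treatment block, so each treatment well has a nearby control group),
#' one blank row carries the no-cell background, and each substance
#' occupies replicate rows of a geometric dilution series. Signal is scaled
#' between a blank mean and an untreated-control mean; per-well noise is
#' additive Gaussian. Optional artifacts: multiplicative linear drift in
#' the row/column indices, and a multiplier on the outer-ring wells.
#'
#' @param rows,cols plate geometry (default 8 x 12).
#' @param n_substances number of substances (each takes `replicates` rows).
#' @param replicates replicate rows per substance.
#' @param n_steps dilution steps per series.
#' @param top top concentration of every series.
#' @param factor dilution factor (default half-log, `sqrt(10)`).
#' @param unit concentration unit label.
#' @param true_curves list (length `n_substances`) of lists with `top`,
#'   `bottom`, `slope`, `ic50` — the true dose-response of each substance
#'   in SI%. Default: full-range curves (`top = 100`, `bottom = 0`,
#'   `slope = 1`) with IC50s log-spaced from 1 to 10 `unit`.
#' @param control_mean,blank_mean mean signal (e.g. RFU) of untreated
#'   control and blank wells.
#' @param noise_sd additive Gaussian noise sd in signal units; the default
#'   corresponds to 2 SI points (2% of the control-blank span).
#' @param drift optional `list(row_slope=, col_slope=)`: the multiplicative
#'   factor `1 + row_slope*row + col_slope*col` (0-based indices).
#' @param edge_effect optional multiplier applied to outer-ring wells.
#' @param si_mode `"regional"` attaches a survival-index well function per
#'   plate half, each normalised against its nearest control column;
#'   `"pooled"` uses one function normalised against all controls.
#' @param seed integer seed; simulated runs are bit-reproducible.
#' @param barcode,plate_name,sample_name identity of the simulated plate.
#' @return a list of class `pw_sim_config`.
#' @export
simulation_config <- function(rows = 8L, cols = 12L,
                              n_substances = 2L, replicates = 2L,
                              n_steps = 8L, top = 100, factor = sqrt(10),
                              unit = "uM", true_curves = NULL,
                              control_mean = 1000, blank_mean = 50,
                              noise_sd = 0.02 * (control_mean - blank_mean),
                              drift = NULL, edge_effect = NULL,
                              si_mode = c("regional", "pooled"),
                              seed = 1L, barcode = "SIM-0001",
                              plate_name = "sim-plate", sample_name = "CEM") {
  si_mode <- match.arg(si_mode)
  if (rows < 5L || cols < 6L)
    stop_validation("simulated layout needs at least a 5 x 6 plate")
  if (noise_sd < 0) stop_validation("noise sd must be >= 0")
  inner_rows <- rows - 2L  # outer ring excluded from measurement roles
  avail_rows <- inner_rows - 1L  # minus the blank row
  if (n_substances * replicates > avail_rows)
    stop_validation(sprintf("%d substances x %d replicate rows exceed the %d available treatment rows",
                            n_substances, replicates, avail_rows))
  if (n_steps > cols - 4L)
    stop_validation(sprintf("%d dilution steps exceed the %d available treatment columns",
                            n_steps, cols - 4L))
  if (is.null(true_curves)) {
    ic50s <- 10^seq(0, 1, length.out = n_substances)
    true_curves <- lapply(ic50s, function(x)
      list(top = 100, bottom = 0, slope = 1, ic50 = x))
  }
  if (length(true_curves) != n_substances)
    stop_validation("true_curves must have one entry per substance")
  for (tc in true_curves)
    if (is.null(tc$ic50) || is.null(tc$slope) || is.null(tc$top) || is.null(tc$bottom))
      stop_validation("each true curve needs top, bottom, slope and ic50")
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         n_substances = as.integer(n_substances), replicates = as.integer(replicates),
         n_steps = as.integer(n_steps), top = top, factor = factor, unit = unit,
         true_curves = true_curves, control_mean = control_mean,
         blank_mean = blank_mean, noise_sd = noise_sd, drift = drift,
         edge_effect = edge_effect, si_mode = si_mode, seed = as.integer(seed),
         barcode = barcode, plate_name = plate_name, sample_name = sample_name),
    class = "pw_sim_config"
  )
}

hill_response <- function(conc, tc) {
  tc$bottom + (tc$top - tc$bottom) / (1 + (conc / tc$ic50)^tc$slope)
}

si_formula_text <- function(ctrl_group) {
  sprintf("(value - avg(BLANK)) / (avg(%s) - avg(BLANK)) * 100", ctrl_group)
}

#' Simulate a plate and its raw reader data
#'
#' Builds the full design chain (plate type, layout with markers and
#' survival-index well functions, substances, master plate with dilution
#' series, barcoded plate) and generates one raw read per the configured
#' signal model:
#' `raw(w) = (blank + v(w) * (control - blank)) * drift(w) * edge(w) + e`,
#' `e ~ N(0, sd^2)`, where the viability `v` is the true Hill response at
#' the well's concentration (1 for controls, 0 for blanks and unused
#' wells).
#'
#' @param config a [simulation_config()].
#' @return a list with `read` (a raw read attachable via
#'   [attach_results()] or [set_raw_values()]), `truth` (true per-substance
#'   curve parameters and the noiseless expected raw value per well),
#'   `plate_type`, `layout`, `master`, `plate` (unimported), `substances`,
#'   `sample` and `config`.
#' @export
simulate_plate <- function(config) {
  stopifnot(inherits(config, "pw_sim_config"))
  set.seed(config$seed)
  rows <- config$rows; cols <- config$cols
  pt <- plate_type(sprintf("sim%dx%d", rows, cols), rows, cols)
  layout <- plate_layout("sim-layout", pt)

  ctrl_l_col <- 1L
  ctrl_r_col <- cols - 2L
  blank_row <- 1L
  treat_rows <- seq(2L, rows - 2L)
  treat_cols <- seq(2L, cols - 3L)[seq_len(config$n_steps)]
  inner_rows <- seq(1L, rows - 2L)

  ctrl_l <- well_label(inner_rows, rep(ctrl_l_col, length(inner_rows)))
  ctrl_r <- well_label(inner_rows, rep(ctrl_r_col, length(inner_rows)))
  blanks <- well_label(rep(blank_row, cols - 4L), seq(2L, cols - 3L))
  layout <- place_marker(layout, "CTRL_L", "control", ctrl_l)
  layout <- place_marker(layout, "CTRL_R", "control", ctrl_r)
  layout <- place_marker(layout, "CTRL_ALL", "control", c(ctrl_l, ctrl_r))
  layout <- place_marker(layout, "BLANK", "blank", blanks)

  substances <- lapply(seq_len(config$n_substances),
                       function(i) substance(sprintf("SUB%02d", i)))
  series <- dilution_series(config$top, config$factor, config$n_steps, config$unit)
  conc <- expand_dilution_series(series)

  assignments <- list()
  sub_wells <- character(0)
  for (i in seq_len(config$n_substances)) {
    m_rows <- treat_rows[(i - 1L) * config$replicates + seq_len(config$replicates)]
    pos <- as.vector(t(outer(m_rows, treat_cols, well_label)))  # row-major
    marker_name <- sprintf("S%02d", i)
    layout <- place_marker(layout, marker_name, "substance", pos)
    assignments[[marker_name]] <- list(
      substance = substances[[i]],
      concentrations = rep(conc, times = config$replicates),  # top-first, left-to-right per row
      unit = config$unit)
    sub_wells <- c(sub_wells, pos)
  }

  if (config$si_mode == "regional") {
    # nearest-control practice: each treatment row is normalised against the
    # control wells sitting in the same row (one per flanking control column)
    for (r in treat_rows) {
      row_ctrl <- well_label(c(r, r), c(ctrl_l_col, ctrl_r_col))
      grp <- sprintf("CTRL_ROW_%s", row_letter(r))
      layout <- place_marker(layout, grp, "control", row_ctrl)
      row_sub <- intersect(sub_wells, well_label(rep(r, length(treat_cols)), treat_cols))
      if (length(row_sub) > 0L)
        layout <- add_well_function(layout, sprintf("SI_%s", row_letter(r)),
                                    si_formula_text(grp), row_sub)
    }
  } else {
    layout <- add_well_function(layout, "SI", si_formula_text("CTRL_ALL"), sub_wells)
  }

  master <- master_plate("sim-master", layout, assignments)
  samp <- assay_sample("cell_line", config$sample_name)
  plate <- create_plate(master, config$barcode, config$plate_name, samp)

  w <- plate$wells
  viability <- numeric(nrow(w))  # unused wells: no cells seeded, background only
  viability[w$label %in% c(ctrl_l, ctrl_r)] <- 1
  for (i in which(!is.na(w$substance))) {
    tc <- config$true_curves[[match(w$substance[i], vapply(substances, `[[`, character(1), "name"))]]
    viability[i] <- hill_response(w$concentration[i], tc) / 100
  }
  span <- config$control_mean - config$blank_mean
  expected <- config$blank_mean + viability * span
  if (!is.null(config$drift)) {
    rs <- if (is.null(config$drift$row_slope)) 0 else config$drift$row_slope
    cs <- if (is.null(config$drift$col_slope)) 0 else config$drift$col_slope
    expected <- expected * (1 + rs * w$row + cs * w$col)
  }
  if (!is.null(config$edge_effect)) {
    edge <- w$row == 0L | w$row == rows - 1L | w$col == 0L | w$col == cols - 1L
    expected[edge] <- expected[edge] * config$edge_effect
  }
  raw <- expected + stats::rnorm(length(expected), 0, config$noise_sd)
  values <- stats::setNames(raw, w$label)

  truth <- list(
    substances = stats::setNames(config$true_curves,
                                 vapply(substances, `[[`, character(1), "name")),
    expected = stats::setNames(expected, w$label)
  )
  list(read = new_raw_read(config$barcode, values,
                           list(file = "simulated", block = 1L)),
       truth = truth, plate_type = pt, layout = layout, master = master,
       plate = plate, substances = substances, sample = samp, config = config)
}

#' Write a raw read as a fixture file
#'
#' Emits either the reader-log dialect or the plain CSV dialect understood
#' by [read_reader_log()] / [read_csv_plate()]. Values are written with 17
#' significant digits so that the read/attach round trip is exact.
#'
#' @param read a raw read (e.g. from [simulate_plate()]).
#' @param path output file path.
#' @param format `"log"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_fixture_files <- function(read, path, format = c("log", "csv")) {
  stopifnot(inherits(read, "pw_raw_read"))
  format <- match.arg(format)
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  if (format == "log") {
    lines <- character(0)
    if (!is.na(read$barcode)) lines <- sprintf("ID1: %s", read$barcode)
    lines <- c(lines, sprintf("%s\t%s", names(read$values), fmt(read$values)))
    writeLines(lines, path)
  } else {
    lines <- c("barcode,well,value",
               sprintf("%s,%s,%s",
                       if (is.na(read$barcode)) "" else read$barcode,
                       names(read$values), fmt(read$values)))
    writeLines(lines, path)
  }
  invisible(path)
}
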