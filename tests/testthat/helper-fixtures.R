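# Shared fixtures: a small 96-well design with one control group, one blank
# group and one substance dilution series, plus independent oracles.

demo_design <- function(replicates = 1L, n_steps = 5L, top = 10, factor = 2) {
  pt <- plate_type("std96", 8, 12)
  lay <- plate_layout("L1", pt)
  lay <- place_marker(lay, "CTRL_B", "control", paste0("B", 2:11))
  lay <- place_marker(lay, "BLANK", "blank", paste0("C", 2:11))
  sub_rows <- LETTERS[4:(3 + replicates)]  # D, E, ...
  sub_wells <- as.vector(t(outer(sub_rows, 2:(1 + n_steps), paste0)))
  lay <- place_marker(lay, "S1", "substance", sub_wells)
  lay <- add_well_function(
    lay, "SI",
    "(value - avg(BLANK)) / (avg(CTRL_B) - avg(BLANK)) * 100",
    sub_wells)
  drug <- substance("drugA")
  series <- dilution_series(top, factor, n_steps)
  mp <- master_plate("M1", lay, list(
    S1 = list(substance = drug,
              concentrations = rep(expand_dilution_series(series), times = replicates))))
  plate <- create_plate(mp, "P0001", "run1", assay_sample("cell_line", "CEM"))
  list(plate_type = pt, layout = lay, master = mp, plate = plate,
       substance = drug, sub_wells = sub_wells,
       concentrations = expand_dilution_series(series))
}

# Fill a demo plate: controls at `control`, blanks at `blank`, substance wells
# from `sub_values` (recycled over the substance wells in row-major order),
# everything else at `background`.
fill_demo_plate <- function(design, sub_values, control = 1100, blank = 100,
                            background = 0) {
  plate <- design$plate
  vals <- stats::setNames(rep(background, nrow(plate$wells)), plate$wells$label)
  vals[paste0("B", 2:11)] <- control
  vals[paste0("C", 2:11)] <- blank
  vals[design$sub_wells] <- rep_len(sub_values, length(design$sub_wells))
  set_raw_values(plate, vals)
}

# Brute-force aggregate oracle over an explicit value vector.
agg_oracle <- function(fn, values) {
  switch(fn,
    avg = if (length(values)) mean(values) else NA_real_,
    sd = if (length(values) >= 2) sd(values) else NA_real_,
    cv = if (length(values) >= 2 && mean(values) != 0) 100 * sd(values) / mean(values) else NA_real_,
    min = if (length(values)) min(values) else NA_real_,
    max = if (length(values)) max(values) else NA_real_,
    median = if (length(values)) median(values) else NA_real_,
    count = length(values))
}

# Dense-grid crossing oracle for the linear-interpolation IC50: evaluate the
# piecewise-linear interpolant of (log10 conc, response) on a fine log grid
# and locate the 50% crossing between adjacent grid points.
oracle_ic50_grid <- function(curve, level = 50, n_grid = 20001L) {
  pts <- curve$points
  lx <- log10(pts$concentration)
  grid <- seq(min(lx), max(lx), length.out = n_grid)
  y <- approx(lx, pts$mean_response, xout = grid, ties = "ordered")$y
  hit <- which(y == level)
  if (length(hit) > 0) return(10^grid[min(hit)])
  s <- (y[-length(y)] - level) * (y[-1] - level)
  i <- which(s < 0)
  if (length(i) == 0) return(NA_real_)
  i <- i[1]
  t <- (level - y[i]) / (y[i + 1] - y[i])
  10^(grid[i] + t * (grid[i + 1] - grid[i]))
}

# Random strictly decreasing dose-response curve that brackets 50%.
random_monotone_curve <- function() {
  n <- sample(4:10, 1)
  conc <- 10^sort(runif(n, -2, 2))
  resp <- sort(runif(n, 0, 100), decreasing = TRUE)
  # force a bracket around 50 by pinning the end points
  resp[1] <- runif(1, 55, 100)
  resp[n] <- runif(1, 0, 45)
  resp <- sort(resp, decreasing = TRUE)
  dose_response(conc, resp, substance = "rnd")
}

tmp_store <- function() store_open(file.path(tempfile("pwstore")))

# Survival-index formula normalised against a given control group.
si_formula <- function(ctrl_group) {
  sprintf("(value - avg(BLANK)) / (avg(%s) - avg(BLANK)) * 100", ctrl_group)
}
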