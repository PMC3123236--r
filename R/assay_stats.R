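# QC statistics and dose-response analysis.

#' Control-well coefficient of variation
#'
#' Computes CV% (`100 * sd / mean`, sample sd) for each control group
#' individually and for all control wells pooled together — the standard
#' per-plate QC readout for tracking control variability. Only non-outlier
#' wells with data enter the computation; a group with fewer than two such
#' wells, or zero mean, yields `NA` for that entry.
#'
#' @param plate a plate with imported data.
#' @return a list of class `pw_cv_report` with `per_group` (named numeric)
#'   and `pooled` (single numeric).
#' @export
control_cv <- function(plate) {
  stopifnot(inherits(plate, "pw_plate"))
  if (!isTRUE(plate$imported)) stop_validation("plate has no imported data")
  layout <- layout_of(plate)
  ctrl <- Filter(function(m) m$kind == "control", layout$markers)
  if (length(ctrl) == 0L) stop_validation("plate layout has no control markers")
  per_group <- vapply(ctrl, function(m) agg_value("cv", group_values(plate, m$name)),
                      numeric(1))
  names(per_group) <- vapply(ctrl, `[[`, character(1), "name")
  pooled_pos <- unique(unlist(lapply(ctrl, `[[`, "positions")))
  w <- plate$wells
  keep <- w$label %in% pooled_pos & !w$outlier & !is.na(w$raw_value)
  pooled <- agg_value("cv", w$raw_value[keep])
  structure(list(per_group = per_group, pooled = pooled), class = "pw_cv_report")
}

#' @export
print.pw_cv_report <- function(x, ...) {
  cat("<CV% report>\n")
  for (g in names(x$per_group))
    cat(sprintf("  %-14s %s\n", g, format(x$per_group[[g]], digits = 4)))
  cat(sprintf("  %-14s %s\n", "pooled", format(x$pooled, digits = 4)))
  invisible(x)
}

#' Z-scores over a well set
#'
#' `z(w) = (x_w - mean) / sd` over the non-outlier raw values of the given
#' wells (sample sd) — the plate-normalised effect measure used in primary
#' screening. If the set's sd is zero all scores are `NA`.
#'
#' @param plate a plate with imported data.
#' @param wells character vector of well labels defining the reference set.
#' @return named numeric vector of scores for the set's non-outlier wells
#'   holding data.
#' @export
z_scores <- function(plate, wells) {
  stopifnot(inherits(plate, "pw_plate"))
  if (!isTRUE(plate$imported)) stop_validation("plate has no imported data")
  w <- plate$wells
  idx <- match(wells, w$label)
  if (anyNA(idx))
    stop_validation(sprintf("unknown well(s): %s", paste(wells[is.na(idx)], collapse = ", ")))
  keep <- idx[!w$outlier[idx] & !is.na(w$raw_value[idx])]
  if (length(keep) < 2L)
    stop_validation("z-scores need at least 2 non-outlier wells with data")
  x <- w$raw_value[keep]
  s <- stats::sd(x)
  z <- if (s == 0) rep(NA_real_, length(x)) else (x - mean(x)) / s
  names(z) <- w$label[keep]
  z
}

#' Construct a dose-response curve from points
#'
#' A curve is a per-substance series of (concentration, mean response)
#' points sorted by ascending concentration, the input to both IC50
#' procedures. [build_dose_response()] derives one from a plate;
#' `dose_response()` builds one directly from vectors.
#'
#' @param concentration positive, distinct concentrations.
#' @param response mean response (e.g. survival index in percent) per
#'   concentration.
#' @param n replicate count per point (default 1).
#' @param sd optional response sd per point (requires `n >= 2`).
#' @param substance substance name carried along for reporting.
#' @param response_name name of the response variable.
#' @param unit concentration unit label.
#' @return an object of class `pw_dose_response` whose `points` element is a
#'   data frame with columns `concentration`, `mean_response`, `n`, `sd`.
#' @export
dose_response <- function(concentration, response, n = 1L, sd = NA_real_,
                          substance = "", response_name = "SI %", unit = "uM") {
  if (length(concentration) < 1L) stop_validation("a curve needs at least one point")
  if (length(concentration) != length(response))
    stop_validation("concentration and response lengths differ")
  if (any(is.na(concentration)) || any(concentration <= 0))
    stop_validation("concentrations must be positive")
  if (anyDuplicated(concentration))
    stop_validation("concentrations must be distinct")
  o <- order(concentration)
  pts <- data.frame(concentration = as.numeric(concentration[o]),
                    mean_response = as.numeric(response[o]),
                    n = as.integer(rep_len(n, length(o))[o]),
                    sd = as.numeric(rep_len(sd, length(o))[o]))
  structure(list(substance = substance, points = pts,
                 response_name = response_name, unit = unit),
            class = "pw_dose_response")
}

#' @export
print.pw_dose_response <- function(x, ...) {
  cat(sprintf("<dose-response> %s: %d points (%s vs %s)\n",
              x$substance, nrow(x$points), x$response_name, x$unit))
  print(x$points, row.names = FALSE)
  invisible(x)
}

# The well function covering a well: first covering function in definition
# order (documented tie-break), or the named one.
covering_well_function <- function(layout, label, well_function = NULL) {
  if (!is.null(well_function)) {
    f <- layout$well_functions[[well_function]]
    if (is.null(f)) stop_reference(sprintf("unknown well function '%s'", well_function))
    return(f)
  }
  for (f in layout$well_functions) if (label %in% f$targets) return(f)
  NULL
}

#' Build a substance's dose-response curve from a plate
#'
#' Evaluates the covering well function (e.g. a survival index) on every
#' non-outlier well of the substance, groups replicates by concentration and
#' summarises each group by its mean, sd (when `n >= 2`) and replicate
#' count. Concentrations whose replicates are all outliers are dropped; a
#' substance with no remaining point is an error.
#'
#' @param plate a plate with imported data.
#' @param substance substance name (or a [substance()]).
#' @param well_function optional well-function name; by default each well
#'   uses the first layout well function targeting it.
#' @return a [dose_response()] curve.
#' @export
build_dose_response <- function(plate, substance, well_function = NULL) {
  stopifnot(inherits(plate, "pw_plate"))
  if (!isTRUE(plate$imported)) stop_validation("plate has no imported data")
  if (inherits(substance, "pw_substance")) substance <- substance$name
  assert_scalar_chr(substance, "substance name")
  w <- plate$wells
  on_plate <- !is.na(w$substance) & w$substance == substance
  if (!any(on_plate))
    stop_reference(sprintf("substance '%s' is not on this plate", substance))
  layout <- layout_of(plate)
  sel <- which(on_plate & !w$outlier & !is.na(w$raw_value))
  if (length(sel) == 0L)
    stop_pw("pw_empty_curve_error",
            sprintf("no usable wells for substance '%s' (all outliers or missing)", substance))
  resp <- vapply(sel, function(i) {
    f <- covering_well_function(layout, w$label[i], well_function)
    if (is.null(f))
      stop_reference(sprintf("no well function covers well %s", w$label[i]))
    eval_well_function(plate, f$formula, w$label[i])
  }, numeric(1))
  conc <- w$concentration[sel]
  ok <- !is.na(resp)
  if (!any(ok))
    stop_pw("pw_empty_curve_error",
            sprintf("all responses missing for substance '%s'", substance))
  groups <- split(resp[ok], conc[ok])
  cs <- as.numeric(names(groups))
  means <- vapply(groups, mean, numeric(1))
  ns <- vapply(groups, length, integer(1))
  sds <- vapply(groups, function(v) if (length(v) >= 2L) stats::sd(v) else NA_real_, numeric(1))
  unit <- "uM"
  for (a in plate$master$assignments)
    if (a$substance$name == substance) unit <- a$unit
  dose_response(cs, means, n = ns, sd = sds, substance = substance, unit = unit)
}

#' Evaluate the piecewise-linear dose-response interpolant
#'
#' Straight lines between the curve's points, drawn on a log10
#' concentration axis (the axis dilution series are geometric on). Returns
#' `NA` outside the measured range.
#'
#' @param curve a [dose_response()] curve.
#' @param concentration concentrations at which to evaluate.
#' @param axis `"log10"` (default) or `"linear"` interpolation axis.
#' @return numeric vector of interpolated responses.
#' @export
response_at <- function(curve, concentration, axis = c("log10", "linear")) {
  stopifnot(inherits(curve, "pw_dose_response"))
  axis <- match.arg(axis)
  pts <- curve$points
  if (nrow(pts) == 1L)
    return(ifelse(concentration == pts$concentration, pts$mean_response, NA_real_))
  x <- if (axis == "log10") log10(pts$concentration) else pts$concentration
  xi <- if (axis == "log10") log10(concentration) else concentration
  stats::approx(x, pts$mean_response, xout = xi, method = "linear",
                rule = 1, ties = "ordered")$y
}

#' IC50 by linear interpolation
#'
#' The assay's default IC50 procedure: the dose-response curve is drawn
#' with straight lines between the points, the two adjacent points closest
#' to the 50% response level that bracket it are identified, and the
#' concentration where the connecting segment crosses 50% is interpolated.
#' Interpolation runs on the log10 concentration axis by default (dilution
#' series are geometric, so plots are log-dose). A point lying exactly at
#' 50% returns its concentration directly. When several adjacent pairs
#' bracket 50% (non-monotone curves), the pair whose responses are jointly
#' closest to 50% wins; ties break toward the lower concentration.
#'
#' @param curve a [dose_response()] curve.
#' @param level response level to cross (default 50).
#' @param axis interpolation axis, `"log10"` (default) or `"linear"`.
#' @return the IC50 concentration, or `NA` with a `"reason"` attribute
#'   (`"no_crossing"`) when no pair of points brackets the level.
#' @export
ic50_linear <- function(curve, level = 50, axis = c("log10", "linear")) {
  stopifnot(inherits(curve, "pw_dose_response"))
  axis <- match.arg(axis)
  pts <- curve$points
  r <- pts$mean_response
  conc <- pts$concentration
  exact <- which(r == level)
  if (length(exact) > 0L) return(conc[min(exact)])
  if (nrow(pts) < 2L)
    return(structure(NA_real_, reason = "no_crossing"))
  lo <- r[-length(r)]
  hi <- r[-1L]
  bracket <- which((lo - level) * (hi - level) < 0)
  if (length(bracket) == 0L)
    return(structure(NA_real_, reason = "no_crossing"))
  score <- abs(lo[bracket] - level) + abs(hi[bracket] - level)
  i <- bracket[which.min(score)]  # which.min ties break to the first = lower conc
  x1 <- if (axis == "log10") log10(conc[i]) else conc[i]
  x2 <- if (axis == "log10") log10(conc[i + 1L]) else conc[i + 1L]
  t <- (level - r[i]) / (r[i + 1L] - r[i])
  x <- x1 + t * (x2 - x1)
  if (axis == "log10") 10^x else x
}

#' IC50 by Hill-equation fit
#'
#' Fits the four-parameter logistic (Hill) model
#' `f(c) = bottom + (top - bottom) / (1 + (c / ic50)^slope)`
#' to the curve points by non-linear least squares. Initialisation:
#' `top = max(response)`, `bottom = min(response)`, `slope = 1` with its
#' sign taken from the response trend, and `ic50` from [ic50_linear()] when
#' defined, else the geometric mean of the concentration range. The IC50 is
#' optimised on the log10 scale and bounded to
#' `[c_min / 100, c_max * 100]`.
#'
#' @param curve a [dose_response()] curve with at least 4 points (the model
#'   has 4 free parameters).
#' @param maxit maximum optimizer iterations.
#' @param tol relative convergence tolerance.
#' @return a list of class `pw_hill_fit` with elements `ic50`, `slope`,
#'   `top`, `bottom`, `rss`, `converged`. On optimizer failure the best
#'   iterate is returned with `converged = FALSE`.
#' @export
ic50_hill <- function(curve, maxit = 200L, tol = 1e-8) {
  stopifnot(inherits(curve, "pw_dose_response"))
  pts <- curve$points
  if (nrow(pts) < 4L)
    stop_validation("Hill fit needs at least 4 points (4 free parameters)")
  conc <- pts$concentration
  r <- pts$mean_response
  lc <- log10(conc)
  # initial values per the documented scheme
  trend <- stats::coef(stats::lm(r ~ lc))[2]
  slope0 <- if (is.na(trend) || trend <= 0) 1 else -1  # decreasing response => positive slope
  ic50_init <- ic50_linear(curve)
  if (is.na(ic50_init)) ic50_init <- sqrt(min(conc) * max(conc))
  lb <- log10(min(conc) / 100)
  ub <- log10(max(conc) * 100)
  l10_init <- min(max(log10(ic50_init), lb), ub)
  start <- c(top = max(r), bottom = min(r), slope = slope0, l10ic50 = l10_init)
  rss_of <- function(p) {
    fit <- p["bottom"] + (p["top"] - p["bottom"]) / (1 + 10^(p["slope"] * (lc - p["l10ic50"])))
    sum((r - fit)^2)
  }
  rss_init <- rss_of(start)
  dat <- data.frame(lc = lc, r = r)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ bottom + (top - bottom) / (1 + 10^(slope * (lc - l10ic50))),
      data = dat, start = as.list(start),
      lower = c(top = -Inf, bottom = -Inf, slope = -Inf, l10ic50 = lb),
      upper = c(top = Inf, bottom = Inf, slope = Inf, l10ic50 = ub),
      control = minpack.lm::nls.lm.control(maxiter = maxit, ftol = tol, ptol = tol)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    p <- stats::coef(fit)
    conv <- isTRUE(fit$convInfo$isConv)
  } else {
    # the LM path can fail outright on zero-residual (exact-fit) problems;
    # a bounded quasi-Newton pass on the RSS then settles it
    opt <- tryCatch(
      stats::optim(start, rss_of, method = "L-BFGS-B",
                   lower = c(-Inf, -Inf, -Inf, lb), upper = c(Inf, Inf, Inf, ub),
                   control = list(maxit = maxit,
                                  factr = max(tol / .Machine$double.eps, 10))),
      error = function(e) NULL
    )
    if (is.null(opt)) {
      p <- start
      conv <- FALSE
    } else {
      p <- opt$par
      conv <- opt$convergence == 0L
    }
  }
  rss <- rss_of(p)
  if (rss > rss_init + 1e-9 * (1 + rss_init)) conv <- FALSE
  structure(
    list(ic50 = unname(10^p["l10ic50"]), slope = unname(p["slope"]),
         top = unname(p["top"]), bottom = unname(p["bottom"]),
         rss = rss, converged = conv),
    class = "pw_hill_fit"
  )
}

#' @export
print.pw_hill_fit <- function(x, ...) {
  cat(sprintf("<Hill fit> ic50 = %.6g, slope = %.4g, top = %.4g, bottom = %.4g, rss = %.4g%s\n",
              x$ic50, x$slope, x$top, x$bottom, x$rss,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Welch two-sample comparison of two data series
#'
#' Two-sided Welch (unequal variance) t-test between two series of values,
#' e.g. the responses retrieved for one substance/concentration key on two
#' lists of plates. When both series are constant the statistic is
#' undefined; `t` and `p` come back `NA` with a `reason`.
#'
#' @param series_a,series_b numeric vectors with at least 2 values each.
#' @return a list with `t`, `p`, `df`, `method` and (when degenerate)
#'   `reason`.
#' @export
compare_series <- function(series_a, series_b) {
  if (length(series_a) < 2L || length(series_b) < 2L)
    stop_validation("each series needs at least 2 values")
  res <- tryCatch(stats::t.test(series_a, series_b, var.equal = FALSE),
                  error = function(e) e)
  if (inherits(res, "error")) {
    return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                method = "Welch two-sample t-test",
                reason = "zero variance in the data"))
  }
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter), method = "Welch two-sample t-test")
}
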