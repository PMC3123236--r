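# Plate report: evaluated well/plate functions, QC and dose-response.

#' Assemble the full calculated report for a plate
#'
#' Gathers everything the data-validation and reporting step needs: per-well
#' raw values, outlier flags and evaluated well functions; per-group and
#' pooled control CV%; every plate-function value (including the
#' auto-created control/blank averages and sds); and per-substance
#' dose-response points with IC50 by linear interpolation and, when
#' enabled, the Hill fit.
#'
#' @param plate a plate with imported data.
#' @param ic50_method `"linear"` (the default), `"hill"`, or `"both"`.
#' @return a list of class `pw_plate_report`.
#' @export
plate_report <- function(plate, ic50_method = c("linear", "hill", "both")) {
  stopifnot(inherits(plate, "pw_plate"))
  ic50_method <- match.arg(ic50_method)
  if (!isTRUE(plate$imported)) stop_validation("plate has no imported data")
  layout <- layout_of(plate)

  wells <- plate$wells
  for (f in layout$well_functions) {
    col <- rep(NA_real_, nrow(wells))
    for (lbl in f$targets) {
      i <- match(lbl, wells$label)
      col[i] <- eval_well_function(plate, f$formula, lbl)
    }
    wells[[f$name]] <- col
  }

  plate_fns <- vapply(layout$plate_functions, function(pf)
    eval_plate_function(plate, pf$formula), numeric(1))
  names(plate_fns) <- vapply(layout$plate_functions, `[[`, character(1), "name")

  has_controls <- any(vapply(layout$markers, function(m) m$kind == "control", logical(1)))
  cv <- if (has_controls) control_cv(plate) else NULL

  substances <- sort(unique(stats::na.omit(wells$substance)))
  dr <- lapply(substances, function(s) {
    curve <- tryCatch(build_dose_response(plate, s), pw_error = function(e) e)
    if (inherits(curve, "error"))
      return(list(substance = s, error = conditionMessage(curve)))
    lin <- ic50_linear(curve)
    entry <- list(substance = s, points = curve$points, unit = curve$unit,
                  ic50_linear = as.numeric(lin),
                  ic50_reason = if (is.na(lin)) attr(lin, "reason") else NA_character_)
    if (ic50_method %in% c("hill", "both")) {
      entry$hill <- tryCatch({
        h <- ic50_hill(curve)
        list(ic50 = h$ic50, slope = h$slope, top = h$top, bottom = h$bottom,
             rss = h$rss, converged = h$converged)
      }, pw_error = function(e) list(error = conditionMessage(e)))
    }
    entry
  })
  names(dr) <- substances

  structure(
    list(plate = list(name = plate$name, barcode = plate$barcode,
                      master = plate$master$name, layout = layout$name,
                      sample = list(name = plate$sample$name, kind = plate$sample$kind)),
         wells = wells, cv = cv, plate_functions = plate_fns,
         dose_response = dr, ic50_method = ic50_method),
    class = "pw_plate_report"
  )
}

#' Write a plate report to disk
#'
#' CSV output is a sectioned file (`[plate]`, `[wells]`, `[cv]`,
#' `[plate_functions]`, one `[dose_response ...]` block per substance);
#' JSON output mirrors the report object. Output is deterministic: the same
#' plate always produces byte-identical files, so reports can be diffed.
#'
#' @param plate a plate with imported data.
#' @param path output file path.
#' @param format `"csv"` or `"json"` (default from the file extension).
#' @param ic50_method passed to [plate_report()].
#' @return the report object, invisibly.
#' @export
write_plate_report <- function(plate, path, format = NULL,
                               ic50_method = c("linear", "hill", "both")) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "json") "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  rep <- plate_report(plate, ic50_method = ic50_method)
  if (format == "json") {
    out <- rep
    class(out) <- NULL
    out$cv <- if (is.null(rep$cv)) NULL else list(per_group = as.list(rep$cv$per_group),
                                                  pooled = rep$cv$pooled)
    out$plate_functions <- as.list(rep$plate_functions)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "columns", pretty = TRUE)
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    num <- function(x) ifelse(is.na(x), "", formatC(x, digits = 15, format = "g"))
    section <- function(title) writeLines(sprintf("[%s]", title), con)
    write_df <- function(df) {
      for (nm in names(df)) if (is.numeric(df[[nm]])) df[[nm]] <- num(df[[nm]])
      utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
    }
    section("plate")
    write_df(data.frame(name = rep$plate$name, barcode = rep$plate$barcode,
                        master = rep$plate$master, layout = rep$plate$layout,
                        sample = rep$plate$sample$name, sample_kind = rep$plate$sample$kind))
    section("wells")
    write_df(rep$wells)
    if (!is.null(rep$cv)) {
      section("cv")
      write_df(data.frame(group = c(names(rep$cv$per_group), "pooled"),
                          cv_percent = c(unname(rep$cv$per_group), rep$cv$pooled)))
    }
    if (length(rep$plate_functions) > 0L) {
      section("plate_functions")
      write_df(data.frame(name = names(rep$plate_functions),
                          value = unname(rep$plate_functions)))
    }
    for (s in names(rep$dose_response)) {
      d <- rep$dose_response[[s]]
      section(sprintf("dose_response %s", s))
      if (!is.null(d$error)) {
        write_df(data.frame(error = d$error))
        next
      }
      write_df(d$points)
      ic50_row <- data.frame(
        ic50_linear = if (is.na(d$ic50_linear)) "undefined" else num(d$ic50_linear),
        reason = ifelse(is.na(d$ic50_reason), "", d$ic50_reason),
        unit = d$unit)
      if (!is.null(d$hill) && is.null(d$hill$error)) {
        ic50_row$ic50_hill <- num(d$hill$ic50)
        ic50_row$hill_slope <- num(d$hill$slope)
        ic50_row$hill_top <- num(d$hill$top)
        ic50_row$hill_bottom <- num(d$hill$bottom)
        ic50_row$hill_converged <- d$hill$converged
      }
      write_df(ic50_row)
    }
  }
  invisible(rep)
}
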