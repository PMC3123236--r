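test_that("arithmetic follows standard precedence and associativity", {
  d <- demo_design()
  plate <- fill_demo_plate(d, 600)
  ev <- function(src) eval_well_function(plate, src, "D2")
  expect_equal(ev("1 + 2 * 3"), 7)
  expect_equal(ev("(1 + 2) * 3"), 9)
  expect_equal(ev("2 - 3 - 4"), -5)      # left association
  expect_equal(ev("12 / 2 / 3"), 2)
  expect_equal(ev("-2 * 3"), -6)
  expect_equal(ev("-(2 + 3)"), -5)
  expect_equal(ev("100/10/2 + 3*2*1"), 11)
})

test_that("the survival-index formula parses to the expected structure", {
  f <- parse_formula("(value - avg(BLANK)) / (avg(CTRL_B) - avg(BLANK)) * 100")
  counts <- c(value = 0, agg = 0)
  walk <- function(n) {
    if (n$type == "value") counts["value"] <<- counts["value"] + 1
    if (n$type == "agg") counts["agg"] <<- counts["agg"] + 1
    if (n$type == "binop") { walk(n$lhs); walk(n$rhs) }
    if (n$type == "neg") walk(n$arg)
  }
  walk(f$ast)
  expect_equal(unname(counts["value"]), 1)
  expect_equal(unname(counts["agg"]), 3)
})

test_that("syntax errors carry a character position", {
  err <- tryCatch(parse_formula("avg("), pw_parse_error = function(e) e)
  expect_s3_class(err, "pw_parse_error")
  expect_false(is.na(err$position))
  expect_match(conditionMessage(err), "position")
  expect_error(parse_formula("foo(X)"), class = "pw_parse_error")   # unknown function
  expect_error(parse_formula("1 + "), class = "pw_parse_error")
  expect_error(parse_formula("1 2"), class = "pw_parse_error")
  expect_error(parse_formula("avg(BLANK) @ 2"), class = "pw_parse_error")
  expect_error(parse_formula("bogusname"), class = "pw_parse_error")
})

test_that("deparse/parse round-trips the AST", {
  sources <- c(
    "1 + 2 * 3",
    "(value - avg(BLANK)) / (avg(CTRL_B) - avg(BLANK)) * 100",
    "-(value / plate(noise)) + median(S1) - count(BLANK)",
    "A1 + B12 * cv(CTRL_B)")
  for (src in sources) {
    f <- parse_formula(src)
    expect_identical(parse_formula(deparse_formula(f))$ast, f$ast, label = src)
  }
})

test_that("well functions compute the survival index from group averages", {
  d <- demo_design()
  plate <- fill_demo_plate(d, 600, control = 1100, blank = 100)
  si <- d$layout$well_functions$SI$formula
  expect_equal(eval_well_function(plate, si, "D2"), 50)  # (600-100)/(1100-100)*100
  expect_equal(eval_well_function(plate, "value", "D2"), 600)
  # degenerate controls: avg(CTRL_B) == avg(BLANK) -> division by zero -> missing
  degenerate <- fill_demo_plate(d, 600, control = 100, blank = 100)
  expect_true(is.na(eval_well_function(degenerate, si, "D2")))
  expect_error(eval_well_function(plate, "avg(NOGROUP)", "D2"),
               class = "pw_reference_error")
})

test_that("plate functions aggregate the plate and reject the value token", {
  d <- demo_design()
  plate <- fill_demo_plate(d, 600)
  vals <- stats::setNames(plate$wells$raw_value, plate$wells$label)
  vals[paste0("B", 2:11)] <- rep(c(90, 100, 110), length.out = 10)
  vals[paste0("B", 2:4)] <- c(90, 100, 110)
  vals[paste0("B", 5:11)] <- 100  # keep mean 100
  plate <- set_raw_values(plate, vals)
  expect_equal(eval_plate_function(plate, "avg(CTRL_B)"),
               mean(vals[paste0("B", 2:11)]))
  expect_equal(eval_plate_function(plate, "sd(CTRL_B)"),
               sd(vals[paste0("B", 2:11)]))
  expect_error(eval_plate_function(plate, "value + 1"), class = "pw_validation_error")
  expect_error(add_plate_function(d$layout, "bad", "value + 1"),
               class = "pw_validation_error")
})

test_that("named plate functions resolve from formulas, and cycles are refused", {
  d <- demo_design()
  lay <- add_plate_function(d$layout, "mean_all", "avg(CTRL_B)")
  lay <- add_plate_function(lay, "sd_all", "sd(CTRL_B)")
  lay <- add_well_function(lay, "Z", "(value - plate(mean_all)) / plate(sd_all)",
                           d$sub_wells)
  mp <- master_plate("MZ", lay, list(
    S1 = list(substance = d$substance, concentrations = d$concentrations)))
  plate <- create_plate(mp, "PZ", "pz", assay_sample("cell_line", "CEM"))
  vals <- stats::setNames(rep(0, 96), plate$wells$label)
  vals[paste0("B", 2:11)] <- c(90, 110, rep(100, 8))
  vals["D2"] <- 110
  plate <- set_raw_values(plate, vals)
  ctrl <- vals[paste0("B", 2:11)]
  expect_equal(eval_well_function(plate, lay$well_functions$Z$formula, "D2"),
               (110 - mean(ctrl)) / sd(ctrl))
  # cycle: f -> g -> f
  lay2 <- add_plate_function(lay, "f", "plate(g) + 1")
  lay3 <- add_plate_function(lay2, "g", "plate(f)")
  mp2 <- master_plate("MZ2", lay3, list(
    S1 = list(substance = d$substance, concentrations = d$concentrations)))
  plate2 <- set_raw_values(create_plate(mp2, "PZ2", "pz2", assay_sample("cell_line", "x")), vals)
  expect_error(eval_plate_function(plate2, "plate(f)"), class = "pw_reference_error")
  expect_error(eval_plate_function(plate, "plate(nosuch)"), class = "pw_reference_error")
})

test_that("missing data propagates as missing, never as an exception", {
  d <- demo_design()
  plate <- set_raw_values(d$plate, c(D2 = 5))  # everything else empty
  expect_true(is.na(eval_well_function(plate, "value + A1", "D2")))  # A1 empty
  expect_true(is.na(eval_well_function(plate, "value", "D3")))       # own well empty
  expect_true(is.na(eval_plate_function(plate, "avg(BLANK)")))       # empty group
  expect_equal(eval_plate_function(plate, "count(BLANK)"), 0)
  expect_true(is.na(eval_well_function(plate, "1 / 0", "D2")))       # div by zero
})

test_that("marking outliers is equivalent to recomputing on the reduced sample", {
  set.seed(101)
  fns <- c("avg", "sd", "cv", "min", "max", "median", "count")
  for (rep_i in 1:10) {
    d <- demo_design()
    ctrl_wells <- paste0("B", 2:11)
    vals <- stats::setNames(runif(96, 50, 1500), d$plate$wells$label)
    plate <- set_raw_values(d$plate, vals)
    out <- sample(ctrl_wells, sample(1:3, 1))
    plate_out <- mark_outlier(plate, out)
    kept <- setdiff(ctrl_wells, out)
    for (fn in fns) {
      got <- eval_plate_function(plate_out, sprintf("%s(CTRL_B)", fn))
      want <- agg_oracle(fn, unname(vals[kept]))
      expect_equal(got, want, label = fn)
    }
    # groups not containing the well are untouched
    expect_equal(eval_plate_function(plate_out, "avg(BLANK)"),
                 eval_plate_function(plate, "avg(BLANK)"))
  }
})

test_that("aggregates match brute-force recomputation on random plates", {
  set.seed(202)
  for (rep_i in 1:10) {
    d <- demo_design()
    vals <- stats::setNames(rnorm(96, 500, 200), d$plate$wells$label)
    plate <- set_raw_values(d$plate, vals)
    for (fn in c("avg", "sd", "cv", "min", "max", "median", "count")) {
      for (grp in c("CTRL_B", "BLANK", "S1")) {
        m <- Filter(function(m) m$name == grp, d$layout$markers)[[1]]
        expect_equal(eval_plate_function(plate, sprintf("%s(%s)", fn, grp)),
                     agg_oracle(fn, unname(vals[m$positions])),
                     label = sprintf("%s(%s)", fn, grp))
      }
    }
  }
})

test_that("evaluation is pure: identical results on an unchanged plate", {
  d <- demo_design()
  plate <- fill_demo_plate(d, c(600))
  si <- d$layout$well_functions$SI$formula
  a <- vapply(d$sub_wells, function(w) eval_well_function(plate, si, w), numeric(1))
  b <- vapply(d$sub_wells, function(w) eval_well_function(plate, si, w), numeric(1))
  expect_identical(a, b)
})
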