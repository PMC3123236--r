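test_that("control CV% is computed per group and pooled", {
  d <- demo_design()
  plate <- fill_demo_plate(d, 600)
  vals <- stats::setNames(plate$wells$raw_value, plate$wells$label)
  vals[paste0("B", 2:11)] <- c(90, 100, 110, rep(100, 7))
  plate <- set_raw_values(plate, vals)
  ctrl <- unname(vals[paste0("B", 2:11)])
  cv <- control_cv(plate)
  expect_equal(unname(cv$per_group["CTRL_B"]), 100 * sd(ctrl) / mean(ctrl))
  expect_equal(cv$pooled, unname(cv$per_group["CTRL_B"]))  # single group: same set
  # the documented 3-well example: sd 10, mean 100 -> 10%
  lay <- plate_layout("Lx", plate_type("tx", 8, 12))
  lay <- place_marker(lay, "C1", "control", c("B2", "B3", "B4"))
  lay <- place_marker(lay, "C2", "control", c("C2", "C3"))
  mp <- master_plate("Mx", lay)
  p <- create_plate(mp, "PB", "pb", assay_sample("cell_line", "x"))
  p <- set_raw_values(p, c(B2 = 90, B3 = 100, B4 = 110, C2 = 100, C3 = 100))
  cv <- control_cv(p)
  expect_equal(unname(cv$per_group["C1"]), 10)
  expect_equal(unname(cv$per_group["C2"]), 0)
  expect_equal(cv$pooled, 100 * sd(c(90, 100, 110, 100, 100)) / 100)
})

test_that("degenerate control groups give missing CV entries", {
  lay <- plate_layout("L", plate_type("t", 8, 12))
  lay <- place_marker(lay, "C1", "control", "B2")
  mp <- master_plate("M", lay)
  p <- set_raw_values(create_plate(mp, "P", "p", assay_sample("cell_line", "x")),
                      c(B2 = 100))
  expect_true(is.na(control_cv(p)$per_group["C1"]))  # sample sd of n=1 undefined
  # no control markers at all
  lay2 <- plate_layout("L2", plate_type("t2", 8, 12))
  lay2 <- place_marker(lay2, "BLANK", "blank", "B2")
  p2 <- set_raw_values(create_plate(master_plate("M2", lay2), "P2", "p2",
                                    assay_sample("cell_line", "x")), c(B2 = 1))
  expect_error(control_cv(p2), class = "pw_validation_error")
})

test_that("CV% is invariant under positive scaling of the raw values", {
  set.seed(33)
  d <- demo_design()
  vals <- stats::setNames(runif(96, 100, 2000), d$plate$wells$label)
  p1 <- set_raw_values(d$plate, vals)
  for (k in c(0.001, 0.5, 7, 1e4)) {
    p2 <- set_raw_values(d$plate, vals * k)
    expect_equal(control_cv(p2)$per_group, control_cv(p1)$per_group)
    expect_equal(control_cv(p2)$pooled, control_cv(p1)$pooled)
  }
})

test_that("z-scores centre and scale by the reference set", {
  lay <- plate_layout("L", plate_type("t", 8, 12))
  lay <- place_marker(lay, "C", "control", c("B2", "B3", "B4"))
  p <- create_plate(master_plate("M", lay), "P", "p", assay_sample("cell_line", "x"))
  p <- set_raw_values(p, c(B2 = 0, B3 = 10, B4 = 5))
  z <- z_scores(p, c("B2", "B3"))
  expect_equal(unname(z["B3"]), (10 - 5) / sd(c(0, 10)))  # +0.70710678
  expect_equal(unname(z["B3"]), 0.7071068, tolerance = 1e-6)
  z3 <- z_scores(p, c("B2", "B3", "B4"))
  expect_equal(unname(z3["B4"]), 0)  # at the mean
  p_flat <- set_raw_values(p, c(B2 = 7, B3 = 7, B4 = 7))
  expect_true(all(is.na(z_scores(p_flat, c("B2", "B3", "B4")))))
  expect_error(z_scores(p, "B2"), class = "pw_validation_error")
})

test_that("dose-response curves group replicates and honour outliers", {
  d <- demo_design(replicates = 2L, n_steps = 5L)
  # response linear in concentration index, replicate rows identical
  si_raw <- c(900, 700, 500, 300, 200)
  plate <- fill_demo_plate(d, rep(si_raw, 2))
  curve <- build_dose_response(plate, "drugA")
  expect_equal(nrow(curve$points), 5)
  expect_equal(curve$points$n, rep(2L, 5))
  expect_true(all(diff(curve$points$concentration) > 0))
  expect_equal(curve$points$sd, rep(0, 5))
  # perturb one replicate, mark it outlier: point reverts to the remaining value
  vals <- stats::setNames(plate$wells$raw_value, plate$wells$label)
  vals["E2"] <- 9999
  plate2 <- set_raw_values(plate, vals)
  c_dirty <- build_dose_response(plate2, "drugA")
  plate3 <- mark_outlier(plate2, "E2")
  c_clean <- build_dose_response(plate3, "drugA")
  top_conc <- max(c_clean$points$concentration)
  i <- which(c_clean$points$concentration == top_conc)
  expect_equal(c_clean$points$n[i], 1L)
  expect_true(is.na(c_clean$points$sd[i]))
  expect_equal(c_clean$points$mean_response[i],
               eval_well_function(plate3, d$layout$well_functions$SI$formula, "D2"))
  expect_gt(c_dirty$points$mean_response[i], c_clean$points$mean_response[i])
  # all replicates outliers -> empty-curve error
  all_out <- mark_outlier(plate, d$sub_wells)
  expect_error(build_dose_response(all_out, "drugA"), class = "pw_empty_curve_error")
  expect_error(build_dose_response(plate, "nosuchdrug"), class = "pw_reference_error")
})

test_that("linear-interpolation IC50 crosses half-way in log10 concentration", {
  curve <- dose_response(c(1, 10), c(75, 25))
  expect_equal(ic50_linear(curve), 10^0.5, tolerance = 1e-12)  # 3.1623
  exact <- dose_response(c(1, 2, 4), c(80, 50, 20))
  expect_equal(ic50_linear(exact), 2)
  high <- dose_response(c(1, 10, 100), c(95, 90, 80))
  res <- ic50_linear(high)
  expect_true(is.na(res))
  expect_equal(attr(res, "reason"), "no_crossing")
  # single point below 50 likewise undefined
  expect_true(is.na(ic50_linear(dose_response(5, 10))))
  # linear-axis variant is exposed behind the same switch
  expect_equal(ic50_linear(curve, axis = "linear"), 5.5)
})

test_that("among multiple bracketing pairs the one jointly closest to 50% wins", {
  # non-monotone: crossings between points 1-2 (75->40) and 3-4 (60->45)
  wavy <- dose_response(c(1, 10, 100, 1000), c(75, 40, 60, 45))
  got <- ic50_linear(wavy)
  # pair (60,45): |60-50|+|45-50| = 15 < pair (75,40): 25+10=35
  t <- (50 - 60) / (45 - 60)
  expect_equal(got, 10^(2 + t * 1))
  # exact tie in joint distance breaks toward the lower concentration
  tie <- dose_response(c(1, 10, 100, 1000), c(70, 30, 70, 30))
  t2 <- (50 - 70) / (30 - 70)
  expect_equal(ic50_linear(tie), 10^(0 + t2 * 1))
})

test_that("linear IC50 agrees with the dense-grid crossing oracle", {
  set.seed(505)
  for (i in 1:200) {
    curve <- random_monotone_curve()
    got <- ic50_linear(curve)
    want <- oracle_ic50_grid(curve)
    expect_lt(abs(got - want) / want, 1e-3)
  }
})

test_that("the piecewise-linear response at the reported IC50 is 50%", {
  set.seed(99)
  for (i in 1:50) {
    curve <- random_monotone_curve()
    ic50 <- ic50_linear(curve)
    expect_equal(response_at(curve, ic50), 50, tolerance = 1e-9)
  }
})

test_that("Hill fit recovers noiseless four-parameter logistic data exactly", {
  conc <- 10^seq(-2, 2, length.out = 8)
  resp <- 0 + (100 - 0) / (1 + (conc / 3)^1)
  fit <- ic50_hill(dose_response(conc, resp))
  expect_true(fit$converged)
  expect_equal(fit$ic50, 3, tolerance = 1e-6)
  expect_equal(fit$slope, 1, tolerance = 1e-4)
  expect_equal(fit$top, 100, tolerance = 1e-4)
  expect_equal(fit$bottom, 0, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-10)
  # steeper curve, shifted asymptotes
  resp2 <- 10 + (90 - 10) / (1 + (conc / 0.7)^2.5)
  fit2 <- ic50_hill(dose_response(conc, resp2))
  expect_equal(fit2$ic50, 0.7, tolerance = 1e-6)
  expect_equal(fit2$slope, 2.5, tolerance = 1e-3)
})

test_that("Hill and linear IC50 agree on symmetric unit-slope curves", {
  conc <- 10^seq(-2, 2, length.out = 9)
  resp <- 100 / (1 + (conc / 2))
  curve <- dose_response(conc, resp)
  lin <- ic50_linear(curve)
  hill <- ic50_hill(curve)$ic50
  expect_lt(abs(hill - lin) / lin, 0.02)
})

test_that("Hill fit refuses under-determined curves", {
  expect_error(ic50_hill(dose_response(c(1, 10, 100), c(90, 50, 10))),
               class = "pw_validation_error")
})

test_that("series comparison is a two-sided Welch t-test", {
  same <- compare_series(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shifted <- compare_series(c(1, 2, 3, 4), c(11, 12, 13, 14))
  ref <- t.test(c(1, 2, 3, 4), c(11, 12, 13, 14))
  expect_equal(shifted$t, unname(ref$statistic))
  expect_equal(shifted$p, ref$p.value)
  degenerate <- compare_series(c(0, 0, 0, 0), c(10, 10, 10, 10))
  expect_true(is.na(degenerate$p))
  expect_match(degenerate$reason, "variance")
  expect_error(compare_series(1, c(1, 2)), class = "pw_validation_error")
})

test_that("the Welch test holds its nominal type-I error rate", {
  set.seed(808)
  rejections <- 0L
  for (i in 1:1000) {
    a <- rnorm(6); b <- rnorm(6)
    if (compare_series(a, b)$p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / 1000
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
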