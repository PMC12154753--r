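test_that("parameter-model evaluation matches the printed equations", {
  ise_m <- ise_equations("male")
  ise_f <- ise_equations("female")

  # male FVC median at the derivation-cohort median demographics
  expect_equal(evaluate_parameter(ise_m$indices$fvc$mu, 174, 28.57),
               4.680042, tolerance = 1e-6)
  # female FEV1/FVC median (log link, positive age coefficient)
  expect_equal(evaluate_parameter(ise_f$indices$fev1_fvc$mu, 157, 34.79,
                                  allow_missing_spline = TRUE),
               exp(1.968086 - 0.416269 * log(157) + 0.009565 * log(34.79)),
               tolerance = 1e-12)
  # intercept-only model returns the intercept for any subject
  c0 <- parameter_model("identity", 2.5)
  expect_equal(evaluate_parameter(c0, c(150, 190), c(20, 60)), c(2.5, 2.5))
})

test_that("predicted medians reproduce the printed forms", {
  ise_m <- ise_equations("male")
  ise_f <- ise_equations("female")
  expect_equal(predict_median(ise_m, "fef2575", 174, 28.57), exp(1.5),
               tolerance = 1e-4)
  expect_equal(predict_median(ise_f, "fvc", 157, 34.79), 3.102473,
               tolerance = 1e-6)
  expect_error(predict_median(ise_m, "pef", 174, 30))
})

test_that("percent predicted is the plain ratio on the percent scale", {
  expect_equal(percent_predicted(4.2, 4.2), 100)
  expect_equal(percent_predicted(0, 3.1), 0)
  expect_equal(percent_predicted(4.64, 4.680042), 99.1444, tolerance = 1e-4)
  # scale-free
  expect_equal(percent_predicted(2 * 4.64, 2 * 4.680042),
               percent_predicted(4.64, 4.680042))
})

test_that("Z-scores under an equation set match the family closed forms", {
  ise_m <- ise_equations("male")
  ise_f <- ise_equations("female")
  expect_equal(zscore_for(ise_m, index = "fvc", measured = 4.64,
                          height = 174, age = 28.57),
               -0.0737073, tolerance = 1e-6)
  expect_equal(zscore_for(ise_f, index = "fvc", measured = 3.18,
                          height = 157, age = 34.79),
               0.1945023, tolerance = 1e-6)
  # measured at the predicted median gives zero
  mu <- predict_median(ise_m, "fef2575", 174, 40)
  expect_equal(zscore_for(ise_m, index = "fef2575", measured = mu,
                          height = 174, age = 40), 0, tolerance = 1e-12)
  # strictly increasing in the measured value
  z <- zscore_for(ise_f, index = "fef2575",
                  measured = seq(1.5, 5, by = 0.25), height = 157, age = 35)
  expect_true(all(diff(z) > 0))
})

test_that("packaged ISE matches the derivation-cohort medians within 5%", {
  med <- list(
    male = list(h = 174, a = 28.57,
                fev1 = 3.98, fvc = 4.64, fev1_fvc = 0.86, fef2575 = 4.44),
    female = list(h = 157, a = 34.79,
                  fev1 = 2.91, fvc = 3.18, fev1_fvc = 0.90, fef2575 = 3.55))
  for (sex in names(med)) {
    eq <- ise_equations(sex)
    m <- med[[sex]]
    for (ix in SPIRO_INDICES) {
      pred <- predict_median(eq, ix, m$h, m$a)
      expect_lt(abs(pred / m[[ix]] - 1), 0.05,
                label = sprintf("%s %s relative error", sex, ix))
    }
  }
})

test_that("packaged ISE carries the printed sigma/nu coefficients exactly", {
  ise_m <- ise_equations("male")
  expect_identical(ise_m$indices$fvc$sigma$intercept, -2.14143)
  expect_identical(ise_m$indices$fvc$sigma$link, "log")
  expect_identical(ise_m$indices$fvc$nu$intercept, -1.8044)
  ise_f <- ise_equations("female")
  expect_identical(ise_f$indices$fef2575$family, "BCPE")
  expect_identical(ise_f$indices$fef2575$tau$intercept, 0.6736)
})

test_that("equation-set JSON round-trips exactly and validates its schema", {
  eq <- ise_equations("female")
  tf <- withr::local_tempfile(fileext = ".json")
  save_equation_set(eq, tf)
  eq2 <- load_equation_set(tf)
  expect_equal(eq2, eq, tolerance = 0)

  # a BCPE index without a tau model is rejected with the field path
  obj <- jsonlite::read_json(tf)
  obj$indices$fef2575$tau <- NULL
  tf2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, tf2, auto_unbox = TRUE, digits = NA)
  expect_error(load_equation_set(tf2), "fef2575.*tau")

  # not an equation-set file
  tf3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), tf3, auto_unbox = TRUE)
  expect_error(load_equation_set(tf3), "format")
})

test_that("declared-but-missing splines need the explicit acknowledgment", {
  pm_spl <- parameter_model("log", -2, spline_declared = TRUE)
  idx <- list(family = "BCCG", mu = pm_spl,
              sigma = parameter_model("log", -2),
              nu = parameter_model("identity", 1))
  idc <- list(fev1 = idx, fvc = idx, fev1_fvc = idx, fef2575 = idx)
  expect_error(equation_set("x", "male", idc), "acknowledg")
  eq <- equation_set("x", "male", idc, splines_omitted_acknowledged = TRUE)
  expect_silent(p <- equation_params(eq, "fvc", 170, 30))
  # direct evaluation without the opt-in errors, naming the situation
  expect_error(evaluate_parameter(pm_spl, 170, 30), "spline")
})

test_that("spline tables interpolate through knots and clamp outside", {
  s <- spline_table(c(20, 30, 40, 60), c(0, 0.1, -0.05, 0.02))
  expect_equal(eval_spline(s, c(20, 30, 40, 60)), c(0, 0.1, -0.05, 0.02))
  expect_equal(eval_spline(s, 10), eval_spline(s, 20))   # clamped left
  expect_equal(eval_spline(s, 90), eval_spline(s, 60))   # clamped right
  expect_error(spline_table(c(30, 20), c(0, 1)), "increasing")
  expect_error(spline_table(25, 0), "knots")
  # a populated spline contributes on the link scale
  pm <- parameter_model("log", -1.2, spline = s)
  expect_equal(evaluate_parameter(pm, 170, 30), exp(-1.2 + 0.1))
})

test_that("ages outside the validity range warn but evaluate", {
  eq <- ise_equations("male")
  expect_warning(predict_median(eq, "fvc", 174, 75), "valid range")
  expect_warning(predict_median(eq, "fvc", 174, 15), "valid range")
  expect_silent(predict_median(eq, "fvc", 174, 45))
})
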