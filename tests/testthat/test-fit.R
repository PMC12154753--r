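# shared fits: a two-sex cohort large enough for stable recovery checks
recov_cohort <- generate_cohort(cohort_spec(n = 10000, female_fraction = 0.5,
                                            seed = 42))

test_that("normal family with identity link reduces to ordinary least squares", {
  d <- recov_cohort[recov_cohort$sex == "male", ]
  fit <- spiro_gamlss(d, "fvc", model_spec("normal", sigma_terms = character()))
  ols <- lm(fvc_l ~ log(height_cm) + log(age_years), data = d)
  expect_lt(max(abs(coef(fit, "mu") - coef(ols))), 1e-6)
  expect_true(fit$converged)
})

test_that("SBC formula and monotonicity in df", {
  expect_equal(sbc(-100, 5, 100), 200 + 5 * log(100))
  expect_equal(sbc(-123.4, 0, 50), 246.8)
  expect_gt(sbc(-100, 6, 100), sbc(-100, 5, 100))
})

test_that("BCCG fit recovers the generating FVC model", {
  truth <- list(male = c(int = -8.37157, blh = 2.05757, bla = -0.20888,
                         lsig = -2.14143, nu = -1.8044),
                female = c(int = -11.26749, blh = 2.61061, bla = -0.22545,
                           lsig = -2.08730, nu = -1.8645))
  for (s in c("male", "female")) {
    fit <- spiro_gamlss(recov_cohort, "fvc",
                        model_spec("BCCG", sigma_terms = character()), sex = s)
    expect_true(fit$converged)
    b <- coef(fit, "mu"); tr <- truth[[s]]
    # the well-conditioned contrasts: age slope, sigma, nu
    expect_lt(abs(b[["log_age"]] - tr[["bla"]]), 0.02)
    expect_lt(abs(exp(coef(fit, "sigma")[["intercept"]] - tr[["lsig"]]) - 1), 0.05)
    expect_lt(abs(coef(fit, "nu")[["intercept"]] - tr[["nu"]]), 0.3)
    # the fitted median surface agrees with the truth surface even though
    # intercept and height slope are individually poorly identified
    d <- recov_cohort[recov_cohort$sex == s, ]
    mu_hat <- predict(fit, d, what = "median")
    mu_true <- exp(tr[["int"]] + tr[["blh"]] * log(d$height_cm) +
                     tr[["bla"]] * log(d$age_years))
    expect_lt(max(abs(mu_hat / mu_true - 1)), 0.02)
    # in-sample quantile residuals of a correct fit are standard normal
    r <- residuals(fit)
    expect_lt(abs(mean(r)), 0.05)
    expect_lt(abs(sd(r) - 1), 0.1)
  }
})

test_that("BCPE fit handles the kurtosis-modelled index", {
  fit <- spiro_gamlss(recov_cohort, "fef2575",
                      model_spec("BCPE", nu_terms = "log_age",
                                 tau_terms = "log_age"), sex = "female")
  expect_true(fit$converged)
  r <- residuals(fit)
  expect_lt(abs(mean(r)), 0.05)
  expect_lt(abs(sd(r) - 1), 0.1)
})

test_that("quantile residuals equal Z-scores under the fitted equation set", {
  d <- recov_cohort[recov_cohort$sex == "male", ][1:800, ]
  fit <- spiro_gamlss(d, "fvc", model_spec("BCCG", sigma_terms = character()))
  pm <- fit_parameter_models(fit)
  idx <- c(list(family = "BCCG"), pm)
  eq <- equation_set("refit", "male",
                     list(fev1 = idx, fvc = idx, fev1_fvc = idx, fef2575 = idx),
                     valid_age_range = c(18, 70))
  expect_equal(residuals(fit), zscore_for(eq, d, "fvc"), tolerance = 1e-12)
  # record at its fitted median has residual zero
  mu1 <- predict(fit, d[1, ], what = "median")
  d1 <- d[1, ]; d1$fvc_l <- mu1
  expect_equal(zscore_for(eq, d1, "fvc"), 0, tolerance = 1e-12)
})

test_that("fitting is invariant to record order", {
  d <- recov_cohort[recov_cohort$sex == "male", ][1:1500, ]
  f1 <- spiro_gamlss(d, "fvc", model_spec("BCCG", sigma_terms = character()))
  set.seed(1); d2 <- d[sample(nrow(d)), ]
  f2 <- spiro_gamlss(d2, "fvc", model_spec("BCCG", sigma_terms = character()))
  expect_lt(max(abs(unlist(coef(f1)) - unlist(coef(f2)))), 1e-5)
})

test_that("degenerate designs raise named errors", {
  d <- recov_cohort[recov_cohort$sex == "male", ][1:200, ]
  d$height_cm <- 174
  expect_error(spiro_gamlss(d, "fvc", model_spec("BCCG")), "log_height")
  expect_error(spiro_gamlss(d[1:30, ], "fvc", model_spec("BCCG")), "50")
  d2 <- recov_cohort[recov_cohort$sex == "male", ][1:200, ]
  d2$fvc_l[5] <- -1
  expect_error(spiro_gamlss(d2, "fvc", model_spec("BCCG")), "positive")
})

test_that("model selection ranks by SBC with the parsimony tie rule", {
  # pure rule: SBC difference 0.5 with df 8 vs 12 -> the df-8 model wins
  elig <- data.frame(candidate = c(1L, 2L), sbc = c(100.5, 100.0),
                     df = c(8, 12))
  expect_equal(spiroref:::.select_from_ranking(elig, delta_sbc = 2), 1L)
  # outside the window SBC rules
  elig2 <- data.frame(candidate = c(1L, 2L), sbc = c(105, 100), df = c(8, 12))
  expect_equal(spiroref:::.select_from_ranking(elig2, delta_sbc = 2), 2L)

  d <- recov_cohort[recov_cohort$sex == "male", ][1:1200, ]
  menu1 <- list(model_spec("BCCG", sigma_terms = character()))
  sel1 <- select_model(d, "fvc", menu1)
  expect_identical(sel1$selected$spec$label, menu1[[1]]$label)
  expect_error(select_model(d, "fvc", list()), "empty")

  # spline-free truth: the spline-free candidate is selected
  menu2 <- list(model_spec("BCCG", sigma_terms = character()),
                model_spec("BCCG", sigma_terms = character(), mu_spline = TRUE))
  sel2 <- select_model(d, "fvc", menu2)
  expect_false(sel2$selected$spec$mu_spline)
  expect_equal(nrow(sel2$ranking), 2)
})

test_that("worm-plot data partitions records and is flat under the null", {
  set.seed(77)
  r <- rnorm(400); ages <- runif(400, 18, 70)
  wd <- worm_plot_data(r, ages, n_bins = 4)
  expect_equal(nrow(wd), 400)
  counts <- table(wd$bin)
  expect_lte(max(counts) - min(counts), 1)  # equal counts +/- 1
  # one bin reduces to a global detrended QQ plot
  wd1 <- worm_plot_data(r, ages, n_bins = 1)
  expect_equal(wd1$y, sort(r) - qnorm(ppoints(400)))

  # null calibration: with standard-normal residuals every worm is centred
  # on zero (per-bin mean deviation; single order statistics in the tails
  # fluctuate by far more than any useful band and are not the diagnostic)
  ok <- 0L
  for (s in 1:20) {
    set.seed(1000 + s)
    rr <- rnorm(4000); aa <- runif(4000, 18, 70)
    w <- worm_plot_data(rr, aa, n_bins = 4)
    centred <- max(abs(tapply(w$y, w$bin, mean)))
    if (centred < 0.15) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})

test_that("centile curves are ordered, and the median curve tracks age decline", {
  eq <- ise_equations("male")
  cc <- centile_curves(eq, "fvc", centiles = c(0.05, 0.5, 0.95),
                       age_grid = 20:60, height = 174)
  wide <- reshape(cc, idvar = "age", timevar = "centile", direction = "wide")
  expect_true(all(wide$`value.0.05` < wide$`value.0.5`))
  expect_true(all(wide$`value.0.5` < wide$`value.0.95`))
  # 50th centile equals the predicted median
  expect_equal(wide$`value.0.5`, predict_median(eq, "fvc", 174, 20:60),
               tolerance = 1e-12)
  # printed age coefficient is negative: the median declines over 20 -> 60
  expect_true(all(diff(wide$`value.0.5`) < 0))
})

test_that("a refitted equation set round-trips through serialization", {
  eq <- refit_equation_set(recov_cohort[1:4000, ], sex = "male")
  expect_s3_class(eq, "equation_set")
  tf <- withr::local_tempfile(fileext = ".json")
  save_equation_set(eq, tf)
  eq2 <- load_equation_set(tf)
  d <- recov_cohort[recov_cohort$sex == "male", ][1:200, ]
  expect_equal(zscore_for(eq2, d, "fvc"), zscore_for(eq, d, "fvc"),
               tolerance = 1e-9)
  # refit reproduces the generating median surface to a few percent
  mu_hat <- predict_median(eq, "fvc", d$height_cm, d$age_years)
  mu_true <- predict_median(ise_equations("male"), "fvc", d$height_cm, d$age_years)
  expect_lt(max(abs(mu_hat / mu_true - 1)), 0.05)
})
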