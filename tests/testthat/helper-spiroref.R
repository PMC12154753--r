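# shared fixtures, built in code

# quadrature oracle: Z-score via numeric CDF inversion of the density
quadrature_zscore <- function(y, mu, sigma, nu, tau = NULL) {
  dens <- if (is.null(tau)) {
    function(t) bccg_density(t, mu, sigma, nu)
  } else {
    function(t) bcpe_density(t, mu, sigma, nu, tau)
  }
  F <- stats::integrate(dens, lower = 1e-8, upper = y,
                        rel.tol = 1e-12, subdivisions = 400L)$value
  if (F <= 0.5) return(stats::qnorm(F))
  # integrate the upper tail instead: avoids 1 - F cancellation
  up <- stats::integrate(dens, lower = y, upper = Inf,
                         rel.tol = 1e-12, subdivisions = 400L)$value
  stats::qnorm(up, lower.tail = FALSE)
}

# random BCCG/BCPE parameter draws restricted to the regime where the
# ignored Box-Cox truncation mass is negligible (< 1e-10): only there is
# the untruncated Z-score an exact CDF inversion, so only there is the
# quadrature-oracle identity well posed at 1e-7
draw_proper_params <- function(bcpe = FALSE) {
  repeat {
    mu <- runif(1, 0.5, 6); s <- runif(1, 0.03, 0.25); nu <- runif(1, -3, 3)
    tau <- if (bcpe) runif(1, 1, 4) else NULL
    if (spiroref:::.truncation_mass(mu, s, nu, tau) < 1e-10)
      return(list(mu = mu, sigma = s, nu = nu, tau = tau))
  }
}

# subject-specific parameters of the packaged male FVC equation at the
# derivation-cohort median demographics
male_fvc_params <- function() {
  list(mu = exp(-8.37157 + 2.05757 * log(174) - 0.20888 * log(28.57)),
       sigma = exp(-2.14143), nu = -1.8044)
}

# minimal all-BCCG equation set (no splines) for structural tests
toy_equation_set <- function(sex = "male") {
  pm <- function(int, blh = 0, bla = 0, link = "log")
    parameter_model(link, int, blh, bla)
  idx <- function(int) list(family = "BCCG", mu = pm(int, 0.5, -0.1),
                            sigma = pm(-2), nu = parameter_model("identity", 1))
  equation_set(name = paste0("toy-", sex), sex = sex,
               indices = list(fev1 = idx(-1.5), fvc = idx(-1.3),
                              fev1_fvc = idx(-0.15), fef2575 = idx(-1.2)))
}

# a cohort row with all eligibility flags false
clean_record <- function(sex = "male", age = 30, height = 170,
                         fev1 = 3.5, fvc = 4.2, fef = 4.0) {
  out <- data.frame(sex = sex, age_years = age, height_cm = height,
                    fev1_l = fev1, fvc_l = fvc, ratio = fev1 / fvc,
                    fef2575_ls = fef, stringsAsFactors = FALSE)
  for (f in EXCLUSION_FLAGS) out[[f]] <- FALSE
  out
}

# multiplicatively bias the median model of every index of an equation set
shift_mu <- function(eq, factor, name = NULL) {
  for (ix in names(eq$indices)) {
    m <- eq$indices[[ix]]$mu
    if (m$link == "log") {
      m$intercept <- m$intercept + log(factor)
    } else {
      m$intercept <- m$intercept * factor
      m$beta_log_height <- m$beta_log_height * factor
      m$beta_log_age <- m$beta_log_age * factor
    }
    eq$indices[[ix]]$mu <- m
  }
  eq$name <- if (is.null(name)) paste0(eq$name, "-x", factor) else name
  eq
}
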