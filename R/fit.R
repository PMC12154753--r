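# GAMLSS-style fitting of spirometric reference models: cyclic (backfitting)
# updates of the distribution parameters, each by penalised weighted least
# squares on its link scale, with P-spline age smooths.

.TERMS <- c("log_height", "log_age")

#' Candidate model specification for reference-equation fitting
#'
#' Describes one candidate in the location-scale-shape model menu: the
#' response family and, per distribution parameter, the linear terms (drawn
#' from log(height) and log(age)), the link, and whether an age P-spline is
#' added. The median model always includes an intercept; splines are allowed
#' on mu and sigma only (published spirometric equations never smooth the
#' shape parameters).
#'
#' @param family \code{"BCCG"}, \code{"BCPE"} or \code{"normal"}.
#' @param mu_link link for the median model (\code{"log"} default;
#'   \code{"identity"} for the normal family).
#' @param mu_terms,sigma_terms,nu_terms,tau_terms character subsets of
#'   \code{c("log_height", "log_age")}; intercepts are implicit.
#' @param mu_spline,sigma_spline add a P-spline in age?
#' @param spline_df target effective degrees of freedom of each spline term
#'   (beyond the linear terms), default 3.
#' @param label optional label used in rankings.
#' @return an object of class \code{"model_spec"}.
#' @export
model_spec <- function(family = c("BCCG", "BCPE", "normal"),
                       mu_link = NULL,
                       mu_terms = c("log_height", "log_age"),
                       mu_spline = FALSE,
                       sigma_terms = "log_age",
                       sigma_spline = FALSE,
                       nu_terms = character(),
                       tau_terms = character(),
                       spline_df = 3,
                       label = NULL) {
  family <- match.arg(family)
  if (is.null(mu_link)) mu_link <- if (family == "normal") "identity" else "log"
  mu_link <- match.arg(mu_link, c("log", "identity"))
  chk <- function(tt, nm) {
    if (length(tt) && !all(tt %in% .TERMS))
      stop(sprintf("'%s' must be a subset of {%s}", nm, paste(.TERMS, collapse = ", ")),
           call. = FALSE)
    tt
  }
  spec <- list(family = family, mu_link = mu_link,
               mu_terms = chk(mu_terms, "mu_terms"),
               mu_spline = isTRUE(mu_spline),
               sigma_terms = chk(sigma_terms, "sigma_terms"),
               sigma_spline = isTRUE(sigma_spline),
               nu_terms = chk(nu_terms, "nu_terms"),
               tau_terms = chk(tau_terms, "tau_terms"),
               spline_df = spline_df)
  if (is.null(label)) {
    bits <- c(family,
              paste0("mu~", paste(c("1", spec$mu_terms,
                                    if (spec$mu_spline) "s(age)"), collapse = "+")),
              paste0("sigma~", paste(c("1", spec$sigma_terms,
                                       if (spec$sigma_spline) "s(age)"), collapse = "+")))
    if (family != "normal")
      bits <- c(bits, paste0("nu~", paste(c("1", spec$nu_terms), collapse = "+")))
    if (family == "BCPE")
      bits <- c(bits, paste0("tau~", paste(c("1", spec$tau_terms), collapse = "+")))
    label <- paste(bits, collapse = "; ")
  }
  spec$label <- label
  structure(spec, class = "model_spec")
}

#' Default candidate menu of location-scale-shape models
#'
#' The cross of family (BCCG, BCPE) with spline placement (none, mu only,
#' mu and sigma), a constant vs log(age) skewness model, and for BCPE a
#' constant vs log(age) kurtosis model. The median model is always
#' log(height) + log(age). This spans every structural form appearing in
#' the published sex-specific equations.
#'
#' @param families families to include.
#' @param spline_df target spline effective df.
#' @return list of \code{\link{model_spec}} objects.
#' @export
default_model_menu <- function(families = c("BCCG", "BCPE"), spline_df = 3) {
  menu <- list()
  for (fam in families) {
    tau_opts <- if (fam == "BCPE") list(character(), "log_age") else list(NULL)
    for (spl in c("none", "mu", "mu+sigma"))
      for (nu_t in list(character(), "log_age"))
        for (tau_t in tau_opts) {
          menu[[length(menu) + 1L]] <- model_spec(
            family = fam,
            mu_spline = spl != "none",
            sigma_spline = spl == "mu+sigma",
            nu_terms = nu_t,
            tau_terms = if (is.null(tau_t)) character() else tau_t,
            spline_df = spline_df)
        }
  }
  menu
}

# log-density vector with invalid parameter regions mapped to -Inf (the
# optimiser treats them as forbidden rather than erroring out)
.ll_vec <- function(family, y, mu, sigma, nu = NULL, tau = NULL) {
  bad <- !is.finite(mu) | mu <= 0 | !is.finite(sigma) | sigma <= 0
  if (family == "BCPE") bad <- bad | !is.finite(tau) | tau <= 0
  if (family != "normal") bad <- bad | !is.finite(nu)
  out <- rep(-Inf, length(y))
  ok <- which(!bad)
  if (!length(ok)) return(out)
  rep_ok <- function(v) if (length(v) == 1L) rep(v, length(ok)) else v[ok]
  muo <- rep_ok(mu); so <- rep_ok(sigma)
  out[ok] <- switch(family,
    normal = stats::dnorm(y[ok], muo, so, log = TRUE),
    BCCG = {
      z <- .boxcox_u(y[ok], muo, so, rep_ok(nu))
      (rep_ok(nu) - 1) * log(y[ok]) - rep_ok(nu) * log(muo) - log(so) +
        stats::dnorm(z, log = TRUE)
    },
    BCPE = {
      u <- .boxcox_u(y[ok], muo, so, rep_ok(nu))
      (rep_ok(nu) - 1) * log(y[ok]) - rep_ok(nu) * log(muo) - log(so) +
        .pe_logdens(u, rep_ok(tau))
    })
  out[!is.finite(out)] <- -Inf
  out
}

.linkinv <- function(eta, link) if (link == "log") exp(eta) else eta

# build the fixed (parametric) design matrix for one parameter
.par_design <- function(terms, lh, la, n) {
  X <- matrix(1, n, 1L, dimnames = list(NULL, "intercept"))
  if ("log_height" %in% terms) X <- cbind(X, log_height = lh)
  if ("log_age" %in% terms) X <- cbind(X, log_age = la)
  X
}

# centred cubic P-spline basis with second-order difference penalty
.make_smooth <- function(age, k = 20) {
  sm <- mgcv::smoothCon(mgcv::s(age, bs = "ps", k = k, m = c(2, 2)),
                        data = data.frame(age = age), absorb.cons = TRUE)[[1]]
  sm
}

# effective df of the spline block at penalty lambda
.edf_spline <- function(A, S, lambda, spl_cols) {
  P <- matrix(0, nrow(A), ncol(A))
  P[spl_cols, spl_cols] <- lambda * S
  H <- tryCatch(solve(A + P, A), error = function(e) NULL)
  if (is.null(H)) return(NA_real_)
  sum(diag(H)[spl_cols])
}

.lambda_for_df <- function(A, S, target, spl_cols) {
  f <- function(loglam) .edf_spline(A, S, 10^loglam, spl_cols) - target
  lo <- -8; hi <- 10
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo <= 0) return(10^lo)
  if (fhi >= 0) return(10^hi)
  10^stats::uniroot(f, c(lo, hi), tol = 1e-3)$root
}

#' Fit a location-scale-shape spirometric reference model
#'
#' Fits one spirometric index against log(height) and log(age) by cyclic
#' backfitting over the distribution parameters (mu, sigma, nu, tau as the
#' family admits). Each cycle updates every parameter by penalised weighted
#' least squares on its link scale, using numerically evaluated first and
#' second derivatives of the log-likelihood with respect to the linear
#' predictor; age smooths use a centred cubic P-spline with a second-order
#' difference penalty whose roughness is chosen to hit the target effective
#' df. Iteration stops when the global deviance is stable (change below
#' \code{tol}) or after \code{max_cycles}; non-convergence is flagged, never
#' silent.
#'
#' @param data cohort data frame with \code{height_cm}, \code{age_years}
#'   and the measured column for \code{index}; if a \code{sex} column is
#'   present and \code{sex} is given, the cohort is subset first.
#' @param index one of \code{"fev1"}, \code{"fvc"}, \code{"fev1_fvc"},
#'   \code{"fef2575"}.
#' @param spec a \code{\link{model_spec}}.
#' @param sex optional subset (\code{"male"}/\code{"female"}).
#' @param tol (penalised) deviance-change convergence tolerance (default
#'   1e-3, the conventional global-deviance criterion for this class of
#'   backfitting algorithms).
#' @param max_cycles maximum outer cycles (default 200).
#' @return an object of class \code{"spiro_gamlss"}: fitted coefficients
#'   and smooths, per-parameter and total effective df, log-likelihood,
#'   SBC, convergence report, and the data needed by its methods
#'   (\code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{residuals}, \code{simulate}, \code{plot}, \code{logLik}).
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_spec(n = 800, seed = 42))
#' fit <- spiro_gamlss(coh, "fvc", model_spec("BCCG", sigma_terms = character()),
#'                     sex = "male")
#' coef(fit, "mu")
#' }
#' @export
spiro_gamlss <- function(data, index, spec = model_spec(), sex = NULL,
                         tol = 1e-3, max_cycles = 200L) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(data))
  index <- match.arg(index, SPIRO_INDICES)
  if (!is.null(sex) && "sex" %in% names(data))
    data <- data[data$sex == sex, , drop = FALSE]
  ycol <- .INDEX_COLUMNS[[index]]
  keep <- stats::complete.cases(data[, c(ycol, "height_cm", "age_years")])
  data <- data[keep, , drop = FALSE]
  y <- data[[ycol]]; height <- data$height_cm; age <- data$age_years
  n <- length(y)
  if (n <= 50) stop("need more than 50 usable records to fit", call. = FALSE)
  if (any(y <= 0)) stop("measured values must be positive", call. = FALSE)
  lh <- log(height); la <- log(age)
  if (stats::var(lh) < 1e-12 && ("log_height" %in% spec$mu_terms))
    stop("singular design: column 'log_height' is constant", call. = FALSE)
  if (stats::var(la) < 1e-12 &&
      ("log_age" %in% c(spec$mu_terms, spec$sigma_terms) || spec$mu_spline))
    stop("singular design: column 'log_age' is constant", call. = FALSE)

  fam <- spec$family
  pars <- switch(fam, normal = c("mu", "sigma"),
                 BCCG = c("mu", "sigma", "nu"),
                 BCPE = c("mu", "sigma", "nu", "tau"))
  links <- c(mu = spec$mu_link, sigma = "log", nu = "identity", tau = "log")

  sm <- if (spec$mu_spline || spec$sigma_spline) .make_smooth(age) else NULL
  P <- list()   # per-parameter design info
  for (p in pars) {
    terms <- spec[[paste0(p, "_terms")]]
    if (is.null(terms)) terms <- character()
    X <- .par_design(terms, lh, la, n)
    has_spl <- (p == "mu" && spec$mu_spline) || (p == "sigma" && spec$sigma_spline)
    Z <- if (has_spl) cbind(X, sm$X) else X
    spl_cols <- if (has_spl) (ncol(X) + 1L):ncol(Z) else integer(0)
    P[[p]] <- list(Z = Z, n_par = ncol(X), spl_cols = spl_cols,
                   has_spl = has_spl, lambda = NA_real_, edf = ncol(X),
                   beta = rep(0, ncol(Z)))
  }

  # --- initial values ---
  ylink <- if (links["mu"] == "log") log(y) else y
  b0 <- stats::lm.fit(P$mu$Z[, seq_len(P$mu$n_par), drop = FALSE], ylink)$coefficients
  P$mu$beta[seq_len(P$mu$n_par)] <- ifelse(is.na(b0), 0, b0)
  eta <- list()
  eta$mu <- drop(P$mu$Z %*% P$mu$beta)
  r0 <- if (links["mu"] == "log") log(y) - eta$mu else (y - eta$mu) / pmax(mean(y), 1e-8)
  s0 <- max(stats::sd(r0), 1e-3)
  if (fam == "normal") s0 <- max(stats::sd(y - .linkinv(eta$mu, links["mu"])), 1e-6)
  P$sigma$beta[1L] <- log(s0)
  eta$sigma <- drop(P$sigma$Z %*% P$sigma$beta)
  if ("nu" %in% pars) { P$nu$beta[1L] <- 1; eta$nu <- drop(P$nu$Z %*% P$nu$beta) }
  if ("tau" %in% pars) { P$tau$beta[1L] <- log(2); eta$tau <- drop(P$tau$Z %*% P$tau$beta) }

  cur_par <- function() {
    out <- list(mu = .linkinv(eta$mu, links["mu"]),
                sigma = .linkinv(eta$sigma, links["sigma"]))
    if ("nu" %in% pars) out$nu <- eta$nu
    if ("tau" %in% pars) out$tau <- exp(eta$tau)
    out
  }
  dev_of <- function(th) -2 * sum(.ll_vec(fam, y, th$mu, th$sigma, th$nu, th$tau))
  ll_at <- function(p, e) {
    th <- cur_par(); th[[p]] <- .linkinv(e, links[p])
    .ll_vec(fam, y, th$mu, th$sigma, th$nu, th$tau)
  }

  dev <- dev_of(cur_par())
  if (!is.finite(dev)) { # fall back to a mild skew start
    if ("nu" %in% pars) { P$nu$beta[1L] <- 0; eta$nu <- drop(P$nu$Z %*% P$nu$beta) }
    dev <- dev_of(cur_par())
  }
  converged <- FALSE; cycle <- 0L
  polish_count <- 0L
  h0 <- 1e-4
  # idx_map / pen_dev support the joint polish step inside the outer loop
  idx_map <- list(); off <- 0L
  for (p in pars) {
    idx_map[[p]] <- off + seq_along(P[[p]]$beta)
    off <- off + length(P[[p]]$beta)
  }
  pen_dev <- function(beta_all) {
    th <- list()
    pen <- 0
    for (p in pars) {
      b <- beta_all[idx_map[[p]]]
      e <- drop(P[[p]]$Z %*% b)
      th[[p]] <- .linkinv(e, links[p])
      if (length(P[[p]]$spl_cols) && is.finite(P[[p]]$lambda)) {
        bs <- b[P[[p]]$spl_cols]
        pen <- pen + P[[p]]$lambda * drop(crossprod(bs, sm$S[[1]] %*% bs))
      }
    }
    if ("tau" %in% pars) th$tau <- pmin(th$tau, 1e3)
    d <- -2 * sum(.ll_vec(fam, y, th$mu, th$sigma, th$nu, th$tau)) + pen
    if (!is.finite(d)) 1e10 else d
  }
  pen_dev_grad <- function(beta_all) {
    # chain rule: d(-2 loglik)/d beta_p = Z_p' (-2 dl/deta_p), with the
    # per-observation eta-derivative taken by central difference
    ee <- list(); th <- list()
    for (p in pars) {
      ee[[p]] <- drop(P[[p]]$Z %*% beta_all[idx_map[[p]]])
      th[[p]] <- .linkinv(ee[[p]], links[p])
    }
    ll_p <- function(p, e2) {
      t2 <- th; t2[[p]] <- .linkinv(e2, links[p])
      .ll_vec(fam, y, t2$mu, t2$sigma, t2$nu, t2$tau)
    }
    g <- numeric(length(beta_all))
    for (p in pars) {
      h <- h0 * pmax(1, abs(ee[[p]]))
      u <- (ll_p(p, ee[[p]] + h) - ll_p(p, ee[[p]] - h)) / (2 * h)
      u[!is.finite(u)] <- 0
      gp <- drop(crossprod(P[[p]]$Z, -2 * u))
      if (length(P[[p]]$spl_cols) && is.finite(P[[p]]$lambda)) {
        bs <- beta_all[idx_map[[p]]][P[[p]]$spl_cols]
        gp[P[[p]]$spl_cols] <- gp[P[[p]]$spl_cols] +
          2 * P[[p]]$lambda * drop(sm$S[[1]] %*% bs)
      }
      g[idx_map[[p]]] <- gp
    }
    g
  }
  pen_of <- function(p) {
    if (!length(P[[p]]$spl_cols) || !is.finite(P[[p]]$lambda)) return(0)
    bs <- P[[p]]$beta[P[[p]]$spl_cols]
    P[[p]]$lambda * drop(crossprod(bs, sm$S[[1]] %*% bs))
  }
  penv <- stats::setNames(numeric(length(pars)), pars)
  while (cycle < max_cycles) {
    cycle <- cycle + 1L
    pdev_prev <- dev + sum(penv)
    for (p in pars) {
      Zp <- P[[p]]$Z
      e <- eta[[p]]
      h <- h0 * pmax(1, abs(e))
      l0 <- ll_at(p, e); lp <- ll_at(p, e + h); lm <- ll_at(p, e - h)
      fin <- is.finite(l0) & is.finite(lp) & is.finite(lm)
      u <- ifelse(fin, (lp - lm) / (2 * h), 0)
      w <- ifelse(fin, -(lp - 2 * l0 + lm) / h^2, 1)
      wbar <- mean(w[w > 0], na.rm = TRUE)
      if (!is.finite(wbar) || wbar <= 0) wbar <- 1
      w <- pmin(pmax(w, 1e-4 * wbar), 1e6 * wbar)
      step <- pmin(pmax(u / w, -10), 10)
      zwork <- e + step
      A <- crossprod(Zp, Zp * w)
      b <- crossprod(Zp, w * zwork)
      if (length(P[[p]]$spl_cols)) {
        if (cycle <= 3L || !is.finite(P[[p]]$lambda)) {
          P[[p]]$lambda <- .lambda_for_df(A, sm$S[[1]], spec$spline_df, P[[p]]$spl_cols)
          penv[[p]] <- pen_of(p)
        }
        Pen <- matrix(0, ncol(Zp), ncol(Zp))
        Pen[P[[p]]$spl_cols, P[[p]]$spl_cols] <- P[[p]]$lambda * sm$S[[1]]
        A <- A + Pen
      }
      beta_new <- tryCatch(drop(solve(A, b)), error = function(err) NULL)
      if (is.null(beta_new) || any(!is.finite(beta_new))) next
      beta_old <- P[[p]]$beta
      pen_old <- penv[[p]]
      fac <- 1
      repeat {
        cand <- beta_old + fac * (beta_new - beta_old)
        eta_cand <- drop(Zp %*% cand)
        th <- cur_par(); th[[p]] <- .linkinv(eta_cand, links[p])
        d <- dev_of(th)
        pen_cand <- if (length(P[[p]]$spl_cols) && is.finite(P[[p]]$lambda)) {
          bs <- cand[P[[p]]$spl_cols]
          P[[p]]$lambda * drop(crossprod(bs, sm$S[[1]] %*% bs))
        } else 0
        if (is.finite(d) &&
            d + pen_cand <= dev + pen_old + 1e-9 * (abs(dev) + 1)) {
          P[[p]]$beta <- cand; eta[[p]] <- eta_cand
          dev <- d; penv[[p]] <- pen_cand
          break
        }
        fac <- fac / 2
        if (fac < 1e-4) break # keep the old value for this cycle
      }
    }
    pdev <- dev + sum(penv)
    if (is.finite(pdev) && abs(pdev_prev - pdev) < max(tol, 1e-3)) {
      if (polish_count >= 3L) { converged <- TRUE; break }
      # joint quasi-Newton step on the penalised deviance: the cyclic
      # updates locate the right neighbourhood but can zigzag when mu and
      # nu are highly correlated; the joint step removes that coupling.
      # Convergence is declared only when this joint step can no longer
      # improve the penalised deviance by more than tol.
      beta0 <- unlist(lapply(pars, function(p) P[[p]]$beta), use.names = FALSE)
      opt <- tryCatch(stats::optim(beta0, pen_dev, gr = pen_dev_grad,
                                   method = "BFGS",
                                   control = list(maxit = 500, reltol = 1e-12)),
                      error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$value) && opt$value <= pen_dev(beta0)) {
        for (p in pars) {
          P[[p]]$beta <- opt$par[idx_map[[p]]]
          eta[[p]] <- drop(P[[p]]$Z %*% P[[p]]$beta)
          penv[[p]] <- pen_of(p)
        }
        dev <- dev_of(cur_par())
      }
      polish_count <- polish_count + 1L
      if (is.finite(dev) && abs(pdev - (dev + sum(penv))) < tol) {
        converged <- TRUE; break
      }
    }
  }

  # effective df per parameter: tr((Z'WZ + P)^{-1} Z'WZ) with converged weights
  edf <- stats::setNames(numeric(length(pars)), pars)
  for (p in pars) {
    Zp <- P[[p]]$Z; e <- eta[[p]]
    h <- h0 * pmax(1, abs(e))
    l0 <- ll_at(p, e); lp <- ll_at(p, e + h); lm <- ll_at(p, e - h)
    w <- -(lp - 2 * l0 + lm) / h^2
    wbar <- mean(w[is.finite(w) & w > 0]); if (!is.finite(wbar) || wbar <= 0) wbar <- 1
    w <- pmin(pmax(ifelse(is.finite(w), w, wbar), 1e-4 * wbar), 1e6 * wbar)
    A <- crossprod(Zp, Zp * w)
    if (length(P[[p]]$spl_cols)) {
      Pen <- matrix(0, ncol(Zp), ncol(Zp))
      Pen[P[[p]]$spl_cols, P[[p]]$spl_cols] <- P[[p]]$lambda * sm$S[[1]]
      edf[p] <- sum(diag(tryCatch(solve(A + Pen, A),
                                  error = function(e2) diag(ncol(Zp)))))
    } else edf[p] <- P[[p]]$n_par
  }
  th <- cur_par()
  loglik <- sum(.ll_vec(fam, y, th$mu, th$sigma, th$nu, th$tau))
  total_df <- sum(edf)

  coefs <- lapply(pars, function(p) {
    b <- P[[p]]$beta
    names(b) <- c(colnames(P[[p]]$Z)[seq_len(P[[p]]$n_par)],
                  if (length(P[[p]]$spl_cols))
                    paste0("spline.", seq_along(P[[p]]$spl_cols)))
    b
  })
  names(coefs) <- pars

  structure(list(index = index, family = fam, spec = spec, links = links[pars],
                 coefficients = coefs,
                 smooth = sm,
                 lambda = stats::setNames(vapply(pars, function(p) P[[p]]$lambda,
                                                 numeric(1)), pars),
                 n_par = stats::setNames(vapply(pars, function(p) P[[p]]$n_par,
                                                numeric(1)), pars),
                 fitted_params = th, eta = eta,
                 edf = edf, total_df = total_df,
                 loglik = loglik, sbc = sbc(loglik, total_df, n),
                 n = n, converged = converged, cycles = cycle,
                 deviance = dev,
                 data = data.frame(y = y, height_cm = height, age_years = age),
                 age_range = range(age)),
            class = "spiro_gamlss")
}

#' Schwarz Bayesian criterion
#'
#' \code{SBC = -2 loglik + df * log(n)}; lower values indicate a better
#' penalised fit.
#'
#' @param loglik log-likelihood of the fitted model.
#' @param total_df total effective degrees of freedom.
#' @param n number of observations.
#' @export
sbc <- function(loglik, total_df, n) -2 * loglik + total_df * log(n)

#' @export
print.spiro_gamlss <- function(x, ...) {
  cat(sprintf("Location-scale-shape fit: %s [%s], n = %d\n",
              x$index, x$spec$label, x$n))
  cat(sprintf("  logLik %.3f | edf %.2f | SBC %.3f | %s (%d cycles)\n",
              x$loglik, x$total_df, x$sbc,
              if (x$converged) "converged" else "NOT CONVERGED", x$cycles))
  invisible(x)
}

#' @export
summary.spiro_gamlss <- function(object, ...) {
  r <- residuals(object)
  out <- list(fit = object,
              coef = object$coefficients,
              edf = object$edf,
              resid_moments = c(mean = mean(r), sd = stats::sd(r),
                                skewness = mean((r - mean(r))^3) / stats::sd(r)^3))
  class(out) <- "summary.spiro_gamlss"
  out
}

#' @export
print.summary.spiro_gamlss <- function(x, ...) {
  print(x$fit)
  for (p in names(x$coef)) {
    cat(sprintf("\n%s coefficients (link = %s, edf = %.2f):\n",
                p, x$fit$links[[p]], x$edf[[p]]))
    b <- x$coef[[p]]
    print(round(b[!startsWith(names(b), "spline.")], 6))
    if (any(startsWith(names(b), "spline.")))
      cat(sprintf("  + P-spline in age (%d basis coefficients, lambda = %.3g)\n",
                  sum(startsWith(names(b), "spline.")), x$fit$lambda[[p]]))
  }
  cat(sprintf("\nquantile residuals: mean %.4f, sd %.4f\n",
              x$resid_moments["mean"], x$resid_moments["sd"]))
  invisible(x)
}

#' @param object a \code{spiro_gamlss} fit.
#' @param parameter which distribution parameter's coefficients to return;
#'   \code{NULL} returns the full named list.
#' @rdname spiro_gamlss
#' @export
coef.spiro_gamlss <- function(object, parameter = NULL, ...) {
  if (is.null(parameter)) object$coefficients
  else object$coefficients[[match.arg(parameter, names(object$coefficients))]]
}

#' @export
logLik.spiro_gamlss <- function(object, ...) {
  structure(object$loglik, df = object$total_df, nobs = object$n,
            class = "logLik")
}

# evaluate one fitted parameter model at new (height, age); ages are clamped
# to the fitted range for the spline part
.predict_param <- function(fit, p, height, age) {
  b <- fit$coefficients[[p]]
  np <- fit$n_par[[p]]
  terms_n <- names(b)[seq_len(np)]
  eta <- rep(b[["intercept"]], length(age))
  if ("log_height" %in% terms_n) eta <- eta + b[["log_height"]] * log(height)
  if ("log_age" %in% terms_n) eta <- eta + b[["log_age"]] * log(age)
  if (np < length(b)) {
    acl <- pmin(pmax(age, fit$age_range[1]), fit$age_range[2])
    Xs <- mgcv::PredictMat(fit$smooth, data.frame(age = acl))
    eta <- eta + drop(Xs %*% b[(np + 1L):length(b)])
  }
  .linkinv(eta, fit$links[[p]])
}

#' Predict from a fitted reference model
#'
#' @param object a \code{spiro_gamlss} fit.
#' @param newdata data frame with \code{height_cm} and \code{age_years}
#'   (default: the training data).
#' @param what \code{"median"} (the predicted reference value), one of the
#'   distribution parameters, \code{"quantile"} (needs \code{centile}), or
#'   \code{"lln"} (5th centile).
#' @param centile probability for \code{what = "quantile"}.
#' @param ... unused.
#' @export
predict.spiro_gamlss <- function(object, newdata = NULL,
                                 what = c("median", "mu", "sigma", "nu", "tau",
                                          "quantile", "lln"),
                                 centile = 0.05, ...) {
  what <- match.arg(what)
  if (is.null(newdata)) newdata <- object$data
  h <- newdata$height_cm; a <- newdata$age_years
  if (what %in% c("median", "mu")) return(.predict_param(object, "mu", h, a))
  if (what %in% names(object$coefficients))
    return(.predict_param(object, what, h, a))
  if (what == "lln") centile <- 0.05
  mu <- .predict_param(object, "mu", h, a)
  sg <- .predict_param(object, "sigma", h, a)
  nu <- if ("nu" %in% names(object$coefficients)) .predict_param(object, "nu", h, a) else NULL
  tau <- if ("tau" %in% names(object$coefficients)) .predict_param(object, "tau", h, a) else NULL
  if (object$family == "normal") stats::qnorm(centile, mu, sg)
  else if (object$family == "BCPE") bcpe_quantile(centile, mu, sg, nu, tau)
  else bccg_quantile(centile, mu, sg, nu)
}

#' Randomised quantile residuals of a fitted model
#'
#' For these continuous families the quantile residual is deterministic:
#' the normal deviate of the fitted CDF at the observation, i.e. exactly
#' the Z-score of each record under the fitted model. Standard-normal
#' residuals indicate a well-specified fit.
#'
#' @param object a \code{spiro_gamlss} fit.
#' @param ... unused.
#' @export
residuals.spiro_gamlss <- function(object, ...) {
  th <- object$fitted_params
  y <- object$data$y
  switch(object$family,
         normal = (y - th$mu) / th$sigma,
         BCCG = bccg_zscore(y, th$mu, th$sigma, th$nu),
         BCPE = bcpe_zscore(y, th$mu, th$sigma, th$nu, th$tau))
}

#' Quantile residuals (alias of the residuals method)
#' @param fit a \code{spiro_gamlss} fit.
#' @export
quantile_residuals <- function(fit) residuals(fit)

#' Simulate responses from a fitted model
#'
#' @param object a \code{spiro_gamlss} fit.
#' @param nsim number of replicate response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame with \code{nsim} columns of simulated responses at
#'   the training subjects' fitted parameters.
#' @export
simulate.spiro_gamlss <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  th <- object$fitted_params
  n <- object$n
  out <- as.data.frame(lapply(seq_len(nsim), function(i) {
    switch(object$family,
           normal = stats::rnorm(n, th$mu, th$sigma),
           BCCG = .rbccg(th$mu, th$sigma, th$nu),
           BCPE = .rbcpe(th$mu, th$sigma, th$nu, th$tau))
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Worm-plot coordinates for residual diagnostics
#'
#' Splits records into age bins of (near-)equal counts and, per bin,
#' returns the detrended QQ coordinates of the quantile residuals: x is
#' the normal order statistic, y the empirical-minus-theoretical gap
#' ("worm"). Worms hugging zero indicate distributional fit across age.
#'
#' @param residuals quantile residuals.
#' @param ages ages (years), same length.
#' @param n_bins number of age-quantile bins (1 gives a global detrended
#'   QQ plot).
#' @return data frame with columns \code{bin}, \code{age_lo}, \code{age_hi},
#'   \code{x} (theoretical quantile) and \code{y} (deviation).
#' @export
worm_plot_data <- function(residuals, ages, n_bins = 4L) {
  stopifnot(length(residuals) == length(ages), n_bins >= 1L)
  n <- length(residuals)
  ord <- order(ages)
  bin_id <- integer(n)
  # equal counts +/- 1 via rank chunking
  bin_id[ord] <- as.integer(cut(seq_len(n), breaks = round(seq(0, n, length.out = n_bins + 1L)),
                                labels = FALSE))
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    i <- which(bin_id == b)
    r <- sort(residuals[i])
    th <- stats::qnorm(stats::ppoints(length(r)))
    data.frame(bin = b, age_lo = min(ages[i]), age_hi = max(ages[i]),
               x = th, y = r - th)
  }))
  rownames(out) <- NULL
  out
}

#' @export
plot.spiro_gamlss <- function(x, which = c("worm", "centiles"), n_bins = 4L, ...) {
  which <- match.arg(which)
  if (which == "worm") {
    wd <- worm_plot_data(residuals(x), x$data$age_years, n_bins)
    op <- graphics::par(mfrow = grDevices::n2mfrow(n_bins)); on.exit(graphics::par(op))
    for (b in unique(wd$bin)) {
      d <- wd[wd$bin == b, ]
      graphics::plot(d$x, d$y, pch = 16, cex = 0.5,
                     xlab = "normal quantile", ylab = "deviation",
                     main = sprintf("ages %.1f-%.1f", d$age_lo[1], d$age_hi[1]),
                     ylim = range(c(d$y, -0.5, 0.5)))
      graphics::abline(h = 0, lty = 2)
    }
  } else {
    ag <- seq(x$age_range[1], x$age_range[2], length.out = 60)
    hmed <- stats::median(x$data$height_cm)
    nd <- data.frame(height_cm = hmed, age_years = ag)
    q05 <- predict(x, nd, what = "quantile", centile = 0.05)
    q50 <- predict(x, nd, what = "median")
    q95 <- predict(x, nd, what = "quantile", centile = 0.95)
    graphics::matplot(ag, cbind(q05, q50, q95), type = "l", lty = c(2, 1, 2),
                      col = 1, xlab = "age (years)", ylab = x$index,
                      main = sprintf("centiles at height %.0f cm", hmed))
  }
  invisible(x)
}

#' Extract the fitted model as printable parameter models
#'
#' Converts a fit into \code{\link{parameter_model}} objects (coefficients
#' on log(height)/log(age) plus the fitted age smooth sampled onto
#' integer-year knots as a \code{\link{spline_table}}) - the form in which
#' refits populate an equation set.
#'
#' @param fit a \code{spiro_gamlss} fit.
#' @return named list of parameter models (mu, sigma, nu[, tau]).
#' @export
fit_parameter_models <- function(fit) {
  stopifnot(inherits(fit, "spiro_gamlss"))
  out <- list()
  for (p in names(fit$coefficients)) {
    b <- fit$coefficients[[p]]
    np <- fit$n_par[[p]]
    spl <- NULL
    if (np < length(b)) {
      knots <- seq(floor(fit$age_range[1]), ceiling(fit$age_range[2]), by = 1)
      Xs <- mgcv::PredictMat(fit$smooth,
                             data.frame(age = pmin(pmax(knots, fit$age_range[1]),
                                                   fit$age_range[2])))
      spl <- spline_table(knots, drop(Xs %*% b[(np + 1L):length(b)]))
    }
    nm <- names(b)[seq_len(np)]
    out[[p]] <- parameter_model(
      link = fit$links[[p]],
      intercept = b[["intercept"]],
      beta_log_height = if ("log_height" %in% nm) b[["log_height"]] else 0,
      beta_log_age = if ("log_age" %in% nm) b[["log_age"]] else 0,
      spline = spl)
  }
  out
}

#' Refit a full sex-specific equation set from a cohort
#'
#' Fits all four spirometric indices with the given (or default) model
#' specifications and assembles the results into an
#' \code{\link{equation_set}} ready for serialization and validation.
#'
#' @param cohort cohort data frame.
#' @param sex which sex to fit.
#' @param specs named list of \code{\link{model_spec}} per index; default
#'   mirrors the structural forms of the published equations (BCCG
#'   everywhere except BCPE for female FEF25-75), spline-free.
#' @param name equation-set label.
#' @return an \code{\link{equation_set}} with attribute \code{"fits"}.
#' @export
refit_equation_set <- function(cohort, sex = c("male", "female"), specs = NULL,
                               name = NULL) {
  sex <- match.arg(sex)
  if (is.null(name)) name <- paste0("refit-", sex)
  if (is.null(specs)) {
    specs <- list(
      fev1 = model_spec("BCCG", nu_terms = "log_age"),
      fvc = model_spec("BCCG", sigma_terms = character()),
      fev1_fvc = model_spec("BCCG", nu_terms = "log_age"),
      fef2575 = if (sex == "female")
        model_spec("BCPE", nu_terms = "log_age", tau_terms = "log_age")
      else model_spec("BCCG", nu_terms = "log_age"))
  }
  fits <- lapply(SPIRO_INDICES, function(ix)
    spiro_gamlss(cohort, ix, specs[[ix]], sex = sex))
  names(fits) <- SPIRO_INDICES
  indices <- lapply(fits, function(f) {
    pm <- fit_parameter_models(f)
    c(list(family = if (f$family == "BCPE") "BCPE" else "BCCG"), pm)
  })
  ages <- cohort$age_years[cohort$sex == sex]
  eq <- equation_set(name = name, sex = sex, indices = indices,
                     valid_age_range = c(floor(min(ages)), ceiling(max(ages))),
                     splines_omitted_acknowledged = TRUE)
  attr(eq, "fits") <- fits
  eq
}

#' Fit a candidate menu and select the best model by SBC
#'
#' Fits every candidate, ranks by ascending SBC, then applies the
#' parsimony tie rule: a converged candidate whose SBC lies within
#' \code{delta_sbc} of the best but with strictly lower total effective df
#' displaces the SBC winner. Candidates whose in-sample quantile residuals
#' are off-centre (|mean| >= 0.1) or mis-scaled (|var - 1| >= 0.15) are
#' vetoed from selection (the full ranking is always returned for audit).
#'
#' @param data cohort data frame.
#' @param index spirometric index.
#' @param menu list of \code{\link{model_spec}} candidates.
#' @param sex optional sex subset.
#' @param delta_sbc SBC window regarded as "no meaningful difference"
#'   (default 2).
#' @param resid_mean_tol,resid_var_tol residual-moment veto thresholds.
#' @return list with \code{selected} (a \code{spiro_gamlss} fit),
#'   \code{ranking} (data frame: label, SBC, df, convergence, residual
#'   moments, vetoed), and \code{fits}.
#' @export
select_model <- function(data, index, menu, sex = NULL, delta_sbc = 2,
                         resid_mean_tol = 0.1, resid_var_tol = 0.15) {
  if (!length(menu)) stop("empty model menu", call. = FALSE)
  fits <- lapply(menu, function(sp)
    tryCatch(spiro_gamlss(data, index, sp, sex = sex),
             error = function(e) structure(list(error = conditionMessage(e)),
                                           class = "spiro_gamlss_failure")))
  ok <- vapply(fits, function(f) inherits(f, "spiro_gamlss"), logical(1))
  if (!any(ok)) stop("no candidate model could be fitted", call. = FALSE)
  rank_df <- do.call(rbind, lapply(which(ok), function(i) {
    f <- fits[[i]]
    r <- residuals(f)
    data.frame(candidate = i, label = f$spec$label, sbc = f$sbc,
               df = f$total_df, converged = f$converged,
               resid_mean = mean(r), resid_var = stats::var(r))
  }))
  rank_df$vetoed <- !rank_df$converged |
    abs(rank_df$resid_mean) >= resid_mean_tol |
    abs(rank_df$resid_var - 1) >= resid_var_tol
  rank_df <- rank_df[order(rank_df$sbc), ]
  rownames(rank_df) <- NULL
  elig <- rank_df[!rank_df$vetoed, , drop = FALSE]
  if (!nrow(elig)) {
    if (!any(rank_df$converged)) stop("all candidate fits failed to converge",
                                      call. = FALSE)
    warning("every candidate failed the residual-moment screen; ",
            "falling back to the lowest-SBC converged fit", call. = FALSE)
    elig <- rank_df[rank_df$converged, , drop = FALSE]
  }
  pick <- .select_from_ranking(elig, delta_sbc)
  list(selected = fits[[pick]], ranking = rank_df, fits = fits)
}

# the SBC/parsimony selection rule on an (eligible) ranking: ascending-SBC
# winner, displaced by any candidate within delta_sbc of it that has
# strictly lower effective df
.select_from_ranking <- function(elig, delta_sbc = 2) {
  elig <- elig[order(elig$sbc), , drop = FALSE]
  window <- elig[elig$sbc <= elig$sbc[1L] + delta_sbc, , drop = FALSE]
  window$candidate[order(window$df, window$sbc)][1L]
}

#' Centile curves of an equation set over age
#'
#' Evaluates reference centiles along an age grid with height held fixed
#' (default policy: a representative sex-specific median height). Curves
#' are non-crossing in the centile direction by quantile monotonicity.
#'
#' @param eq an \code{\link{equation_set}}.
#' @param index spirometric index.
#' @param centiles probabilities.
#' @param age_grid ages (years).
#' @param height fixed height (cm); default 174 (male) / 157 (female).
#' @return data frame with \code{age}, \code{centile}, \code{value}.
#' @export
centile_curves <- function(eq, index, centiles = c(0.05, 0.5, 0.95),
                           age_grid = seq(18, 70, by = 1), height = NULL) {
  stopifnot(inherits(eq, "equation_set"))
  if (is.null(height)) height <- if (eq$sex == "male") 174 else 157
  out <- do.call(rbind, lapply(centiles, function(ct) {
    p <- equation_params(eq, index, height, age_grid)
    v <- if (p$family == "BCPE") bcpe_quantile(ct, p$mu, p$sigma, p$nu, p$tau)
         else bccg_quantile(ct, p$mu, p$sigma, p$nu)
    data.frame(age = age_grid, centile = ct, value = v)
  }))
  rownames(out) <- NULL
  out
}
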