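#' Questionnaire exclusion flags
#'
#' The eligibility-questionnaire items, in the criteria listing order (which
#' also fixes the reported exclusion-reason precedence).
#' @export
EXCLUSION_FLAGS <- c("current_smoker", "lives_with_smoker", "former_smoker",
                     "chronic_disease", "recent_surgery_or_acute_symptoms",
                     "pregnant")

.COHORT_COLUMNS <- c("sex", "age_years", "height_cm", "fev1_l", "fvc_l",
                     "ratio", "fef2575_ls", EXCLUSION_FLAGS)

# Calibrate a shifted log-normal (age = shift + X, X ~ LN(meanlog, sdlog))
# to a target median and upper quartile.
.shifted_lnorm_pars <- function(median, q3, shift = 18) {
  stopifnot(median > shift, q3 > median)
  meanlog <- log(median - shift)
  sdlog <- log((q3 - shift) / (median - shift)) / stats::qnorm(0.75)
  c(meanlog = meanlog, sdlog = sdlog)
}

#' Specification of a synthetic spirometry cohort
#'
#' Describes the demographic and distributional structure of a generated
#' cohort: two sexes with right-skewed adult age distributions (shifted
#' log-normal calibrated to the sex-specific median and upper quartile of
#' the derivation study: males 28.57 [Q3 40.68] y, females 34.79 [Q3 45.92]
#' y, truncated to 18-70 y), sex-specific truncated-normal heights matched
#' to the study medians and quartiles (males 174 [170-178] cm on 155-193,
#' females 157 [154-161] cm on 154-176), and spirometric outcomes drawn
#' from the per-subject BCCG/BCPE distributions of a "truth" equation set.
#' FEV1 is derived as ratio x FVC so FEV1 <= FVC holds by construction.
#'
#' @param n number of subjects (> 0).
#' @param female_fraction probability a subject is female (study phase one:
#'   0.331).
#' @param truth named list with \code{male} and \code{female}
#'   \code{\link{equation_set}}s used as the generating model; defaults to
#'   the packaged ISE.
#' @param flag_prevalence named numeric vector of prevalences in [0, 1] for
#'   the questionnaire exclusion flags (defaults: all zero, i.e. an
#'   already-screened cohort; the study does not report the per-criterion
#'   breakdown, so these are free parameters).
#' @param age_range,age_median,age_q3 sex-named parameters of the shifted
#'   log-normal age model.
#' @param height_median,height_q3,height_range sex-named parameters of the
#'   truncated-normal height model.
#' @param seed integer seed; every random draw in
#'   \code{\link{generate_cohort}} flows from it.
#' @return an object of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n, female_fraction = 0.331, truth = NULL,
                        flag_prevalence = NULL,
                        age_range = c(18, 70),
                        age_median = c(male = 28.57, female = 34.79),
                        age_q3 = c(male = 40.68, female = 45.92),
                        height_median = c(male = 174, female = 157),
                        height_q3 = c(male = 178, female = 161),
                        height_range = list(male = c(155, 193),
                                            female = c(154, 176)),
                        seed = 1L) {
  stopifnot(n > 0, female_fraction > 0, female_fraction < 1)
  if (is.null(truth))
    truth <- list(male = ise_equations("male"), female = ise_equations("female"))
  for (s in c("male", "female")) {
    if (!inherits(truth[[s]], "equation_set"))
      stop(sprintf("'truth$%s' must be an equation_set", s), call. = FALSE)
  }
  fp <- stats::setNames(rep(0, length(EXCLUSION_FLAGS)), EXCLUSION_FLAGS)
  if (!is.null(flag_prevalence)) {
    bad <- setdiff(names(flag_prevalence), EXCLUSION_FLAGS)
    if (length(bad)) stop("unknown exclusion flag(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    if (any(flag_prevalence < 0 | flag_prevalence > 1))
      stop("flag prevalences must lie in [0, 1]", call. = FALSE)
    fp[names(flag_prevalence)] <- flag_prevalence
  }
  structure(list(n = as.integer(n), female_fraction = female_fraction,
                 truth = truth, flag_prevalence = fp,
                 age_range = age_range, age_median = age_median, age_q3 = age_q3,
                 height_median = height_median, height_q3 = height_q3,
                 height_range = height_range, seed = as.integer(seed),
                 age_model = "shifted log-normal (18 + lognormal), truncated to age_range"),
            class = "cohort_spec")
}

# BCCG random draws by inverting the Z-score; the negligible truncation
# region (transform argument <= 0) is redrawn.
.rbccg <- function(mu, sigma, nu) {
  n <- length(mu)
  y <- .boxcox_u_inv(stats::rnorm(n), mu, sigma, nu)
  bad <- which(!is.finite(y) | y <= 0)
  while (length(bad)) {
    y[bad] <- .boxcox_u_inv(stats::rnorm(length(bad)), mu[bad], sigma[bad], nu[bad])
    bad <- bad[!is.finite(y[bad]) | y[bad] <= 0]
  }
  y
}

.rbcpe <- function(mu, sigma, nu, tau) {
  n <- length(mu)
  draw <- function(k, i) .boxcox_u_inv(.pe_quantile(stats::runif(k), tau[i]),
                                       mu[i], sigma[i], nu[i])
  y <- draw(n, seq_len(n))
  bad <- which(!is.finite(y) | y <= 0)
  while (length(bad)) {
    y[bad] <- draw(length(bad), bad)
    bad <- bad[!is.finite(y[bad]) | y[bad] <= 0]
  }
  y
}

.draw_index <- function(eq, index, height, age) {
  p <- equation_params(eq, index, height, age)
  if (p$family == "BCPE") .rbcpe(p$mu, p$sigma, p$nu, p$tau)
  else .rbccg(p$mu, p$sigma, p$nu)
}

# location of the untruncated normal such that the [lo, hi]-truncated
# distribution has the requested median (one-sided truncation shifts the
# median, so the raw study median cannot be used as the location directly)
.trunc_center <- function(median_target, sd, lo, hi) {
  f <- function(m) {
    plo <- stats::pnorm(lo, m, sd); phi <- stats::pnorm(hi, m, sd)
    stats::pnorm(median_target, m, sd) - (plo + phi) / 2
  }
  stats::uniroot(f, c(lo - 4 * sd, hi + 4 * sd), tol = 1e-8)$root
}

.rtrunc <- function(n, rfun, lo, hi) {
  x <- rfun(n)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rfun(length(bad))
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Generate a synthetic spirometry cohort
#'
#' Draws demographics and spirometric outcomes per \code{\link{cohort_spec}}.
#' Outcomes for FVC, FEV1/FVC and FEF25-75 are drawn from the truth
#' equation set's family at each subject's (mu, sigma, nu[, tau]); FEV1 is
#' then derived as ratio x FVC, which enforces FEV1 <= FVC. Reproducible:
#' the same spec (including seed) yields an identical cohort.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return a data frame of class \code{"spiro_cohort"} with columns
#'   \code{sex}, \code{age_years}, \code{height_cm}, \code{fev1_l},
#'   \code{fvc_l}, \code{ratio}, \code{fef2575_ls} and the six logical
#'   questionnaire flags; the generating spec is attached as attribute
#'   \code{"spec"}.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  sex <- ifelse(stats::runif(n) < spec$female_fraction, "female", "male")
  age <- numeric(n); height <- numeric(n)
  fvc <- numeric(n); ratio <- numeric(n); fef <- numeric(n)
  for (s in c("male", "female")) {
    i <- which(sex == s)
    if (!length(i)) next
    ap <- .shifted_lnorm_pars(spec$age_median[[s]], spec$age_q3[[s]],
                              shift = spec$age_range[1])
    age[i] <- .rtrunc(length(i), function(k)
      spec$age_range[1] + stats::rlnorm(k, ap["meanlog"], ap["sdlog"]),
      spec$age_range[1], spec$age_range[2])
    hsd <- (spec$height_q3[[s]] - spec$height_median[[s]]) / stats::qnorm(0.75)
    hr <- spec$height_range[[s]]
    hctr <- .trunc_center(spec$height_median[[s]], hsd, hr[1], hr[2])
    height[i] <- .rtrunc(length(i), function(k)
      stats::rnorm(k, hctr, hsd), hr[1], hr[2])
    eq <- spec$truth[[s]]
    fvc[i]   <- .draw_index(eq, "fvc", height[i], age[i])
    ratio[i] <- pmin(.draw_index(eq, "fev1_fvc", height[i], age[i]), 1)
    fef[i]   <- .draw_index(eq, "fef2575", height[i], age[i])
  }
  out <- data.frame(sex = sex, age_years = age, height_cm = height,
                    fev1_l = ratio * fvc, fvc_l = fvc, ratio = ratio,
                    fef2575_ls = fef, stringsAsFactors = FALSE)
  for (f in EXCLUSION_FLAGS)
    out[[f]] <- stats::runif(n) < spec$flag_prevalence[[f]]
  class(out) <- c("spiro_cohort", "data.frame")
  attr(out, "spec") <- spec
  out
}

#' Apply the eligibility (inclusion/exclusion) filter
#'
#' A record is kept iff the subject is an adult (age >= 18) and every
#' questionnaire exclusion flag is false. Each excluded record is annotated
#' with its first matching reason; precedence follows the criteria listing
#' order (current smoker, lives with a smoker, former smoker, chronic
#' disease, recent surgery or acute respiratory symptoms, pregnancy), with
#' under-age checked first. Filtering is idempotent.
#'
#' @param records a cohort data frame (see \code{\link{generate_cohort}}).
#' @return list with elements \code{kept} (eligible records) and
#'   \code{excluded} (records with an added \code{exclusion_reason} column).
#' @export
apply_inclusion_filters <- function(records) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  if (n) {
    under <- records$age_years < 18
    reason[under] <- "under_18"
    for (f in EXCLUSION_FLAGS) {
      hit <- is.na(reason) & as.logical(records[[f]])
      reason[hit] <- f
    }
  }
  kept <- records[is.na(reason), , drop = FALSE]
  excluded <- records[!is.na(reason), , drop = FALSE]
  if (nrow(excluded)) excluded$exclusion_reason <- reason[!is.na(reason)]
  else excluded$exclusion_reason <- character(0)
  list(kept = kept, excluded = excluded)
}

#' Split a cohort into derivation and validation phases
#'
#' Randomly partitions records into a validation set of size
#' \code{n_validation} meeting a per-sex minimum (guaranteeing the
#' reference-equation validation sample-size rule can be satisfied) and a
#' derivation set with the remainder. The two phases are disjoint and their
#' union is the input.
#'
#' @param records a cohort data frame.
#' @param n_validation validation-set size.
#' @param min_per_sex minimum validation records per sex; an error is
#'   raised when unachievable.
#' @return list with \code{derivation} and \code{validation} data frames.
#' @export
split_phases <- function(records, n_validation, min_per_sex = 0L) {
  stopifnot(is.data.frame(records), n_validation >= 1,
            n_validation <= nrow(records))
  idx_m <- which(records$sex == "male")
  idx_f <- which(records$sex == "female")
  if (2 * min_per_sex > n_validation)
    stop("per-sex minima exceed the requested validation size", call. = FALSE)
  if (length(idx_m) < min_per_sex || length(idx_f) < min_per_sex)
    stop(sprintf("cannot meet min_per_sex = %d (males available: %d, females: %d)",
                 min_per_sex, length(idx_m), length(idx_f)), call. = FALSE)
  take <- c(if (min_per_sex > 0) sample(idx_m, min_per_sex),
            if (min_per_sex > 0) sample(idx_f, min_per_sex))
  rest <- setdiff(seq_len(nrow(records)), take)
  extra <- n_validation - length(take)
  if (extra > 0) take <- c(take, sample(rest, extra))
  take <- sort(take)
  list(derivation = records[-take, , drop = FALSE],
       validation = records[take, , drop = FALSE])
}

#' Write a cohort to CSV
#'
#' One row per subject; UTF-8, comma-separated, "." decimal, header
#' required; sex encoded "male"/"female"; flags as TRUE/FALSE. Identical
#' cohorts produce byte-identical files.
#'
#' @param cohort a cohort data frame.
#' @param path file to write.
#' @return \code{path}, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  missing <- setdiff(.COHORT_COLUMNS, names(cohort))
  if (length(missing))
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  utils::write.csv(as.data.frame(cohort)[, .COHORT_COLUMNS], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort CSV
#'
#' Validates the documented header, coerces types, normalizes FEV1/FVC
#' ratios reported on the percent scale (values > 1.5 are divided by 100 -
#' published tables mix the two conventions) and warns about implausible
#' heights. Malformed numeric fields raise line-numbered errors.
#'
#' @param path CSV file in the cohort schema.
#' @return a \code{"spiro_cohort"} data frame.
#' @export
read_cohort_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e)
      stop("not a valid cohort CSV: ", conditionMessage(e), call. = FALSE))
  missing <- setdiff(.COHORT_COLUMNS, names(df))
  if (length(missing))
    stop("cohort CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  num_cols <- c("age_years", "height_cm", "fev1_l", "fvc_l", "ratio", "fef2575_ls")
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) & df[[cl]] != "NA")
    if (length(bad))
      stop(sprintf("malformed numeric value in column '%s' at data line(s) %s",
                   cl, paste(utils::head(bad + 1L, 5L), collapse = ", ")),
           call. = FALSE)
    df[[cl]] <- v
  }
  if (!all(df$sex %in% c("male", "female")))
    stop("column 'sex' must be 'male' or 'female'", call. = FALSE)
  for (f in EXCLUSION_FLAGS) df[[f]] <- as.logical(df[[f]])
  pct <- which(df$ratio > 1.5)
  if (length(pct)) {
    df$ratio[pct] <- df$ratio[pct] / 100
    warning(sprintf("%d FEV1/FVC ratio(s) > 1.5 interpreted as percent and divided by 100",
                    length(pct)), call. = FALSE)
  }
  odd_h <- which(df$height_cm < 110 | df$height_cm > 210)
  if (length(odd_h))
    warning(sprintf("%d height(s) outside 110-210 cm; check units", length(odd_h)),
            call. = FALSE)
  class(df) <- c("spiro_cohort", "data.frame")
  df
}
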