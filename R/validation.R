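# Phase-two validation statistics: Z-score summaries, the GLI +/-0.5
# suitability rule, equation-set comparison and phase-equivalence testing.

#' Summarise how an equation set fits a validation cohort
#'
#' Computes, for one index and the equation set's sex, each subject's
#' predicted (median) value, percent of predicted and Z-score, and returns
#' the summary mirroring a validation table row: mean and SD of Z (the
#' suitability quantities) plus median and quartiles of Z, predicted value
#' and predicted percent. Quantiles use linear interpolation (type 7).
#'
#' @param eq an \code{\link{equation_set}}.
#' @param cohort cohort data frame (subset to \code{eq$sex} internally when
#'   a \code{sex} column is present).
#' @param index spirometric index.
#' @return an object of class \code{"zscore_summary"}.
#' @export
summarize_validation <- function(eq, cohort, index) {
  stopifnot(inherits(eq, "equation_set"), is.data.frame(cohort))
  index <- match.arg(index, SPIRO_INDICES)
  if ("sex" %in% names(cohort))
    cohort <- cohort[cohort$sex == eq$sex, , drop = FALSE]
  col <- .INDEX_COLUMNS[[index]]
  m <- cohort[[col]]
  keep <- is.finite(m) & m > 0 & is.finite(cohort$height_cm) & is.finite(cohort$age_years)
  cohort <- cohort[keep, , drop = FALSE]
  if (!nrow(cohort)) stop("no usable records for this index and sex", call. = FALSE)
  pred <- predict_median(eq, index, cohort$height_cm, cohort$age_years)
  pct <- percent_predicted(cohort[[col]], pred)
  z <- zscore_for(eq, cohort, index)
  q3 <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(index = index, sex = eq$sex, equation = eq$name,
                 n = nrow(cohort),
                 mean_z = mean(z), sd_z = stats::sd(z),
                 z_quartiles = q3(z),
                 predicted_quartiles = q3(pred),
                 percent_quartiles = q3(pct),
                 z = z, predicted = pred, percent = pct),
            class = "zscore_summary")
}

#' @export
print.zscore_summary <- function(x, ...) {
  cat(sprintf("%s / %s [%s], n = %d\n", x$index, x$sex, x$equation, x$n))
  cat(sprintf("  predicted value  %.2f (%.2f-%.2f)\n",
              x$predicted_quartiles[2], x$predicted_quartiles[1], x$predicted_quartiles[3]))
  cat(sprintf("  predicted percent %.2f%% (%.2f-%.2f)\n",
              x$percent_quartiles[2], x$percent_quartiles[1], x$percent_quartiles[3]))
  cat(sprintf("  Z-score mean (SD) %.2f (%.2f); median (Q1-Q3) %.2f (%.2f-%.2f)\n",
              x$mean_z, x$sd_z, x$z_quartiles[2], x$z_quartiles[1], x$z_quartiles[3]))
  invisible(x)
}

#' Population suitability check for a reference equation
#'
#' The GLI criterion: an equation set suits a population when the mean
#' Z-score of a validation sample lies strictly within +/- \code{cutoff}
#' (default 0.5; a mean of exactly 0.5 fails).
#'
#' @param summary a \code{\link{summarize_validation}} result (or any list
#'   with \code{mean_z}).
#' @param cutoff absolute mean-Z bound.
#' @return list with \code{pass} (logical), \code{mean_z} and \code{margin}
#'   (\code{cutoff - |mean_z|}; negative when failing).
#' @export
suitability_check <- function(summary, cutoff = 0.5) {
  mz <- summary$mean_z
  list(pass = abs(mz) < cutoff, mean_z = mz, cutoff = cutoff,
       margin = cutoff - abs(mz))
}

#' Compare several equation sets on one validation cohort
#'
#' Summarises each set and ranks by |mean Z| (ties by |SD of Z - 1|). The
#' sign of the mean Z marks the direction of bias: negative means the set
#' predicts high (overestimates the index), positive means it
#' underestimates.
#'
#' @param cohort cohort data frame.
#' @param sets named list of \code{\link{equation_set}}s (same sex).
#' @param index spirometric index.
#' @return list with \code{ranking} data frame (name, n, mean_z, sd_z,
#'   direction, suitability pass) and \code{summaries}.
#' @export
compare_equation_sets <- function(cohort, sets, index) {
  if (!length(sets)) stop("no equation sets to compare", call. = FALSE)
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- vapply(sets, function(e) e$name, character(1))
  sums <- lapply(sets, summarize_validation, cohort = cohort, index = index)
  df <- do.call(rbind, lapply(names(sums), function(nm) {
    s <- sums[[nm]]
    data.frame(name = nm, n = s$n, mean_z = s$mean_z, sd_z = s$sd_z,
               direction = if (s$mean_z < 0) "overestimates"
                           else if (s$mean_z > 0) "underestimates" else "unbiased",
               suitable = suitability_check(s)$pass)
  }))
  df <- df[order(abs(df$mean_z), abs(df$sd_z - 1)), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  list(ranking = df, summaries = sums)
}

#' Mann-Whitney U test (midranks, tie-corrected, exact for small samples)
#'
#' Two-sided test that two samples come from the same distribution. U is
#' computed from rank sums with midranks for ties. For
#' \code{min(n_a, n_b) <= exact_limit} the two-sided p-value is obtained by
#' complete enumeration of all group assignments of the pooled (mid)ranks;
#' otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param a,b numeric samples.
#' @param exact_limit largest min-group size for which enumeration is used
#'   (default 8).
#' @return list with \code{U} (for sample \code{a}), \code{z} (normal
#'   deviate, \code{NA} under enumeration), \code{p} (two-sided) and
#'   \code{method}.
#' @export
mann_whitney_u <- function(a, b, exact_limit = 8L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 1L || nb < 1L) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(a, b)
  r <- rank(pooled)                      # midranks
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mU <- na * nb / 2
  if (min(na, nb) <= exact_limit && (na + nb) <= 24L) {
    idx <- utils::combn(na + nb, na)
    Us <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(Us - mU) >= abs(U - mU) - 1e-9)
    return(list(U = U, z = NA_real_, p = p, method = "exact enumeration"))
  }
  N <- na + nb
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  varU <- na * nb / 12 * ((N + 1) - tie_term)
  if (varU <= 0) return(list(U = U, z = 0, p = 1, method = "normal approximation"))
  z <- (U - mU - sign(U - mU) * 0.5) / sqrt(varU)
  list(U = U, z = z, p = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation")
}

#' Validation sample-size rule
#'
#' Checks a validation cohort against the minimum recommended for
#' validating spirometric reference equations in a population: at least
#' 300 subjects with at least 150 of each sex.
#'
#' @param cohort cohort data frame with a \code{sex} column.
#' @param min_total,min_per_sex rule thresholds.
#' @return list with counts, per-rule results, and overall \code{pass}.
#' @export
sample_size_check <- function(cohort, min_total = 300L, min_per_sex = 150L) {
  n_m <- sum(cohort$sex == "male"); n_f <- sum(cohort$sex == "female")
  res <- list(n_male = n_m, n_female = n_f, n_total = n_m + n_f,
              total_ok = (n_m + n_f) >= min_total,
              male_ok = n_m >= min_per_sex, female_ok = n_f >= min_per_sex)
  res$pass <- res$total_ok && res$male_ok && res$female_ok
  res
}

#' One-sample Kolmogorov-Smirnov check against the standard normal
#'
#' Used on quantile residuals / Z-scores: under a well-specified reference
#' model they are standard normal. Wraps the classical one-sample KS test
#' with its asymptotic p-value.
#'
#' @param values numeric sample.
#' @return list with \code{statistic} (in [0, 1]) and \code{p}.
#' @export
ks_normality <- function(values) {
  values <- values[is.finite(values)]
  kt <- suppressWarnings(stats::ks.test(values, "pnorm"))
  list(statistic = unname(kt$statistic), p = unname(kt$p.value))
}

#' Full phase-two validation report
#'
#' Runs \code{\link{summarize_validation}} and \code{\link{suitability_check}}
#' for every index of one or more equation sets against a validation
#' cohort, mirroring the published validation-table structure.
#'
#' @param cohort validation cohort.
#' @param sets named list of \code{\link{equation_set}}s (may mix sexes).
#' @param cutoff suitability cutoff.
#' @return data frame, one row per set x index.
#' @export
validation_report <- function(cohort, sets, cutoff = 0.5) {
  if (inherits(sets, "equation_set")) sets <- stats::setNames(list(sets), sets$name)
  rows <- list()
  for (nm in names(sets)) {
    eq <- sets[[nm]]
    for (ix in SPIRO_INDICES) {
      s <- summarize_validation(eq, cohort, ix)
      sc <- suitability_check(s, cutoff)
      rows[[length(rows) + 1L]] <- data.frame(
        equation = nm, sex = eq$sex, index = ix, n = s$n,
        predicted_median = s$predicted_quartiles[2],
        predicted_q1 = s$predicted_quartiles[1],
        predicted_q3 = s$predicted_quartiles[3],
        percent_median = s$percent_quartiles[2],
        percent_q1 = s$percent_quartiles[1],
        percent_q3 = s$percent_quartiles[3],
        mean_z = s$mean_z, sd_z = s$sd_z,
        z_median = s$z_quartiles[2],
        suitable = sc$pass, margin = sc$margin)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
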