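# one larger cohort shared by the distributional assertions
big_cohort <- generate_cohort(cohort_spec(n = 10000, seed = 2024))

test_that("generation is deterministic under a fixed seed", {
  spec <- cohort_spec(n = 200, seed = 7)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  # and changes with the seed
  expect_false(identical(generate_cohort(cohort_spec(n = 200, seed = 8)),
                         generate_cohort(spec)))
})

test_that("sex split matches the derivation-study female fraction", {
  coh <- generate_cohort(cohort_spec(n = 966, seed = 31))
  n_f <- sum(coh$sex == "female")
  # binomial(966, 0.331): mean 320, sd ~14.6; allow 3.5 sigma
  expect_lt(abs(n_f - 320), 52)
})

test_that("demographics reproduce the study structure", {
  for (s in c("male", "female")) {
    d <- big_cohort[big_cohort$sex == s, ]
    expect_true(all(d$age_years >= 18 & d$age_years <= 70))
    skew <- mean((d$age_years - mean(d$age_years))^3) / sd(d$age_years)^3
    expect_gt(skew, 0)  # right-skewed adult ages
    med_h <- if (s == "male") 174 else 157
    expect_lt(abs(median(d$height_cm) - med_h), 2)
    expect_lt(abs(median(d$age_years) - (if (s == "male") 28.57 else 34.79)), 2.5)
  }
  # FEV1 <= FVC by construction
  expect_true(all(big_cohort$fev1_l <= big_cohort$fvc_l))
  expect_true(all(big_cohort$ratio > 0 & big_cohort$ratio <= 1))
})

test_that("directly drawn indices are standard normal under the truth set", {
  for (s in c("male", "female")) {
    eq <- ise_equations(s)
    d <- big_cohort[big_cohort$sex == s, ]
    for (ix in c("fvc", "fev1_fvc", "fef2575")) {
      z <- zscore_for(eq, d, ix)
      expect_lt(abs(mean(z)), 0.05, label = sprintf("%s %s mean Z", s, ix))
      expect_lt(abs(sd(z) - 1), 0.05, label = sprintf("%s %s SD Z", s, ix))
    }
    # FEV1 is derived as ratio x FVC; it satisfies the clinical
    # suitability bound but not the exact-draw property
    z1 <- zscore_for(eq, d, "fev1")
    expect_lt(abs(mean(z1)), 0.5)
  }
})

test_that("eligibility filter keeps clean adults and reports first reasons", {
  # one record per criterion, each with exactly one flag raised
  rows <- do.call(rbind, lapply(EXCLUSION_FLAGS, function(f) {
    r <- clean_record(); r[[f]] <- TRUE; r
  }))
  res <- apply_inclusion_filters(rows)
  expect_equal(nrow(res$kept), 0)
  expect_setequal(res$excluded$exclusion_reason, EXCLUSION_FLAGS)

  # all-clean adults are all kept
  clean <- do.call(rbind, replicate(5, clean_record(), simplify = FALSE))
  res2 <- apply_inclusion_filters(clean)
  expect_equal(nrow(res2$kept), 5)
  expect_equal(nrow(res2$excluded), 0)

  # 3 smokers + 1 pregnant + 6 clean -> 6 kept, 4 excluded
  mix <- do.call(rbind, replicate(10, clean_record(), simplify = FALSE))
  mix$current_smoker[1:3] <- TRUE
  mix$pregnant[4] <- TRUE
  res3 <- apply_inclusion_filters(mix)
  expect_equal(nrow(res3$kept), 6)
  expect_equal(nrow(res3$excluded), 4)

  # precedence: a current smoker who is also pregnant reports smoking first
  both <- clean_record(); both$current_smoker <- TRUE; both$pregnant <- TRUE
  expect_equal(apply_inclusion_filters(both)$excluded$exclusion_reason,
               "current_smoker")
  # minors are excluded before any flag
  minor <- clean_record(age = 16); minor$current_smoker <- TRUE
  expect_equal(apply_inclusion_filters(minor)$excluded$exclusion_reason,
               "under_18")
})

test_that("filtering is an idempotent partition", {
  coh <- generate_cohort(cohort_spec(
    n = 500, seed = 12,
    flag_prevalence = c(current_smoker = 0.2, pregnant = 0.05,
                        chronic_disease = 0.1)))
  res <- apply_inclusion_filters(coh)
  expect_equal(nrow(res$kept) + nrow(res$excluded), nrow(coh))
  again <- apply_inclusion_filters(res$kept)
  expect_equal(nrow(again$kept), nrow(res$kept))
  expect_equal(nrow(again$excluded), 0)
})

test_that("phase split is a disjoint partition honouring per-sex minima", {
  coh <- generate_cohort(cohort_spec(n = 2000, female_fraction = 0.45, seed = 3))
  set.seed(99)
  sp <- split_phases(coh, n_validation = 344, min_per_sex = 150)
  expect_equal(nrow(sp$validation), 344)
  expect_gte(sum(sp$validation$sex == "male"), 150)
  expect_gte(sum(sp$validation$sex == "female"), 150)
  expect_equal(nrow(sp$derivation) + nrow(sp$validation), nrow(coh))
  # disjoint by construction: row indices partition the input
  expect_equal(sort(c(rownames(sp$derivation), rownames(sp$validation))),
               sort(rownames(coh)))
  # unachievable minima raise errors
  small <- coh[1:100, ]
  expect_error(split_phases(small, 90, min_per_sex = 60), "per-sex")
  mostly_male <- coh[coh$sex == "male", ][1:200, ]
  expect_error(split_phases(mostly_male, 100, min_per_sex = 50), "females")
})

test_that("cohort CSV round-trips and normalizes percent-scale ratios", {
  coh <- generate_cohort(cohort_spec(n = 120, seed = 5))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, tf)
  back <- read_cohort_csv(tf)
  for (cl in c("age_years", "height_cm", "fev1_l", "fvc_l", "ratio", "fef2575_ls"))
    expect_equal(back[[cl]], coh[[cl]], tolerance = 1e-9)
  expect_identical(back$sex, coh$sex)

  # ratios printed on the percent scale are brought back to fractions
  coh2 <- coh; coh2$ratio[1:4] <- coh2$ratio[1:4] * 100
  tf2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh2, tf2)
  expect_warning(b2 <- read_cohort_csv(tf2), "percent")
  expect_equal(b2$ratio[1:4], coh$ratio[1:4], tolerance = 1e-9)

  # malformed numeric cells raise line-numbered errors
  lines <- readLines(tf)
  lines[3] <- sub("^([^,]*,)[^,]*", "\\1not_a_number", lines[3])
  tf3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, tf3)
  expect_error(read_cohort_csv(tf3), "age_years.*line")

  # a non-cohort file is rejected
  expect_error(read_cohort_csv(system.file("extdata", "ise_male.json",
                                           package = "spiroref")),
               "cohort CSV")
  # missing columns are named
  tf4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(sex = "male", age_years = 30), tf4,
                   row.names = FALSE)
  expect_error(read_cohort_csv(tf4), "missing column")
})
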