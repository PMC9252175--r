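test_that("generation is deterministic given the seed", {
  g1 <- generate_cohort(cohort_spec(seed = 33))
  g2 <- generate_cohort(cohort_spec(seed = 33))
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$truth, g2$truth)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(g1$cohort, p1)
  write_cohort(g2$cohort, p2)
  expect_identical(readLines(p1), readLines(p2))
  g3 <- generate_cohort(cohort_spec(seed = 34))
  expect_false(identical(g1$cohort, g3$cohort))
})

test_that("zero noise collapses replicates to identical readings", {
  gen <- generate_cohort(cohort_spec(seed = 3, noise_scale = 0))
  reps <- gen$cohort[sprintf("z_50khz_c_rep%d_ohm", 1:5)]
  expect_true(all(apply(reps, 1, function(r) diff(range(r)) == 0)))
  # and the reference equals true FFM exactly
  expect_equal(gen$cohort$ffm_dexa_kg, gen$truth$ffm_true_kg)
})

test_that("the default cohort passes its own diagnostics", {
  v <- validate_cohort(default_gen$cohort)
  expect_true(all(v$pass))
  expect_true(all(c("check", "observed", "target", "tolerance", "pass")
                  %in% names(v)))
})

test_that("per-sex fat structure lands on its targets", {
  # closed-form mean of the truncated normal the generator draws from
  tmean <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  gen <- generate_cohort(cohort_spec(n = 400, seed = 21))
  fat <- gen$truth$fat_fraction
  is_m <- gen$cohort$sex == "M"
  expect_lt(abs(mean(fat[is_m]) - tmean(0.2035, 0.0755, 0.0832, 0.4839)),
            3 * 0.0755 / sqrt(sum(is_m)))
  expect_lt(abs(mean(fat[!is_m]) - tmean(0.3318, 0.059, 0.0832, 0.4839)),
            3 * 0.059 / sqrt(sum(!is_m)))
  expect_true(all(gen$truth$ffm_true_kg < gen$cohort$tbm_kg))
})

test_that("an adversarial cohort is flagged by validation", {
  bad <- default_gen$cohort
  bad$ffm_dexa_kg[1] <- bad$tbm_kg[1] + 5
  v <- validate_cohort(bad)
  row <- v[v$check == "FFM < TBM for all subjects", ]
  expect_false(row$pass)
})

test_that("infeasible specs are rejected", {
  expect_error(cohort_spec(n = 0), "n >= 1")
  m <- list(age = c(mean = 25, sd = 8, min = 56, max = 18),
            height = c(mean = 178, sd = 6, min = 156, max = 196),
            fat = c(mean = 0.2, sd = 0.07, min = 0.08, max = 0.48),
            bmi_base = 19.6, bmi_sd = 1.7, arm_base = 17.5,
            arm_fat_shift = 0)
  expect_error(cohort_spec(male = m), "infeasible")
})

test_that("feature derivation is consistent with the raw columns", {
  co <- default_gen$cohort
  f <- derive_features(co, 10, "b")
  expect_equal(f$sex, as.numeric(co$sex == "M"))
  expect_equal(f$bmi, co$tbm_kg / (co$height_cm / 100)^2)
  expect_equal(f$arm_volume, f$arm_volume_cm3 / 1e6)
  reps <- as.matrix(co[sprintf("z_10khz_b_rep%d_ohm", 1:5)])
  expect_equal(f$resistance, apply(reps, 1, median))
  expect_equal(f$bi, co$height_cm^2 / f$resistance)
  # replicate aggregation is pluggable
  f2 <- derive_features(co, 10, "b", agg = mean)
  expect_equal(f2$resistance, rowMeans(reps))
})

test_that("cohort CSV round-trips and rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(default_gen$cohort, path)
  back <- read_cohort(path)
  expect_equal(back$tbm_kg, default_gen$cohort$tbm_kg)
  expect_equal(dim(back), dim(default_gen$cohort))
  crippled <- default_gen$cohort[setdiff(names(default_gen$cohort),
                                         "tbm_kg")]
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(crippled, path2, row.names = FALSE)
  expect_error(read_cohort(path2), "tbm_kg")
})
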