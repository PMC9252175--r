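test_that("OLS recovers the generating coefficients exactly without noise", {
  f <- default_features_50c
  y <- predict_ffm_ttc(f$arm_volume, f$bmi, f$tbm, f$bi)
  fit <- fit_ols(f, y, c("arm_volume", "bmi", "tbm", "bi"))
  expect_equal(unname(coef(fit)),
               c(182.858, -0.796, 0.464, 0.435, 11.729), tolerance = 1e-8)
})

test_that("n = p + 1 observations interpolate with zero residuals", {
  set.seed(2)
  f <- data.frame(a = runif(3), b = runif(3))
  y <- runif(3)
  fit <- fit_ols(f, y)
  expect_equal(unname(predict(fit, f)), y, tolerance = 1e-10)
})

test_that("OLS equals the closed-form normal-equations solution", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:10, 1); p <- sample(1:3, 1)
    f <- as.data.frame(matrix(runif(n * p), n))
    names(f) <- paste0("x", seq_len(p))
    y <- runif(n)
    fit <- fit_ols(f, y)
    xx <- cbind(1, as.matrix(f))
    beta <- unname(drop(solve(t(xx) %*% xx, t(xx) %*% y)))
    # coef() orders features first, intercept last
    expect_equal(unname(coef(fit)), beta[c(2:(p + 1), 1)],
                 tolerance = 1e-8)
  }
})

test_that("rank-deficient designs fail loudly, naming the collinear column", {
  f <- data.frame(a = 1:6, b = 2 * (1:6), y_noise = rnorm(6))
  expect_error(fit_ols(f[c("a", "b")], rnorm(6)), "collinear.*b")
  expect_error(fit_ols(data.frame(a = 1:3), rnorm(3), c("a", "zz")),
               "zz")
})

test_that("the expected unique in-bag count matches exhaustive enumeration", {
  # n = 2: resamples (1,1),(1,2),(2,1),(2,2) have 1,2,2,1 unique subjects
  expect_equal(expected_inbag_unique(2), 1.5)
  # n = 3: enumerate all 27 equally likely resamples
  draws <- expand.grid(1:3, 1:3, 1:3)
  enum <- mean(apply(draws, 1, function(x) length(unique(x))))
  expect_equal(expected_inbag_unique(3), enum)
})

test_that("Monte-Carlo calibration converges to the analytic in-bag count", {
  cal <- oob_calibration(42, n_boot = 20000, seed = 8)
  expect_equal(cal$mean_inbag_unique, expected_inbag_unique(42),
               tolerance = 0.01)
  expect_equal(cal$mean_inbag_unique + cal$mean_oob, 42)
})

test_that("bootstrap evaluation is reproducible and internally consistent", {
  f <- default_features_50c
  b1 <- bootstrap_oob(f, f$ffm_ref, c("sex", "age", "tbm", "bi"),
                      n_boot = 50, seed = 99, model_kind = "SC")
  b2 <- bootstrap_oob(f, f$ffm_ref, c("sex", "age", "tbm", "bi"),
                      n_boot = 50, seed = 99, model_kind = "SC")
  expect_identical(b1$mape_mean, b2$mape_mean)
  expect_identical(coef(b1), coef(b2))
  expect_equal(b1$mean_inbag_unique + b1$mean_oob, b1$n)
  b3 <- bootstrap_oob(f, f$ffm_ref, c("sex", "age", "tbm", "bi"),
                      n_boot = 1, seed = 7)
  expect_true(is.finite(b3$mape_mean))
  expect_error(bootstrap_oob(f[1:4, ], f$ffm_ref[1:4],
                             c("sex", "age", "tbm", "bi")), "too small")
})

test_that("mean bootstrap coefficients approach truth as noise shrinks", {
  truth <- c(182.858, -0.796, 0.464, 0.435, 11.729)
  dev_at <- function(sd_noise) {
    set.seed(12)
    f <- default_features_50c
    y <- predict_ffm_ttc(f$arm_volume, f$bmi, f$tbm, f$bi) +
      rnorm(nrow(f), 0, sd_noise)
    b <- bootstrap_oob(f, y, c("arm_volume", "bmi", "tbm", "bi"),
                       n_boot = 300, seed = 5)
    # scale-free deviation of the mean coefficient vector
    max(abs((unname(coef(b)) - truth) / truth))
  }
  devs <- vapply(c(2, 0.2, 0.002), dev_at, numeric(1))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[3], 1e-2)
})

test_that("the condition sweep covers the grid and flags absent conditions", {
  sw <- condition_sweep(default_gen$cohort, n_boot = 30, seed = 2)
  expect_s3_class(sw, "condition_sweep")
  expect_equal(nrow(sw), 18)
  expect_equal(nrow(best_condition(sw)), 2)
  # single-cell sweep reduces to a direct bootstrap_oob run
  sw1 <- condition_sweep(default_gen$cohort, model_kinds = "TTC",
                         frequencies = 50, positions = "c",
                         n_boot = 40, seed = 6)
  expect_equal(nrow(sw1), 1)
  cell_seed <- 6 + 1000L * 2L + 100L * 3L + 10L * 2L
  f <- default_features_50c
  direct <- bootstrap_oob(f, f$ffm_ref, c("arm_volume", "bmi", "tbm", "bi"),
                          n_boot = 40, seed = cell_seed, model_kind = "TTC")
  expect_equal(sw1$mape_mean, direct$mape_mean)
  expect_equal(sw1$r2_mean, direct$r2_mean)
  broken <- default_gen$cohort[
    !grepl("^z_50khz_c", names(default_gen$cohort))]
  expect_error(condition_sweep(broken, n_boot = 5, seed = 1),
               "50 kHz, position c")
})
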