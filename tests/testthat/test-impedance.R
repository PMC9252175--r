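test_that("frustum resistance matches cylinder and slab-integration oracles", {
  # cylinder rho h / (pi r^2), r = 5
  expect_equal(frustum_resistance(10 * pi, 10 * pi, 10, 100),
               100 * 10 / (pi * 25))
  expect_equal(frustum_resistance(40, 15, 60, 150), 188.4956,
               tolerance = 1e-6)
  expect_equal(frustum_resistance(40, 15, 60, 150),
               frustum_resistance_quad(40, 15, 60, 150), tolerance = 1e-9)
  expect_equal(frustum_resistance(40, 15, 0, 150), 0)
  expect_error(frustum_resistance(0, 15, 10, 100), "positive")
})

test_that("R times geometric-mean area equals rho h for all frusta", {
  fr <- random_frusta(100, seed = 3)
  r <- frustum_resistance(fr$c_base, fr$c_top, fr$h, fr$rho)
  area <- pi * (fr$c_base / (2 * pi)) * (fr$c_top / (2 * pi))
  expect_equal(r * area, fr$rho * fr$h, tolerance = 1e-12)
})

test_that("hand-to-hand resistance is a series sum, permutation-invariant", {
  seg <- function(cb, ct, l, rho)
    list(c_base = cb, c_top = ct, length = l, resistivity = rho)
  arm <- seg(40, 15, 60, 150)
  expect_equal(hand_to_hand_resistance(list(arm, arm)),
               2 * frustum_resistance(40, 15, 60, 150))
  expect_equal(hand_to_hand_resistance(list(arm, arm), torso_resistance = 20),
               396.9911, tolerance = 1e-4)
  s2 <- seg(35, 16, 55, 200)
  s3 <- seg(30, 14, 50, 100)
  expect_equal(hand_to_hand_resistance(list(arm, s2, s3)),
               hand_to_hand_resistance(list(s3, arm, s2)))
  # default equals explicit zero torso
  expect_equal(hand_to_hand_resistance(list(arm, s2)),
               hand_to_hand_resistance(list(arm, s2), torso_resistance = 0))
  expect_error(hand_to_hand_resistance(list()), "non-empty")
})

test_that("arm-volume proxy is V * TBM/FFM with guarded domain", {
  expect_equal(impedance_proxy(6109.06, 69.56, 50.99), 8333.913,
               tolerance = 1e-4)
  expect_equal(impedance_proxy(2 * 6109.06, 69.56, 50.99),
               2 * impedance_proxy(6109.06, 69.56, 50.99))
  expect_error(impedance_proxy(6000, 70, 70), "less than")
  expect_error(impedance_proxy(6000, 70, -2), "positive")
})

test_that("proxy fit recovers exact collinearity and the null case", {
  x <- c(1000, 2000, 3000, 4000)
  fit <- fit_proxy(x, 0.05 * x + 20)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 0.05)
  expect_equal(fit$intercept, 20)
  set.seed(5)
  flat <- fit_proxy(runif(2000, 1000, 9000), rnorm(2000, 500, 50))
  expect_lt(flat$r_squared, 0.01)
  expect_error(fit_proxy(rep(10, 5), 1:5), "degenerate")
  expect_error(fit_proxy(1:2, 1:2), "at least 3")
})

test_that("proxy r^2 on the default cohort brackets the reported range", {
  f <- default_features_50c
  proxy <- impedance_proxy(f$arm_volume_cm3, f$tbm,
                           default_gen$truth$ffm_true_kg)
  fit <- fit_proxy(proxy, f$resistance)
  expect_gt(fit$r_squared, 0.6)
  expect_lt(fit$r_squared, 0.95)
})

test_that("proxy r^2 degrades as measurement noise grows", {
  r2_at <- function(noise_sd) {
    sp <- cohort_spec(n = 300, seed = 17)
    sp$resistivity$cond_noise_sd["50", "c"] <- noise_sd
    gen <- generate_cohort(sp)
    f <- derive_features(gen$cohort, 50, "c")
    fit_proxy(impedance_proxy(f$arm_volume_cm3, f$tbm,
                              gen$truth$ffm_true_kg),
              f$resistance)$r_squared
  }
  r2 <- vapply(c(0, 80, 250), r2_at, numeric(1))
  expect_true(all(diff(r2) < 0))
})
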