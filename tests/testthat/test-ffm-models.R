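test_that("published SC equation evaluates exactly", {
  expect_equal(predict_ffm_sc(1, 27.02, 69.56, 52.554), 50.6746,
               tolerance = 1e-4)
  # sex coefficient reads off as the male-female gap
  expect_equal(predict_ffm_sc(1, 27.02, 69.56, 52.554) -
                 predict_ffm_sc(0, 27.02, 69.56, 52.554), 2.835)
  # age linearity: +10 years is exactly -1.02 kg
  expect_equal(predict_ffm_sc(1, 37.02, 69.56, 52.554) -
                 predict_ffm_sc(1, 27.02, 69.56, 52.554), -1.02)
  expect_error(predict_ffm_sc(2, 30, 70, 50), "sex")
})

test_that("published TTC equation evaluates exactly, with unit handling", {
  expect_equal(predict_ffm_ttc(0.00610906, 23.6, 69.56, 52.554), 49.1973,
               tolerance = 1e-4)
  expect_equal(predict_ffm_ttc(6109.06, 23.6, 69.56, 52.554, units = "cm3"),
               predict_ffm_ttc(0.00610906, 23.6, 69.56, 52.554))
  dv <- 0.002
  expect_equal(predict_ffm_ttc(0.006 + dv, 23.6, 69.56, 52.554) -
                 predict_ffm_ttc(0.006, 23.6, 69.56, 52.554),
               182.858 * dv)
  expect_error(predict_ffm_ttc(-0.006, 23.6, 69.56, 52.554), "positive")
})

test_that("generic evaluation is identical to the dedicated operations", {
  set.seed(11)
  n <- 1000
  dat <- data.frame(sex = sample(0:1, n, TRUE), age = runif(n, 18, 60),
                    tbm = runif(n, 45, 100), bi = runif(n, 20, 90),
                    arm_volume = runif(n, 0.003, 0.011),
                    bmi = runif(n, 18, 39))
  expect_identical(predict(ffm_sc_published(), dat),
                   predict_ffm_sc(dat$sex, dat$age, dat$tbm, dat$bi))
  expect_identical(predict(ffm_ttc_published(), dat),
                   predict_ffm_ttc(dat$arm_volume, dat$bmi, dat$tbm,
                                   dat$bi))
})

test_that("both published estimators are affine in their features", {
  set.seed(23)
  for (i in 1:20) {
    x1 <- list(arm_volume = runif(1, 0.003, 0.011), bmi = runif(1, 18, 39),
               tbm = runif(1, 45, 100), bi = runif(1, 20, 90))
    x2 <- list(arm_volume = runif(1, 0.003, 0.011), bmi = runif(1, 18, 39),
               tbm = runif(1, 45, 100), bi = runif(1, 20, 90))
    a <- runif(1)
    mix <- as.data.frame(Map(function(u, v) a * u + (1 - a) * v, x1, x2))
    m <- ffm_ttc_published()
    expect_equal(predict(m, mix),
                 a * predict(m, as.data.frame(x1)) +
                   (1 - a) * predict(m, as.data.frame(x2)),
                 tolerance = 1e-12)
  }
})

test_that("model container enforces its contract", {
  expect_error(ffm_model("m", c("a", "b"), c("", ""), 1, 0), "equal length")
  expect_error(ffm_model("m", c("a", "a"), c("", ""), c(1, 2), 0), "unique")
  m0 <- ffm_model("int_only", character(0), character(0), numeric(0), 11.729)
  expect_equal(predict(m0, data.frame(x = 1)), 11.729)
  m <- ffm_ttc_published()
  expect_error(predict(m, list(arm_volume = 0.006, bmi = 23)), "missing")
  expect_error(predict(m, list(arm_volume = 0.006, bmi = 23, tbm = 70,
                               bi = 50, junk = 1)), "unexpected")
  expect_equal(unname(coef(m)),
               c(182.858, -0.796, 0.464, 0.435, 11.729))
})

test_that("models survive a JSON round trip", {
  m <- ffm_ttc_published()
  path <- withr::local_tempfile(fileext = ".json")
  write_ffm_model(m, path)
  m2 <- read_ffm_model(path)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$intercept, m$intercept)
  dat <- data.frame(arm_volume = 0.0061, bmi = 23.6, tbm = 69.56, bi = 52.6)
  expect_equal(predict(m2, dat), predict(m, dat))
})
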