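# shared fixtures: one default cohort, generated once per test run
default_gen <- generate_cohort(cohort_spec(seed = 1))
default_features_50c <- derive_features(default_gen$cohort, 50, "c")

# random valid frusta (base circumference >= top) for geometry tests
random_frusta <- function(n, seed) {
  set.seed(seed)
  c_top <- runif(n, 5, 30)
  data.frame(c_base = c_top + runif(n, 0, 30), c_top = c_top,
             h = runif(n, 5, 80), rho = runif(n, 50, 400))
}

# numeric-integration oracles: linear-radius solid of revolution
frustum_volume_quad <- function(c_base, c_top, h) {
  r1 <- c_base / (2 * pi); r2 <- c_top / (2 * pi)
  stats::integrate(function(z) pi * (r1 + (r2 - r1) * z / h)^2,
                   0, h, rel.tol = 1e-12)$value
}
frustum_resistance_quad <- function(c_base, c_top, h, rho) {
  r1 <- c_base / (2 * pi); r2 <- c_top / (2 * pi)
  stats::integrate(function(z) rho / (pi * (r1 + (r2 - r1) * z / h)^2),
                   0, h, rel.tol = 1e-12)$value
}
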