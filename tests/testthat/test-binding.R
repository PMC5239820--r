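test_that("flat-PMF standard-state free energy matches the closed form", {
  flat <- pmf_profile(seq(0, 2, length.out = 200), rep(0, 200),
                      referenced = TRUE)
  cfg <- binding_config()
  dg <- delta_g_meta(flat, cfg)
  kT <- kB * 298
  expected <- -kT * log((1 / 1.66) * pi * 0.2^2 * 0.9)
  expect_equal(as.numeric(dg), expected, tolerance = 1e-9)
  expect_equal(as.numeric(dg), 1.591, tolerance = 0.001)
})

test_that("square-well PMF matches the piecewise closed form", {
  pmf <- square_well_pmf(depth = -5)
  kT <- kB * 298
  integral <- 0.7 + 0.2 * exp(5 / kT)
  expected <- -kT * log((1 / 1.66) * pi * 0.2^2 * integral)
  dg <- delta_g_meta(pmf, binding_config())
  expect_equal(as.numeric(dg), expected, tolerance = 1e-4)
  expect_equal(as.numeric(dg), -2.519, tolerance = 0.005)
})

test_that("deep-well limit: deepening the site shifts dG_meta linearly", {
  dg1 <- as.numeric(delta_g_meta(square_well_pmf(depth = -12)))
  dg2 <- as.numeric(delta_g_meta(square_well_pmf(depth = -15)))
  expect_equal(dg1 - dg2, 3, tolerance = 1e-6)
})

test_that("scaling the cross-section shifts dG_meta by exactly kT log(1/lambda)", {
  flat <- pmf_profile(seq(0, 2, length.out = 200), rep(0, 200),
                      referenced = TRUE)
  lam <- 2.5
  dg1 <- as.numeric(delta_g_meta(flat, binding_config()))
  dg2 <- as.numeric(delta_g_meta(flat, binding_config(S_star = lam * pi * 0.04)))
  expect_equal(dg2 - dg1, kB * 298 * log(1 / lam), tolerance = 1e-12)
})

test_that("dG_meta is stable under grid refinement on smooth PMFs", {
  wfun <- function(z) -4 * exp(-(z - 0.5)^2 / (2 * 0.1^2))
  za <- seq(0, 2, length.out = 200)
  zb <- seq(0, 2, length.out = 2000)
  dga <- as.numeric(delta_g_meta(pmf_profile(za, wfun(za), referenced = TRUE)))
  dgb <- as.numeric(delta_g_meta(pmf_profile(zb, wfun(zb), referenced = TRUE)))
  expect_equal(dga, dgb, tolerance = 5e-4)
})

test_that("site-boundary sensitivity is exposed to the caller", {
  flat <- pmf_profile(seq(0, 2, length.out = 200), rep(0, 200),
                      referenced = TRUE)
  dg <- delta_g_meta(flat, binding_config())
  kT <- kB * 298
  # for a flat PMF the 0.8/1.0 nm probes give exactly kT log(0.9/0.8)
  expect_equal(site_sensitivity(dg), kT * log(0.9 / 0.8), tolerance = 1e-9)
  # a deep narrow well hides the boundary: sensitivity nearly zero
  deep <- delta_g_meta(square_well_pmf(depth = -12))
  expect_lt(site_sensitivity(deep), 1e-3)
})

test_that("dG_meta refuses unreferenced or unsampled input", {
  flat <- pmf_profile(seq(0, 2, length.out = 200), rep(0, 200))
  expect_error(delta_g_meta(flat), "referenced")
  fes <- reconstruct_fes(single_hill(height = 0.1, center = c(1.6, 0)))
  pmf <- set_reference_level(project_pmf(fes))
  expect_error(delta_g_meta(pmf), "unsampled")
})

test_that("FEP estimator is exact on degenerate series", {
  t <- seq(0, 99, by = 1)
  zero <- restraint_series(t, rep(0, 100))
  expect_identical(delta_g_restr(zero)$estimate, 0)
  expect_identical(delta_g_restr(zero)$std, 0)
  const <- restraint_series(t, rep(3.7, 100))
  expect_equal(delta_g_restr(const)$estimate, 3.7)
  expect_identical(delta_g_restr(const)$std, 0)
})

test_that("FEP estimator recovers the two-state closed form", {
  kT <- kB * 298
  set.seed(31)
  v <- sample(rep(c(0, 50), each = 1000))
  ser <- restraint_series(seq_along(v), v)
  res <- delta_g_restr(ser, n_boot = 100, seed = 5)
  expected <- -kT * log(0.5)        # +0.4104 kcal/mol at 298 K
  expect_close(expected, 0.4104, tol = 1e-3)
  expect_lt(abs(res$estimate - expected), 3 * res$std + 1e-6)
})

test_that("FEP estimator matches a brute-force oracle on white noise", {
  kT <- kB * 298
  set.seed(77)
  v <- abs(rnorm(4000, 0.3, 0.3))
  ser <- restraint_series(seq_along(v), v)
  res <- delta_g_restr(ser, n_boot = 100, seed = 9)
  brute <- -kT * log(mean(exp(-v / kT)))   # all samples, no decimation
  expect_lt(abs(res$estimate - brute), 3 * res$std + 1e-6)
})

test_that("Jensen bound holds on 1000 random series", {
  set.seed(123)
  ok <- vapply(1:1000, function(i) {
    n <- sample(80:160, 1)
    v <- switch(1 + (i %% 3),
                abs(rnorm(n, runif(1, 0, 2), runif(1, 0.01, 2))),
                rexp(n, rate = runif(1, 0.5, 5)),
                runif(n, 0, 10))
    ser <- restraint_series(seq_len(n), v)
    res <- delta_g_restr(ser, n_boot = 2, seed = i)
    # bound is on the decimated samples the estimator actually used
    step <- max(1L, as.integer(ceiling(res$g)))
    res$estimate <= mean(v[seq(1L, n, by = step)]) + 1e-9
  }, logical(1))
  expect_true(all(ok))
})

test_that("FEP decimation demands enough independent samples", {
  # strongly correlated short series: after thinning fewer than 10 remain
  x <- rep(c(0, 0.5), each = 40) + rnorm(80, sd = 1e-3)
  ser <- restraint_series(seq_along(x), abs(x))
  expect_error(delta_g_restr(ser), "independent samples")
})

test_that("FEP bootstrap is reproducible and leaves the RNG state alone", {
  set.seed(1)
  v <- abs(rnorm(2000, 0.2, 0.2))
  ser <- restraint_series(seq_along(v), v)
  before <- runif(1)
  set.seed(1); v2 <- abs(rnorm(2000, 0.2, 0.2)); runif(1)
  a <- delta_g_restr(ser, n_boot = 50, seed = 42)
  b <- delta_g_restr(ser, n_boot = 50, seed = 42)
  expect_identical(a, b)
})

test_that("combining corrections follows the two bookkeeping identities", {
  r <- combine_dg(-8.00, dG_restr = 2.66)
  expect_equal(r$dG_bind, -5.34)
  expect_equal(r$method, "restraint")
  e <- combine_dg(-11.76, dG_emp = 5.86)
  expect_equal(e$dG_bind, -5.90)
  expect_equal(e$method, "empirical")
  expect_equal(combine_dg(0, dG_restr = 0)$dG_bind, 0)
  expect_error(combine_dg(-5), "exactly one")
  expect_error(combine_dg(-5, dG_restr = 1, dG_emp = 1), "exactly one")
  # quadrature error propagation
  q <- combine_dg(-8, dG_restr = 2.66, dG_meta_err = 0.3, dG_restr_err = 0.4)
  expect_equal(q$err, 0.5)
  # a dg_restr object carries its own error
  ser <- restraint_series(1:100, rep(1.5, 100))
  q2 <- combine_dg(-8, dG_restr = delta_g_restr(ser), dG_meta_err = 0.3)
  expect_equal(q2$dG_bind, -6.5)
  expect_equal(q2$err, 0.3)
})
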