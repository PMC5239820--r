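# shared fixtures; expensive toy runs are generated once per session and
# cached in this environment so several test files can reuse them
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a converged-ish well-tempered run on the default double-well preset
dw_run <- function() cached("dw_run", {
  simulate_wtmetad(toy_binding_model("double_well"),
                   nsteps = 1.5e6, dt = 0.002, seed = 101)
})

dw_truth <- function() cached("dw_truth", {
  toy_delta_f(toy_binding_model("double_well"))
})

# a tiny hand-built hills record for exact bookkeeping tests
single_hill <- function(height = 0.1195, center = c(0.9, 0.1), gamma = 20) {
  hills_record(times = 1, centers = matrix(center, ncol = 2),
               widths = c(0.04, 0.043), heights = height, gamma = gamma)
}

# square-well PMF: w = depth on [z1, z2], 0 elsewhere; nodes are placed on
# both sides of the discontinuities so the piecewise-linear Boltzmann
# interpolant reproduces the step profile
square_well_pmf <- function(depth = -5, z1 = 0.4, z2 = 0.6, eps = 1e-9) {
  z <- sort(unique(c(seq(0, 2, by = 0.005), z1 - eps, z2 + eps)))
  w <- ifelse(z >= z1 & z <= z2, depth, 0)
  pmf_profile(z, w, referenced = TRUE)
}

# AR(1) series with known statistical inefficiency (1 + phi)/(1 - phi)
ar1_series <- function(n, phi, seed) {
  set.seed(seed)
  x <- numeric(n)
  x[1] <- rnorm(1)
  innov <- rnorm(n - 1, sd = sqrt(1 - phi^2))
  for (i in 2:n) x[i] <- phi * x[i - 1] + innov[i - 1]
  x
}

# absolute-difference comparison for printed-table values (testthat's
# tolerance is relative, which is the wrong scale near zero)
expect_close <- function(actual, expected, tol = 0.0105) {
  expect_lt(abs(actual - expected), tol)
}
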