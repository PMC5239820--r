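test_that("identical seeds give bit-identical runs", {
  a <- simulate_wtmetad(toy_binding_model("double_well"), nsteps = 5e4,
                        dt = 0.002, seed = 7)
  b <- simulate_wtmetad(toy_binding_model("double_well"), nsteps = 5e4,
                        dt = 0.002, seed = 7)
  expect_identical(a, b)
  c <- simulate_wtmetad(toy_binding_model("double_well"), nsteps = 5e4,
                        dt = 0.002, seed = 8)
  expect_false(identical(a$trajectory$cv1, c$trajectory$cv1))
})

test_that("zero-temperature, zero-bias dynamics stays at a minimum", {
  model <- toy_binding_model("double_well", T = 0)
  # locate the tilted left minimum numerically
  zmin <- optimize(function(z) toy_potential(model, z, 0), c(0.2, 0.9),
                   tol = 1e-10)$minimum
  run <- simulate_wtmetad(model, nsteps = 1e4, dt = 0.002, seed = 1,
                          init = c(zmin, 0), deposit = FALSE)
  expect_lt(max(abs(run$trajectory$cv1 - zmin)), 1e-6)
  expect_lt(max(abs(run$trajectory$cv2)), 1e-6)
})

test_that("frictionless, noiseless integration conserves energy", {
  model <- toy_binding_model("double_well", friction = 0, T = 298)
  # T > 0 draws an initial velocity; friction 0 disables the O-step noise
  run <- simulate_wtmetad(model, nsteps = 1e5, dt = 0.002, seed = 3,
                          init = c(0.6, 0.1), deposit = FALSE)
  drift <- diff(range(run$trajectory$energy))
  expect_lt(drift, 0.02)
})

test_that("unbiased sampling reproduces the Boltzmann marginal of z", {
  # low-barrier double well so unbiased dynamics crosses freely
  model <- toy_binding_model("double_well", params = list(h = 1, tilt = 1))
  run <- simulate_wtmetad(model, nsteps = 2e6, dt = 0.002, seed = 12,
                          out_stride = 50, deposit = FALSE)
  z <- run$trajectory$cv1
  g <- statistical_inefficiency(z)
  z_ind <- z[seq(1, length(z), by = ceiling(g))]
  breaks <- seq(0.1, 1.9, length.out = 10)
  z_ind <- z_ind[z_ind > 0.1 & z_ind < 1.9]
  obs <- table(cut(z_ind, breaks))
  # expected bin masses from the quadrature profile
  zq <- seq(0.1, 1.9, length.out = 721)
  F <- toy_free_energy_profile(model, zq, walls = toy_walls())
  dens <- exp(-(F - min(F)) / (kB * model$T))
  cdf <- cumsum(dens) / sum(dens)
  pbin <- diff(stats::approx(zq, cdf, xout = breaks, rule = 2)$y)
  pbin <- pbin / sum(pbin)
  test <- suppressWarnings(stats::chisq.test(as.numeric(obs), p = pbin))
  expect_gt(test$p.value, 1e-3)
})

test_that("well-tempered run recovers the double-well free-energy gap", {
  run <- dw_run()
  pmf <- project_pmf(reconstruct_fes(run$hills))
  est <- pmf_delta_f(pmf)
  expect_equal(est, dw_truth(), tolerance = 0.15)
})

test_that("a model with no solvent has identically zero S and V(S)", {
  m <- solvent_trap_model(M = 0)
  traj <- simulate_solvent_trap(m, restraint_on = TRUE, nsteps = 2e4,
                                dt = 0.001, seed = 1)
  expect_true(all(traj$S == 0))
  expect_true(all(traj$V_S == 0))
})

test_that("dry-state fraction responds to the solvent site affinity", {
  # deep solvent well: the site is essentially always wet
  wet <- unbiased_restraint_series(solvent_trap_model(eps_W = 8),
                                   nsteps = 3e5, dt = 0.001, seed = 4)
  # broad repulsive site: the solvent stays away, the site is essentially dry
  dry <- unbiased_restraint_series(
    solvent_trap_model(eps_W = -8, w_site = 0.3, eps_R = 0),
    nsteps = 3e5, dt = 0.001, seed = 4)
  expect_lt(attr(wet, "dry_fraction"), 0.01)
  expect_gt(attr(dry, "dry_fraction"), 0.8)
})

test_that("restraint series are reproducible and well-formed", {
  m <- solvent_trap_model()
  a <- unbiased_restraint_series(m, nsteps = 5e4, dt = 0.001, seed = 11)
  b <- unbiased_restraint_series(m, nsteps = 5e4, dt = 0.001, seed = 11)
  expect_identical(a, b)
  expect_true(all(a$V_S >= 0))
  expect_equal(unique(round(diff(a$times), 9)), a$dt_out)
})

test_that("with the restraint on, an unbound ligand sees a dry site", {
  m <- solvent_trap_model()
  traj <- simulate_solvent_trap(m, restraint_on = TRUE, params = NULL,
                                nsteps = 5e5, dt = 0.001, seed = 5)
  # unbiased, ligand stays unbound; S must sit below the quartic onset width
  onset_width <- (kB * m$T / m$restraint$k_s)^0.25
  expect_lt(mean(traj$S), m$restraint$S_0 + onset_width)
})

test_that("trapped solvent is the mechanism that blocks binding attempts", {
  # pool binding attempts from unrestrained runs over several seeds:
  # attempts made against an occupied site should fail more often
  att <- do.call(rbind, lapply(1:4, function(s) {
    traj <- simulate_solvent_trap(solvent_trap_model(), restraint_on = FALSE,
                                  nsteps = 1e6, dt = 0.001, seed = 100 + s)
    hysteresis_signature(traj)$attempts
  }))
  expect_gt(nrow(att), 20)
  corr <- cor(as.numeric(att$occupied), as.numeric(att$success))
  expect_lt(corr, 0)
})

test_that("divergent integration aborts with a diagnostic", {
  model <- toy_binding_model("double_well", friction = 0.001)
  expect_error(
    simulate_wtmetad(model, nsteps = 1e5, dt = 0.5, seed = 1, deposit = FALSE),
    "diverged")
})
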