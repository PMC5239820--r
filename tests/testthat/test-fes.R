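test_that("single-hill reconstruction matches the scaled Gaussian closed form", {
  h <- single_hill(height = 0.1195, center = c(0.9, 0.1), gamma = 20)
  grid <- fes_grid()
  fes <- reconstruct_fes(h, grid, cutoff = Inf)
  mult <- 20 / 19
  # closed form: F = -mult * h * G(x) shifted so min(F) = 0
  G <- outer(grid$z, grid$c, function(z, c)
    0.1195 * exp(-0.5 * ((z - 0.9) / 0.04)^2 - 0.5 * ((c - 0.1) / 0.043)^2))
  expected <- -mult * G
  expected <- expected - min(expected)
  expect_equal(fes$F, expected, tolerance = 1e-14)
  # depth from the deepest grid node to the far field equals mult times
  # the node value of the Gaussian (the grid does not hit the center exactly)
  depth <- max(fes$F[fes$sampled]) - min(fes$F)
  expect_equal(depth, mult * max(G), tolerance = 1e-10)
})

test_that("standard-metadynamics reconstruction uses multiplier 1", {
  wt <- reconstruct_fes(single_hill(gamma = 20), cutoff = Inf)
  std <- reconstruct_fes(single_hill(gamma = Inf), cutoff = Inf)
  depth <- function(f) max(f$F[f$sampled]) - min(f$F)
  expect_equal(depth(wt) / depth(std), 20 / 19, tolerance = 1e-10)
})

test_that("reconstruction is linear in the deposited hills", {
  one <- single_hill(height = 0.1)
  two <- hills_record(c(1, 2), matrix(rep(c(0.9, 0.1), each = 2), ncol = 2),
                      c(0.04, 0.043), c(0.05, 0.05), gamma = 20)
  f1 <- reconstruct_fes(one, cutoff = Inf)
  f2 <- reconstruct_fes(two, cutoff = Inf)
  expect_equal(f1$F, f2$F, tolerance = 1e-12)
})

test_that("reconstruction rejects empty and out-of-grid hills", {
  empty <- structure(list(times = numeric(0),
                          centers = matrix(numeric(0), ncol = 2),
                          widths = matrix(numeric(0), ncol = 2),
                          heights = numeric(0), gamma = 20),
                     class = "hills_record")
  expect_error(reconstruct_fes(empty), "empty hills")
  outside <- hills_record(c(1, 2), rbind(c(0.5, 0), c(2.5, 0)),
                          c(0.04, 0.043), c(0.1, 0.1), gamma = 20)
  expect_error(reconstruct_fes(outside), "hill 2")
  expect_error(reconstruct_fes(single_hill(), t_end = 0.5), "no hills")
})

test_that("unsampled nodes carry the explicit ceiling, never silent zeros", {
  fes <- reconstruct_fes(single_hill(), cutoff = 6)
  expect_true(any(!fes$sampled))
  expect_true(all(fes$F[!fes$sampled] == fes$ceiling))
  expect_equal(fes$ceiling, max(fes$F[fes$sampled]) + 5 * kB * 298)
})

test_that("projection reduces flat and separable surfaces correctly", {
  grid <- fes_grid(nz = 50, nc = 40)
  base <- list(z = grid$z, c = grid$c, T = 298, gamma = 20,
               sampled = matrix(TRUE, 50, 40), ceiling = Inf,
               t_window = c(0, 1))
  # independent of CV 2: w(z) = F(z) + const
  F1 <- function(z) 2 * (z - 1)^2
  fes <- base
  fes$F <- matrix(F1(grid$z), 50, 40)
  class(fes) <- "free_energy_surface"
  w <- project_pmf(fes)$w
  expect_equal(w - w[1], F1(grid$z) - F1(grid$z[1]), tolerance = 1e-10)
  # separable: F(z, c) = F1(z) + F2(c) projects to F1(z) + const
  fes$F <- outer(F1(grid$z), 3 * grid$c^2, "+")
  w <- project_pmf(fes)$w
  expect_equal(w - w[1], F1(grid$z) - F1(grid$z[1]), tolerance = 1e-10)
})

test_that("projection reproduces the two-level column closed form", {
  # two c-nodes with values {0, D}: w = -kT log((e^0 + e^(-bD))/2 * dc)
  kT <- kB * 298
  D <- 3
  fes <- structure(list(z = c(0, 1), c = c(-1, 1),
                        F = rbind(c(0, D), c(0, 0)),
                        sampled = matrix(TRUE, 2, 2), ceiling = Inf,
                        T = 298, gamma = 20, t_window = c(0, 1)),
                   class = "free_energy_surface")
  w <- project_pmf(fes)$w
  expected1 <- -kT * log((exp(0) + exp(-D / kT)) / 2 * 2)
  expected2 <- -kT * log(2)  # both levels zero, dc range = 2
  expect_equal(w[1], expected1, tolerance = 1e-12)
  expect_equal(w[2], expected2, tolerance = 1e-12)
  # D -> Inf recovers the lower level (relative to the flat column)
  fes$F[1, 2] <- 1e6
  wlim <- project_pmf(fes)$w
  expect_equal(wlim[1] - wlim[2], kT * log(2), tolerance = 1e-9)
})

test_that("projection flags fully unsampled columns at the ceiling", {
  fes <- reconstruct_fes(single_hill(), cutoff = 6)
  pmf <- project_pmf(fes)
  expect_true(any(pmf$flagged))
  expect_true(all(pmf$w[pmf$flagged] == fes$ceiling))
  far <- which(abs(fes$z - 0.9) > 0.5)
  expect_true(all(pmf$flagged[far]))
})

test_that("projection commutes with adding a constant to the FES", {
  fes <- reconstruct_fes(dw_run()$hills)
  w0 <- project_pmf(fes)$w
  fes$F <- fes$F + 7
  fes$ceiling <- fes$ceiling + 7
  w7 <- project_pmf(fes)$w
  expect_equal(w7, w0 + 7, tolerance = 1e-9)
})

test_that("reference level fixes the unbound plateau mean to zero", {
  z <- seq(0, 2, length.out = 201)
  # constant profile
  pmf <- pmf_profile(z, rep(7, 201))
  ref <- set_reference_level(pmf)
  expect_equal(ref$w, rep(0, 201))
  expect_true(isTRUE(attr(ref, "referenced")))
  # idempotence
  expect_equal(set_reference_level(ref)$w, ref$w)
  # linear profile: mean over in-range nodes is subtracted
  pmf <- pmf_profile(z, 3 * z)
  ref <- set_reference_level(pmf, c(1.4, 1.8))
  sel <- z >= 1.4 & z <= 1.8
  expect_equal(ref$w, 3 * z - mean(3 * z[sel]))
  expect_equal(mean(ref$w[sel]), 0)
})

test_that("reference level errors on unsampled or empty ranges", {
  pmf <- project_pmf(reconstruct_fes(single_hill()))
  expect_error(set_reference_level(pmf, c(1.4, 1.8)), "unsampled")
  flat <- pmf_profile(seq(0, 1, by = 0.1), rep(0, 11))
  expect_error(set_reference_level(flat, c(1.4, 1.8)), "no grid node")
})

test_that("grid refinement changes the projected PMF only marginally", {
  hills <- dw_run()$hills
  coarse <- project_pmf(reconstruct_fes(hills, fes_grid(nz = 200, nc = 100)))
  fine <- project_pmf(reconstruct_fes(hills, fes_grid(nz = 399, nc = 199)))
  # doubling the resolution keeps every coarse node (399 = 2 * 200 - 1);
  # compare the well-sampled free-energy range (within 5 kcal/mol of the
  # minimum, the display convention) between the z-walls; the scarcely
  # visited wall shoulders carry only a handful of hills and are excluded
  shared <- match(round(coarse$z, 10), round(fine$z, 10))
  ok <- !is.na(shared) & !coarse$flagged &
    coarse$w < min(coarse$w[!coarse$flagged]) + 5 &
    coarse$z > 0.1 & coarse$z < 1.8
  d <- coarse$w[ok] - fine$w[shared[ok]]
  expect_lt(max(abs(d - mean(d))), 0.05)
})

test_that("time-window FES averaging behaves like the snapshot mean", {
  hills <- dw_run()$hills
  t_end <- max(hills$times)
  avg <- fes_time_average(hills, window = c(t_end / 2, t_end), n_snapshots = 5)
  last <- reconstruct_fes(hills, t_end = t_end)
  # the averaged surface must lie between the window-start and window-end
  # surfaces in total bias (well-tempered bias only grows)
  first <- reconstruct_fes(hills, t_end = t_end / 2)
  rng <- function(f) max(f$F[f$sampled]) - min(f$F[f$sampled])
  expect_gt(rng(avg), 0)
  expect_lte(rng(avg), rng(last) + rng(first))
  expect_true(all(avg$F[!avg$sampled] == avg$ceiling))
})
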