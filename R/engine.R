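#' Run well-tempered metadynamics on a 2D toy model
#'
#' Integrates Langevin dynamics (BAOAB splitting) on the collective-variable
#' coordinates of a [toy_binding_model()] while depositing well-tempered
#' Gaussian hills. The funnel restraint acts on the toy as a flat-bottom
#' pair of quartic walls on z ([toy_walls()]); CV 2 is reflected at the
#' \[-1, 1\] bounds of the cosine variable (hills are not reflected).
#'
#' Stability requires `dt * friction < 0.1` and
#' `dt^2 * max|U''| / mass < 0.1`; the defaults satisfy both for the bundled
#' presets and a violated criterion triggers a divergence diagnostic at run
#' time.
#'
#' @param model a [toy_binding_model()]
#' @param geom a [funnel_geometry()] (only the z-walls act on the toy)
#' @param params a [wt_params()]
#' @param nsteps number of integration steps
#' @param dt time step (ps)
#' @param seed integer RNG seed; identical seeds give bit-identical output
#' @param out_stride record the trajectory every `out_stride` steps
#' @param init length-2 initial (z, c); default near the preset's bound well
#' @param z_lo onset of the lower z-wall (nm)
#' @param deposit set `FALSE` for an unbiased run (no hills)
#' @return a list with elements `trajectory` (class `fmd_trajectory`:
#'   `times`, `cv1`, `cv2`, `energy`, `seed`) and `hills`
#'   (a [hills_record()]; empty when `deposit = FALSE`)
#' @export
simulate_wtmetad <- function(model, geom = funnel_geometry(),
                             params = wt_params(), nsteps = 1e6, dt = 0.002,
                             seed = 1, out_stride = 100,
                             init = c(0.5, 0), z_lo = 0.05, deposit = TRUE) {
  stopifnot(inherits(model, "toy_binding_model"),
            inherits(geom, "funnel_geometry"),
            inherits(params, "wt_params"))
  if (dt * model$friction >= 0.1)
    warning("dt * friction >= 0.1: integration may be inaccurate")
  walls <- toy_walls(geom, z_lo = z_lo)
  res <- engine_wtmetad_2d(model$preset_id, unname(model$params),
                           model$mass, model$friction, model$T,
                           params$W0, params$sigma1, params$sigma2,
                           params$stride, params$gamma,
                           walls$z_wall, walls$k_wall, walls$z_lo, walls$k_lo,
                           1.0, init[1], init[2],
                           as.integer(nsteps), dt, as.integer(out_stride),
                           as.numeric(seed), deposit, 6.0)
  traj <- structure(list(times = res$times, cv1 = res$cv1, cv2 = res$cv2,
                         energy = res$energy, seed = seed, dt_out = dt * out_stride,
                         model = model$preset),
                    class = "fmd_trajectory")
  hills <- if (length(res$hill_times) > 0)
    hills_record(res$hill_times,
                 cbind(res$hill_cv1, res$hill_cv2),
                 c(params$sigma1, params$sigma2),
                 res$hill_heights, gamma = params$gamma)
  else
    structure(list(times = numeric(0), centers = matrix(numeric(0), ncol = 2),
                   widths = matrix(numeric(0), ncol = 2), heights = numeric(0),
                   gamma = params$gamma),
              class = "hills_record")
  list(trajectory = traj, hills = hills)
}

#' @export
print.fmd_trajectory <- function(x, ...) {
  cat(sprintf("Toy trajectory: %d frames, t = [%g, %g] ps, seed %s\n",
              length(x$times), min(x$times), max(x$times), format(x$seed)))
  invisible(x)
}

#' Simulate the solvent-trap channel
#'
#' Langevin dynamics of a [solvent_trap_model()]: a ligand driven along the
#' channel by 1D well-tempered metadynamics while `M` solvent particles
#' compete for the binding site. With `restraint_on = TRUE` the dry-state
#' restraint energy V(S) of [coordination_restraint_energy()] is part of the
#' Hamiltonian whenever `S >= S_0`, keeping solvent out of the site; the
#' solvent then starts in the reservoir (the dry state), otherwise in the
#' site (the trapped state).
#'
#' @param model a [solvent_trap_model()]
#' @param restraint_on logical, apply the water restraint
#' @param params a [wt_params()] for the 1D metadynamics on the ligand
#'   coordinate, or `NULL` for unbiased dynamics
#' @param nsteps,dt,seed,out_stride as in [simulate_wtmetad()]
#' @return an `fmd_trajectory` with fields `times`, `cv1` (ligand z), `S`,
#'   `V_S`, `seed`, plus the deposited 1D hills as attribute `"hills"`
#' @export
simulate_solvent_trap <- function(model, restraint_on = TRUE,
                                  params = wt_params(), nsteps = 1e6,
                                  dt = 0.001, seed = 1, out_stride = 100) {
  stopifnot(inherits(model, "solvent_trap_model"))
  metad_on <- !is.null(params)
  if (!metad_on) params <- wt_params()
  z_init <- .solvent_trap_init(model, restraint_on, include_ligand = TRUE)
  r <- model$restraint
  res <- engine_solvent_trap(model$eps_L, model$eps_W, model$z_site, model$w_site,
                             model$eps_R, model$L_res, model$L_chan,
                             model$A_rep, model$d_rep,
                             model$z_virtual, r$k_s, r$S_0, r$n, r$m, r$r_0,
                             restraint_on, TRUE, metad_on,
                             params$W0, params$sigma1, params$stride, params$gamma,
                             model$mass, model$friction, model$T,
                             z_init, as.integer(nsteps), dt,
                             as.integer(out_stride), as.numeric(seed), 1.195e5)
  traj <- structure(list(times = res$times, cv1 = res$cv1, S = res$S,
                         V_S = res$V_S, seed = seed, dt_out = dt * out_stride,
                         model = "solvent_trap"),
                    class = "fmd_trajectory")
  attr(traj, "hills") <- list(times = res$hill_times, centers = res$hill_cv1,
                              heights = res$hill_heights)
  attr(traj, "restraint_on") <- restraint_on
  traj
}

# initial coordinates: ligand unbound; solvent in the site unless the dry
# state is being imposed, in which case it starts in the reservoir
.solvent_trap_init <- function(model, restraint_on, include_ligand) {
  M <- model$M
  sol <- if (M == 0) numeric(0)
         else if (restraint_on) -0.35 - model$d_rep * (seq_len(M) - 1)
         else model$z_site - 0.1 + model$d_rep * (seq_len(M) - 1)
  if (include_ligand) c(1.5, sol) else sol
}

#' Restraint-energy series from an unrestrained host simulation
#'
#' Simulates the solvent-trap model without the ligand and without the
#' restraint (the unrestrained "free host" ensemble) and records the
#' restraint energy V(S) that the dry-state wall *would* have contributed.
#' This is the input ensemble of the one-step FEP estimator
#' [delta_g_restr()]. The fraction of frames with V(S) = 0 (the dry-state
#' fraction) is attached as attribute `"dry_fraction"`.
#'
#' @param model a [solvent_trap_model()]
#' @param nsteps,dt,seed,out_stride as in [simulate_wtmetad()]
#' @return a `restraint_series` object (see [restraint_series()])
#' @export
unbiased_restraint_series <- function(model, nsteps = 1e6, dt = 0.001,
                                      seed = 1, out_stride = 10) {
  stopifnot(inherits(model, "solvent_trap_model"))
  z_init <- .solvent_trap_init(model, restraint_on = FALSE, include_ligand = FALSE)
  r <- model$restraint
  p <- wt_params()
  res <- engine_solvent_trap(model$eps_L, model$eps_W, model$z_site, model$w_site,
                             model$eps_R, model$L_res, model$L_chan,
                             model$A_rep, model$d_rep,
                             model$z_virtual, r$k_s, r$S_0, r$n, r$m, r$r_0,
                             FALSE, FALSE, FALSE,
                             p$W0, p$sigma1, p$stride, p$gamma,
                             model$mass, model$friction, model$T,
                             z_init, as.integer(nsteps), dt,
                             as.integer(out_stride), as.numeric(seed), 1.195e5)
  out <- restraint_series(res$times, res$V_S)
  out$S <- res$S
  out$seed <- seed
  attr(out, "dry_fraction") <- mean(res$V_S == 0)
  out
}

#' Restraint-energy time series
#'
#' Container for a V(S) time series sampled on a uniform time grid, the
#' input of the one-step FEP estimator [delta_g_restr()].
#'
#' @param times sample times (ps), uniformly spaced
#' @param V_S restraint energies (kcal/mol), non-negative
#' @return an object of class `restraint_series` with fields `times`, `V_S`
#'   and `dt_out` (the output stride in ps)
#' @export
restraint_series <- function(times, V_S) {
  times <- as.numeric(times); V_S <- as.numeric(V_S)
  if (length(times) != length(V_S)) stop("times and V_S must have equal length")
  if (length(times) < 2L) stop("a restraint series needs at least two samples")
  dts <- diff(times)
  if (any(abs(dts - dts[1]) > 1e-9 * max(abs(dts[1]), 1)))
    stop("times must be uniformly spaced")
  if (any(V_S < -1e-12)) stop("V_S must be non-negative")
  structure(list(times = times, V_S = pmax(V_S, 0), dt_out = dts[1]),
            class = "restraint_series")
}

#' @export
print.restraint_series <- function(x, ...) {
  cat(sprintf("Restraint series: %d samples, stride %g ps, mean V(S) = %.4g kcal/mol\n",
              length(x$times), x$dt_out, mean(x$V_S)))
  invisible(x)
}

#' Count visits to the bound state
#'
#' Counts entries into the bound state using a hysteretic (Schmitt-trigger)
#' pair of thresholds: an entry is registered when the ligand coordinate
#' drops below `bound` after last having been above `unbound`, which makes
#' the count insensitive to boundary flicker.
#'
#' @param traj an `fmd_trajectory` with a `cv1` field
#' @param bound bound-state threshold on z (nm)
#' @param unbound unbound re-arming threshold on z (nm), `> bound`
#' @return integer number of binding events
#' @export
count_bound_visits <- function(traj, bound = 0.4, unbound = 0.8) {
  stopifnot(unbound > bound)
  z <- traj$cv1
  armed <- z[1] > unbound
  visits <- 0L
  for (i in seq_along(z)) {
    if (armed && z[i] < bound) { visits <- visits + 1L; armed <- FALSE }
    else if (!armed && z[i] > unbound) armed <- TRUE
  }
  visits
}

#' Mechanistic hysteresis signature
#'
#' For an unrestrained solvent-trap trajectory, correlates the success of
#' each binding attempt with the solvent occupancy of the site just before
#' the attempt. An attempt starts when the ligand crosses below `approach`
#' from above; it succeeds if z drops below `bound` within `horizon` ps.
#' Trapped solvent should make occupied-site attempts fail, i.e. the
#' point-biserial correlation between "S >= 1 at attempt" and success should
#' be negative.
#'
#' @param traj an `fmd_trajectory` from [simulate_solvent_trap()]
#' @param approach attempt threshold on z (nm)
#' @param bound bound-state threshold on z (nm)
#' @param horizon look-ahead time (ps)
#' @return list with the per-attempt data frame and the correlation
#'   (`NA` if fewer than 3 attempts or a constant column)
#' @export
hysteresis_signature <- function(traj, approach = 0.7, bound = 0.4,
                                 horizon = 50) {
  z <- traj$cv1; S <- traj$S; t <- traj$times
  cross <- which(z[-1] < approach & z[-length(z)] >= approach) + 1L
  if (length(cross) == 0)
    return(list(attempts = data.frame(), correlation = NA_real_))
  nh <- max(1L, round(horizon / traj$dt_out))
  occupied <- S[cross] >= 1
  success <- vapply(cross, function(i) {
    j <- min(length(z), i + nh)
    any(z[i:j] < bound)
  }, logical(1))
  attempts <- data.frame(time = t[cross], occupied = occupied, success = success)
  corr <- if (nrow(attempts) >= 3 && var(occupied) > 0 && var(success) > 0)
    cor(as.numeric(occupied), as.numeric(success)) else NA_real_
  list(attempts = attempts, correlation = corr)
}
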