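#' Uniform 2D grid specification for FES reconstruction
#'
#' @param z_range,nz range and number of nodes over CV 1 (nm); default 200
#'   nodes over \[0, 2\]
#' @param c_range,nc range and number of nodes over CV 2; default 100 nodes
#'   over \[-1, 1\]
#' @return a list with node vectors `z` and `c`
#' @export
fes_grid <- function(z_range = c(0, 2), nz = 200, c_range = c(-1, 1), nc = 100) {
  if (nz < 2 || nc < 2) stop("grids need at least two nodes per axis")
  list(z = seq(z_range[1], z_range[2], length.out = nz),
       c = seq(c_range[1], c_range[2], length.out = nc))
}

# shared hill-to-grid accumulation; hills added in record order so that
# incremental and one-shot sums agree exactly
.accumulate_bias <- function(V, grid, hills, idx, cutoff) {
  if (length(idx) == 0L) return(V)
  grid_add_hills(V, grid$z, grid$c,
                 hills$centers[idx, 1], hills$centers[idx, 2],
                 hills$widths[idx, 1], hills$widths[idx, 2],
                 hills$heights[idx], cutoff)
}

.check_hills_in_grid <- function(hills, grid) {
  out1 <- hills$centers[, 1] < min(grid$z) | hills$centers[, 1] > max(grid$z)
  out2 <- hills$centers[, 2] < min(grid$c) | hills$centers[, 2] > max(grid$c)
  bad <- which(out1 | out2)
  if (length(bad))
    stop(sprintf("hill %d lies outside the reconstruction grid (center %.4g, %.4g)",
                 bad[1], hills$centers[bad[1], 1], hills$centers[bad[1], 2]))
  invisible(TRUE)
}

# wrap a summed-bias matrix into a free_energy_surface
.fes_from_bias <- function(V, grid, gamma, T, t_window) {
  mult <- if (is.finite(gamma)) gamma / (gamma - 1) else 1
  sampled <- V > 0
  if (!any(sampled)) stop("no grid node carries any bias: empty reconstruction")
  F <- -mult * V
  F <- F - min(F[sampled])
  ceiling_value <- max(F[sampled]) + 5 * kB * T
  F[!sampled] <- ceiling_value
  structure(list(z = grid$z, c = grid$c, F = F, sampled = sampled,
                 ceiling = ceiling_value, T = T, gamma = gamma,
                 t_window = t_window),
            class = "free_energy_surface")
}

#' Reconstruct the free-energy surface from deposited hills
#'
#' Sums the deposited Gaussians up to `t_end` on a uniform grid and applies
#' the well-tempered inversion `F(s) = -gamma/(gamma - 1) V_bias(s)`
#' (multiplier 1 for `gamma = Inf`, i.e. standard metadynamics). Heights are
#' taken as deposited (already scaled by the well-tempered factor at
#' deposition time, the PLUMED-1.x file convention); a pre-scaled-to-unity
#' hills dialect can be handled by passing `gamma = Inf` together with
#' rescaled heights. The surface is shifted so its sampled minimum is zero;
#' nodes that received no bias are set to an explicit ceiling (max sampled
#' value + 5 kB T) and flagged in the `sampled` mask, never left as silent
#' zeros.
#'
#' @param hills a [hills_record()]; must be non-empty, with all centers
#'   inside the grid
#' @param grid a [fes_grid()]
#' @param t_end only hills with deposition time `<= t_end` enter (ps)
#' @param cutoff per-dimension Gaussian cutoff in sigmas; `Inf` disables
#'   truncation (exact mode used by oracle tests); the default 6 bounds the
#'   per-hill truncation error by `height * exp(-18)`
#' @param T temperature used for the ceiling offset (K)
#' @return an object of class `free_energy_surface` with fields `z`, `c`,
#'   `F` (nz x nc matrix, kcal/mol), `sampled`, `ceiling`, `T`, `gamma`,
#'   `t_window`
#' @export
reconstruct_fes <- function(hills, grid = fes_grid(), t_end = Inf,
                            cutoff = 6, T = 298) {
  stopifnot(inherits(hills, "hills_record"))
  if (length(hills$times) == 0L) stop("empty hills record: nothing to reconstruct")
  .check_hills_in_grid(hills, grid)
  idx <- which(hills$times <= t_end)
  if (length(idx) == 0L)
    stop("no hills deposited at or before t_end = ", t_end, " ps")
  V <- matrix(0, length(grid$z), length(grid$c))
  V <- .accumulate_bias(V, grid, hills, idx, cutoff)
  .fes_from_bias(V, grid, hills$gamma, T, t_window = c(0, t_end))
}

#' Time-window averaged free-energy surface
#'
#' Mean of FES snapshots reconstructed on a uniform schedule of
#' `n_snapshots` times inside `window` (the snapshot-mean convention used
#' for displaying a surface averaged over the late part of a run). The
#' alternative - a single reconstruction at the window end - is
#' [reconstruct_fes()] with `t_end = window[2]`. Snapshots are averaged
#' after the well-tempered inversion but before the zero shift; a node
#' counts as sampled if it is sampled in the first snapshot.
#'
#' @param hills a [hills_record()]
#' @param grid a [fes_grid()]
#' @param window numeric length-2 time window (ps)
#' @param n_snapshots number of snapshots averaged
#' @param cutoff,T as in [reconstruct_fes()]
#' @return a `free_energy_surface`
#' @export
fes_time_average <- function(hills, grid = fes_grid(), window, n_snapshots = 20,
                             cutoff = 6, T = 298) {
  stopifnot(inherits(hills, "hills_record"), length(window) == 2L,
            window[1] < window[2])
  .check_hills_in_grid(hills, grid)
  snaps <- seq(window[1], window[2], length.out = n_snapshots)
  V <- matrix(0, length(grid$z), length(grid$c))
  Vsum <- NULL
  prev <- -Inf
  first_sampled <- NULL
  for (tt in snaps) {
    idx <- which(hills$times > prev & hills$times <= tt)
    V <- .accumulate_bias(V, grid, hills, idx, cutoff)
    prev <- tt
    if (is.null(Vsum)) {
      Vsum <- V
      first_sampled <- V > 0
    } else Vsum <- Vsum + V
  }
  if (!any(first_sampled)) stop("no bias inside the averaging window")
  Vbar <- Vsum / n_snapshots
  fes <- .fes_from_bias(Vbar, grid, hills$gamma, T, t_window = window)
  # sampled status is defined by the first snapshot (conservative)
  fes$sampled <- first_sampled
  fes$F[!first_sampled] <- fes$ceiling
  fes
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf("Free-energy surface: %d x %d grid, %.1f%% sampled, gamma = %g\n",
              length(x$z), length(x$c), 100 * mean(x$sampled), x$gamma))
  cat(sprintf("  ceiling %g kcal/mol, window [%g, %g] ps\n",
              x$ceiling, x$t_window[1], x$t_window[2]))
  invisible(x)
}

#' Project a 2D FES to a 1D potential of mean force
#'
#' Boltzmann projection over CV 2:
#' `w(z) = -kB T log( int dc exp(-F(z, c)/kB T) )` evaluated by the
#' trapezoidal rule over the CV 2 nodes, at temperature `T`. Ceiling-valued
#' (unsampled) nodes enter with their explicit ceiling energy, which gives
#' them negligible Boltzmann weight; a z column with no sampled node at all
#' is set to the ceiling and flagged.
#'
#' The projection satisfies `w(z) <= min_c F(z, c)` up to the additive
#' constant (which is later fixed by [set_reference_level()]).
#'
#' @param fes a `free_energy_surface`
#' @param T projection temperature (K); defaults to the surface temperature
#' @return an object of class `pmf` with fields `z`, `w`, `flagged`
#'   (logical: column had no sampled node), `ceiling`, `T`
#' @export
project_pmf <- function(fes, T = fes$T) {
  stopifnot(inherits(fes, "free_energy_surface"))
  kT <- kB * T
  nz <- length(fes$z)
  w <- numeric(nz)
  flagged <- logical(nz)
  for (i in seq_len(nz)) {
    if (!any(fes$sampled[i, ])) {
      w[i] <- fes$ceiling
      flagged[i] <- TRUE
      next
    }
    f <- fes$F[i, ]
    f0 <- min(f)
    w[i] <- f0 - kT * log(.trapz(fes$c, exp(-(f - f0) / kT)))
  }
  structure(list(z = fes$z, w = w, flagged = flagged, ceiling = fes$ceiling,
                 T = T),
            class = "pmf")
}

#' @export
print.pmf <- function(x, ...) {
  cat(sprintf("PMF over CV 1: %d nodes on [%g, %g] nm%s\n",
              length(x$z), min(x$z), max(x$z),
              if (isTRUE(attr(x, "referenced"))) ", referenced" else ""))
  if (any(x$flagged))
    cat(sprintf("  %d unsampled column(s) at ceiling\n", sum(x$flagged)))
  invisible(x)
}

#' Set the unbound reference level of a PMF
#'
#' Shifts the PMF so that its unweighted mean over the grid nodes inside
#' `ref_range` (endpoints inclusive) is zero, fixing the additive constant
#' to the unbound plateau, `w(z*) = 0`. Idempotent. The operation errors if
#' the reference range contains no node or an unsampled (ceiling) node.
#'
#' @param pmf a `pmf` from [project_pmf()]
#' @param ref_range numeric length-2 reference window on z (nm)
#' @return the referenced `pmf` (attribute `"referenced"` set)
#' @export
set_reference_level <- function(pmf, ref_range = c(1.4, 1.8)) {
  stopifnot(inherits(pmf, "pmf"), length(ref_range) == 2L)
  sel <- pmf$z >= ref_range[1] & pmf$z <= ref_range[2]
  if (!any(sel)) stop("reference range contains no grid node")
  if (any(pmf$flagged[sel]))
    stop("reference range contains unsampled nodes: cannot set the unbound level")
  pmf$w <- pmf$w - mean(pmf$w[sel])
  attr(pmf, "referenced") <- TRUE
  attr(pmf, "ref_range") <- ref_range
  pmf
}

#' Construct a PMF object directly from values
#'
#' Convenience constructor for analytic or externally supplied PMFs (e.g. a
#' flat or square-well profile used as a closed-form check, or a profile
#' read from a text table).
#'
#' @param z grid nodes (nm), sorted increasing (uniform spacing not required)
#' @param w free-energy values (kcal/mol)
#' @param T temperature (K)
#' @param referenced logical: is the additive constant already fixed to the
#'   unbound plateau?
#' @return a `pmf` object
#' @export
pmf_profile <- function(z, w, T = 298, referenced = FALSE) {
  z <- as.numeric(z); w <- as.numeric(w)
  if (length(z) != length(w)) stop("z and w must have equal length")
  if (is.unsorted(z, strictly = TRUE)) stop("z must be strictly increasing")
  out <- structure(list(z = z, w = w, flagged = rep(FALSE, length(z)),
                        ceiling = Inf, T = T),
                   class = "pmf")
  if (referenced) attr(out, "referenced") <- TRUE
  out
}
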