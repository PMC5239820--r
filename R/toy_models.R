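#' Two-dimensional toy binding model
#'
#' An analytic background potential U(z, c) over the two collective
#' variables (CV 1 = z in nm, CV 2 = c in \[-1, 1\]) on which the Langevin
#' engine runs. Two presets are provided:
#'
#' * `"double_well"`: a quartic double well in z with a linear tilt plus a
#'   harmonic term in c,
#'   `U = h ((q^2 - 1)^2) + tilt (z - z0) + kc c^2` with `q = (z - z0)/w`.
#'   Defaults (`h = 4, z0 = 1, w = 0.5, tilt = 2, kc = 1`) place wells near
#'   z = 0.5 and 1.5 nm separated by a ~5 kcal/mol barrier with a
#'   free-energy difference of about 2 kcal/mol (the exact value is always
#'   obtained by quadrature, see [toy_delta_f()]).
#' * `"binding"`: a single orientation-dependent binding funnel,
#'   `U = -eps exp(-(z - zb)^2/(2 wz^2)) (1 - c)/2`, deepest (6 kcal/mol by
#'   default) at (z = 0.5 nm, c = -1), emulating a bound pose aligned with
#'   the host axis.
#'
#' The free-energy profile of every preset is computable by quadrature,
#' which is what makes these models usable as parameter-recovery oracles.
#'
#' @param preset `"double_well"` or `"binding"`
#' @param params named list overriding individual preset parameters
#' @param mass reduced mass (consistent toy units: kcal/mol ps^2 nm^-2)
#' @param friction Langevin friction (1/ps)
#' @param T temperature (K)
#' @return an object of class `toy_binding_model`
#' @export
toy_binding_model <- function(preset = c("double_well", "binding"),
                              params = list(), mass = 1, friction = 2, T = 298) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    double_well = list(h = 4, z0 = 1, w = 0.5, tilt = 2, kc = 1),
    binding     = list(eps = 6, zb = 0.5, wz = 0.15))
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameters for preset '", preset, "': ",
         paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  p <- vapply(defaults, as.numeric, numeric(1))
  structure(list(preset = preset,
                 preset_id = match(preset, c("double_well", "binding")) - 1L,
                 params = p, mass = mass, friction = friction, T = T),
            class = "toy_binding_model")
}

#' @export
print.toy_binding_model <- function(x, ...) {
  cat(sprintf("Toy binding model '%s' (mass %g, friction %g /ps, T %g K)\n",
              x$preset, x$mass, x$friction, x$T))
  cat("  ", paste(sprintf("%s = %g", names(x$params), x$params), collapse = ", "),
      "\n")
  invisible(x)
}

#' Background potential of a toy model
#'
#' Evaluates U(z, c) of a [toy_binding_model()], delegating to the same
#' compiled routine the Langevin engine integrates, so that quadrature
#' oracles and dynamics share one definition of the potential.
#'
#' @param model a [toy_binding_model()]
#' @param z,c coordinates (recycled to a common length)
#' @param walls optional wall list as produced by [toy_walls()]; when given,
#'   the quartic z-walls the engine applies are added, which is what any
#'   free-energy truth must include
#' @return potential energy (kcal/mol)
#' @export
toy_potential <- function(model, z, c, walls = NULL) {
  stopifnot(inherits(model, "toy_binding_model"))
  n <- max(length(z), length(c))
  z <- rep_len(as.numeric(z), n); c <- rep_len(as.numeric(c), n)
  u <- preset_u(model$preset_id, unname(model$params), z, c)
  if (!is.null(walls)) {
    u <- u + ifelse(z > walls$z_wall, walls$k_wall * (z - walls$z_wall)^4, 0)
    u <- u + ifelse(z < walls$z_lo, walls$k_lo * (walls$z_lo - z)^4, 0)
  }
  u
}

#' Wall settings applied to the toy z coordinate
#'
#' For the 2D collective-variable toy the funnel reduces to flat-bottom
#' walls on z alone: the geometry's axial wall above `z_wall` and a lower
#' quartic wall keeping z out of the unphysical region below `z_lo`. The
#' funnel cross-section enters only through the `S_star` bookkeeping of
#' [binding_config()].
#'
#' The lower wall is much stiffer than the axial wall: it stands in for the
#' hard repulsive bottom of the cavity, which must stay effectively
#' impenetrable even under the gamma-fold flattening of the sampled
#' landscape in well-tempered metadynamics.
#'
#' @param geom a [funnel_geometry()]
#' @param z_lo onset of the lower wall (nm)
#' @param k_lo lower wall force constant (kcal mol-1 nm-4)
#' @return a list with `z_wall`, `k_wall`, `z_lo`, `k_lo`
#' @export
toy_walls <- function(geom = funnel_geometry(), z_lo = 0.05,
                      k_lo = 100 * geom$k_wall) {
  list(z_wall = geom$z_wall, k_wall = geom$k_wall, z_lo = z_lo, k_lo = k_lo)
}

#' Quadrature free-energy profile of a toy model
#'
#' F(z) = -kB T log integral over c in \[-1, 1\] of exp(-U(z, c)/kB T),
#' computed by the trapezoidal rule on `nc` nodes. This is the exact
#' (up to quadrature error) profile against which metadynamics
#' reconstructions are validated.
#'
#' @param model a [toy_binding_model()]
#' @param z vector of axial positions (nm)
#' @param walls optional wall list ([toy_walls()]) to include
#' @param nc number of quadrature nodes over c
#' @return free energy F(z) (kcal/mol), same length as `z`
#' @export
toy_free_energy_profile <- function(model, z, walls = NULL, nc = 401) {
  kT <- kB * model$T
  cg <- seq(-1, 1, length.out = nc)
  vapply(z, function(zz) {
    u <- toy_potential(model, zz, cg, walls)
    u0 <- min(u)
    u0 - kT * log(.trapz(cg, exp(-(u - u0) / kT)))
  }, numeric(1))
}

#' Quadrature free-energy difference between two basins
#'
#' The Boltzmann free-energy difference
#' `dF = F(z < divider) - F(z > divider)
#'     = -kB T log( I(z < divider) / I(z > divider) )`,
#' where I are configurational integrals of exp(-U/kB T) over the 2D
#' (z, c) space including the engine's z-walls. Used as the ground truth in
#' parameter-recovery tests; the identical functional applied to a
#' reconstructed PMF is [pmf_delta_f()].
#'
#' @param model a [toy_binding_model()]
#' @param divider basin boundary on z (nm)
#' @param walls wall list ([toy_walls()]); included by default since the
#'   engine always applies them
#' @param z_range integration range on z (nm)
#' @param nz,nc quadrature nodes
#' @return free-energy difference (kcal/mol), left minus right basin
#' @export
toy_delta_f <- function(model, divider = 1.0, walls = toy_walls(),
                        z_range = c(-0.1, 2.1), nz = 2001, nc = 201) {
  kT <- kB * model$T
  zg <- seq(z_range[1], z_range[2], length.out = nz)
  cg <- seq(-1, 1, length.out = nc)
  # Boltzmann integral per z column, trapezoid over c
  col <- vapply(zg, function(zz) {
    u <- toy_potential(model, zz, cg, walls)
    .trapz(cg, exp(-u / kT))
  }, numeric(1))
  left <- zg <= divider
  -kT * log(.trapz(zg[left], col[left]) / .trapz(zg[!left], col[!left]))
}

#' Free-energy difference between basins of a 1D PMF
#'
#' Same functional as [toy_delta_f()] applied to a gridded potential of mean
#' force: `-kB T log( int_{z<divider} e^{-w/kBT} / int_{z>divider} )`.
#' Invariant under adding a constant to w, so it needs no reference level.
#'
#' @param pmf a `pmf` object ([project_pmf()])
#' @param divider basin boundary (nm)
#' @return free-energy difference (kcal/mol)
#' @export
pmf_delta_f <- function(pmf, divider = 1.0) {
  stopifnot(inherits(pmf, "pmf"))
  kT <- kB * pmf$T
  w <- pmf$w - min(pmf$w)   # guard exp underflow; the ratio is shift-invariant
  b <- exp(-w / kT)
  left <- pmf$z <= divider
  if (sum(left) < 2 || sum(!left) < 2)
    stop("divider leaves fewer than two grid nodes in a basin")
  -kT * log(.trapz(pmf$z[left], b[left]) / .trapz(pmf$z[!left], b[!left]))
}

#' One-dimensional solvent-trap model
#'
#' A minimal mechanistic analogue of solvent molecules trapped in a binding
#' cavity: a ligand and `M` solvent particles move in a 1D channel. A
#' Gaussian site well at `z_site` attracts the ligand (depth `eps_L`) and
#' the solvent (depth `eps_W`); solvent can retreat into a reservoir behind
#' the site (down to `-L_res`) at a confinement cost `eps_R`, while the
#' ligand is confined to \[0, `L_chan`\]. A truncated `A (d/|dz|)^12` pair
#' repulsion prevents particles from crossing, so solvent sitting in the
#' site blocks the ligand's entry, and displacing it into the penalized
#' reservoir is thermally activated - the hysteresis mechanism. The coordination number S of
#' the solvent around a virtual atom at `z_virtual` feeds the dry-state
#' restraint of [coordination_restraint()].
#'
#' With `eps_W > 0` and `M >= 1` the unbiased stationary distribution puts
#' solvent in the site whenever the ligand is out, which is the precondition
#' for the trapped-solvent hysteresis.
#'
#' @param M number of solvent particles
#' @param eps_L,eps_W site well depths for ligand and solvent (kcal/mol)
#' @param z_site,w_site site well center and Gaussian width (nm)
#' @param eps_R reservoir confinement penalty for solvent (kcal/mol)
#' @param L_res reservoir extent behind the site (nm)
#' @param L_chan channel length (nm)
#' @param A_rep,d_rep pair repulsion amplitude (kcal/mol) and contact
#'   distance (nm)
#' @param z_virtual virtual-atom position for the coordination number (nm)
#' @param restraint a [coordination_restraint()]
#' @param mass,friction,T Langevin parameters as in [toy_binding_model()]
#' @return an object of class `solvent_trap_model`
#' @export
solvent_trap_model <- function(M = 2, eps_L = 5, eps_W = 3,
                               z_site = 0.2, w_site = 0.12,
                               eps_R = 1.5, L_res = 0.8, L_chan = 2.0,
                               A_rep = 0.2, d_rep = 0.25,
                               z_virtual = 0.2,
                               restraint = coordination_restraint(),
                               mass = 1, friction = 5, T = 298) {
  stopifnot(inherits(restraint, "coordination_restraint"))
  if (M != round(M) || M < 0) stop("M must be a non-negative integer")
  structure(list(M = as.integer(M), eps_L = eps_L, eps_W = eps_W,
                 z_site = z_site, w_site = w_site, eps_R = eps_R, L_res = L_res,
                 L_chan = L_chan, A_rep = A_rep, d_rep = d_rep,
                 z_virtual = z_virtual, restraint = restraint,
                 mass = mass, friction = friction, T = T),
            class = "solvent_trap_model")
}

#' @export
print.solvent_trap_model <- function(x, ...) {
  cat(sprintf(
    "Solvent-trap model: %d solvent particle(s), eps_L = %g, eps_W = %g kcal/mol\n",
    x$M, x$eps_L, x$eps_W))
  cat(sprintf("  site at %g nm (width %g), reservoir to %g nm, channel to %g nm\n",
              x$z_site, x$w_site, -x$L_res, x$L_chan))
  invisible(x)
}
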