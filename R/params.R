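#' Funnel restraint geometry
#'
#' Parameters of the cone-plus-cylinder funnel restraint and of the steep
#' axial wall. The funnel confines the unbound guest to a cylinder of radius
#' `R_cyl` along the host axis for `z >= z_cc`, and opens as a cone of
#' half-angle `alpha` below `z_cc`. The quartic wall acts above `z_wall` to
#' keep the guest away from periodic images.
#'
#' Defaults are the values used throughout the package's host-guest setup:
#' `z_cc = 1.0` nm, `R_cyl = 0.2` nm, `alpha = 45` degrees,
#' `kappa = 478` kcal mol-1 nm-2, `z_wall = 1.85` nm (the wall onset varies
#' slightly with guest size in practice, so it is configurable) and
#' `k_wall = 1.195e5` kcal mol-1 nm-4.
#'
#' @param z_cc axial switch point between cone and cylinder (nm)
#' @param R_cyl cylinder radius (nm)
#' @param alpha cone half-angle (degrees), in (0, 90)
#' @param kappa funnel force constant (kcal mol-1 nm-2)
#' @param z_wall onset of the axial quartic wall (nm), must exceed `z_cc`
#' @param k_wall wall force constant (kcal mol-1 nm-4)
#' @return an object of class `funnel_geometry`
#' @seealso [funnel_radius()], [funnel_energy()], [wall_energy()]
#' @export
funnel_geometry <- function(z_cc = 1.0, R_cyl = 0.2, alpha = 45,
                            kappa = 478, z_wall = 1.85, k_wall = 1.195e5) {
  for (nm in c("z_cc", "R_cyl", "alpha", "kappa", "z_wall", "k_wall"))
    .stopifnot_scalar(get(nm), nm)
  if (z_cc <= 0) stop("z_cc must be positive")
  if (R_cyl <= 0) stop("R_cyl must be positive")
  if (alpha <= 0 || alpha >= 90) stop("alpha must lie strictly between 0 and 90 degrees")
  if (kappa <= 0) stop("kappa must be positive")
  if (k_wall <= 0) stop("k_wall must be positive")
  if (z_wall <= z_cc) stop("z_wall must exceed z_cc")
  structure(list(z_cc = z_cc, R_cyl = R_cyl, alpha = alpha, kappa = kappa,
                 z_wall = z_wall, k_wall = k_wall),
            class = "funnel_geometry")
}

#' Water coordination-number restraint parameters
#'
#' The dry-state restraint is a quartic wall on a generalized water
#' coordination number S of a virtual atom in the binding cavity:
#' `V(S) = k_s (S - S_0)^4` for `S >= S_0`, zero otherwise, with
#' `S = sum_i (1 - (r_iv/r_0)^n) / (1 - (r_iv/r_0)^m)` summed over solvent
#' molecules. The steep switching exponents make the restraint act only on
#' molecules immediately trying to enter the cavity.
#'
#' @param k_s force constant (kcal/mol); default 2.39e5
#' @param S_0 coordination threshold (dimensionless); default 0.02
#' @param n,m switching exponents, integers with `m > n > 0`; defaults 16, 32
#' @param r_0 switching radius (nm); default 0.35
#' @return an object of class `coordination_restraint`
#' @seealso [coordination_number()], [coordination_restraint_energy()]
#' @export
coordination_restraint <- function(k_s = 2.39e5, S_0 = 0.02, n = 16L, m = 32L,
                                   r_0 = 0.35) {
  for (nm in c("k_s", "S_0", "n", "m", "r_0")) .stopifnot_scalar(get(nm), nm)
  if (n != round(n) || m != round(m)) stop("n and m must be integers")
  if (!(m > n && n > 0)) stop("switching exponents must satisfy m > n > 0")
  if (r_0 <= 0) stop("r_0 must be positive")
  if (k_s <= 0) stop("k_s must be positive")
  if (S_0 < 0) stop("S_0 must be non-negative")
  structure(list(k_s = k_s, S_0 = S_0, n = as.integer(n), m = as.integer(m),
                 r_0 = r_0),
            class = "coordination_restraint")
}

#' Well-tempered metadynamics deposition parameters
#'
#' Hill deposition settings for well-tempered metadynamics in the
#' two-dimensional collective-variable space (CV 1 = axial projection z in
#' nm, CV 2 = cosine of the orientation angle, dimensionless). The deposited
#' height decays with the accumulated bias as
#' `W = W0 exp(-V / (kB * (gamma - 1) * T))`.
#'
#' Defaults: initial height 0.1195 kcal/mol, widths 0.04 nm and 0.043,
#' stride 1.0 ps, bias factor 20, temperature 298 K.
#'
#' @param W0 initial hill height (kcal/mol)
#' @param sigma1 Gaussian width along CV 1 (nm)
#' @param sigma2 Gaussian width along CV 2 (dimensionless)
#' @param stride deposition interval (ps)
#' @param gamma bias factor (> 1; `Inf` gives standard metadynamics heights)
#' @param T temperature (K)
#' @return an object of class `wt_params`
#' @seealso [wt_hill_height()], [simulate_wtmetad()]
#' @export
wt_params <- function(W0 = 0.1195, sigma1 = 0.04, sigma2 = 0.043,
                      stride = 1.0, gamma = 20, T = 298) {
  for (nm in c("W0", "sigma1", "sigma2", "stride", "T"))
    .stopifnot_scalar(get(nm), nm)
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma))
    stop("'gamma' must be a numeric scalar")
  if (gamma <= 1) stop("bias factor gamma must exceed 1")
  if (W0 <= 0) stop("W0 must be positive")
  if (sigma1 <= 0 || sigma2 <= 0) stop("Gaussian widths must be positive")
  if (stride <= 0) stop("stride must be positive")
  if (T <= 0) stop("T must be positive")
  structure(list(W0 = W0, sigma1 = sigma1, sigma2 = sigma2, stride = stride,
                 gamma = gamma, T = T),
            class = "wt_params")
}

#' Standard-state binding configuration
#'
#' Conventions used to turn a referenced potential of mean force w(z) into a
#' standard-state binding free energy: the standard concentration
#' `C0 = 1/1.66` nm-3 (1 M), the effective cross-section `S_star = pi R_cyl^2`
#' swept by the axially restrained unbound ligand, the binding-site boundary
#' on z (site is `z < site_max`, default 0.9 nm), the reference range over
#' which the unbound plateau of the PMF is averaged (default 1.4-1.8 nm) and
#' the free energy `dG_a_site` of restraining the bound ligand on the axis
#' (zero for a funnel that does not touch the bound state).
#'
#' @param C0 standard concentration (nm-3)
#' @param S_star effective cross-section (nm2); default `pi * 0.2^2`
#' @param site_max site boundary on z (nm)
#' @param ref_range numeric length-2, reference window on z (nm)
#' @param dG_a_site axial-restraint free energy of the bound ligand (kcal/mol)
#' @param T temperature (K)
#' @return an object of class `binding_config`
#' @seealso [delta_g_meta()], [set_reference_level()]
#' @export
binding_config <- function(C0 = 1 / 1.66, S_star = pi * 0.2^2, site_max = 0.9,
                           ref_range = c(1.4, 1.8), dG_a_site = 0, T = 298) {
  for (nm in c("C0", "S_star", "site_max", "dG_a_site", "T"))
    .stopifnot_scalar(get(nm), nm)
  if (!is.numeric(ref_range) || length(ref_range) != 2L || ref_range[1] >= ref_range[2])
    stop("ref_range must be an increasing numeric pair")
  if (S_star <= 0) stop("S_star must be positive")
  if (C0 <= 0) stop("C0 must be positive")
  if (site_max >= ref_range[1])
    stop("site_max must lie below the reference range")
  structure(list(C0 = C0, S_star = S_star, site_max = site_max,
                 ref_range = ref_range, dG_a_site = dG_a_site, T = T),
            class = "binding_config")
}

#' @export
print.funnel_geometry <- function(x, ...) {
  cat("Funnel restraint geometry\n")
  cat(sprintf("  cone -> cylinder at z_cc = %g nm, R_cyl = %g nm, alpha = %g deg\n",
              x$z_cc, x$R_cyl, x$alpha))
  cat(sprintf("  kappa = %g kcal/mol/nm^2; wall: onset %g nm, k = %g kcal/mol/nm^4\n",
              x$kappa, x$z_wall, x$k_wall))
  invisible(x)
}

#' @export
print.wt_params <- function(x, ...) {
  cat(sprintf("Well-tempered deposition: W0 = %g kcal/mol, sigma = (%g nm, %g),\n",
              x$W0, x$sigma1, x$sigma2))
  cat(sprintf("  stride = %g ps, bias factor = %g, T = %g K\n",
              x$stride, x$gamma, x$T))
  invisible(x)
}

#' @export
print.coordination_restraint <- function(x, ...) {
  cat(sprintf("Coordination restraint: k_s = %g kcal/mol, S_0 = %g, n/m = %d/%d, r_0 = %g nm\n",
              x$k_s, x$S_0, x$n, x$m, x$r_0))
  invisible(x)
}

#' @export
print.binding_config <- function(x, ...) {
  cat(sprintf("Binding config: C0 = %g nm^-3, S* = %g nm^2, site z < %g nm,\n",
              x$C0, x$S_star, x$site_max))
  cat(sprintf("  reference range %g-%g nm, dG_a_site = %g kcal/mol, T = %g K\n",
              x$ref_range[1], x$ref_range[2], x$dG_a_site, x$T))
  invisible(x)
}
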