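#' Funnel radius at a given axial position
#'
#' Radius of the funnel restraint: a cone of half-angle `alpha` below the
#' switch point `z_cc`, `R_f(z) = R_cyl + (z_cc - z) tan(alpha)`, joining a
#' cylinder of constant radius `R_cyl` above it. The join is sharp but
#' continuous.
#'
#' @param z axial position(s) (nm); vectorized
#' @param geom a [funnel_geometry()]
#' @return funnel radius (nm), same length as `z`
#' @examples
#' funnel_radius(1.5, funnel_geometry())  # cylinder region: 0.2 nm
#' funnel_radius(0.5, funnel_geometry())  # cone region: 0.7 nm
#' @export
funnel_radius <- function(z, geom = funnel_geometry()) {
  stopifnot(inherits(geom, "funnel_geometry"))
  tana <- tan(geom$alpha * pi / 180)
  ifelse(z < geom$z_cc, geom$R_cyl + (geom$z_cc - z) * tana, geom$R_cyl)
}

#' Funnel restraint energy
#'
#' Flat-bottom quadratic restraint on the radial distance r from the host
#' axis: zero inside the funnel, `kappa (r - R_f(z))^2` outside. Continuous
#' and once-differentiable at the funnel surface.
#'
#' @param r radial distance(s) from the axis (nm), non-negative
#' @param z axial position(s) (nm)
#' @param geom a [funnel_geometry()]
#' @return restraint energy (kcal/mol)
#' @export
funnel_energy <- function(r, z, geom = funnel_geometry()) {
  if (any(r < 0)) stop("radial distance r must be non-negative")
  rf <- funnel_radius(z, geom)
  ifelse(r > rf, geom$kappa * (r - rf)^2, 0)
}

#' Axial wall energy
#'
#' Steep repulsive quartic wall on the axial coordinate,
#' `k_wall (z - z_wall)^4` for `z > z_wall`, zero below, preventing the
#' unbound guest from drifting away from the host.
#'
#' @param z axial position(s) (nm)
#' @param geom a [funnel_geometry()]
#' @return wall energy (kcal/mol)
#' @export
wall_energy <- function(z, geom = funnel_geometry()) {
  ifelse(z > geom$z_wall, geom$k_wall * (z - geom$z_wall)^4, 0)
}

#' Generalized water coordination number
#'
#' `S = sum_i (1 - (r_i/r_0)^n) / (1 - (r_i/r_0)^m)` over the supplied
#' solvent-to-virtual-atom distances. Each term lies in (0, 1], tends to 1 as
#' r tends to 0 and to 0 at large r; the removable singularity at r = r_0
#' is evaluated explicitly as its limit `n/m`.
#'
#' @param distances numeric vector of distances (nm), non-negative; may be
#'   empty (S = 0)
#' @param restr a [coordination_restraint()]
#' @return the coordination number S (dimensionless scalar)
#' @examples
#' coordination_number(0.35, coordination_restraint())  # exactly n/m = 0.5
#' @export
coordination_number <- function(distances, restr = coordination_restraint()) {
  stopifnot(inherits(restr, "coordination_restraint"))
  if (length(distances) == 0L) return(0)
  if (any(distances < 0)) stop("distances must be non-negative")
  x <- distances / restr$r_0
  n <- restr$n; m <- restr$m
  term <- numeric(length(x))
  at_r0 <- abs(x - 1) < 1e-12
  term[at_r0] <- n / m
  small <- !at_r0 & x < 1e-12
  term[small] <- 1
  rest <- !at_r0 & !small
  if (any(rest)) {
    lx <- log(x[rest])
    # (1 - x^n)/(1 - x^m) via expm1 for numerical stability near x = 1
    term[rest] <- expm1(n * lx) / expm1(m * lx)
  }
  sum(term)
}

#' Water-restraint energy
#'
#' Quartic wall on the coordination number: `k_s (S - S_0)^4` for
#' `S >= S_0`, zero below. This is the dry-state restraint energy V(S) whose
#' free-energy cost is later recovered by one-step FEP ([delta_g_restr()]).
#'
#' @param S coordination number(s), non-negative
#' @param restr a [coordination_restraint()]
#' @return restraint energy (kcal/mol)
#' @export
coordination_restraint_energy <- function(S, restr = coordination_restraint()) {
  if (any(S < 0)) stop("S must be non-negative")
  ifelse(S >= restr$S_0, restr$k_s * (S - restr$S_0)^4, 0)
}

#' Well-tempered hill height
#'
#' Height of the next Gaussian hill under the well-tempered deposition rule,
#' `W = W0 exp(-V / (kB (gamma - 1) T))`, where V is the bias already
#' accumulated at the deposition point. `gamma = Inf` recovers standard
#' metadynamics (constant height W0).
#'
#' @param V_current accumulated bias at the deposition point (kcal/mol)
#' @param params a [wt_params()]
#' @return hill height (kcal/mol), in (0, W0]
#' @export
wt_hill_height <- function(V_current, params = wt_params()) {
  stopifnot(inherits(params, "wt_params"))
  if (!is.finite(params$gamma)) return(rep_len(params$W0, length(V_current)))
  dT <- (params$gamma - 1) * params$T
  params$W0 * exp(-V_current / (kB * dT))
}

#' Deposited-hill record
#'
#' Container for the Gaussian hills deposited during a (well-tempered)
#' metadynamics run in the two-dimensional collective-variable space.
#'
#' @param times deposition times (ps), strictly increasing
#' @param centers n x 2 matrix of hill centers (CV 1 in nm, CV 2
#'   dimensionless)
#' @param widths Gaussian widths; either a length-2 vector (shared by all
#'   hills) or an n x 2 matrix
#' @param heights deposited heights (kcal/mol), positive
#' @param gamma bias factor used during deposition (may be `Inf`)
#' @return an object of class `hills_record`
#' @seealso [bias_energy()], [reconstruct_fes()], [read_hills()]
#' @export
hills_record <- function(times, centers, widths, heights, gamma = 20) {
  times <- as.numeric(times)
  centers <- matrix(as.numeric(centers), ncol = 2)
  if (is.null(dim(widths)) && length(widths) == 2L)
    widths <- matrix(rep(as.numeric(widths), each = length(times)), ncol = 2)
  widths <- matrix(as.numeric(widths), ncol = 2)
  heights <- as.numeric(heights)
  n <- length(times)
  if (nrow(centers) != n || nrow(widths) != n || length(heights) != n)
    stop("times, centers, widths and heights must describe the same number of hills")
  if (n > 1 && any(diff(times) <= 0))
    stop("hill deposition times must be strictly increasing")
  if (any(!is.finite(heights)) || any(heights <= 0))
    stop("hill heights must be positive and finite")
  if (any(!is.finite(widths)) || any(widths <= 0))
    stop("hill widths must be positive and finite")
  if (!(is.numeric(gamma) && length(gamma) == 1L && gamma > 1))
    stop("gamma must be a scalar > 1 (possibly Inf)")
  structure(list(times = times, centers = centers, widths = widths,
                 heights = heights, gamma = gamma),
            class = "hills_record")
}

#' @export
print.hills_record <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Hills record: %d hills, t = [%g, %g] ps, bias factor %g\n",
              n, if (n) min(x$times) else NA, if (n) max(x$times) else NA,
              x$gamma))
  invisible(x)
}

#' @export
length.hills_record <- function(x) length(x$times)

#' Metadynamics bias energy at a point
#'
#' Sum of the deposited Gaussians with deposition time `<= t`, evaluated at a
#' point of the collective-variable space. With the default `cutoff = Inf`
#' every hill contributes exactly; a finite cutoff (in standard deviations
#' per dimension) zeroes contributions beyond it, bounding the truncation
#' error per hill by `height * exp(-cutoff^2 / 2)` (at the 6-sigma cutoff
#' used for gridded reconstruction this is below `W0 * exp(-18)`).
#'
#' @param point numeric length-2, the (CV 1, CV 2) evaluation point
#' @param hills a [hills_record()]
#' @param t time (ps); hills deposited after `t` are ignored
#' @param cutoff per-dimension cutoff in units of sigma (default `Inf`)
#' @return bias energy (kcal/mol)
#' @export
bias_energy <- function(point, hills, t = Inf, cutoff = Inf) {
  stopifnot(inherits(hills, "hills_record"), length(point) == 2L)
  if (t < 0) stop("t must be non-negative")
  keep <- hills$times <= t
  if (!any(keep)) return(0)
  d1 <- (point[1] - hills$centers[keep, 1]) / hills$widths[keep, 1]
  d2 <- (point[2] - hills$centers[keep, 2]) / hills$widths[keep, 2]
  g <- hills$heights[keep] * exp(-0.5 * (d1^2 + d2^2))
  if (is.finite(cutoff)) g[abs(d1) > cutoff | abs(d2) > cutoff] <- 0
  sum(g)
}
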