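---
title: "Funnel metadynamics binding free energies: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Funnel metadynamics binding free energies: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funmetad)
```

## The problem and the method

Absolute host-guest binding free energies can be computed from the potential
of mean force (PMF) along a binding axis, provided the unbound ligand is
confined to a known volume. Funnel metadynamics achieves this with a
flat-bottom restraint shaped as a cone around the binding site that narrows
into a cylinder of radius $R_\mathrm{cyl}$ along the host symmetry axis:
inside the funnel the restraint energy is zero, outside it grows as
$\kappa\,[r - R_f(z)]^2$, where $R_f(z)$ is the funnel radius at axial
position $z$ (`funnel_radius()`, `funnel_energy()`). Because the restraint
never touches the bound ligand, the bound-state free energy is unperturbed
($\Delta G_a^{site} = 0$), while the unbound ligand explores a tube of known
cross-section $S^* = \pi R_\mathrm{cyl}^2$ - which is exactly what converts
a PMF depth into a standard-state binding free energy:

$$
e^{-\beta \Delta G_{meta}} \;=\;
C^0 S^* e^{\beta \Delta G_a^{site}}
\int_{site} dz\; e^{-\beta\,[w(z) - w(z^*)]},
$$

with $C^0 = 1/1.66\;\mathrm{nm}^{-3}$ the 1 M standard concentration,
the site defined as $z < 0.9$ nm, and the reference level $w(z^*)$ the mean
of the PMF over the unbound plateau $1.4 \le z \le 1.8$ nm
(`binding_config()`, `set_reference_level()`, `delta_g_meta()`).

Sampling along the axis is driven by well-tempered metadynamics in two
collective variables - the axial projection $z$ (CV 1, nm) and the cosine
of the guest-orientation angle (CV 2, dimensionless, bounded to
$[-1, 1]$) - with Gaussian hills of widths 0.04 nm and 0.043 deposited
every 1.0 ps, initial height 0.1195 kcal/mol, and bias factor
$\gamma = 20$; deposited heights decay as
$W = W_0\,e^{-V/(k_B (\gamma - 1) T)}$ (`wt_params()`,
`wt_hill_height()`). The free-energy surface is recovered from the hill sum
by the well-tempered inversion $F = -\tfrac{\gamma}{\gamma-1} V$
(`reconstruct_fes()`) and projected onto $z$ by Boltzmann averaging over
CV 2 at 298 K (`project_pmf()`).

Deep, single-mouth binding cavities add a complication: water trapped in
the site must leave through the same channel the ligand enters, which
creates a kinetic barrier orthogonal to the collective variables and a
hysteresis between binding and unbinding passages. The package implements
the dry-state protocol that removes it: a quartic wall
$V(S) = k_s (S - S_0)^4$ on a generalized water coordination number

$$
S = \sum_i \frac{1 - (r_{iv}/r_0)^n}{1 - (r_{iv}/r_0)^m},
\qquad n = 16,\; m = 32,\; r_0 = 0.35\ \mathrm{nm},
$$

keeps water out of the cavity during metadynamics
(`coordination_restraint()`, `coordination_number()`). The free-energy cost
of this artificial restraint is ligand-independent and is paid back by a
one-step free-energy perturbation over the unrestrained host ensemble,
$\Delta G_{restr} = -k_B T \ln \langle e^{-V(S)/k_B T}\rangle_0$
(`delta_g_restr()`), so that
$\Delta G_{bind} = \Delta G_{meta} + \Delta G_{restr}$ (`combine_dg()`).
The one-step form is adequate only when the dry state is visited
spontaneously in the unrestrained simulation (a few percent of the time is
enough); the estimator refuses series with fewer than ten statistically
independent samples rather than return a meaningless number.

## The toy engine: what it emulates and what it does not

All-atom simulations of real hosts are outside this package's scope.
Instead, a Langevin engine (BAOAB splitting, compiled) runs two model
systems designed so that every analysis stage sees realistic input:

* **2D collective-variable models** (`toy_binding_model()`): the
  coordinates *are* CV 1 and CV 2, moving on an analytic potential
  $U(z, c)$. The `double_well` preset (quartic wells near $z = 0.5$ and
  $1.5$ nm, ~5 kcal/mol barrier, free-energy gap of about 2 kcal/mol) is
  the parameter-recovery workhorse because its free energy is computable by
  quadrature (`toy_delta_f()`); the `binding` preset reproduces the
  qualitative topology of a host-guest surface (single minimum at
  $z \approx 0.5$ nm, $\cos\theta = -1$, 6 kcal/mol deep). On these models
  the funnel reduces to flat-bottom quartic walls on $z$ alone
  (`toy_walls()`); the $S^* = \pi R_\mathrm{cyl}^2$ factor remains a pure
  accounting convention, which is tested analytically rather than
  simulated.
* **the solvent-trap channel** (`solvent_trap_model()`): a ligand and $M$
  solvent particles in one dimension. A Gaussian site well attracts both;
  solvent can retreat into a reservoir behind the site at a confinement
  penalty $\varepsilon_R$; a truncated $A\,(d/|\Delta z|)^{12}$ repulsion
  prevents crossing. Solvent sitting in the site therefore physically
  blocks the ligand, and displacing it is thermally activated - a minimal
  mechanistic analogue of trapped cavity water. The defaults
  ($M = 2$, $\varepsilon_L = 5$, $\varepsilon_W = 3$,
  $\varepsilon_R = 1.5$ kcal/mol) were chosen once, by quadrature on the
  two-solvent configuration integral, so that the unrestrained host is dry
  a few percent of the time and the restraint correction is
  $\sim$2.3 kcal/mol - the regime in which the one-step FEP is the right
  estimator. An exact two-particle quadrature of
  $\langle e^{-V(S)/k_BT}\rangle_0$ serves as the oracle for the FEP tests.

What passing tests on these models demonstrates: the bookkeeping
(well-tempered inversion, projection, referencing, standard-state
conversion, FEP filtering and bootstrap, convergence errors) is correct,
and the dry-state restraint does cure a genuine trapped-solvent hysteresis
(with the restraint the bound state is visited roughly twice as often on
this toy; the separation is decisive over seeds but smaller than for real
hosts, where the solvent barrier is steeper). What it does not demonstrate:
force-field accuracy, water structure, or any property of real octa-acid
complexes - the packaged prediction table carries those published numbers,
and the error-metric stage evaluates them as data.

## Convergence and errors

$\Delta G_{meta}(t)$ is re-evaluated on a uniform schedule by running the
full reconstruction pipeline on the hills up to each time
(`dg_meta_timeseries()`; the incremental bias accumulation is bitwise
identical to a fresh reconstruction, which is asserted in the tests). The
final value is the average over the last window $W$, and its uncertainty is
the **maximum of two numbers**: the standard deviation of the estimates
inside that window, and the absolute difference between the means of the
two last consecutive blocks of length $W$, which accounts for residual
drift (`final_estimate()`). The fluctuation is deliberately an SD, not an
SEM (the conservative reading; a `fluctuation = "sem"` switch is provided).

For the FEP stage the raw $V(S)$ series is thinned by the statistical
inefficiency $g = 1 + 2\sum_t (1 - t/N)\,\hat\rho(t)$, truncated at the
first non-positive autocorrelation (`statistical_inefficiency()`); the
decimation interval is $\lceil g \rceil$ frames and the bootstrap (100
repeats, explicit seed) resamples the thinned set. Both $g$ (frames) and
$g \cdot \Delta t_{out}$ (ps) are reported, since the filtering time is the
physically meaningful quantity.

## Numerical choices

* Units: kcal/mol, nm, ps; $k_B = 0.0019872041$ kcal mol$^{-1}$ K$^{-1}$.
* Gridded reconstruction: 200 x 100 nodes over $[0, 2] \times [-1, 1]$ by
  default; Gaussians truncated at 6 sigma per dimension (per-hill error
  $< W_0 e^{-18}$); `cutoff = Inf` disables truncation for exact oracles.
  Unsampled nodes carry an explicit ceiling (max sampled + $5 k_B T$,
  mirroring the display convention for unsampled regions), never silent
  zeros.
* Hill heights are stored as deposited (already well-tempered-scaled), the
  PLUMED-1.x file convention, so reconstruction multiplies by
  $\gamma/(\gamma-1)$; `gamma = Inf` handles the pre-scaled dialect.
* CV 2 is non-periodic and bounded; the dynamics reflects at $\pm 1$ but
  hills are **not** reflected (the boundary-kernel correction is left off
  by default since the surfaces of interest keep their minima away from the
  boundary).
* The site integral interpolates the Boltzmann factor, not the PMF,
  linearly within bins, with a partial final segment when `site_max` falls
  between nodes; non-uniform grids are accepted, and a discontinuous test
  profile is gridded with nodes on both sides of the jump so the
  piecewise-linear interpolant matches the step closed form.
* The cone-cylinder join of the funnel is sharp
  ($R_f = R_\mathrm{cyl} + (z_{cc} - z)\tan\alpha$ below $z_{cc}$); the
  removable singularity of the switching function at $r = r_0$ is evaluated
  explicitly as $n/m$.
* The engines draw noise from mt19937_64 through an explicit Box-Muller
  transform, so a seed reproduces a trajectory bit for bit across standard
  libraries; every output header records the seed.
* Time-window FES averaging is the mean of FES snapshots on a uniform
  schedule (cosmetic, for surface display); the normative time averaging
  for results is on the $\Delta G_{meta}(t)$ series itself, which is what
  `final_estimate()` consumes.

## Problem sizes used by the shipped studies

The parameter-recovery study runs twenty 12 ns double-well trajectories
(6e6 steps of 2 fs-equivalent, hills every 1 ps) and evaluates
$\Delta F(t)$ every 240 ps with an averaging window of 5.5 ns. The window
is chosen long relative to the run (about 0.46 of it) so that the two error
blocks span most of the trajectory and the block-difference term sees the
decaying well-tempered transient; with short windows the error bars measure
only the late-time fluctuation and understate the run-to-run spread, while
runs much shorter than 12 ns leave a visible transient bias in the
recovered gap (about +0.16 kcal/mol at 3 ns, gone by 12 ns). The
hysteresis study uses five or six paired 1.5 ns channel runs; the
restraint-on runs visit the bound state roughly 1.6-1.9 times as often, and
the paired one-sided Wilcoxon test is significant at $p \approx 0.03$ with
complete separation. The FEP study uses a 4 ns unrestrained host run
(~1600 independent samples after thinning).

## Known limitations

* The toy models share no force field or geometry with real hosts; all
  quantitative agreement with published per-system binding free energies
  enters through the packaged prediction table, not through simulation.
* The flexible-ligand variant of the orientation variable is not
  implemented; CV 2 is the rigid-axis cosine.
* No reweighting estimators are provided; the free energy comes from
  direct bias inversion only, which is the convention the workflow targets.
* The one-step FEP refuses, but cannot repair, ensembles that never visit
  the dry state; multi-window FEP is out of scope.
* The convergence error is a heuristic (max of fluctuation and block
  difference); on the toy it covers the true error in $\ge 90\%$ of seeded
  runs at the shipped problem sizes, but it is not a confidence interval
  with guaranteed coverage.
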