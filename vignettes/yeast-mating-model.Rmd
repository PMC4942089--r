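---
title: "Modelling yeast mating as a stochastic moving-boundary problem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling yeast mating as a stochastic moving-boundary problem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(matesim)
```

# The model

`matesim` simulates the mating of budding yeast cells in two dimensions.
Each haploid cell is a deforming region bounded by its plasma membrane; an
**a**-cell and an alpha-cell sense each other's pheromone (alpha-factor and
**a**-factor respectively), polarise an intracellular signalling circuit
toward the gradient, grow a mating projection (shmoo) in that direction,
and mate when the projection tips meet. The model couples three layers:

1. **Geometry.** Each cell carries its own level-set function
   $\phi(x,t)$ on a shared uniform grid: the membrane is
   $\Gamma=\{\phi=0\}$, the interior $\phi<0$, and the extracellular space
   is the set outside every cell. The membrane moves with normal speed $V$
   by the Hamilton–Jacobi equation $\phi_t + V\,|\nabla\phi| = 0$,
   discretised with a first-order Godunov upwind scheme; $\phi$ is
   periodically rebuilt as an exact signed distance to the extracted
   membrane polyline.

2. **Extracellular fields.** Alpha-factor $f_\alpha$, **a**-factor $f_a$
   and (for Bar1+ **a**-cells) the protease field $B$ obey
   diffusion–decay–source equations on the extracellular nodes with
   no-flux conditions at the outer rectangle and at every membrane:
   $$\partial_t f = D\,\Delta f + S(x,t) - k\,f + \kappa_1 f\,\eta(x,t).$$
   Secretion is a Gaussian shell on the membrane,
   $S = A\exp(-100\phi^2)$ with $A=1000/\sqrt{2\pi}$ (isotropic), or
   $S = A\exp(-100\phi^2 - 20(1-u_2/u_{2,\max})^2)$ once the cell has
   polarised (polarised secretion, the default). Background alpha-factor
   production adds a uniform rate $C$ on all exterior nodes. Bar1
   accelerates alpha-factor decay through
   $k_\alpha + k_{deg}\,B/(\max B + \varepsilon)$.
   Because the fields relax much faster than the membrane moves, the
   default solver replaces explicit stepping by a quasi-steady-state (QSS)
   sparse solve $D\Delta f - k_{eff} f + S = 0$ (symmetric
   positive-definite, Cholesky-factorised and cached); an explicit
   Euler–Maruyama stepper is kept for verification, and the test suite
   checks the two agree to 1% on a two-cell fixture.

3. **Membrane polarity.** On each membrane live two stages of a generic
   pheromone-response cascade: $u_1$ (a G$\beta\gamma$ surrogate) is driven
   by the normalised ligand
   $\tilde f = f/\max_{\Gamma} f + 0.1$ through a saturating Hill term
   $k_{10}/(1+(\beta_1 \tilde f)^{-q_1})$, amplified by cooperative
   positive feedback, and degraded at a rate modulated by an integral
   controller $v_1$ that pins the spatial mean $\bar u_1$ to the setpoint
   $k_{1ss}$; $u_2$ (active Cdc42) repeats the same structure with $u_1$
   as input. Multiplicative noise acts on $u_1$ and $v_1$ only; the
   increments are i.i.d. Normal(0, dt) per marker per step. Lateral
   diffusion uses an exact spectral substep on the periodic marker ring.
   The **polarisome** is the centre of the minimum-length membrane
   interval holding at least $\tau=0.4$ of the total $u_2$ mass, and the
   membrane grows at
   $$V = V_{amp}\; \tilde u_2 \;\max(0, \langle n, d_{max}\rangle),$$
   where $d_{max}$ is the outward normal at the polarisome and
   $\tilde u_2$ is a filtered copy of $u_2$ (below). Mating succeeds at
   the first 50-s sample where the minimum distance between the partners'
   polarisomes has dropped below the mesh size and the sampled distance
   has decreased on average over the trailing five samples.

Units: lengths in micrometres, one model time unit is 100 s (membrane step
0.01 time units = 1 s; field step $4\times10^{-4}$), diffusion constants
in $\mu m^2$/time-unit ($D_\alpha = 100$, $D_a = 10$ by default), decay
rates 1/time-unit, $V_{amp} = 2\times10^{-4}\,\mu$m/s. Cells start as
circles of radius 1 um; assays run to $T = 1800$ s.

# Parameter choices and calibration

The reaction constants of the polarity cascade are not uniquely pinned by
published values; the package fixes one set (see `polarity_params()`) by a
documented calibration with four requirements:

* a uniform state under uniform ligand stays uniform indefinitely
  (symmetry is not broken spuriously), and the integral-feedback means
  converge to their setpoints;
* a static 20% ligand gradient polarises $u_2$ within about two time
  units, with the $\tau=0.4$ window centred on the gradient maximum and a
  peak-to-mean ratio near 5, so the $\tau=0.4$ interval is a meaningful
  "tip";
* with $\beta_1 = 2.5$ (the supersensitive mutant; default 0.92) the
  input term saturates: its relative difference across the membrane falls
  below 1%, destroying gradient discrimination while leaving the mean
  drive intact — the cell still polarises, but in a noise-selected
  direction;
* under the default noise ($\kappa_1=5$, $\kappa_2=3$, $\kappa_3=0.1$)
  the noise-free two-cell scenario must still mate and the stochastic
  two-cell scenario must mate in a majority of replicates.

Two calibration decisions deserve emphasis. First, the integral-feedback
gains ($k_{14}=0.3$, $k_{24}=0.1$) are deliberately low: high-gain
controllers develop relaxation oscillations in which the $u_2$ peak
collapses and re-forms elsewhere, which under noise turns into episodic
polarisome relocation and ruins mating trajectories. Second, the
stage-2 setpoint $k_{2ss}=1.5$ fixes the (arbitrary) concentration scale
of $u_2$ so that tip speed $V_{amp}\tilde u_2$ closes the 2-um gap
between default-position cells comfortably within the 1800-s assay
window; the Vamp-halving experiment (mating time doubles) is unaffected
because it is a pure ratio.

## Velocity filtering

The raw $u_2$ profile fluctuates strongly under the prescribed noise, and
the growth direction $d_{max}$ would jitter with it. The velocity
therefore uses a filtered profile: a circular moving average over 8% of
the membrane length followed by an exponential temporal filter with a
30-s time constant. The *recorded* polarisome (used for the success
criterion and all readouts) is located on the raw $u_2$, which defines
it. The polarisation latch that switches secretion from isotropic to
polarised fires when $\max u_2 > 2\,\overline{u_2}$.

## Polarisome tie-break

Among equal-length minimal windows the implementation prefers the window
containing the most mass, then the smallest start index. A pure
smallest-start rule would systematically displace the centre of a
symmetric peak by several markers and break the mirror symmetry of
noise-free two-cell runs; the mass-maximal rule is deterministic and
exactly centred for symmetric profiles.

## External noise in QSS mode

In QSS mode the field noise term cannot be integrated directly, so the
membrane samples receive an equivalent noise calibrated against the
explicit stochastic stepper on a small fixture: relative standard
deviation $0.067\,\kappa_1/\sqrt{D}$ per membrane step, spatially
smoothed to the measured angular correlation length of about 0.4 um, and
independent across steps (the measured step-to-step correlation is
0.2). This reproduces the stationary membrane-level fluctuation
statistics of the explicit scheme at a small fraction of its cost.

# Numerical choices

* Mesh 0.04 um (the reference resolution; the success threshold is the
  mesh size). 400 markers per membrane.
* Level-set advance every 5 membrane steps with the time-averaged
  velocity (internally substepped if the CFL number would exceed 0.5);
  signed-distance reinitialisation every 10 advances; band mapping
  (marker-to-node correspondences) rebuilt every 4 advances. Batch assays
  relax these cadences slightly (reinitialisation and field refresh every
  12 steps, band mapping every 5 advances) — the membrane moves well
  under one node spacing between rebuilds either way.
* QSS field refresh every 10 membrane steps (10 s); the Bar1-modulated
  alpha-factor operator is refactorised only when the decay field has
  moved by more than a quarter of $k_{deg}$ (the protease profile drifts
  with the slow geometry, so the operator stays accurate between
  refactorisations).
* Velocity extension and the polarised source interpolate marker
  quantities to band nodes by angle about the cell centroid: smooth and
  mirror-symmetric, unlike nearest-marker assignment whose tie-breaking
  imposes a chiral bias.
* Cell contact: where a marker comes within 0.02 um of another membrane
  and its outward normal points into it, its normal velocity is zeroed;
  markers sliding along the interface keep growing, so touching tips can
  still align. Simulations never merge membranes (mating stops at tip
  contact).
* Negative concentrations produced by Euler–Maruyama undershoot are
  clamped to zero and counted.
* A pinched-off contour speck (rare, noise-driven) is dropped and $\phi$
  rebuilt from the dominant component; the event is logged.

# What the assays measure

* **Mating efficiency (ME)** — fraction of replicate simulations meeting
  the success criterion (batches of 20).
* **Direction plots** — per-simulation time-averaged projection angles
  $(\theta_\alpha, \theta_a)$, the alpha-cell counted counterclockwise
  and the **a**-cell clockwise so that partners pointing at each other
  lie on the identity diagonal; the scatter is summarised by the mean
  perpendicular distance $|\theta_a-\theta_\alpha|/\sqrt2$ to the
  diagonal, over all replicates. (The coordinate difference
  $|\theta_a-\theta_\alpha|$ is an equally defensible convention; the
  perpendicular distance is what "distance from the diagonal" means
  geometrically, and is the package default.)
* **Mating discrimination (MD)** — among successes in multi-alpha
  scenarios, the fraction with the pheromone-producing partner.
* **Mating competition** — two **a**-cell genotypes racing for one
  alpha-cell; win counts per genotype.
* **Fisher's exact test** — all pairwise comparisons of mating
  proportions; one-sided where the hypothesis is directional (e.g. Bar1+
  efficiency exceeds bar1-delta), two-sided otherwise.

A worked example:

```{r example}
cfg <- build_scenario("two_cell")
r <- run_simulation(cfg, seed = 1)
r
batch <- run_batch("two_cell", reps = 20, seed_base = 100)
mating_efficiency(batch)
diagonal_deviation(batch)
```

# Problem sizes used by the shipped tests and the acceptance script

Full-resolution runs (mesh 0.04, 400 markers) are used for the
mating-efficiency batches of the acceptance script, at roughly 13 s per
simulation. The test suite exercises the same code paths at a coarsened
solver resolution (mesh 0.08, 200 markers) where a run takes a few
seconds; at that resolution the final tip-to-tip locking is measurably
poorer and mating efficiencies are lower than at the reference mesh, so
quantitative efficiency checks in the suite are made against wide
intervals, and the reference-resolution numbers are produced by the
acceptance script. The supersensitive batch (whose readouts — zero
efficiency and a large direction-plot scatter — are insensitive to the
mesh) also runs coarsened in the script to keep its runtime modest.

# What the synthetic scenarios do and do not capture

The scenario generator reproduces the study geometries: paired cells 4 um
or 2.5 um apart, the discrimination triangle (one **a**-cell equidistant
from a producer and a non-producer alpha-cell), the competition triangle
(Bar1+ and bar1-delta **a**-cells racing for one alpha-cell), the offset
variant (the **a**-cell 0.1 um below the midline), and the five-cell
cross (one producer among four alpha-cells around a central **a**-cell).
They emulate pheromone-mediated communication between ideal circular
cells on an empty plane. They do not model receptor occupancy or ligand
depletion by binding, pheromone-induced Bar1 expression, cell-cycle
state, crowding by non-participating cells, or the third dimension; all
of these affect quantitative mating statistics in real mating mixes, so
agreement in these assays demonstrates internal consistency of the
modelled mechanisms (polarised secretion, Bar1 gradient sharpening,
sensitivity tuning), not a calibrated prediction for any particular
strain.

# Known limitations

* The polarity constants are a calibrated set, not a fit; other sets
  reproducing the four calibration properties exist.
* At solver meshes coarser than the 0.04-um reference the success
  criterion (threshold = mesh size) interacts with poorer tip locking;
  efficiency comparisons should be made within one resolution only.
* The QSS noise emulation reproduces stationary membrane-level
  statistics, not the full space-time correlation structure of the
  explicit stochastic field.
* Simulations stop at tip contact; membrane fusion and later stages are
  out of scope.
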