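---
title: "Driven polycatenane translocation through crystalline pores: model and methods"
author: "porelink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driven polycatenane translocation through crystalline pores: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porelink)
```

## The scientific problem

A poly[4]catenane is a polymer of four mechanically interlocked rings: each
consecutive pair of rings forms a Hopf link, so the chain is held together by
topology rather than covalent bonds between rings.  When such a molecule is
pulled through a pore barely wide enough to admit it, the interlocked
junctions (the "knots") must pass through the channel as four-strand bundles,
whereas the ring bodies pass as two-strand hairpins.  In the small-pore limit
the microstructure of a crystalline pore wall matters: the channel carved out
of a crystal is not a smooth cylinder but a sequence of constrictions whose
shape changes abruptly as the carving radius crosses a lattice shell.  This
package simulates that process with coarse-grained Langevin dynamics and
computes the statistics that characterise it: translocation profiles under
two definitions, waiting times, knot-passage events, in-pore ring
orientations, and the Shannon entropy of the orientation distribution.

## Model

**Force field.**  Beads of mass $m$ interact through the purely repulsive
WCA potential, the Lennard-Jones potential truncated at $r_c = 2^{1/6}\sigma$
and shifted so that it vanishes continuously at the cutoff.  Bonded beads
additionally feel the FENE potential with spring constant
$k_b = 30\,\epsilon\sigma^{-2}$ and maximum extension $R_0 = 1.5\,\sigma$
(the Kremer-Grest convention: WCA acts on bonded pairs too, providing the
excluded-volume core that keeps bonds from collapsing).  `fene_force()` and
`wca_energy()` expose the closed forms; the compiled engine evaluates the
same expressions.

**Dynamics.**  Each polymer bead obeys the underdamped Langevin equation
$m\ddot{\mathbf r} = \mathbf F_{\rm cons} - \gamma\dot{\mathbf r} +
\boldsymbol\xi(t) + \mathbf f^{\rm ext}$, integrated with the
velocity-Verlet Langevin scheme at $\Delta t = 0.0025\,\tau$, where
$\tau = \sigma\sqrt{m/\epsilon}$.  The Gaussian random force has standard
deviation $\sqrt{2\gamma k_BT/\Delta t}$ per component per step.  The
friction coefficient and the temperature are not recoverable from the study
conditions; we use the standard coarse-grained choices $\gamma = 1\,m/\tau$
and $k_BT = 1\,\epsilon$, both configurable through `sim_params()` and
recorded in every trajectory's metadata.  The driving force
$|\mathbf f^{\rm ext}| = 1\,\epsilon\sigma^{-1}$ acts along $+x$ on every
bead whose axial coordinate lies inside the pore, $x \in [x_p, x_p + 4\sigma]$
with $x_p = 0$.  (Driving along $+x$ rather than $-x$ is a pure reflection of
the coordinate convention with no observable consequence.)  Hydrodynamic
interactions are outside the scope of the model.

**Pore.**  The wall is an FCC slab of frozen beads, $20\sigma \times
20\sigma$ transverse (periodic) and $4\sigma$ thick along the open pore
axis.  A cylindrical pore of radius $r$ is carved by removing every wall
bead whose centre lies within radial distance $r$ of the axis; all radii
quoted by the package are this carving radius, so the WCA-accessible radius
is smaller.  The wall beads are never integrated.

**Lattice constant.**  The nearest-neighbour wall spacing is the one
model-defining parameter that the study conditions leave open, and the
phenomenology depends on it strongly.  We use a conventional FCC cell of
edge $a = 2\sigma$ (nearest-neighbour distance $\sqrt 2\,\sigma$), for three
reasons.  First, it is exactly commensurate with the slab: ten cells across
the periodic $20\sigma$ directions and two through the $4\sigma$ thickness,
so the crystal is unstrained.  Second, the wall remains impenetrable: the
largest gap between wall beads ($\sqrt2\,\sigma$) is far below twice the WCA
range.  Third, the transverse lattice then has a shell of sites at radial
distance $\sqrt 2\,\sigma \approx 1.414\,\sigma$ from the pore axis — between
the carving radii $1.4\sigma$ and $1.5\sigma$.  For $r \le 1.4$ those four
diagonal beads ring the channel in every second lattice layer and gate the
passage (and especially the orientation) of ring strands; at $r = 1.5$ they
are carved away and the channel opens to the next shell at $2\sigma$.  This
gives the abrupt change in translocation dynamics between $r = 1.4$ and
$r = 1.5$ a concrete geometric origin.  A denser wall (we piloted
nearest-neighbour spacings down to $1.0\sigma$) generates confinement
barriers larger than the total driving force, so chains are expelled from
the pore and never translocate — incompatible with a driven-translocation
study at this force.

**Initial state and equilibration.**  The first ring is built as a thin
stadium ("hairpin") loop elongated along $-x$ whose apex bead sits on the
axis at $x = 4.5\sigma$, just past the exit plane; the remaining rings are
circles on the cis side, placed in alternating orthogonal planes so that
every consecutive pair is a Hopf link (verified at build time by exact
polygonal Gauss linking numbers; non-adjacent pairs must be unlinked).  The
apex bead is held fixed while the rest of the chain is thermalised, then
released for production.  Threading the full pore before release matters:
with a shallowly threaded chain the driving force acts on too few beads to
exceed the confinement barrier of the narrow channels and the chain is
expelled before translocation can begin.  A capped steepest-descent
minimisation removes construction overlaps before any dynamics.
Equilibration is monitored through the radius of gyration; stationarity is
declared when a Mann-Kendall trend test on the most recent $600\tau$ of the
Rg series (thinned to one sample per $20\tau$, because Rg decorrelates over
tens of $\tau$) is non-significant at the 5% level.  Production integrates
until every bead has passed the exit plane, or flags the replica incomplete
at a step cap; incomplete and non-equilibrated replicas are excluded from
ensemble averages and counted in the sweep summary.

## Translocation statistics

Two definitions of the translocation fraction are computed from every
trajectory, with sub-frame crossing times obtained by linear interpolation
of the axial coordinate between frames:

* **Irreversible** — bead $i$ is counted from its *first* passage time
  $\tau_i$ onwards: $x^{\rm irrev}(\tau) = N^{-1}\sum_i H(\tau - \tau_i)$.
  The time at fraction $k/N$ is the $k$-th order statistic of the $\tau_i$;
  the waiting time is the gap between consecutive order statistics.
* **Reversible** — the instantaneous census
  $x^{\rm rev}(\tau) = N^{-1}\sum_i H(x_i(\tau) - x_p)$, which fluctuates as
  beads recross the entrance.  The time reported at fraction $k/N$ is the
  last time the census permanently attains that level; the total time is
  therefore the final entrance crossing.  It coincides with the
  irreversible total exactly when the final crossing is a first passage —
  the typical driven-chain situation; on strongly fluctuating trajectories
  the reversible total exceeds the irreversible one by the
  terminal-recrossing correction, and the package reports the final
  entrance crossing as *the* total translocation time.  The waiting time at
  level $k/N$ is the total
  dwell time of the census at that level, computed up to the final crossing,
  so the waiting times partition the total time exactly.  The raw census
  series is exposed alongside.

It follows that $\tau(x^{\rm irrev}) \le \tau(x^{\rm rev})$ at every
fraction, with equality on strictly monotone trajectories; the package
asserts these properties in its test suite on both synthetic and simulated
trajectories.  Savitzky-Golay smoothing (window 9 fraction bins, order 3 by
default) is available for presentation of waiting-time profiles and is never
applied before peak statistics unless requested.

**Knot-passage events** are the maximal time intervals during which the
beads inside the pore span at least two distinct rings.  Intervals separated
by less than the debounce window (default $2\tau$) are merged, since
single-bead flicker at the pore mouth otherwise fragments one physical
passage into many.  A completed poly[4]catenane replica is expected to yield
three events (one per Hopf junction); replicas with a different debounced
count are flagged but still reported.  Each event carries its duration
$\Delta\tau$ and the reversible-census fractions at its boundaries
($\Delta x$).

**Orientation.**  The orientation of the in-pore bead cloud is the angle
$\theta$ between $\hat z$ (a fixed direction perpendicular to the pore axis)
and the normal of the least-squares plane through the in-pore beads,
computed by singular value decomposition as the direction of least variance.
Since a plane normal is defined up to sign, $\theta$ is folded to
$[0^\circ, 90^\circ]$; a further fold about $45^\circ$
($\theta \to 90^\circ - \theta$), reflecting the four-fold symmetry of the
crystal cross-section, is emitted alongside as `theta_folded`.  At each
knot-entry event the orientation of the ring already resident in the pore
(the ring with the most in-pore beads just before the event) is sampled at
the event start.  The Shannon entropy $S = -\sum_x p_x \ln p_x$ of the
binned angle distribution (default $5^\circ$ bins on $[0, 90]$, so
$\max S = \ln 18$) summarises how constrained the orientations are; samples
fewer than three beads or collinear clouds are skipped and logged.

## Replica pipeline

`run_sweep()` loops over pore radii and seeded replicas, with every
replica's seed derived deterministically from the sweep's `seed_base`, so a
sweep reproduces byte-identically.  Replicas are the independent unit:
means and 95% confidence intervals (Student-$t$ quantiles below 30
replicas) are computed from per-replica values, never from pooled frames.
Profiles are averaged at fixed fraction $k/N$, which makes replica profiles
directly commensurable.  `jump_statistics()` reports the difference and
ratio of the ensemble-mean total translocation times between two radii
(positive difference = slowdown at the smaller pore) and the corresponding
difference of mean knot-passage durations, with standard errors combined in
quadrature.

## Synthetic trajectories

Every analysis stage is testable without running dynamics.
`crossing_schedule()` + `make_trajectory()` generate piecewise-linear
per-bead axial paths realising prescribed first-crossing times, recrossing
episodes and ring co-occupancy patterns, with ground-truth annotations
returned alongside; transverse Ornstein-Uhlenbeck noise (amplitude in
$\sigma$, correlation time in $\tau$) emulates the qualitative positional
autocorrelation of Langevin dynamics without touching the axial schedule.
`make_orientation_fixture()` produces in-pore bead clouds on planes of
prescribed tilt.  Because the analysers interpolate linearly between frames,
fixtures whose breakpoints lie on the frame grid are recovered exactly at
zero noise; noisy fixtures are recovered within documented tolerances
(e.g. $2^\circ$ at $0.01\sigma$ plane noise).  What passing these tests does
*not* show is physical fidelity of any particular trajectory — the fixtures
are statistical stand-ins, not dynamics.

## Problem sizes and numerical choices

The full study behind the headline numbers used 140 replicas per condition
across 11 radii.  The package's own experiments are desk-scale by design:
the jump experiment runs order-10 seeded replicas of the poly[4]catenane at
$r = 1.4$ and $1.5$ (a few minutes on one core), which resolves the jump in
mean total translocation time at its reported $\sim$300$\tau$ scale while
leaving quantities that need larger ensembles (the factor-4 vs factor-3
polycatenane/ring contrast, the $45^\circ$ insertion-angle mode) to bigger
runs that the same functions support by raising `replicas`.

Worth knowing when extending the package:

* Neighbour handling is a Verlet pair list (polymer-polymer plus a static
  cell grid over the frozen wall) with a $0.4\sigma$ skin, rebuilt when any
  bead has moved half the skin; the contract is exactness of the force sum,
  not a particular structure.
* The thermostat noise uses a deterministic splitmix64 + ziggurat Gaussian
  sampler, so trajectories are bit-reproducible for a given seed across
  platforms, independent of R's RNG state.
* A FENE bond reaching $R_0$ aborts the replica with a diagnostic (this is
  an integration blow-up signal, not a recoverable event); such replicas
  are excluded from averages and counted.
* Frame sampling defaults to $0.5\tau$ (200 steps), fine enough to resolve
  single-bead crossings; crossing times are interpolated within frames.
* Degenerate analysis inputs follow explicit conventions: empty histogram
  bins contribute $0\ln 0 = 0$; orientation samples need three
  non-collinear beads; a bead already past the entrance at the first frame
  is counted as crossed at the start time.

## Known limitations

The lattice constant, friction, temperature and threading depth are choices
where the study conditions are silent; all are configurable, and the
defaults are the ones under which the package's acceptance experiments are
run.  Absolute translocation times depend on these choices — comparisons
across radii (differences, ratios) are the meaningful outputs.  The wall is
rigid and athermal; hydrodynamics are absent; knot-passage detection relies
on ring co-occupancy rather than a mathematical knot invariant, which is
exactly the event definition of the study this package replicates.
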