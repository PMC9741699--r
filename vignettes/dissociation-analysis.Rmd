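---
title: "Analysing protein dimer dissociation from biased simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing protein dimer dissociation from biased simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`dissockit` analyses the dissociation of a two-chain protein complex — the
motivating system is the CH3–CH3 interface that pairs antibody heavy
chains — sampled by metadynamics along the distance between the two
domains' centres of mass. The package covers the full chain from raw
trajectories to thermodynamic and kinetic summaries:

1. **Descriptors**: per-frame centre-of-mass (COM) distance, fraction of
   native contacts *Q*, and solvent-accessible surface area (SASA).
2. **State definition**: sigmoid membership functions turn descriptor
   series into a state curve in [0, 1]; its decay marks the
   bound → encounter → unbound transitions.
3. **Free energy**: reconstruction from deposited Gaussian hills,
   time-dependent-bias reweighting, combination of repeated runs, the
   depth of the bound minimum with leave-one-out (LOO) error bounds, and
   the correlation of depths with experimental melting temperatures.
4. **Contacts**: typed noncovalent inter-chain contacts (hydrogen bonds by
   backbone/side-chain class, salt bridges, pi-cation, pi- and T-stacking,
   hydrophobic), their occurrence per window, a strict >20% filter, and
   coarse-graining by secondary-structure element for flareplots.
5. **Orientation**: six interdomain metrics — centre-axis length dC, the
   torsion AB about that axis, and four tilt angles (AC1, AC2, BC1, BC2) —
   with circular statistics for the torsion.
6. **Markov state models**: inverse CA-distance features, tICA, k-means
   microstates, a reversible transition-matrix estimator, implied
   timescales, PCCA+ macrostates, mean first-passage times, and the
   Chapman–Kolmogorov test; plus average-linkage RMSD clustering for
   representative extraction.
7. **Pipeline**: `run_system()` / `run_panel()` orchestrate all stages per
   system and correlate bound-minimum depths against melting temperatures.

Because microsecond all-atom trajectories cannot be shipped or recomputed
at desk scale, the package carries a first-class synthetic-data module —
toy dimers, programmed dissociations and 1-D Langevin metadynamics on
known potentials — so that every stage is testable against ground truth.

# The state definition

The membership of a frame in the bound state is modelled with the logistic
function

$$m(x) = \frac{1}{1 + e^{-s\,(x - x_0)}}$$

with slope $s$ and turning point $x_0$. For the bound → encounter
transition, the parameters are fitted to the *bound reference
distribution* of each descriptor (an unbiased run, or the early window of
the biased runs): the histogram (Freedman–Diaconis bins) is cut at its
mode, the half on the dissociation side is rescaled to [0, 1], and the
logistic is fitted to the rescaled half. The COM distance uses the right
half (it grows on dissociation, $s < 0$), *Q* the left half ($s > 0$).
The fit anchors the mode bin at membership 1 with a large least-squares
weight: the rescaling is defined so that the bound basin has membership
≈ 1, and an unanchored fit through a Gaussian half would plateau at only
≈ 0.93 at the mode. The product of the distance and *Q* memberships is
the state curve; the first sustained drop below 0.5 (the logistic
midpoint) is the dissociation point.

For the encounter → unbound transition the bound-window histograms carry
no information — both *Q* and SASA leave their bound ranges long before
full dissociation. Instead, both time series plateau once the complex is
fully apart, so each series is fitted with a four-parameter logistic in
time, normalized between its fitted plateau levels (*Q* falling, SASA
rising), and the two normalized curves are multiplied. The first sustained
drop of this product below 0.05 ("approaches zero") marks the unbound
state. A fitted plateau separation smaller than three residual standard
deviations means the run never dissociates and the membership stays 1.

Both detections require the curve to stay below threshold for a dwell
window — by default 1% of the trajectory (at least 10 frames); the
pipeline uses 5% because metadynamics broadens the bound basin before the
actual escape and brief excursions are not dissociations. Both thresholds
and the dwell are configurable; the values are choices of this package —
there is no field-standard number for when a state curve counts as
"dissociating" or as having "approached zero".

# Free-energy reconstruction and the bound-minimum depth

With constant-height hills (standard, non-well-tempered metadynamics,
matching the constant 0.1 kJ/mol height) the free-energy estimate is
$F(s) = -V(s, t)$, the negative of the accumulated bias, min-shifted to
zero. Each run contributes data only up to its detected dissociation
frame. Per-run probability densities are obtained by Boltzmann inversion
of the truncated free-energy curve, restricted to the CV range the run
sampled; runs are combined as a weighted average of densities with scalar
weights $e^{\beta c(t)}$, where

$$c(t) = \frac{1}{\beta}\,\ln \frac{\int e^{\beta V(s,t)}\,ds}{\int ds}$$

is the time-dependent bias offset (the standard-metadynamics limit of the
time-dependent-bias estimator, with a flat reference measure over the
grid). A per-frame reweighting route — frame weights
$e^{\beta(V(s_i,t_i) - c(t_i))}$ histogrammed on the grid — is available
(`reweighted_histogram()`, `loo_depth(density = "histogram")`) and reduces
exactly to plain histogramming when no hills were deposited.

The depth of the bound minimum is the free-energy difference between the
minimum inside a user-given bound region and the *transition level*: the
maximum of F between that minimum and the largest sampled CV value. Two
numerical safeguards matter here, both calibrated against synthetic
ground truth:

* grid points within 0.15 nm (three default hill widths) of the upper
  grid edge are excluded — a sampling edge or reflective wall receives
  Gaussian deposition from one side only, and its artificial deficit
  would otherwise masquerade as a high transition level;
* both the minimum and the maximum are read off a 0.05 nm moving-average
  smoothed profile — hill deposition leaves kJ/mol-scale oscillations,
  and raw per-bin extremes systematically overestimate the depth.

The LOO uncertainty recombines the runs leaving one out at a time and
reports the minimum and maximum of the resulting depths. This envelope is
a *sensitivity band*, not a calibrated confidence interval: for $n$
exchangeable runs the drop-one range contracts like (run range)/$n$,
about half the sampling error of the combined estimate itself, so the
band should be read as "how much any single run moves the answer". The
package's own calibration on a 10 kJ/mol well (10 runs × 10 independent
repetitions) recovers the depth to 10.2 ± 0.15 kJ/mol while the LOO band
half-width is only ≈ 0.1 kJ/mol — the truth falls inside the band in
roughly 2 of 10 repetitions, and no exchangeable-run estimator can make
that rate high.

# The synthetic-data module

`build_toy_dimer()` places two mirror-image chains of pseudo-residues
(N, CA, C, O plus one side-chain pseudo-atom) on a regular lattice, with a
designed set of inter-chain contact pairs at 3 Å across the interface —
exactly these pairs fall below the conventional 4.5 Å heavy-atom contact
cutoff. Interface pairs alternate between hydrophobic (LEU–LEU) and salt
bridge (LYS–ASP) so the typed-contact machinery has realistic targets.

`generate_dissociation_trajectory()` emulates the two-step mechanism:
bound jitter, then an encounter window in which chain b twists by a set
torsion about the interdomain axis and the *peripheral* interface pairs
(those farthest from the torsion axis) release while the central pairs
stay pinned as a hinge, then full separation beyond twice the contact
cutoff. Peripheral-first release mirrors the observed staged loss in
which the outer strand contacts go before the central strand core.

`simulate_langevin_metadynamics()` integrates one CV on a known potential
(harmonic, calibrated tilted double well, or tabulated) with Gaussian
hills deposited at the instantaneous CV position. Units: kJ/mol, nm, ps;
$k_B = 0.008314463$ kJ/mol/K; mobility $1/(\gamma m)$ with friction
$\gamma$ in 1/ps. The default integrator is the Leimkuhler–Matthews
(BAOAB-limit) scheme rather than plain Euler–Maruyama: at the default
timestep (0.002 ps) the Euler scheme's configurational bias alone puts
the sampled density ~0.11 total-variation away from the Boltzmann truth
on the reference double well, while the BAOAB-limit scheme stays within
~0.01; Euler–Maruyama remains available via `integrator = "em"`. The
bias is evaluated as the exact sum of deposited Gaussians (hills are
bucketed by centre and truncated at eight standard deviations, an error
below 10^-14 of a hill height); reflective walls act at the domain edges.

What the generator does *not* emulate: explicit solvent, force-field
energetics, multidimensional CVs, barostats — a passing test shows the
analysis machinery is correct, not that any force field is.

# Markov-state-model choices

Features are inverse CA–CA distances of the designated interface pairs
(changes at small separation are emphasized). tICA solves the symmetrized
time-lagged covariance problem with a 10^-8 ridge on C(0); components are
C(0)-orthonormal. Microstates come from k-means with deterministic
k-means++ seeding (ties to the lowest index, 10 restarts). Transition
counts are collected inside each trajectory at the chosen lag, restricted
to the largest strongly connected state set; the default estimator
symmetrizes counts, which guarantees reversibility with stationary
distribution proportional to the symmetrized row sums (a reversible
maximum-likelihood iteration is available). Implied timescales are
$t_i = -\tau / \ln \lambda_i$. PCCA+ is implemented as an inner-simplex
vertex search on the dominant right-eigenvector simplex; memberships are
clipped to be non-negative and renormalized, and the crisp assignment is
the argmax. Mean first-passage times solve the standard linear system on
the microstate chain and are aggregated with stationary weights. The
Chapman–Kolmogorov test compares macrostate-level $T(k\tau)$ predictions
against re-estimates, with bootstrap bands over trajectories (contiguous
blocks when only one trajectory is available). The lags of 10 ns (tICA)
and 9 ns (MSM) used for the antibody systems are expressed in frames via
the trajectory's frame spacing.

# The pipeline and the synthetic panel

`run_system()` loads each run, computes descriptors (native contacts come
from the unbiased reference structure when one is provided), fits the
memberships once per system, classifies each run's frames, truncates each
run's free-energy data at its dissociation frame, combines runs into a
depth with LOO bounds, accumulates typed-contact occurrence separately
for the bound and encounter windows (concatenating runs), and summarizes
orientation variability per window. `run_panel()` does this per system
and correlates depths with melting temperatures, excluding — but still
tabulating — systems without a measured value.

`synthesize_system()` builds a complete synthetic system: a Gaussian well
of chosen depth on the COM-distance CV (its plateau height *is* the true
bound-minimum depth), metadynamics runs that escape it, an unbiased
reference run confined to the basin (the conventional-MD analogue), and
toy-dimer trajectories driven by the CV so that the geometric descriptors
track the sampled CV exactly. Desk-scale defaults — 16–20 residues per
chain, 8 interface pairs, 3 runs of a few times 10^5 steps, hills of
0.2–0.5 kJ/mol every 500–2000 steps, ~250–300 saved frames — are chosen
so a full panel runs in minutes; they are stated here once and used
consistently by the tests and the acceptance script.

# Known limitations

* The depth estimator inherits a small positive bias (~0.2 kJ/mol on a
  10 kJ/mol well) from taking a maximum over a fluctuating plateau; it
  cancels in rankings, which is what the melting-temperature correlation
  uses.
* Truncating runs at the detected dissociation systematically stops the
  fill 1–2 kT short of the rim (escape happens before the bias reaches
  it), so truncated absolute depths are conservative; rankings are
  preserved.
* The orientation axes are built from principal components of each
  domain's core and transported by Kabsch superposition; values are
  comparable within this package but not numerically identical to other
  interdomain-orientation tools with different anchor definitions.
* Hydrogen-bond detection falls back to donor–acceptor distances when the
  input carries no hydrogens (the declared no-angle mode).
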