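# dissockit

Dissociation analysis of two-chain protein complexes from biased molecular
simulations, written for the interface that decides antibody heavy-chain
pairing: the CH3–CH3 dimer. Given metadynamics runs along the
centre-of-mass (COM) distance of the two domains — trajectories plus
PLUMED-style HILLS/COLVAR records — the package reconstructs how, and how
strongly, the two chains hold together:

* **descriptors** per frame: COM distance, fraction of native contacts
  *Q*, solvent-accessible surface area (Shrake–Rupley);
* **states**: logistic memberships `1/(1 + exp(-s (x - x0)))` fitted on
  the bound-state descriptor distributions define a product state curve in
  [0, 1]; its first sustained drop marks dissociation, and the product of
  the plateau-normalized *Q* and SASA time series marks the unbound state;
* **free energy**: `F(s) = -V(s, t)` from the deposited hills, per-run
  truncation at dissociation, c(t)-weighted combination of repetitions,
  Boltzmann inversion, bound-minimum depth with leave-one-out bounds, and
  Pearson/Spearman correlation of depths against melting temperatures;
* **contacts**: typed inter-chain contacts (hydrogen bonds split
  backbone/side-chain, salt bridges, pi-cation, pi-/T-stacking,
  hydrophobic; distance-only van der Waals pairs are never reported),
  occurrence per state window, a strict "higher than 20%" filter, and
  coarse-graining by secondary-structure element for flareplots;
* **orientation**: centre-axis distance dC, interdomain torsion AB
  (circular statistics) and four tilt angles per frame;
* **Markov state models**: inverse CA-distance features, tICA, k-means
  microstates, reversible transition-matrix estimation, implied
  timescales, PCCA+ macrostates, mean first-passage times,
  Chapman–Kolmogorov validation, and average-linkage RMSD clustering.

A synthetic-data module (toy dimers, programmed two-step dissociations,
1-D Langevin metadynamics on known potentials) generates every input the
pipeline needs, so the whole stack is verifiable against ground truth on
a laptop.

## Worked example

```r
library(dissockit)

# a synthetic system: Gaussian well of depth 10 kJ/mol on the COM CV,
# three metadynamics runs plus an unbiased bound-state reference
rec <- synthesize_system("demo", well_depth = 10, out_dir = "demo",
                         tm_celsius = 70, n_runs = 3, n_steps = 2e5,
                         seed = 5, residues_per_chain = 16,
                         n_interface_pairs = 8, traj_frames = 250)
res <- run_system(rec, pipeline_config(sasa_points = 120))
res$depth
#> <depth_estimate> 10.1 kJ/mol [LOO 9.82, 10.5], n=3
sapply(res$runs, function(r) r$t_dissociation)
#> [1]  NA 203 209
head(res$occurrence_bound, 3)
#>           type resno_a resno_b occurrence
#> 30 hydrophobic      11      11  0.4658537
#> 32 hydrophobic      14      14  0.4390244
#> 33 hydrophobic       2       2  0.4024390
```

The depth estimate is the free-energy difference (kJ/mol) between the
bound minimum and the transition region of the combined, truncated
free-energy profile — here it recovers the designed 10 kJ/mol well — and
the LOO bracket shows how much any single run moves it. `t_dissociation`
is the frame at which the distance × Q state curve first stays below 0.5
(`NA` marks a run that never dissociates; its full data then enter the
free-energy estimate); the occurrence table gives the fraction of
bound-window frames in which each typed inter-chain contact is present.
`run_panel()` repeats this over systems and correlates depths with
melting temperatures, excluding (but tabulating) systems without one.

The methods vignette (`vignettes/dissociation-analysis.Rmd`) documents the
models, the tunable parameters and their defaults, the numerical choices,
and what the synthetic generator does and does not emulate.

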