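# quasibound

Ranking congeneric ligands — and spotting activity cliffs — from the
structural stability of their key protein–ligand hydrogen bond.

Steered-pulling ("dynamic undocking") simulations drag the key H-bond
donor–acceptor distance from its bound value (~2.9 Å) to a quasi-bound state
(~5 Å) where the bond is broken but the ligand is still in the pocket. Each
pulling cycle yields a work profile `W(r)`; the per-trajectory quasi-bound
work is

```
Wi = max_{r >= r_min} W(r) - W(r_min),   r_min = argmin W over the bound window (2.7-3.3 Å)
```

and the quasi-bound free energy is the Jarzynski exponential average over N
cycles,

```
ΔG_QB = -kB·T · ln[ (1/N) Σ_i exp(-Wi / kB·T) ]
```

with a bootstrap standard deviation from 100 random subsamples of 40
trajectories. For a similarity-matched pair of ligands (MACCS keys, Tanimoto
coefficient), `ΔΔG_QB = ΔG_QB(weak) − ΔG_QB(strong)`; a pair is predicted an
*activity cliff* (a >100-fold potency gap, `ΔΔG_bind > 2.73` kcal/mol) when
`ΔΔG_QB ≤ −5` kcal/mol. Classification quality on imbalanced pair sets is
summarised with the Matthews correlation coefficient

```
MCC = (TP·TN − FP·FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))
```

The method's applicability domain is delimited by a two-step heuristic: a
representative ligand must show a robust main interaction (ΔG_QB > 15
kcal/mol) *and* dissociate in one step — trajectories from random-force
(RAMD-like) unbinding simulations must show no metastable intermediate in
which the H-bond is broken while the ligand centroid is still in the pocket.

The package is aimed at computational chemists who run such pulling
protocols (or want to prototype them): it provides the estimators, the pair
construction and evaluation machinery, the mechanism classifier, and a
Brownian-dynamics generator of synthetic work profiles, dissociation
trajectories and congeneric series with known ground truth, so the whole
pipeline is testable without a molecular dynamics engine.

## Worked example

Recover a known 10 kcal/mol barrier from synthetic pulling data:

```r
library(quasibound)

landscape <- single_barrier_landscape(height = 10)   # ground truth
profiles  <- brownian_smd(landscape, smd_protocol(speed = 0.5),
                          n_trajectories = 120, seed = 1)
wi <- extract_quasi_bound_works(profiles)
jarzynski_free_energy(wi$w_i)
#> [1] 9.663816
bootstrap_uncertainty(wi$w_i, jarzynski_config(seed = 1))
#> [1] 0.01125001
```

The estimate lands 0.34 kcal/mol below the true barrier: the 50 kcal/mol/Å²
pulling spring slightly smooths the barrier top (see the methods vignette).

Benchmark the estimator against the nine-ligand HSP90α series with measured
kinetics (shipped as `table1_vernalis()`):

```r
bm <- benchmark_table1()
bm[bm$excluded & bm$force_field == "PFROSST" & bm$against == "pkd", ]
#>   force_field against excluded pearson_r spearman_rho n
#> 1     PFROSST     pkd     TRUE 0.6856642    0.8263621 8
```

ΔG_QB ranks the eight well-behaved ligands' affinities with ρ = 0.83, and
(under the GAFF force field) their off-rates with r = 0.85 — structural
stability of the key interaction tracks binding kinetics more directly than
equilibrium affinity.

The numbered scripts under `analysis/` run the full set of analyses —
benchmark correlations, published pair-set classification metrics
(MCC = 0.52, precision 45%), barrier recovery, mechanism classification
(98% of multistep and 96% of one-step trajectories recovered), and the
end-to-end synthetic series (MCC = 0.85 against ground-truth cliff labels) —
writing their tables under `results/`:

```sh
Rscript analysis/01_table1_benchmark.R
Rscript analysis/05_synthetic_series.R
```

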