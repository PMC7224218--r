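# nichechange

Quantify how the realized climatic niche of an invading alien species
changes between its native and invaded range, and measure what that
change does to niche-based predictions of its potential distribution.
The package is aimed at invasion macroecologists running niche-shift
analyses and ensemble niche models (ENMs) — and at anyone who wants
those analyses testable: a synthetic-data module generates two-range
worlds with *known* niche dynamics so every stage of the pipeline can
be checked against ground truth without downloading occurrence or
climate data.

## What it computes

**Gridded niche comparison (COUE framework).** A PCA is calibrated on
the pooled environmental backgrounds of the two ranges; occurrence
densities are Gaussian-kernel smoothed onto a 100×100 grid of the
first two components. Within *analogous* climates (available in both
ranges, at the `I_75`/`I_100` background percentiles) niche change
decomposes into

- stability `S` — proportion of the invaded niche overlapping the native niche,
- expansion `E = 1 − S` — invaded-niche density outside the native niche,
- unfilling `U` — native-niche density the invader has not (yet) occupied,

plus the density-centroid shift, a five-class niche topology, and
Schoener's overlap `D = 1 − ½ Σ|z₁ − z₂|` (0 = no overlap, 1 =
identical niches).

**Conservatism tests.** One-tailed permutation tests on `D`: niche
*equivalency* (pooled occurrences randomly re-allocated between
ranges, 1,000 reps) and niche *similarity* (observed density patterns
re-centred at random background locations; `N↔P` shifts both ranges,
`N→P` the invaded range only). Conservatism is inferred when the
observed overlap beats 95% of the null.

**n-dimensional hypervolumes.** Gaussian-KDE hypervolumes (Silverman
bandwidths, `h_j = 1.06 s_j n^{−1/(k+4)}`) of each niche in k
leading PCs, represented by uniform random points at the `H_75`/`H_100`
density boundaries; compared by Jaccard similarity, centroid and
minimum distance, intersection volume and unique fractions.

**Ensemble niche models.** Prevalence-balanced presence/pseudo-absence
datasets (10,000 background points by default, 0.5 prevalence), nested
70/30 evaluation and 70/30 × 10 inner train/test splits, a pluggable
learner contract (shipped: quadratic GLM, spline GAM, ridge logistic,
Gaussian density-ratio, boosted stumps), AUC and maximised TSS
scoring, TSS-weighted ensembles, reciprocal projection to the other
range (`E_inv`, `E_nat`) and clamping (extrapolation) masks.

## Worked example

```r
library(nichechange)

# a synthetic two-range world: 30% unfilling, no expansion, no shift
bgs <- make_env_backgrounds(background_config(n_points = 3000, seed = 11))
tr  <- niche_truth(unfilling_frac = 0.3, n_native = 1000, n_invaded = 1000,
                   seed = 12)
sim <- simulate_species(tr, bgs)

m   <- fit_env_space(bgs$native, bgs$invaded, n_components = 2)
sbn <- project_env(bgs$native, m);  sbi <- project_env(bgs$invaded, m)
g   <- build_grid(sbn, sbi, R = 100)
gn  <- occurrence_density(project_env(sim$native[, c("env1","env2")], m), sbn, g)
gi  <- occurrence_density(project_env(sim$invaded[, c("env1","env2")], m), sbi, g)

coue_metrics(gn, gi)
#> COUE niche-change metrics
#>                I75 I100
#> Stability (%) 99.7 99.7
#> Unfilling (%) 13.7 13.7
#> Expansion (%)  0.3  0.3
#> Schoener's D: 0.735 | topology: partial-overlap
#> Centroid shift: (0.106, -0.090), |shift| = 0.139
#> Expansion into non-analogous space: 0.0%
```

The estimated unfilling (~14%) sits below the injected 30%: kernel
smoothing lets the invaded niche's estimated support bleed past the
true occupancy boundary, a known conservative bias of density-based
unfilling estimates (see the methods vignette). Expansion is
estimated nearly unbiasedly. A full study — niche metrics, both
conservatism tests, hypervolumes at `H_75`/`H_100`, and the three
reciprocally evaluated ensembles — runs with one call:

```r
cfg <- study_config(out_dir = "study_out", seed = 1,
                    scenario = list(truth = tr, background = background_config(seed = 11)))
bundle <- run_study(cfg)   # writes table1_coue.csv, table2_hypervolume.csv,
                           # table3_enm.csv, density grids, run.log
```

A command-line front end with `simulate | niche | tests | hypervolume
| enm | all` subcommands lives at `inst/cli/nichechange.R`.

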