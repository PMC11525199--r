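# clonefate

Quantitative analysis of clonal dynamics and mutant selection in stratified
squamous epithelium, for researchers studying somatic evolution in normal
tissue: lineage-tracing labs measuring clone sizes in mouse esophagus, and
groups relating mutant-clone burden in human epithelium to donor covariates.

The package has two halves.

**Clone dynamics (mouse).** A single-progenitor branching model: progenitors
divide at rate λ (per week), each division producing two progenitors
(probability r(1+δ)), one progenitor and one differentiating cell (1−2r), or
two differentiating cells (r(1−δ)); differentiating basal cells stratify at
rate γ and first-suprabasal cells shed at rate μ. δ = 0 is homeostasis; the
expected progenitor count per founder is exp(2rδλt). The package provides an
exact Gillespie simulator, two independent exact solvers for the clone-size
distribution f(m, n) over m basal and n suprabasal cells (a truncated
master equation via uniformization, and a generating-function/FFT transform),
maximum-likelihood fitting of (r, δ) with profile-likelihood plausible
intervals, and a likelihood-ratio test of fate balance (δ = 0).

**Clone-size statistics and mutant selection (mouse + human).** Normalized
2D clone-size histograms and residual heatmaps, geometric (spatial) median
clone sizes, Peacock's two-sample 2D Kolmogorov–Smirnov test with
permutation p-values, exact/approximate two-tailed Mann–Whitney,
minimum-likelihood two-tailed binomial tests (accurate down to p ~ 1e-300),
aligned-rank-transform factorial ANOVA, and the human PIK3CA analysis:
Path/GoF classification against a packaged annotation snapshot, per-donor
clone densities and summed VAF, the age × weight × pathogenicity OLS model
with sequential ANOVA and Tukey post hoc, per-group accumulation rates in
clones dm⁻² yr⁻¹, and patchwork clone layouts.

A synthetic-data module generates lineage-tracing cohorts and donor mutation
tables with known ground truth, so the full pipeline is testable offline.

## Worked example

```r
library(clonefate)

wt  <- default_params("WT")   # lambda 1.9/wk, r 0.1, delta 0,   gamma 3.5, mu 1.2
mut <- default_params("MUT")  # same rates, delta 0.5

# simulate a mutant cohort, observed at 10 and 21 days post-induction
rec <- filter_clones(simulate_cohort(mut, 1000, c(10, 21), seed = 1),
                     "at_least_one_basal")
#> 222 of 2000 clone records removed by rule 'at_least_one_basal'

fit_clone_model(rec, profile_params = "delta")
#> Single-progenitor model fit (conditioning: at_least_one_basal )
#>   loglik = -5780.174, converged = TRUE
#>   delta      = 0.4652  plausible interval [0.2210, 0.9000]
```

The fitted δ is the fate bias: about 2rδ ≈ 0.09 extra progenitors per
average division, and the plausible interval (profile log-likelihood within
1.92 of its maximum) contains the generating value 0.5 while excluding 0 —
the homeostatic model cannot explain these clone sizes, which is exactly
what `fate_balance_test(rec)` quantifies (here LR = 19.2, p = 1.2e-05).

On the human side:

```r
pathgof_enrichment(37, 57)        # observed Path/GoF share of missense clones
#> $fraction
#> [1] 64.91228
#> $p_value
#> [1] 1.122535e-48

total_area(698, 2)                # 698 gridded 2 mm^2 samples
#> [1] 13.96

ds  <- gen_donor_dataset(donor_design(seed = 1))
res <- density_model(donor_density_table(ds$donors, ds$mutations))
subset(res$rates, effect_class == "Path/GoF")
#>   weight_class effect_class rate_dm2_yr     ci_lo    ci_hi
#> 3       non-OW     Path/GoF     3.92637 -0.571097  8.42383
#> 4        OW-OB     Path/GoF    13.66767  5.120460 22.21487
```

Rates are clones per dm² of epithelium per year of donor age; the synthetic
cohort was designed with true rates 2.2 (non-OW) and 9.8 (OW–OB), and both
lie inside the per-group 95% CIs (which are wide at this cohort's ~1.6 cm²
of sequenced epithelium per donor).

## Command line

```sh
Rscript inst/cli/clonefate.R synth --kind donors --out out/ --seed 1
Rscript inst/cli/clonefate.R ks2d --a a.tsv --b b.tsv --n-perm 999 --seed 1 --out out/
```

Subcommands: `simulate`, `hist`, `ks2d`, `fit`, `density`, `synth`,
`enrich`. Every output directory contains a `provenance.json` sufficient to
reproduce the run. Exit codes: 0 success, 2 validation error, 3 numerical
failure.

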