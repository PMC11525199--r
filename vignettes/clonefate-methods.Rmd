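---
title: "Models and methods behind clonefate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clonefate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

clonefate quantifies two linked questions about squamous epithelium: how a
single labelled progenitor grows into a clone (mouse lineage tracing), and
how selection shapes the landscape of *PIK3CA* missense mutant clones in
human esophagus (targeted deep sequencing). This vignette records the models,
the numerical choices, and what the synthetic-data generators do and do not
emulate.

## The single-progenitor model

The basal layer of esophageal epithelium contains a single functional
population of dividing progenitors. The model tracks three cell types per
clone: progenitors ($p$), post-mitotic basal cells ($d$), and cells of the
first suprabasal layer ($s$). Progenitors divide at rate $\lambda$ per week;
a division yields two progenitors with probability $r(1+\delta)$, one of each
type with probability $1-2r$, and two post-mitotic cells with probability
$r(1-\delta)$. Post-mitotic basal cells stratify at rate $\gamma$; first
suprabasal cells are shed at rate $\mu$. Only the first suprabasal layer is
modelled because the imaging data count basal plus first-suprabasal cells;
cells above that layer are invisible to the measurement.

The fate-imbalance parameter $\delta$ is the scientific quantity of interest:
$\delta = 0$ is homeostasis (the progenitor count per founder is a
martingale, mean 1 forever), while $\delta > 0$ gives exponential expansion
of the mean progenitor number, $\mathbb{E}[p(t)] = e^{2 r \delta \lambda t}$,
with lower suprabasal fractions and fewer fully differentiated "floating"
clones — the joint signature that distinguishes a fate bias from a faster
division rate.

Observables are always the pair $(m, n)$ with $m = p + d$ basal and $n = s$
suprabasal cells; $p$ and $d$ are not separately visible.

### Default rates

The fitted per-genotype rates in the source study live in supplementary
material that is not part of this re-implementation's inputs. Defaults are
therefore anchored to the published lineage-tracing literature for mouse
esophagus: $\lambda = 1.9$/week, $r = 0.1$, $\gamma = 3.5$/week. The shedding
rate $\mu = 1.2$/week is a realistic first-suprabasal residence time of
a few days. The mutant condition uses $\delta = 0.5$, i.e. an excess of
$2r\delta = 0.1$ progenitors per average division — a modest per-division
tilt that still produces severalfold clone-size differences by six months,
matching the qualitative published picture. These defaults were chosen once
and define the stated world of every simulation-based test. One visible
consequence: with $\mu = 1.2$/week the homeostatic floating-clone fraction
rises over the first three weeks of chase and then declines as fully
differentiated clones shed out, so monotone-growth claims about it are
asserted on the rising limb only.

### Three numerical routes, cross-checked

1. **Event-driven simulation** (`simulate_clone`, `simulate_cohort`): exact
   Gillespie trajectories in C++, with a counter-based SplitMix64 substream
   per clone so that cohorts are bit-reproducible and independent of
   evaluation order.
2. **Truncated master equation** (`exact_distribution`): the generator on
   the capped $(p, d, s)$ lattice (absorbing overflow class) is exponentiated
   by uniformization — a Poisson mixture of powers of the uniformized jump
   matrix, evaluated with sparse matrix–vector products. Caps grow until the
   overflow mass is below $10^{-6}$; probability is conserved to $10^{-9}$.
3. **Generating-function transform** (`pgf_mn_distribution`): the process is
   a three-type Markov branching process, so the PGF from one founder obeys
   the Kolmogorov backward equations; two of the three equations have closed
   forms and the third is integrated by RK4 with $\lambda h \le 0.04$ on a
   grid of roots of unity, then inverted by 2D FFT. Aliasing plays the role
   of truncation overflow and is controlled by enlarging the transform grid
   until the mass near the grid edge is below $10^{-7}$.

Routes 2 and 3 agree to total-variation distance below $10^{-6}$; route 1
agrees with route 2 within Monte-Carlo error (TV < 0.01 at $10^5$ clones).
Route 3 is roughly two orders of magnitude faster and is the default
likelihood engine; route 2 is the reference oracle.

## Fitting and the plausible interval

`clone_loglik` sums $\log P(m, n \mid \theta, t)$ over clones, with the
distribution renormalized over the conditioning set (by default clones with
at least one basal cell, the inclusion rule of the size-over-time panels).
`fit_clone_model` maximizes over free parameters (default $r$ and $\delta$;
division and stratification rates are externally constrained and fixed from
configuration) by coarse grid search plus Nelder–Mead refinement.

The *plausible interval* of a parameter is operationalized as the
profile-likelihood region $\{\theta:\ \max\ell - \ell_{\text{prof}}(\theta)
\le 1.92\}$ (half the 95% $\chi^2_1$ quantile), computed by marching outward
from the optimum and warm-starting each nuisance search — the $(r, \delta)$
surface is a curved ridge (the growth rate constrains the product
$r\delta$), and warm-started golden-section search follows it reliably.

`fate_balance_test` is the likelihood-ratio test of $\delta = 0$ against a
free $\delta$, with $p$ from $\chi^2_1$. The free optimum is found by
coordinate descent from the null optimum followed by a simplex polish;
without the polish the statistic is visibly truncated on the ridge. At very
weak designs (few clones, chase under two weeks) the LRT is noticeably
conservative — a genuine small-sample property, not an implementation
artifact (the test suite's calibration design, 400 clones observed at 10 and
28 days, sits in the regime where the $\chi^2_1$ null is accurate).

## Clone-size statistics

2D histograms $f_{m,n}$ are relative frequencies per condition and
timepoint, with explicit overflow pooling beyond stated maxima; difference
heatmaps are elementwise residuals of histograms with identical geometry and
filter. The *geometric median* is interpreted as the spatial (Fermat) median
— the minimizer of summed Euclidean distances — computed by Weiszfeld
iteration with the Vardi–Zhang safeguard, which is well defined on tied
integer points. The coordinate-wise alternative was considered and rejected
because "geometric median" names the spatial median in standard usage.

Peacock's 2D two-sample KS statistic maximizes the quadrant-probability
discrepancy over all origins on the pooled coordinate grid and all four
quadrant orientations (the Fasano–Franceschini variant, restricting origins
to data points, is available as an option and is never larger). P-values are
by label permutation, $(1 + \#\{D_b \ge D\})/(1 + B)$: the asymptotic null
is unreliable for heavily tied integer data. This estimator is exactly valid
but *super-uniform under ties*; with samples of a few hundred integer points
the tie mass is small and the p-value distribution is indistinguishable from
uniform, which is how the calibration suite exercises it.

The aligned-rank-transform ANOVA uses the standard three-alignment scheme
(effects estimated from cell means; one alignment per effect; mid-ranks; a
full two-way ANOVA on ranks of which only the aligned effect's row is
reported). With the tested effect entered last, sequential and marginal sums
of squares coincide on the balanced designs used throughout. The aligned-rank
interaction F-test is known to be liberal below roughly ten observations per
cell; its calibration is therefore checked at fifteen per cell.

The two-tailed binomial test uses the minimum-likelihood definition — sum
of all point probabilities not exceeding that of the observed count, with a
$1 + 10^{-7}$ slack against floating error — evaluated in log space so that
enrichment p-values of order $10^{-48}$ are computed without underflow.

## The human mutant-clone-density analysis

Missense *PIK3CA* variants are classified Path/GoF against a packaged,
versioned snapshot of pathogenic/gain-of-function annotations (recurrent
helical- and kinase-domain hotspots); everything else missense is Unkn/NE,
non-missense is excluded. Donor-level responses are clone counts per cm² of
sequenced epithelium (a gridded array of 2 mm² samples) or summed VAF.

The factorial analysis is OLS on two rows per donor (one per effect class)
with the full `age × weight_class × effect_class` design, sequential ANOVA
in that entry order, and Tukey HSD between the four weight × pathogenicity
groups. Accumulation *rates* and their 95% CIs come from per-group simple
linear regressions instead of the pooled factorial covariance: clone counts
are Poisson, so the residual variance differs several-fold between groups,
and the pooled estimate materially understates the uncertainty of the
fast-accumulating group (measured CI coverage 0.77 pooled versus 0.97
per-group on synthetic cohorts). Rates are reported in clones dm⁻² yr⁻¹
(× 100 from cm⁻² yr⁻¹), the unit in which the headline human rates are
quoted.

## What the synthetic generators emulate

`gen_tracing_dataset`: separate mice per condition and timepoint, Poisson
clone counts per mouse, every clone an independent founder simulated from
the condition's parameters at timepoints 10, 30, 90 and 180 days (1 month =
30 days). Not emulated: spatial interactions between clones, per-mouse rate
heterogeneity, imaging misclassification. A green recovery test therefore
establishes correctness of the inference machinery under the model, not
robustness to biological over-dispersion.

`gen_donor_dataset`: 8 non-overweight and 10 overweight–obese donors (the
study's cohort sizes), ages uniform on 35–75, 80 × 2 mm² samples per donor,
Poisson clone counts with class-specific rates linear in age from an onset
age of 30 (Path/GoF slopes 0.098 and 0.022 cm⁻² yr⁻¹ for OW–OB and non-OW —
the study's headline 9.8 and 2.2 dm⁻² yr⁻¹ — one shared Unkn/NE slope),
VAFs from Beta(1, 40) truncated at a detection floor of 0.01, and H1047R
making up 19% of Path/GoF clones. Not emulated: shared clones spanning
adjacent samples, sequencing error, donor-level covariates beyond age and
BMI. The interaction-power check runs at 400 samples (8 cm²) per donor —
the patchwork-panel area — because at the study-like 1.6 cm² per donor the
designed slopes give only ~0.26 power; the power criterion is a property of
the design, and the vignette states the design it is evaluated at.

## Degenerate inputs and tie-breaking

Validation errors name the violated bound. Quadrant boundary ties in the 2D
KS statistic are resolved by taking the maximum over all four closed/open
orientations (deterministic, conservative). A degenerate ART alignment (all
aligned values equal, e.g. noiseless additive data under the interaction
alignment) reports F = 0, p = 1 with a ties flag rather than NaN. Clone
records incompatible with the stated conditioning (a floating clone under
the at-least-one-basal rule) are an error, not silently dropped. All
randomized entry points take explicit seeds and record them in their
outputs; CLI runs write a provenance file sufficient to reproduce them.

## Known limitations

Per-animal heterogeneity is handled at the summary level (per-mouse dots),
not in the likelihood; the model assumes a single $\gamma$ for both
genotypes; the fitted $(r, \delta)$ ridge means individual parameters are
much less certain than the product $2r\delta\lambda$ that controls growth;
and the human analysis treats per-sample clones as independent, which
overcounts clones that straddle sample boundaries.
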