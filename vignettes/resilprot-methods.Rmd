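---
title: "Methods: models, estimators and the synthetic world of resilprot"
author: "resilprot maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and the synthetic world of resilprot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`resilprot` links the plasma proteome of young, visually healthy pigs —
quantified with 11-plex tandem mass tags (TMT), 10 samples plus one pooled
reference channel per run — to performance and disease-resilience phenotypes
recorded later under a natural polymicrobial disease challenge. The package
covers five analysis stages (normalization, genomic heritability, genetic
correlations, phenotypic association scans, preranked enrichment) and a
synthetic-data generator that emulates the statistical structure of such a
study so that every stage is testable without animal data.

# Normalization of protein abundances (model 1)

Protein abundances are log2-transformed and each protein is modelled
separately on its non-missing samples:

y = Batch + Tag + EntryAge + ref(group1) + ref(group2) + Run + e

with fixed batch and TMT-tag effects, the age at entry into the quarantine
nursery as a covariate, and the log2 reference-channel value of the sample's
run fitted as two group-specific covariates (each set to zero for runs of
the other measurement group, because the pooled reference differs between
the two groups). Run is a random intercept, `Run ~ N(0, I s2_run)`.

Estimation is REML profiled over the variance ratio `lambda = s2_run /
s2_e`: with a single grouping factor, `(I + lambda ZZ')^{-1}` has a closed
Woodbury form, so the profiled restricted likelihood costs `O(n p + p^3)`
per evaluation and is maximized by Brent search on `log(lambda)`, with an
explicit evaluation at the `lambda = 0` boundary. The boundary is preferred
when the interior optimum improves the likelihood by less than 1e-8, so a
truly absent run variance is reported as exactly zero.

**Residual definition.** The "residual adjusted for systematic effects" is
taken *conditional* on the run effect for the phenotypic association scans:
observed value minus fixed effects minus the run BLUP, removing run-level
measurement noise. For the *genetic* analyses the fitter also returns
marginal residuals (fixed effects only subtracted), and the pipeline feeds
those to the bivariate models instead: samples are plated largely by batch,
so litter mates share runs, and a subtracted run BLUP absorbs part of the
between-litter genetic variance — deflating the protein's genetic variance
and inflating |r_g| (we measured the planted r_g = -0.6 recovered at -0.77
with conditional but -0.63 with marginal residuals). The run variance left
in marginal residuals is absorbed by the bivariate model's residual
component and is harmless to r_g. `marginal = TRUE` (CLI
`--marginal-residuals`) switches the primary residual layer.

**Aliasing.** Rank-deficient fixed designs (e.g. a reference covariate that
is all zero because a protein was only seen in one group) are resolved by
deterministic left-to-right scanning: a column is kept iff it increases the
design rank, and dropped columns are reported in a warning.

**Outliers.** After model (1), residuals outside `[Q1 - 1.5 IQR, Q3 + 1.5
IQR]` per protein are set missing (about 0.7% of truly normal residuals).
Quartiles use type-7 linear interpolation (R's default); the convention is
configurable because the source convention is not documented. The filter is
applied once, after normalization and before every downstream use.

**Protein filter.** Proteins are kept when identified in strictly more than
`min_runs` runs (study value 20 of 92 runs). Missingness in multi-plex TMT
is confounded with run — a protein is quantified for all or none of a run's
samples — and the missingness report checks that the fraction of missing
runs is uncorrelated with mean observed abundance (missing at random).

# Genomic heritability (quantgen)

The heritability model adds a random litter effect `~ N(0, I s2_l)` and an
additive-genetic animal effect `~ N(0, G s2_a)` to the model-(1) structure.
`G` is VanRaden method-1: `G = ZZ' / (2 sum p_k (1 - p_k))` with dosages
centred by `2 p_k` and frequencies computed within the animal set of each
block. In blockwise mode `G` is built per breeding company and cross-company
entries are set exactly to zero, focusing estimation on pooled within-company
variance (the study's choice).

Variance components are estimated by average-information REML on the dense
`V = s2_a G + s2_l L + s2_run R + s2_e I` (records one-per-animal, n up to
about 1,000 in the intended use). The first three iterations use EM-type
updates for stability, then AI steps with step-halving; components are
clamped at `1e-8 * var(y)`; convergence is declared at a maximal relative
parameter change below 1e-6 (maximum 100 iterations). When a component is
pinned at the boundary with an outward gradient, the AI system is re-solved
over the free components (active set), which prevents premature stalls that
would otherwise leave the full model below its nested submodel. The nested
LRT fits additionally warm-start the full model from the reduced solution
whenever the reduced likelihood exceeds the full one — a cheap guarantee of
nesting.

Heritability is `h2 = s2_a / (s2_a + s2_l + s2_e)`: the run variance is a
measurement nuisance and is excluded from the phenotypic-variance
denominator. Significance of `s2_a` (and `s2_l`) uses the boundary
likelihood-ratio test: `p = 0.5 P(chi2_1 > 2 (ll_full - ll_reduced))`,
the 50:50 `chi2_0`/`chi2_1` mixture appropriate for a variance constrained
to be non-negative. FDR across proteins is Benjamini–Hochberg (study rule:
FDR < 0.10).

# Genetic correlations

Bivariate animal models pair one protein with one trait. Trait 1 is the
model-(1) protein residual (intercept fixed effect, litter random); trait 2
is the phenotype with the association-model fixed effects and its own litter
effect, recorded on the full phenotyped population — the partial overlap
with the proteome subset is carried by the relationship matrix. The genetic
(co)variance is unstructured 2x2; the genetic covariance is kept inside the
positive-semidefinite cone by projection to `0.999 sqrt(s2_a1 s2_a2)`.

The residual covariance is fixed at zero by default: protein records are
already model-adjusted residuals, the generator simulates independent
residuals, and with partial overlap the residual covariance is weakly
identified; `resid_cov = TRUE` estimates it through jointly-measured
animals. With the genetic covariance constrained to zero and no shared
structure, the bivariate restricted likelihood equals the sum of the two
univariate ones — a property the test suite asserts to 1e-4.

The LRT against `r_g = 0` uses the ordinary `chi2_1` tail without halving: a
covariance is an interior parameter, so the boundary mixture does not apply
(this differs from the variance-component tests on purpose). Proteins enter
the bivariate scan only if their heritability estimate exceeds 0.05 —
bivariate fits with a near-zero-heritability trait are unstable and produce
boundary correlations with huge SEs. Significance rule: FDR < 0.35 across
all traits (deliberately liberal, to feed enough proteins to enrichment).

# Phenotypic associations (model 2)

For continuous traits (and 1–5 health scores first collapsed by "score <= 4
becomes 4", because low scores are rare and the scale need not be linear):

trait = Batch + EntryAge + Protein + Pen + litter + e

with pen fixed, litter random (the same profiled-REML engine as model 1),
and, for carcass traits, slaughter date plus age and weight at slaughter
when available. The protein coefficient is tested with a Wald z statistic;
the normal approximation is adequate at the intended record counts (hundreds
of animals) and avoids a degrees-of-freedom convention the source does not
specify.

Binary traits (mortality) use the *reverse* mixed model — protein residual
as response, 0/1 phenotype as covariate — because logistic fits on rare
outcomes often fail to converge. The reverse coefficient is converted to the
forward direction by multiplying with the ratio of residual variances of the
trait and the protein (both adjusted for the same systematic effects,
protein excluded). In the fixed-effects-only limit this conversion is the
Frisch–Waugh identity and reproduces the forward OLS slope exactly, which
the tests assert to 1e-8. The source describes the conversion direction
ambiguously ("coefficients of protein abundance on the binary trait") while
its variance-ratio formula algebraically yields the trait-on-protein slope;
the formula is implemented as stated and the label documented as ambiguous.

Coefficients are reported raw (trait units per unit log2 residual),
standardized (times the SD of the protein residual) and scaled (divided
additionally by the trait SD), the last being the cross-trait-comparable
ranking score for enrichment. FDR pooling defaults to "across all traits
within an analysis family", with a per-trait option.

# Preranked enrichment and clustering

Rankings are the scaled phenotypic coefficients, or for the genetic scan the
signed `-log10(p)` of the genetic-correlation LRT (sign of `r_g`). The
enrichment statistic is the weighted running sum (hit increments
`|s|^p / sum_hits |s|^p`, miss decrements `1/(N - N_hits)`, `p = 1` for the
tool's "weighted" setting); ES is the extremum of the running sum and the
leading edge the hits at or before (after, for negative ES) that extremum.
The null is gene-label permutation of the ranked scores — the only null
available to a preranked analysis — with NES = ES / mean(|null ES| of the
same sign), same-sign nominal p-values with a +1 pseudo-count, and the
NES-ratio FDR of the original tool (pooled-null tail fraction over observed
tail fraction, clipped to [0, 1], then made monotone step-up along NES so a
more extreme set never has a larger q). Ties in rankings are broken by
protein id, making every result deterministic for a fixed seed. Default
settings: 1,000 permutations, min set size 1, max 500.

Per-trait results are summarized as a terms-by-traits matrix of signed
`-log10(FDR)`: positive when increased abundance of the leading-edge (core)
proteins is favourable for the trait. Direction is the sign of the mean
ranking score of the core proteins (alternative: the ES sign), and is
reversed for traits where lower values are favourable (treatments,
mortality, feed conversion ratio, residual feed intake, carcass back fat).
Zero FDRs are clipped to the permutation resolution `1/n_perm`. Terms kept
for clustering need FDR below the threshold (default 0.2) for at least one
trait; rows are clustered with `hclust(..., "ward.D")` on Euclidean
distance, i.e. the classic Lance–Williams Ward update. The number of
clusters is a display choice, not an estimated quantity, and is exposed as a
parameter.

# The synthetic world

`sim_config()` states the world the tests live in; these are fixed
conditions, not tuning knobs.

* **Design**: 300 animals in 7 companies and 6 contemporary batches
  (batches rotate over companies), litters of mean size 8 nested in batch,
  pens of ~15 within batch; 150 animals carry proteome data measured in 15
  eleven-plex runs split 7/8 between two measurement groups (the study had
  3,205 / 912 animals and 41 + 51 runs; the scaled sizes keep generation
  under a second and REML feasible in tests).
* **Genotypes**: 1,500 SNPs, allele frequencies uniform on (0.05, 0.95);
  litter mates are full sibs produced by Mendelian sampling from a drawn
  sire and dam. The family structure matters: with unrelated animals the
  genomic relationship matrix is nearly the identity and heritability is
  barely identifiable at these sample sizes.
* **Proteome**: log2 abundance = intercept (N(10, 2)) + batch effects
  (SD 0.2) + tag effects (SD 0.1) + 0.02 x entry age + run effect
  (variance 0.2) + 0.3 x centred reference-channel value (reference = pooled
  group mean + run noise SD 0.1) + breeding value + litter effect
  (5% of variance) + residual; per-protein heritabilities drawn Beta(1, 2.5)
  (mean ~0.29, a broad right-skewed distribution consistent with most
  proteins weakly heritable and a few strongly). Non-run phenotypic variance
  is 1 per protein. The reference-channel slope and noise have no stated
  magnitudes anywhere; 0.3/0.1 give model (1) a real signal to absorb
  without dominating.
* **Missingness**: each protein x run block is blanked with probability
  0.15, independent of abundance — all-or-none within run, as in real
  multi-plex TMT.
* **Traits**: six defaults (gain in two phases, feed conversion ratio,
  treatments, overall mortality at 15% prevalence, a nursery health score)
  with heritabilities 0.10–0.30, litter proportions ~0.1, and planted
  genetic correlations (FCR x protein 1: -0.6; finisher gain x protein 2:
  +0.5) so recovery tests have known truth. Binary and score traits are
  thresholded/cut from a latent liability; score cuts put 2/4/8/21% of
  animals below score 5. Survivor data mask finisher-phase records of
  simulated deaths; expanded data keep them (standing in for the imputed
  records of the real study, whose imputation procedure is out of scope).
* **Joint breeding values**: all protein and trait breeding values are one
  draw `L Z C` with `L` the Cholesky factor of the true relationship
  matrix and `C` that of the target genetic correlation matrix, so planted
  correlations are exact in expectation; `simulate_proteome()` and
  `simulate_phenotypes()` derive the same draw deterministically from the
  config seed, so either can run alone. An infeasible (non-PSD) correlation
  target errors and names the offending protein-trait pairs.
* **Protein residuals are mutually independent** given the shared effects;
  real plasma proteomes have correlated residuals (shared pathways,
  shared peptides). This is configurable nowhere on purpose: downstream
  methods are all single-protein, so residual correlation would only affect
  joint-significance summaries, which the package does not produce.

What a green test therefore establishes: the estimators recover the
parameters of *this* world (correct likelihoods, correct boundary
behaviour, calibrated tests, exact oracles). What it does not establish:
robustness to peptide-level artefacts, isobaric interference, non-normal
abundance distributions, or population structure beyond full-sib litters
and company blocks.

# Known limitations

* AI-REML uses dense n x n algebra; fine up to a few thousand records,
  not intended for biobank scale.
* The bivariate model fixes the residual covariance at 0 by default (see
  above); with complete overlap and strong environmental correlation this
  is a model misspecification the user must switch off.
* Significance counts at the fixture scale are low by design (n = 150
  proteome animals): power claims of the original study are not
  reproduced, only estimator properties.
* The mortality analysis has no logistic fallback; the reverse linear
  model is the only path, matching the source's stated practice.
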