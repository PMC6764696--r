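---
title: "The five-sector resource-allocation model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The five-sector resource-allocation model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sector5)
```

# The model

Bulk expression of a growing cell population reflects a resource-allocation
problem: polymerases, cofactors and ribosomes are limited, so what one gene
gains another loses.  Working on *fractional* expression — each gene's share
of the summed signal in a sample — makes this reallocation explicit.  For a
raw signal $g_i$ the package uses

$$f_i = \log_{10}\!\left[10^6 \, \frac{g_i}{\sum_j g_j}\right],$$

so that $\sum_i 10^{f_i} = 10^6$ in every sample and the values are
invariant to per-sample scaling (`fractional_expression()`).

Within one nutrient condition, profiles across growth rates are decomposed
by SVD.  Empirically the first two components dominate, and they have a
physical reading: $\vec v_1$ is a flat baseline, $\vec v_2$ a monotone
growth direction, so each gene is approximated by

$$\vec f_i \approx a_i \vec v_1 + b_i \vec v_2,$$

with $a_i$ the growth-independent baseline share and $b_i$ the monotone
response to growth (`nutrient_svd()`).  Sign indeterminacy of the SVD is
resolved by requiring $\sum_t v_{1,t} > 0$ and a positive correlation of
$\vec v_2$ with growth rate; the data decide nothing else.

Two classification rules then partition the genome into five sectors:

* **Specificity** (between two nutrients): a gene is *specific* when its
  baseline loading moves by more than $k$ standard deviations (default
  $k = 3$) of all genes' signed differences (`pairwise_specificity()`).
* **Growth response** (within one nutrient): the genes with the
  `n_invariant` smallest $|b_i|$ (default 2500 at genome scale) are
  *invariant*; the rest are *positive* or *negative* by the sign of $b_i$
  (`growth_response_class()`).

`aggregate_partition()` combines the calls: a gene nonspecific in at least
`nonspecific_min` of the 15 nutrient pairs (default 9, the strict
more-than-half reading; 8 gives the at-least-half reading) is nonspecific;
nonspecific genes invariant in at least `invariant_min` of the 6 nutrients
(default 4) are **invariant**, the rest are **positive** or **negative** by
majority vote of their per-nutrient classes; specific genes are
**activated** or **repressed** by the same vote.  Exact vote ties fall to
the sign of the summed loadings — a deterministic rule that uses magnitude
information (zero total falls to negative).

The same five sectors can be read off promoter-activity (PA) libraries:
`partition_pa()` ranks each growth transition by the distance of the
fractional-activity ratio to one ($|\log r|$ by default; `distance =
"linear"` preserves the literal $|r - 1|$ reading), takes the top
`n_invariant = 350` as invariant and the `n_specific = 50` most extreme in
each direction as activated/repressed, with promoters below an activity
floor ($10^{-4}$) in both conditions set aside.  Ranking ties break by
gene identifier; a promoter active only in the high-growth condition gets
ratio $+\infty$ and ranks first among activated (limit behaviour).  The
per-gene *typical class* is the modal label over transitions; modal ties
take the label of the highest-growth transition.

# Null machinery

All "is this sector different" questions use one engine
(`sector_randomization_null()`): genes are randomly reassigned to sectors,
preserving sector sizes, and the observed per-sector statistic is
standardized against the randomization sample (10000 draws by default;
`exact = TRUE` enumerates all assignments on small instances).  When the
null has zero spread the z-score is reported as 0 (observed equals the
null) or signed infinity — never `NaN` — so downstream thresholding is
total.  Enrichment of discrete overlaps uses the upper-tail hypergeometric
distribution with Holm step-down adjustment; distribution comparisons use
the two-sample Kolmogorov–Smirnov test (asymptotic p-values; the sample
sizes here are in the thousands).

# Regulatory coherence

The *regulatory coherence* of a gene, per nutrient, is the mean Pearson
correlation between its profile across growth rates and the profiles of
the TFs that regulate it (`regulatory_coherence()`).  Constant profiles
have undefined correlation and are excluded.  Significance comes from a
permutation null (`coherence_null()`, 1000 permutations by default): each
gene's profile is independently permuted across the growth-rate positions,
which preserves every gene's value distribution while destroying growth
alignment.  Swapping whole profiles between genes is available via
`mode = "across_gene"`; the within-gene default is the stricter reading,
since it also preserves each gene's variance.  A gene is significantly
coherent when its one-sided z exceeds 2; across nutrients a gene counts as
coherent when significant in at least one condition.  With no planted
signal the call rate is the normal upper tail beyond 2, about 2.3%.

`tf_sector_enrichment()` asks which TFs act on coherent genes of a
particular sector more than chance expects: for each TF the proportions of
its coherent targets per sector (per-TF normalization) are standardized
against partition-label randomization.  `network_hierarchy()` condenses
strongly connected components and strips sink layers iteratively; levels
count from the bottom, and every edge between components points downward.

# Chromatin analyses

Continuous promoter scores (nucleosome fragility, cis/trans variability,
expression, noise) and binary features (TATA, TFIID dominance, short
nucleosome-free regions) are summarized per sector with the randomization
engine.  The chromatin-modifier compendium (mutant × gene log2 ratios) is
normalized to unit variance per profile (means untouched); the
*chromatin regulatory effect* of a modifier on a gene group is the mean
absolute normalized ratio, contrasted between specific and nonspecific
genes (`cre_strength()`).

`modifier_signed_effects()` examines the signed mean effect of each
modifier on the negative, invariant and positive sectors.  The
permutation sample provides the per-sector scale; significance is assessed
for the observed mean against zero — the no-effect point of a log2
ratio — using the permutation SD corrected for finite-population
shrinkage.  This choice needs a word.  A label-permutation band is
centered on the modifier's own grand mean, so it can only see *contrasts*
between sectors: "expression of everything but negative genes drops"
(an activator) and "expression of negative genes rises" (a repressor) are
then indistinguishable, because the two patterns differ only by a global
shift that the permutation removes.  Real compendium profiles are
approximately mean-centered by array normalization, so there the two
readings coincide; for planted, uncentered effects only the zero-centered
band recovers the intended classes.  `center = "null_mean"` restores the
literal deviation-from-grand-mean band, and `band = "quantile"` replaces
the 2-SD band by the central 95.45% of the null sample.  Classification:
*dual* if the positive-sector mean is significantly negative and the
invariant or negative mean significantly positive; *activator* if both the
invariant and positive means are significantly negative and no sector is
significantly positive; *repressor* if the negative mean is significantly
positive and no sector significantly negative.  Requiring both downward
calls for an activator keeps the pure-noise misclassification rate within
the few-percent range a 2-SD rule implies.

Mutant profiles are contaminated by a slow-growth expression signature
(most chromatin-modifier deletions grow slowly).  The signature is
estimated from a reference matrix as the rank-1 SVD approximation's
largest-norm column, normalized to unit length
(`slow_growth_signature()`), and removed from each profile by a
Gram–Schmidt projection $p \mapsto p - (p \cdot s)\,s$
(`remove_slow_growth()`), leaving profiles exactly orthogonal to the
signature.  Removal happens before unit-variance normalization, then
variance is renormalized; the projection also removes whatever part of a
genuine effect overlaps the signature, a deliberate, conservative bias.

# The synthetic-data generator

`simulate_dataset()` plants ground truth for every pipeline input:

* **Expression** — per nutrient, $a_i \vec v_1 + b_i \vec v_2$ plus
  Gaussian noise on the fractional-log scale, with $\vec v_2$ a centered,
  linearly increasing unit vector over the growth rates (the simplest
  monotone basis).  Defaults emulate a chemostat design: six nutrients,
  six dilution rates 0.05–0.30/h, 5000 genes, sector composition
  (repressed, negative, invariant, positive, activated) =
  (1.1%, 40%, 28%, 30.6%, 0.3%), growth slope 0.5, noise 0.025 (5% of the
  slope).  Specific genes receive a staircase of baseline shifts across
  nutrients (unit `baseline_shift_sd`, default 1) so every pairwise
  comparison separates them.
* **Feasibility of the 3-SD rule.**  The pairwise threshold is
  $3\,\mathrm{SD}(d)$ of the very differences being tested, hence
  *scale-free* in the shift size: with a specific fraction $q$ and
  equal-magnitude shifts the threshold is about $3\sqrt{q(1-q)}$ times the
  shift, which exceeds the shift itself once $q \gtrsim 0.127$.  Above
  that bound **no** shift, however large, is ever called — the
  configuration validator warns about such compositions.  The default
  composition ($q \approx 0.014$) leaves a three-fold margin.
* **Normalization vs rank.**  Exact sum-to-one normalization is nonlinear
  on the log scale, so it adds a per-sample shift that leaks about
  $10^{-5}$ of variance beyond rank 2.  The default output keeps the
  normalization invariant; `normalize_fractions = FALSE` returns the
  exactly rank-2 planted matrix for closure checks.  Exact recovery of
  planted loadings additionally requires the loading vectors to be
  uncorrelated across genes — otherwise the singular directions rotate
  within their span — which the recovery fixtures realize with a balanced
  composition and a flat baseline.
* **Marginal specificity.**  `specificity_mode = "marginal"` plants a
  small cohort whose baseline pattern clears the per-pair threshold in
  exactly 7 of the 15 comparisons (nonspecific in 8), so the gene flips
  between specific (strict `>8` rule) and nonspecific (`>=8` rule).
  Because per-pair thresholds scale with the pair's separation in the
  majority staircase cohort, the pattern is expressed in
  threshold-per-unit-separation units, (0, 0, 0, 2.65, 3.25, 4.45), chosen
  so every in/out margin is at least 20% of the local threshold.  These
  genes carry a reduced growth loading to stay clear of the invariant
  quota without inheriting the baseline contamination that correlated
  loadings induce.
* **Network** — targets draw regulator counts from Poisson means
  mirroring the observed gradient (specific 5.06, growth-dependent 3.3,
  invariant 2.56); an edge is *coherent* with probability
  `coherent_fraction`, drawing its TF from the target's growth class so
  their profiles correlate positively.  A planted coherent target is a
  non-invariant gene all of whose edges are coherent.
* **Compendium** — 170 mutants in three behaviour classes (activator:
  invariant and positive genes down; dual: negative up, positive down;
  repressor: negative up), effect size 0.3 on unit noise, with
  twice-magnitude noise on specific genes (stronger chromatin effects
  there).  `slow_growth_lambda` adds a shared slow-growth profile (a
  stress-like sector tilt plus gene-level variation, unit RMS) with
  per-mutant amplitudes; the reference matrix carries the same profile as
  its dominant mode.
* **Promoter activity** — fractions of the form
  $p_i (1 + \gamma_i x_c)$ with mirrored gene pairs so columns sum to one
  exactly; tiers of $|\gamma|$ (0, ~0.35, ~0.65) separate invariant,
  positive/negative and activated/repressed promoters, a handful of
  promoters sit below the activity floor everywhere, and bounded baseline
  spreads keep every active promoter above the floor in all conditions.
* **Tracks** — sector-tilted continuous scores and Bernoulli binary
  features (fragility, trans-variability, expression high / noise low on
  positive genes; TATA on negative/repressed; TFIID and shNFR on
  positive/invariant), plus stress-response-like gene sets drawn inside
  the negative/repressed (induced) and positive (repressed) sectors.

A single master seed drives one derived stream per generator, so partial
runs reproduce exactly.  What the generator does **not** emulate: real
yeast gene names and chromosomal structure, absolute mRNA counts,
cell-cycle population structure, heteroscedastic microarray noise (the
Gaussian choice on the fractional-log scale is a stand-in; no noise model
is implied by the data themselves), TF combinatorics beyond class-matched
correlation, and dependence between the six inputs beyond the shared
sector labels.  Passing recovery tests therefore demonstrates the
correctness and calibration of the machinery, not the biological validity
of any particular dataset.

# Numerical choices and degenerate inputs

* Zero signals map to $-\infty$ fractional values; affected genes are
  dropped from that nutrient's SVD and from the genome-wide partition
  (complete-case; no imputation model is assumed).
* All ranking ties break by gene identifier; exact unit ratios beyond the
  invariant quota and zero loadings beyond it are labelled invariant with
  a degeneracy warning, so labels always partition the gene set.
* z-scores with zero null spread use the 0 / signed-infinity sentinel.
* The scaling fit (`class_scaling()`) is least squares through the origin
  with the uncentered $R^2$, reported against the growth-rate-ratio null.
* Problem sizes: the test suite runs in well under a minute on one CPU
  (fixtures of 400–3000 genes, nulls of 300–2000 draws); the acceptance
  script uses 2000–5000 genes and 1000–2000 draws per null, a scale at
  which every calibration quantity is stable to a couple of percent.

# Known limitations

The genome-scale invariant quota (2500) does not rescale automatically
with gene-universe size — pass the value appropriate to your instance.
The aggregation counts assume one expression series per (nutrient, rate);
replicate handling is the caller's responsibility.  KS p-values are
asymptotic and the coherence null is conditional on the observed network;
both are adequate at the scales above but should be revisited for very
small designs.  The PA classifier's quota contract requires enough
rankable genes in both directions; directional shortages are filled as far
as possible with a warning.
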