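---
title: "Modelling gut-microbiome perturbation, recovery and covariation with mbrecov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gut-microbiome perturbation, recovery and covariation with mbrecov}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbrecov)
```

## The analysis problem

`mbrecov` analyses longitudinal 16S-style count tables from perturbation
studies: animals sampled densely around a course of a broad-spectrum
antibiotic (a treatment window of days 0–6, with optional fecal
transfaunation — re-administration of the animal's own pretreatment feces —
on day 7) and sparsely through a months-long recovery, in three experimental
groups (untreated controls `CON`, antibiotic-only `ABX`, antibiotic plus
transfaunation `ABXFT`). Four questions structure the pipeline:

1. **Alpha diversity**: how hard does within-sample diversity crash, and how
   fast does it rebound?
2. **Beta diversity**: how far does each animal's community move from its
   own pretreatment baseline, and does it come back?
3. **Covariation**: which taxon pairs rise and fall together once the
   community is perturbed — the candidate keystone taxa and
   antibiotic-resistant guilds?
4. **Resistome**: how do antibiotic-resistance-gene (ABR) loads and family
   proportions track treatment?

Every stage is exercisable end-to-end on synthetic data with planted ground
truth, which is how the package tests itself.

## Preprocessing and compositional treatment

Sequencing counts are compositional: only relative information survives
library-size normalisation. The pipeline therefore works on the centered
log-ratio (CLR) scale,

$$\mathrm{clr}(x)_j = \log x_j - \tfrac{1}{D}\sum_k \log x_k,$$

where covariance between taxa is meaningful, and propagates count
uncertainty by Dirichlet Monte-Carlo resampling: each animal's series is
replicated `n_instances` times (default 128), each replicate drawing a
composition per timepoint from $\mathrm{Dirichlet}(\text{counts} + 0.5)$
before the CLR transform. The 0.5 prior per cell (a Jeffreys-style
concentration, the ALDEx2 convention) also resolves zeros, so the CLR is
always defined.

Filters follow the boundary semantics of their definitions literally:
samples with fewer than 10,000 reads are discarded (a sample with exactly
10,000 is kept); rarefaction to 15,000 reads is uniform subsampling
*without replacement* (hypergeometric, QIIME2 semantics), so rarefied
presence/absence profiles are comparable across depths; taxa present in
fewer than 5 samples are dropped (exactly 5 survives); genera holding less
than 0.01% of total counts fold into an `Other` row, and the fraction of
counts moved is logged. For the association analysis the chain is: drop
pretreatment samples, drop rare taxa, collapse to genus, fold `Other` —
applied to raw (unrarefied) counts, because the Dirichlet resampling models
depth noise directly. Whether the low-abundance threshold applies before or
after genus collapsing is not uniquely determined by its definition; we
apply it after (the order in which the steps are stated), and the chain
records counts removed at each step so the choice is auditable.

## Diversity

Shannon diversity defaults to log base 2 (bits), with the base recorded on
the output; natural log is available, since the classical Shannon–Weaver
index uses it. Unweighted UniFrac is implemented from the tree: a branch
belongs to a sample when any descendant leaf has count > 0, and the distance
is the branch length unique to one sample divided by the branch length
spanned by either. Presence is assessed after rarefaction — that is what
makes presence comparable between samples of different depth. A brute-force
per-edge enumeration oracle (independent code path) confirms the postorder
implementation exactly on random trees. Distance-from-baseline uses each
animal's day −4 sample (the transfaunation inoculum day) as its baseline,
falling back to the nearest pretreatment sample with a logged message.
Ordination is classical PCoA (double-centered $-\tfrac12 D^2$,
eigendecomposition), and the baseline group comparison is a tie-corrected
Kruskal–Wallis test.

## Trajectory smooths and group contrasts

Group trajectories (for alpha diversity or distance-from-baseline) are
penalized cubic B-spline smooths per experimental group — interior knots at
day quantiles (10 by default), second-difference penalty — plus
ridge-penalized animal-level intercepts for the repeated-measures structure,
fitted by penalized least squares with both smoothing parameters chosen by
GCV on a logarithmic grid. Pointwise 95% bands come from the Bayesian
covariance of the penalized fit, $\sigma^2 (X'X + S_\lambda)^{-1}$. The
test suite cross-checks the fitted group means against an independent
additive-model fit (`mgcv::gam` with factor-by smooths and a subject random
effect).

Group contrasts are permutation tests: the statistic is the integrated
squared difference between two fitted group smooths over the common day
range; the null permutes group labels at the *animal* level (animals, not
samples, are exchangeable under repeated measures), refitting at the
observed fit's smoothing parameters; $p = (1 + \#\{T_{perm} \ge
T_{obs}\})/(1 + n_{perm})$. This replaces parametric spline t/F tests with
an inference whose validity needs only animal exchangeability; calibration
(type-I error at most ~1.6× nominal) and power (≥ 80% for a persistent
2-SD group offset with 5 animals per group) are verified by simulation in
the test suite.

## The covariation engine

The core model treats one animal's CLR matrix $Y$ ($D$ taxa × $T$
timepoints at days $t$) as matrix-normal,

$$Y \mid \Sigma \sim \mathcal{MN}(M,\; \Sigma,\; K), \qquad
K = \sigma_k^2\, k_{SE}(t, t'; \ell) + \lambda I, \qquad
\Sigma \sim \mathcal{IW}(\nu, \Xi),$$

with $M$ the per-taxon row mean. The squared-exponential column covariance
$K$ absorbs the irregular temporal spacing and autocorrelation of the
sampling schedule; the taxon–taxon covariance $\Sigma$ is the inference
target. Conjugacy gives the exact posterior

$$\Sigma \mid Y \sim \mathcal{IW}\!\left(\nu + T,\; \Xi + (Y - M) K^{-1} (Y - M)'\right),$$

verified in the tests against the closed-form posterior mean with $K = I$.
Covariance draws are converted to correlation matrices and pooled across
Dirichlet instances and across the animals of a group — animals are
biological replicates, and pooling draws approximates a group-level
posterior without inventing a hierarchical prior. Edges are summarised per
unordered pair by the posterior median and equal-tailed 95% credible
interval; an edge is *significant* when the interval excludes zero and
*strong* when $|\tilde\rho| > 0.5$ (strict), the two flags stored
independently.

Parameter defaults, with reasons:

* **Lengthscale $\ell$ = 10 days** — between the dense (2-day) and sparse
  (weekly–monthly) sampling intervals, so treatment-phase dynamics are
  correlated but the long recovery tail is not one rigid curve. A
  sensitivity sweep is a one-line loop over `gp_config(lengthscale = ...)`.
* **Nugget $\lambda$ = 0.1** — observation noise on the CLR scale; also
  keeps $K$ invertible when days repeat.
* **Prior $\nu = D + 3$, $\Xi = I$** — the smallest degrees of freedom with
  a proper mean, identity scale.
* **Kernel variance $\sigma_k^2$ = 0.05** — in a matrix-normal model only
  the product $\Sigma \otimes K$ is identifiable, so this parameter is
  really the weight of the prior scale $\Xi$ relative to the whitened
  evidence $Y K^{-1} Y'$. A smooth kernel with $\ell = 10$ leaves a
  15-point series only ~4 effective temporal degrees of freedom; at
  $\sigma_k^2 = 1$ a unit prior scale would contribute as much as a quarter
  of the evidence and shrink every correlation far toward zero. At 0.05 the
  prior sits about two orders of magnitude below the evidence of a
  unit-variance series — weakly informative in effect, not just in name.
* **Equal-tailed intervals**, not HPD: the simplest reproducible convention.
* **Correlation-then-pool**: each covariance draw is converted to a
  correlation matrix before pooling across animals, so animals with
  different overall variability contribute on a common scale.

Per-taxon CLR trajectories (median and 50%/95% bands across instances) are
available via `log_ratio_trajectory()`; a taxon whose log ratio *rises*
while the community crashes is the signature of antibiotic resistance —
its abundance need not increase, it only needs to fall less than the mean.

## The synthetic-data generator

The generator inverts the analysis model so that ground truth is planted on
exactly the scale the analysis measures. Per animal, latent log abundances
are matrix-normal with row covariance `latent_sd^2 * true_correlation`
(identity plus disjoint ±0.8 pairs by default) and column covariance a
squared-exponential kernel (lengthscale 10 days) over the sampling days;
counts are multinomial from the softmax of the latent state at a uniform
random depth. Design choices that matter:

* **Sampling days** `-6, -4, -2, 0, 2, 4, 6, 8, 10, 13, 20, 34, 62, 90,
  118`: dense through the treatment window, sparse through recovery,
  mirroring a ~125-day study with an 11-animal cohort split 4/4/3 across
  CON/ABX/ABXFT.
* **Perturbation = 10 natural-log units** subtracted from susceptible taxa
  during days 0–6, decaying exponentially afterwards at a group-specific
  rate (ABX 0.05/day, ABXFT 0.2/day). Because counts are compositional,
  only the shift *relative to the unperturbed (resistant) taxa* matters: a
  uniform shift of all taxa would be invisible. Ten log units (~4 orders of
  magnitude, consistent with published log-reductions of susceptible gut
  taxa under beta-lactams) lets the resistant minority dominate the
  community and pushes typical susceptible taxa below the detection limit
  of a 15,000-read sample — reproducing both the drastic alpha-diversity
  crash and the large presence-based (UniFrac) shift that real antibiotic
  courses cause.
* **Resistant taxa** (~5% of taxa) are left unshifted; their CLR rises
  during treatment purely compositionally — the planted analogue of
  *Bacteroides*/*Parabacteroides*.
* **Transfaunation** is a convex blend (weight 0.5) of the post-day-7
  latent state with the animal's own day −4 state. No quantitative
  engraftment model exists to copy; the blend weight is a free parameter of
  the design, not an estimate.
* **Base abundance spread** `base_abundance_sd = 2` (log scale) emulates a
  raw, heavy-tailed feature table whose rare taxa flicker around the
  rarefaction detection limit — this is what gives unweighted UniFrac its
  presence dynamics in unperturbed controls. For studies of the association
  engine itself we set it to 1, emulating the narrower abundance range of a
  genus table *after* rare-taxon filtering and `Other` folding — the input
  the engine actually receives; with raw-table spread, planted pairs
  landing on rare taxa are masked by irreducible count noise, which is
  precisely the regime the pre-filters exist to exclude.
* The generator can export the latent CLR trajectories
  (`export_latent = TRUE`, off by default) so recovery tests can compare
  inferred correlations against the planted latent states, not just the
  counts.

What the generator does **not** emulate: read-level error, chimeras,
taxonomy misclassification, realistic phylogenetic signal in abundances
(the tree is random), time-varying correlation structure, or diet/season
covariates. Passing tests therefore demonstrate that the machinery recovers
what it assumes — planted smooth compositional dynamics — not that real
lemur data satisfy those assumptions.

## Resistome summaries

ABR gene tables (gene × sample counts, gene→family map over the
tetracycline, beta-lactam, aminoglycoside, macrolide, vancomycin,
multi-drug-resistance and sulphonamide families, plus per-sample total
reads) are summarised as per-sample family proportions, ABR relative
abundance (ABR reads / total reads), group × day means ± SEM over animals
(SEM reported missing for single-animal cells), and a qualitative
pre→treatment→recovery trend per group. The cross-sectional comparison of
ABR load against lifetime antibiotic exposure adds a permutation Spearman
test as a clearly-labelled quantitative aid — at six animals it is a
screen, not an inference.

## Numerical choices and degenerate inputs

* Rarefaction drops samples below the target depth rather than erroring.
* `clr_transform` refuses zeros — zeros are a resampling concern, upstream.
* The GP kernel refuses to factor when days repeat with `nugget = 0` and
  says so; the error names the fix.
* Quantiles are type-7 throughout (R default).
* A fully tied Kruskal–Wallis input returns H = 0, p = 1 rather than NaN.
* Samples with zero ABR reads yield all-zero family proportions with a
  warning, never NaN.
* All randomness flows from explicit seeds; `run_pipeline()` derives fixed
  per-stage offsets from one root seed, and the run report carries a hash
  of the analysis settings.

## Problem sizes used in the test suite

The simulation studies in the tests are sized to demonstrate the
statistical properties at desk scale: association calibration at D = 20
taxa, T = 15 timepoints, 3 animals, 32 Dirichlet instances and 50 draws per
instance over 20 seeds; planted-correlation recovery at D = 30 with 5
animals over 20 seeds; trajectory calibration and power at 200 simulations
with 199 permutations; UniFrac oracle equivalence on 50 random trees of up
to 12 leaves. Larger sizes change nothing structurally — every routine is
vectorised over draws and instances.

## Known limitations

* The inverse-Wishart posterior is exact only under the fixed kernel; the
  lengthscale is a modelling choice, not estimated. Misspecifying it
  rescales the effective sample size of the evidence (the sensitivity sweep
  helper makes this cheap to examine).
* Pooling correlation draws across animals approximates, but is not, a
  hierarchical posterior; with few animals the pooled interval mixes
  between-animal variation into the credible interval.
* Permutation contrasts need at least two animals per group, and their
  resolution is limited by the number of distinct animal-label
  permutations.
* The `Other` row and unresolved-rank labels are analysis constructs; they
  should not be interpreted as taxa.
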