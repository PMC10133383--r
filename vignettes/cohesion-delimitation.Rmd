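---
title: "Cohesion species delimitation: models, tests, and design choices"
author: "cohesiondelim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohesion species delimitation: models, tests, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohesiondelim)
```

## The problem

Under the cohesion species concept, an evolutionary lineage is a separate
species when its populations are neither *genetically exchangeable* (no
realistic potential for gene flow) nor *ecologically interchangeable* (they
do not occupy equivalent niche space). For dispersal-limited taxa such as
trapdoor spiders — deeply structured genetically but often morphologically
and ecologically homogeneous — delimitation decisions hinge on how these two
mechanisms are operationalized and combined. This package implements both
lines of evidence as explicit, testable procedures, plus the decision rules
that combine them, and a synthetic-data generator that provides ground-truth
worlds for every stage.

## Ecological interchangeability

### The SDM

Suitability is modeled as a Gibbs distribution over the cells of an
environmental raster stack: \(q_i(\beta) \propto \exp(\beta \cdot f(x_i))\),
where \(f\) maps a cell's (min–max normalized) layer values to maximum-entropy
feature classes — linear (L), quadratic (Q), pairwise-product (P), and hinge
(H) transforms. Coefficients maximize the penalized presence log-likelihood

\[\frac{1}{n}\sum_{p}\beta\cdot f(x_p) - \log \tfrac{1}{B}\sum_b e^{\beta\cdot f(x_b)}
  - \mathrm{rm}\sum_j \lambda_j |\beta_j|,\]

with the partition function estimated over a uniform background sample and
per-feature penalty weights \(\lambda_j = \max(\sqrt{s^2_j/n},\,10^{-3})\)
(\(s^2_j\) the presence sample variance of feature \(j\)) — the convention of
tying each feature's penalty to the sampling uncertainty of its presence
mean. Note that the weights *increase* with feature variance; this follows
the established maximum-entropy convention (a feature whose presence mean is
noisier is constrained more loosely). Optimization is proximal-gradient
(FISTA) with backtracking; convergence is declared when the relative change
in the penalized objective falls below `1e-6` (at most 500 iterations), and
non-converged fits are flagged and excluded from model selection.

Candidate models cross feature classes `{L, LQ, H, LQH, LQP, LQPH}` with
regularization multipliers `{0.5, 1, 2, 3, 4}` — 30 models, a conventional
candidate grid — and are ranked by
\(\mathrm{AICc} = 2k - 2\ln L + 2k(k+1)/(n-k-1)\), where \(k\) counts nonzero
coefficients, \(n\) is the thinned presence count, and \(\ln L\) sums log raw
(sum-to-one) suitabilities at presence cells. Ties break toward smaller
\(k\), then smaller rm, then feature-class code order. Occurrences are
thinned to one record per grid cell before fitting.

### Raw and logistic views

The **raw** view normalizes \(e^{\beta\cdot f}\) to sum to 1 over non-missing
cells; it is the operand of Schoener's
\(D = 1 - \tfrac12\sum_i |p_{A,i} - p_{B,i}|\). The **logistic** display view
is \(cr/(1+cr)\) with \(c = e^{H}\), \(H\) the Shannon entropy of the raw
distribution (the MaxEnt convention; for a uniform surface \(c\) equals the
cell count). Habitat-suitability thresholds (0.5, 0.75) are taken on this
view. We deliberately did *not* calibrate \(c\) so that the mean logistic
value at presences is 0.5: when occurrences are sampled proportionally to
suitability, presences already sit at the top of the surface and that
calibration caps the logistic near 0.7 — no cell could ever exceed a 0.75
threshold, making threshold-based background regions undefined.

### Background regions and the two randomization tests

Three "available environment" definitions per lineage: the minimum convex
polygon (MCP) of its occurrence points (cells whose centers fall inside or
on the hull; degenerate point sets fall back to a one-cell-width buffered
bounding box), and the cells whose logistic suitability strictly exceeds
0.5 or 0.75. Regions are authoritative as *cell sets*; polygons are derived
exports. The 0.75 region is nested in the 0.5 region by construction.

The **equivalency (identity) test** asks whether two niches are identical:
pool both lineages' occurrences, repartition at random into the original
sample sizes, refit both SDMs, and record the null D. It is one-tailed
(`p_lower = (1 + #{D_null <= D_obs}) / (reps + 1)`, rejection at
`p < 0.05`). The **background-similarity test** asks whether observed
overlap is higher (niche conservatism) or lower (niche divergence) than
expected given what is available to a lineage: replicates draw the lineage's
presence count of cells uniformly without replacement from its background
region, fit an SDM, and compare D against the other lineage's observed
surface; two-tailed at 0.025 per tail against the null quantiles. Replicate
fits reuse the observed models' selected feature class and regularization
multiplier (full per-replicate reselection is available via
`reselect_per_rep`, at ~30x the cost).

A structural asymmetry worth knowing: a high-suitability core region
(thresh75) draws pseudo-occurrences that are *more* environmentally
concentrated than the real, thinned occurrences, so its null overlap is
biased low and the test can effectively only detect conservatism. Divergence
is expressed by broad regions (MCP), whose interstitial unsuitable
environments push null models toward the landscape average. This mirrors the
empirical observation that MCP backgrounds obscure conservatism signals that
threshold backgrounds reveal — background choice is not a nuisance
parameter, which is exactly why the package computes all three.

## Genetic exchangeability

From per-locus phased alignments, variable biallelic sites are identified
(any site carrying a gap or ambiguity code, or more than two alleles, is
excluded entirely); five replicate matrices of one random SNP per locus
quantify sensitivity to site choice. Genotypes (0/1/2 allele counts, NA
where an individual lacks the locus) are one-hot encoded — three indicator
columns per locus, all-zero for missing — giving one row per individual.

The variational autoencoder compresses this matrix through encoder layers to
a 2-D Gaussian latent (mean and sd per individual) and decodes it back;
the loss is Bernoulli reconstruction cross-entropy plus KL divergence to a
standard-normal prior. The architecture (hidden widths `max(32, d/10)` and
16, ELU activations, full-batch Adam at learning rate `1e-3`, 500 epochs,
implemented natively with manual backpropagation — no deep-learning backend
is required) targets the few-dozen-individual regime; all values are
overridable. Three replicates per SNP set are trained with derived seeds and
the lowest-final-loss replicate is kept. Morphometric tables take the PCA
route instead: log transform, mean imputation, centering and unit scaling,
with a deterministic sign convention.

The qualitative "separate vs overlapping clusters" call is operationalized:
**separate** iff the mean silhouette width of the lineage labels is ≥ 0.35
*and* the adjusted Rand index of k-means (k = number of labels) against the
labels is ≥ 0.9. Both thresholds are recorded in every verdict; they are
package-defined quantifications of a judgment that is usually made visually.

## The decision engine

Genetic exchangeability is **rejected** iff (allopatric pair AND separate
molecular clustering) OR (parapatric pair AND separate clustering AND an
asserted barrier to gene flow). Molecular verdicts from multiple SNP
datasets aggregate by majority, ties failing toward non-rejection;
morphology is recorded but non-decisive. Barrier presence is always
user-asserted metadata. Sympatric pairs (an extension beyond the source
framework) reject only with separate clustering plus an explicit
reproductive-isolation assertion. Ecological interchangeability is
**rejected** iff the equivalency test rejects identity AND every similarity
direction used indicates divergence; the headline verdict uses a
configurable background method (default thresh75), with all methods
reported. Two policies map verdicts to conclusions: `conservative_both`
(separate species only when both mechanisms are rejected — the
conservative reading) and `flowchart_either`. The former never yields more
species than the latter.

## The synthetic worlds

The generator states worlds; it is not a tuning dial.

* **Climate**: Gaussian-kernel-smoothed white noise per layer, standardized;
  inter-layer correlation imposed by empirical whitening followed by mixing
  through the symmetric square root of the target matrix. Geographic space
  is a planar unit grid — the analysis is cell-based, and no CRS math is
  carried.
* **Occurrences**: cells drawn with probability proportional to an
  axis-aligned Gaussian niche
  \(\prod_k \exp(-(x_k-o_k)^2/2\tau_k^2)\), jittered within the cell.
  Identical niches make lineages statistically exchangeable — the
  equivalency test's null world. Presets use \(\tau = 0.5\) (layer-sd units)
  with off-center optima so that suitable habitat is a small fraction of the
  extent, as for narrow-range endemics modeled over a broad cropped region;
  divergent presets separate optima by four tolerances in two layers.
* **Loci**: the F-model. Each variable site's ancestral frequency is
  Uniform(0.1, 0.9); along every branch of the lineage tree the frequency
  drifts to Beta\((p(1-F)/F,\,(1-p)(1-F)/F)\) (mean \(p\), variance
  \(Fp(1-p)\)); \(F = 0\) is exact panmixia, handled without division.
  Haplotype alleles are Bernoulli draws; two haplotypes per individual; an
  individual is present at a locus with probability = completeness, both
  haplotypes dropping together (capture dropout is per library). The Hudson
  ratio-of-averages \(F_{ST}\) between two daughters has expectation
  \(F\), which is the generator's parameter-recovery check. No coalescent
  machinery (recombination, migration) — the F-model suffices for
  clustering tests.
* **Traits**: log-normal, correlated through a shared allometric size
  factor; `lineage_shift` displaces lineage mean size in within-lineage
  size-sd units (`0` = the fully overlapping regime; the shift rides the
  axis a morphometric PCA's first component captures).

What a green test does **not** establish: the climate fields have no
seasonal/semantic structure (no attempt to mimic real bioclimatic variable
meanings); occurrence sampling has no spatial bias or detection error; the
F-model has no linkage, selection, or gene flow after divergence; trait
divergence is one-dimensional. Results on these worlds validate the
machinery, not any empirical claim about real lineages.

## Numerical choices and degenerate inputs

* Correlation filtering is greedy: repeatedly remove, from the
  highest-|r| pair above threshold, the member with the larger mean |r|
  against the remaining layers (ties drop the later layer in stack order).
  Absolute correlation is used — strong negative correlation is equally
  redundant. Constant layers get r = 0 and are flagged. The filter is
  idempotent.
* Extents are half-open on cell centers; cells index row-major from the
  top-left.
* The equivalency pool is the union of *thinned* records; replicate
  partitions are re-thinned, so replicate sample sizes can drop slightly
  when the two lineages share cells.
* AICc is invalid (NA) when \(n - k - 1 \le 0\); such candidates cannot be
  selected.
* Permutation p-values use the `(1 + count)/(reps + 1)` convention, so they
  are never zero.
* Similarity outcomes compare the observed D against `stats::quantile`
  (type 7) null quantiles; the per-tail p-values are also reported.
* VAE log-variances are clamped to \([-10, 10]\); replicates with non-finite
  loss are discarded with a warning, and only if all replicates diverge is
  an error raised.

## Known limitations

* No reprojection or resampling: input layers must share one grid. Raster
  I/O is plain-text (TSV + JSON header); there is no GeoTIFF dependency in
  this implementation.
* The exact feature-class/regularization grid behind any given published
  30-model candidate set is usually unavailable; the default grid is a
  conventional stand-in, overridable in `sdm_config()`.
* Cross-validation metrics (AUC, omission) are out of scope — selection is
  by AICc only. No clamping/extrapolation handling.
* Supervised delimitation against an externally trained classifier is out
  of scope (it depends on a training model that cannot be recreated here);
  the decision engine accepts such verdicts as additional molecular
  evidence columns.
* Whether a published analysis drew background pseudo-occurrences with or
  without replacement is often unstated; this implementation draws cells
  without replacement, consistent with one-record-per-cell thinning.
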