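---
title: "Methods: niche overlap statistics and ploidy-aware variant filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: niche overlap statistics and ploidy-aware variant filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoniche)
```

# The problem

When a polyploid complex hides two biological species — here a diploid
(2n = 32) segregated from a widespread tetraploid (2n = 64) *Cyclocarya* —
three independent lines of evidence are usually combined: do the cytotypes
occupy distinct climatic niches, do they differ morphologically, and do
putatively neutral genome-wide markers separate them? `cytoniche`
implements that evidence chain as a reusable, fully testable pipeline, plus
a synthetic-data module so every stage can be exercised with known ground
truth and no external downloads.

# Climatic niche comparison

## Occurrence thinning

Herbarium records cluster around collection localities; duplicate-like
records inflate local density. Records closer than a threshold (default
1 km) great-circle distance — computed with the haversine formula on a
sphere of radius 6371 km — are removed by a greedy, first-wins scan in
input order. The scan is per species by default: the analysis compares
species-specific niches, and letting one species' records suppress the
other's would bias sample sizes (`per_species = FALSE` is available for
the global variant). First-wins greediness is deterministic, order-stable
and idempotent; the exact retained set of the optimal ("maximum
independent set") formulation is NP-hard and no published workflow uses
it.

## Predictor extraction, pruning, standardization

Raster values are read from the cell containing each point, with no
interpolation — the standard for 30 arc-second bioclim layers, and
bit-reproducible. Records hitting nodata or leaving the extent are
dropped and reported. Because bioclim variables are strongly collinear,
variables are pruned until no retained pair exceeds a Pearson |r|
threshold (default 0.8; the absolute value is used because strongly
negative correlation is equally redundant). The rule is greedy — among
variables in a violating pair, drop the one with the largest mean |r|
against the other retained variables — and is tested against an
exhaustive-subset oracle. A `keep` list can pin a published retained set.
Remaining columns are z-scored (denominator n − 1) on the pooled
two-species matrix, since the PCA fits one joint niche space.

Since no GeoTIFF-capable R stack is assumed, layers travel on disk as
ESRI ASCII grids (plain-text, single band, WGS84) and in memory as
`env_layer` objects; any raster exported from standard GIS tools in that
format is accepted.

## PCA niche space

The niche plane is the first two principal components of the
standardized matrix (covariance PCA of z-scored data, equivalent to
correlation PCA of the raw predictors — matching the standardize-then-PCA
order). Eigenvector sign is arbitrary, so each loading vector is flipped
to make its largest-magnitude element positive; this keeps scores stable
across runs and platforms.

## Density grids, D, B, isopleths

Each species' scores are smoothed with a Gaussian product-kernel KDE
evaluated at the centers of a shared 100 × 100 grid and renormalized to
total mass 1. The grid spans the pooled per-axis range padded by three
pooled Scott bandwidths, so kernel tails are captured; a shared grid is
required because Schoener's D is undefined across different grids. The
default bandwidth is Scott's rule per group (h_j = sd_j · n^(−1/6) in two
dimensions); Silverman's rule or a fixed bandwidth can be selected, and
the bandwidth used is recorded in the output.

On matched grids:

* Schoener's D = 1 − ½ Σ |p₁ − p₂|, in [0, 1];
* Levins' B (standardized) = (1/Σp² − 1)/(n_cells − 1), 0 for a point
  mass, 1 for a uniform niche — the standardized form is used because it
  is the one bounded on the unit interval;
* the 50% isopleth is the highest-density region: cells accumulated in
  decreasing density order until half the mass is enclosed, ties at the
  cut density included.

D is computed over the full grid; an isopleth-restricted D (masses
renormalized inside the union of the two species' highest-density
regions) is exposed as an option, since workflows differ on this point.
Background-environment conditioning (ecospat-style availability
correction) is deliberately out of scope: D here compares occurrence
densities only.

## Permutation inference

The null "the two clouds are exchangeable" is simulated by reshuffling
species labels over the pooled scores, preserving group sizes (so KDE
bandwidth behavior stays comparable), refitting both KDEs on the same
grid, and recording D; the p-value is one-tailed lower with the add-one
correction, p = (1 + #{D_null ≤ D_obs})/(1 + R), because the scientific
question is whether observed overlap is *smaller* than expected. The
whole test is seeded and reproducible. Type-I behavior is verified by
simulation (50 identical-niche repetitions × 200 replicates; the
rejection rate at α = 0.05 must sit inside its binomial 95% CI).

# Morphometrics

Leaflet dimensions and ratios are compared with the Wilcoxon rank-sum
test on untransformed data (exact enumeration when the combined n ≤ 12
with no ties, otherwise the midrank normal approximation with tie and
continuity corrections); flower diameters and elevations with the t test
(Welch by default — no equal-variance claim is warranted — pooled
Student's form selectable). Tests are two-sided by default and no
multiple-testing correction is applied across leaflet classes, matching
how such comparisons are conventionally reported. Leaflet-pair counts
are tabulated per species as a contingency table.

The determination key is coded as inclusive character ranges
(leaflets/compound leaf 5–9 vs 9–13; male flower diameter 4–6 vs 3–4 mm;
stamens 30–35 vs 18–20; flowering months 4–5 vs 5–6). Values the ranges
share — 9 leaflets, 4.0 mm, month 5 — match both species and abstain
rather than invent precision; a specimen is assigned only when all
provided characters are compatible with exactly one species and at least
one character is decisive. The key's "rarely 11" / "rarely 15" extremes
are excluded from the coded ranges: including rare extremes would make
the leaflet character permanently indecisive.

# Neutral-SNP filtering and downstream emitters

The filter cascade runs in the fixed order:

1. **depth window** — keep sites whose total depth lies in
   [mean/3, 2·mean], bounds inclusive, with the mean taken across all
   input sites. "Mean sequencing depth" is interpreted as the mean of
   site-level total depths (per-sample mode available), since site totals
   are what joint callers report;
2. **region exclusion** — drop sites inside TE intervals or inside CDS
   intervals grown by a 2-kb flank on both sides (VCF positions 1-based,
   BED half-open 0-based, GFF3 1-based closed, all converted
   consistently);
3. **singleton removal** — count minor-allele copies over all non-missing
   allele slots, ploidy-aware (a tetraploid 0/0/0/1 contributes one
   copy), and drop sites with minor count exactly 1, whichever allele is
   minor;
4. **20-kb spacing** — greedy left-to-right per chromosome.

Depth, region and singleton membership are site-intrinsic, so their
order only affects the per-stage bookkeeping, not the final set; spacing
runs last so a site removed for quality never blocks a retained,
well-spaced neighbour. Every stage reports input/removed/survivor
counts, and on synthetic data those counts must equal the generator's
independent by-construction bookkeeping exactly.

**Fragment sampling** cuts per-sample consensus sequences into 1000-bp
fragments anchored at reference position 0 and spaced 20 kb; a fragment
is discarded when any sample has more than 50 `N` bases in it, or when no
alignment column free of `N` in every sample is variable. Ambiguity is
excluded from the polymorphism test because an `N` column cannot
evidence variation. Fragment starts are reference-anchored (0, 20000,
…) rather than anchored at the first aligned base.

**Dxy** between groups of arbitrary ploidy is, per site, the mean over
all inter-group pairs of non-missing allele copies of the indicator that
the copies differ (pairwise-complete). Site values are averaged over the
site set supplied, so monomorphic sites contribute zero and the caller
controls the denominator. Note a consequence of the copy-pair
definition: two groups with identical *polymorphic* composition still
have Dxy > 0 (e.g. two 0/1 heterozygotes give 0.5); Dxy only vanishes
when the groups share no polymorphism and no fixed difference.

**STRUCTURE export** codes every individual as tetraploid: four rows per
individual, diploids padded with two rows of −9 across all loci, missing
copies also −9.

# The synthetic-data module

The generator is first-class, tested code — it defines the study
conditions under which the pipeline's claims are verified.

*Environmental layers* are linear combinations of two smooth latent
spatial gradients plus independent low-frequency sinusoid fields, all
orthonormalized over cells; a target inter-layer correlation matrix is
realized as its closest rank-2-plus-diagonal approximation (the spatial
fields live on two latent gradients, mirroring the effectively
low-dimensional structure of real bioclim stacks). The default 5-layer
design plants two redundant blocks with within-block r = 0.85, so the
|r| > 0.8 pruning stage is always exercised. A gentle sinusoidal warp
(amplitude 0.03 of the gradient range) keeps the fields from being
exactly planar while leaving the space-to-environment mapping close
enough to affine that configured niche Gaussians are realized faithfully
(at amplitude ~0.1 the warp's Jacobian visibly distorts the sampled
covariance).

*Occurrences* are placed by density-weighted inversion of that mapping:
cells are sampled with probability proportional to the species' Gaussian
niche density at the cell's environmental values, and points are
jittered uniformly within the cell. Empirical environmental covariance
therefore converges to the configured covariance as n grows (verified at
n = 2000 within 10%), provided the configured niche sits well inside the
extent; a niche as wide as the study region is truncated by the
available environment, exactly as in nature. A configured fraction of
records (default 0.1) is resampled within 1 km of another record to
emulate clustered duplicate collections. The default scenario — a
widespread broad-niched tetraploid (n = 300, niche SD 0.85) and a
narrower diploid (n = 120, SD 0.45) with distinct optima over a
subtropical-China-sized extent at 0.05° resolution — gives low overlap
and a ~2–3× breadth contrast, the qualitative structure of the real
comparison. What the generator does *not* emulate: spatial sampling
bias beyond duplicate clusters, interactions or dispersal limits
(occurrences are an inhomogeneous point process driven purely by
climate), non-Gaussian niche shapes, and raster measurement error — so
passing tests demonstrate correctness of the *statistics*, not that real
data meet their assumptions.

*Traits* are drawn from per-species normal distributions (dimensions,
flower diameters) and discrete leaflet-pair distributions, with sample
sizes and default parameter values matching the published measurement
design (38/104/37 vs 47/92/46 apical/lateral/basal leaflets, 72 flowers,
pair-count tables 13/20/5 of 38 and 3/23/21 of 47). Values are truncated
at a small positive floor, which at the default coefficients of
variation (< 20%) is essentially never hit.

*Variants* get unique sorted positions, negative-binomial per-sample
depths with an 8% site fraction of coverage anomalies (half ~4×
inflated, emulating collapsed repeats; half ~0.15×, emulating poorly
covered regions — without them a depth window can never bind), allele
frequencies from a U-shaped Beta(0.6, 0.6), binomial per-sample copy
counts at each sample's ploidy, a planted singleton fraction, 2% missing
genotype cells, and random CDS/TE interval sets. During generation the
survivor count of every cascade stage is computed by independent plain
arithmetic; the pipeline must reproduce those counts exactly. Linkage
disequilibrium, coalescent genealogies and read-level errors are not
simulated.

# Numerical and design notes

* All randomness is seeded; each generator function takes its own seed,
  so adding one generator never perturbs another's stream.
* Problem sizes in the tests and the acceptance script (2000 points per
  species for the KDE oracle, 50 × 200 for the type-I simulation, 5000
  sites for the cascade, 100-kb chromosomes for fragments) were chosen as
  the smallest sizes at which the stochastic tolerances are comfortably
  stable under repeat simulation.
* The KDE-grid D carries a small positive bias from kernel smoothing
  (each KDE is the truth convolved with its kernel); at n = 2000 and
  Scott bandwidths this stays within 0.03 of the dense-integration
  analytic value for well-separated Gaussians, hence the 0.05 oracle
  tolerance.
* Degenerate inputs fail loudly: all-identical score clouds (zero
  bandwidth), constant columns at z-scoring, fewer than two
  non-degenerate PCA dimensions, malformed intervals (start ≥ end),
  ploidies outside {2, 4}. Empty occurrence or variant sets flow through
  with empty outputs and zero-count reports.
* One published ambiguity is left to configuration rather than resolved:
  the retained-predictor list of the original analysis ("nine relatively
  independent predictors" vs eight named variables) can be pinned via
  `keep`; the pruning default makes no attempt to guess the ninth.

# Known limitations

Thinning is O(n²) per species (fine to ~10⁴ records). The permutation
test refits 2(R+1) KDEs; at the default 100 × 100 grid and 1000
replicates this is a few tens of seconds for a few hundred records. The
rank-2 layer construction cannot realize arbitrary correlation matrices
exactly — realized off-block correlations are approximations, reported in
the generator's truth record. Dxy is per-SNP (divergence per variant
site), not per-bp sequence divergence; converting to per-bp requires the
monomorphic site count, which the caller supplies through the site set.
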