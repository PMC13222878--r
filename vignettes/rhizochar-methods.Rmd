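---
title: "Methods and design choices in rhizoChar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in rhizoChar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rhizoChar quantifies how a soil amendment (biochar in the motivating
experiments) reshapes root–microbe interactions in rhizoboxes. This
vignette documents the statistical procedures, their assumptions, every
tunable that matters, and the design decisions taken where the
methodology was genuinely open — so that results can be interpreted and
the package extended without reverse-engineering the code.

## Zymography

A membrane zymogram is a grey-value image in which brightness is, over
the calibrated range, an affine function of extracellular enzyme
activity. `fitCalibration()` fits grey = slope · activity + intercept by
ordinary least squares over the calibration standards (at least two
distinct activities; identical activities make the line non-invertible
and are rejected). `greyToActivity()` inverts the line per pixel to
nmol cm⁻² h⁻¹; back-calculated negative activities — possible when the
background sits below the zero-activity standard — are clamped to zero
and counted, never silently kept.

**Hotspot rule.** A pixel is a hotspot when its grey value *strictly
exceeds* mean + 2 · SD of the region of interest. Two conventions had to
be fixed:

* the standard deviation is the *sample* SD (n − 1 denominator) —
  the field literature does not state which; with typical ROIs of 10⁴–10⁶
  pixels the difference is far below any other error source, but a
  convention has to be pinned for the oracle tests to be exact;
* percent hotspot area is 100 · N_h / (N_h + N_b), i.e. hotspot pixels
  over all ROI pixels. The formula as usually printed divides by
  N_h − N_b, which is negative whenever hotspots are rarer than
  background (the normal case) — a near-certain sign typo. The literal
  form remains available as `eq1AsPrinted = TRUE` for audit.

Because mean + 2 SD is equivariant under affine rescaling of grey
values, the detected mask and percent area are invariant to exposure or
bit-depth changes that act affinely on the image; the suite asserts this
property on random images. On pure Gaussian noise the expected hotspot
fraction is the upper 2-SD tail mass (≈ 2.3 %), which is the calibration
check used in acceptance.

**Compartments.** The rhizoplane is the root footprint mask itself (the
registration of the rhizobox photograph to the membrane is assumed done
upstream; the mask is an input). The rhizosphere is a band of
`bandWidthPx` pixels around the root: morphological dilation with a
square (8-connectivity / chessboard) structuring element, minus the
root, clipped to the ROI; the remainder of the ROI is bulk-soil
background. The band width is configurable (default 3 px in the
generator) because no fixed rhizosphere width exists in physical units —
it depends on pixel size and soil. Per-compartment hotspot percentages
can use a compartment-local threshold (default, so each compartment is
judged against its own grey distribution) or one global threshold;
both modes are provided because published per-compartment figures rarely
state which was used. Empty compartments report NA statistics, never 0.

## Community profiling

* **Rare-taxon filter.** A taxon is kept when its study-wide relative
  abundance is ≥ the threshold (default 0.005 %, the common 16S
  artefact-removal level). The boundary is inclusive: "remove below the
  threshold" leaves the equality case ambiguous, and keeping it makes
  the filter idempotent at the printed threshold.
* **Shannon diversity** uses natural logarithms (H in nats); the index
  is base-ambiguous in the literature, and nats make H = ln k exact on
  uniform k-taxon samples, which the suite asserts.
* **PERMANOVA** is implemented in-package in Anderson's sum-of-squares
  formulation on squared dissimilarities, with label permutation and the
  add-one convention p = (1 + #{F\* ≥ F}) / (1 + n_perm), so p is never
  exactly zero. vegan's `adonis2` is used in the tests as an independent
  cross-check of the pseudo-F, never as the implementation — the
  package needs an enumerable, seed-stable permutation stream for its
  exactness tests. Note that with strongly separated groups the minimum
  attainable p is not 1/(n_perm + 1): label permutations that preserve
  the partition reproduce the observed F exactly, so the floor is about
  the fraction of partition-preserving permutations.
* **Differential abundance** is a per-taxon two-sided Wilcoxon rank-sum
  test on relative abundances with Benjamini–Hochberg correction
  (q-values). The test function is pluggable; the rank test is the
  default because genus-level relative abundances are heavily
  non-normal. Direction is the sign of the mean relative-abundance
  difference.

## Co-occurrence networks

Networks are built separately per condition (site × compartment ×
treatment) — pooling conditions would manufacture correlations from
between-condition mean differences.

* **Screen.** Spearman by default (robust to the monotone distortions
  of compositional counts); Pearson available. p-values use the
  t approximation on n − 2 df, the convention of the classic `rcorr`
  screen, so thresholds match analyses done that way. At n = 6 this
  approximation agrees with the exact 720-permutation null within 0.1,
  which is the documented tolerance of the small-n test. The screen
  accepts raw counts or relative abundances (default: relative); the
  choice is recorded in the screen result. No multiple-testing
  correction is applied to edges by default — the edge rule is raw
  p < 0.01, as commonly practised; a corrected screen can be had by
  passing adjusted matrices to `buildNetwork()`.
* **Edges.** Strictly p < `edgeAlpha` (default 0.01). Negative
  correlations form edges too, with sign kept as an attribute; degree
  counts both signs. Isolated taxa are dropped by default so node counts
  describe connected genera.
* **Topology.** Degree and betweenness per node (paths unweighted),
  global transitivity, average path length over connected pairs only
  (co-occurrence networks are routinely disconnected; averaging over
  connected pairs is igraph's convention and is stated here because it
  changes the number), and modularity of the Louvain partition on
  absolute correlation weights.
* **Null models.** "Random graphs with the same number of nodes and
  edges" does not pin a model down; the default is Erdős–Rényi G(n, m),
  the weakest (and therefore most conservative to *pass*) constraint.
  Per metric the two-sided empirical p counts null graphs at least as
  far from the ensemble mean as the observation, add-one convention;
  the network is "non-random" when any tested metric has p < 0.05. The
  metric list is configurable because a single-metric verdict is what
  the self-null calibration checks (an any-of-k verdict is anti-
  conservative by construction).
* **Hubs.** The k (default 10) highest-degree nodes; ties broken by
  betweenness, then label, deterministically, with a warning when a tie
  crosses the k-th position — hub lists are published artefacts and must
  not depend on storage order. `hubShift()` is pure set algebra;
  |maintained| + |lost| = |maintained| + |gained| = k always.

## Modules and trait associations

Louvain community detection (greedy modularity, seeded, absolute-rho
weights) assigns every node a module; modules are relabelled dense from
1 by size (ties by summed degree, then smallest member label) so
"module 1" always means the largest. The top four modules per network
are carried into association analysis by default.

The bridge from a module (a set of taxa) to a sample-level variable is
the **module profile**: the per-sample mean of the z-scored relative
abundances of member taxa. It is scale-free across taxa of very
different absolute abundance and linear in each member; an eigen-profile
(first principal axis) is the natural alternative and can be computed
from the same inputs, but the z-mean is kept as the default for
transparency. Associations are Spearman rho per (module, trait) with
two-sided t-approximation p on pairwise-complete units (missing trait
values are allowed), significant at p < 0.01. The Mantel confirmation
correlates the Euclidean distance matrix of module profiles with that of
the trait table (simultaneous row/column permutation, add-one, one-sided
on r — the standard Mantel direction); any two aligned distance matrices
can be supplied, since published analyses are rarely explicit about
which matrices entered their Mantel tests. A confirmation rule of
p < 0.01 *and r > 0.4* is the package's reading of the (impossible)
"r > 4" sometimes printed for such heat-map edges; both thresholds are
arguments.

Comparing untreated and treated association matrices requires a shared
module labelling. Module identity across independently detected
partitions is established by greedy maximum-Jaccard matching of member
sets (`matchModules()`), and the match scores are reported rather than
hidden — a low Jaccard means "module M2 (treated)" is only nominally the
same object as "module M2 (untreated)". `classifyShift()` then labels
each significant (module, trait) pair *new* (treated only), *maintained*
(both) or *missed* (untreated only); the set identities
new ∪ maintained = treated-significant and missed ∪ maintained =
untreated-significant hold by construction and are property-tested.

## The synthetic-data generator

The generator exists so that every stage has a recovery test with known
truth, offline.

* **Communities.** Taxa are assigned round-robin to modules; each module
  has one standard-normal latent factor per sample; a taxon's counts are
  negative-binomial with log mean = baseline + coupling · factor.
  Negative-binomial (rather than multinomial) keeps overdispersion
  (default size 5, a realistic 16S level) controllable independently of
  depth; the latent-factor construction makes the induced within-module
  correlation easy to reason about, and coupling = 0 is an exact null.
  Defaults — 20–50 samples, 40 taxa, 4 modules, coupling 2 — give
  within-module Spearman correlations strong enough that module recovery
  is expected, which is what a recovery test needs.
* **Traits.** trait = effect · latent factor of its linked module +
  Gaussian noise (defaults effect 2, noise SD 0.1); module id 0 requests
  pure noise. Planted couplings are therefore monotone and detectable by
  Spearman at p < 0.01 with high power at 50 samples.
* **Zymograms.** A branching seeded random walk draws the root
  footprint; root pixels (the planted hotspot set) get background + gain
  on top of Gaussian background noise. This is deliberately minimal:
  compartment logic only needs a connected footprint, and hotspot
  recovery only needs a known mask and a controllable contrast
  (gain / background SD).

What the generator does *not* emulate: sequencing depth variation and
zero-inflation beyond the negative binomial, compositional closure
effects beyond the implicit total constraint, taxonomic structure,
spatially correlated membrane noise, or the real factorial design's
effect sizes. Passing recovery tests therefore show the algorithms are
correct and calibrated on their stated models — not that the study's
field effect sizes are reproduced. One consequence of compositional
closure is visible even here: a trait coupled to module 1 also
correlates (negatively) with other modules' relative-abundance profiles,
so recovery tests assert detection of the planted pair, not exclusivity.

## Determinism and numerical conventions

Every stochastic operation takes an explicit seed and restores the
caller's RNG state, so generators and tests are pure functions of their
arguments. All permutation p-values use the add-one convention. All file
I/O is UTF-8 with tab/comma auto-detection; grey values are read as-is
(8-bit 0–255, 16-bit 0–65535, never rescaled; RGB reduced by the
Rec. 709 luminance rule). `runPipeline()` derives each stage's seed from
the config seed, and two runs from one config are byte-identical — the
pipeline test hashes every output file.

The suite and the acceptance script run at deliberately desk-sized
problems (50 × 40 community tables, 100–200 permutation replicates,
99-graph null ensembles, 10–50 seeds per stochastic claim), chosen so
the full suite completes in well under a minute per file while binomial
tolerances on calibration rates stay meaningful.

## Known limitations

* Correlation networks on compositional data are biased towards negative
  correlation; SparCC/SPIEC-EASI-style compositional inference is out of
  scope because the method being packaged is plain correlation
  screening.
* The Mantel test and PERMANOVA permute units assuming exchangeability;
  nested rhizobox designs (samples within boxes) are not modelled.
* The G(n, m) null keeps only (n, m); degree-preserving rewiring is a
  stricter alternative a user may prefer for hub-heavy networks.
* Module matching by Jaccard is greedy, not optimal assignment; with
  near-equal overlaps the matching (and hence shift labels) can be
  unstable, which is why match scores are part of the output.
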