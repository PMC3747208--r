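---
title: "Integrative species delimitation with delimkit: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative species delimitation with delimkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delimkit)
```

delimkit implements an integrative-taxonomy workflow for delimiting species
from a single mitochondrial barcode locus plus traditional morphology. The
pipeline proposes *primary species hypotheses* from two quantitative
single-locus methods with very different rationales — the distribution of
pairwise genetic distances (ABGD) and the branching-rate structure of an
ultrametric genealogy (GMYC) — retains only groupings on which the methods
agree, and then characterizes each candidate species with population-genetic
statistics and validates it against multivariate morphology. This vignette
explains each model, its assumptions, the tunable parameters, and the design
choices made where the methods leave details open.

## Distances and diversity

All sequence statistics run on an aligned matrix (`seq_alignment`) over the
nucleotide alphabet plus IUPAC ambiguity codes, `N`, `?` and `-`; everything
that is not an unambiguous base is treated as missing. Pairwise distances use
**pairwise deletion**: a pair is compared only at sites where both sequences
carry a plain base. Segregating sites and nucleotide diversity default to the
same policy, with complete deletion available as a flag
(`complete_deletion = TRUE`); the choice matters only for alignments with
appreciable missing data.

The Kimura two-parameter distance corrects transitions (P) and
transversions (Q) separately,

$$d = -\tfrac12\ln(1 - 2P - Q) - \tfrac14\ln(1 - 2Q),$$

and is the model used throughout the pipeline because it is the standard for
COI barcoding. Saturated pairs (log argument $\le 0$) raise an error rather
than returning infinity; a pipeline that needs to survive saturation can fall
back to p-distances explicitly. Group summaries report both the standard
deviation and the standard error of the pairwise-distance set, because
published tables are ambiguous about which dispersion they print.

Haplotype collapsing is strict by default — two sequences are one haplotype
only when they match exactly, missing characters included — with a
missing-tolerant mode that merges sequences agreeing at every mutually
unambiguous site. Strictness is conservative and reproducible; the tolerant
mode can chain-merge through low-quality sequences and is opt-in.

## ABGD: the barcode gap

ABGD assumes that intraspecific divergences are bounded by some prior `P`
while interspecific divergences are larger, leaving a "barcode gap" in the
ranked pairwise-distance curve. The published method leaves the gap-width
test implementation-defined, so this package states its rule explicitly: the
local slope at rank $i$ is the mean of consecutive differences over a
trailing window of $w = \max(3, \lceil 0.1\,m\rceil)$ ranked distances, and
the gap between ranks $i$ and $i+1$ is significant when it exceeds `x`
(default 1.5) times that slope and its right edge exceeds `P`. The returned
threshold is the midpoint of the first significant gap, so that
"distance below threshold" captures the entire left mode. Sequences are then
grouped by single linkage below the threshold, and the procedure recurses
within each group (re-detecting a gap among within-group distances) until
nothing splits or `max_depth` (default 10) is reached. Zero distances —
duplicate haplotypes — are excluded from the ranked list but kept in the
graph.

The scan evaluates a logarithmic grid of priors between `p_min` (0.001) and
`p_max` (0.1), 100 steps by default, and reports *stable* partitions:
identical groupings (up to relabelling) across at least three consecutive
priors. Group counts should fall as the prior grows; the scan asserts this
monotone-coarsening property and flags violations rather than hiding them.
Only the initial-partition variant of the method is implemented; the
original tool's model-based theta refinement is out of scope.

## Trees

The GMYC input is an ultrametric genealogy. Trees are accepted as Newick
input, and a strict-clock UPGMA builder is provided as plumbing for users
without a clock-calibrated tree: node heights are half the average linkage
distance, labels are sorted before clustering so ties break
deterministically, and the output is exactly ultrametric. Ultrametricity is
enforced within a relative tolerance of $10^{-6}$ of tree height (the worst
tip is named on failure). Polytomies are resolved into zero-length
bifurcations with a warning, and tied internal-node heights are perturbed by
$10^{-10}$ so that event times are distinct, which the likelihood requires.
Heights are in expected substitutions per site throughout — no calendar
calibration — so the fitted threshold is directly comparable to
substitution-scaled divergence.

## GMYC: the mixed Yule-coalescent threshold model

Between the root and a threshold time $T$, branching is modelled as
diversification among species-level lineages; below $T$, as coalescence
within delimited entities. For the interval following the $i$-th oldest
event, with $k_i$ species-level lineages and $n_{ij}$ lineages inside entity
$j$, the hazard is

$$b_i = \lambda_1 k_i^{p_1} + \lambda_2 \sum_j \left[n_{ij}(n_{ij}-1)\right]^{p_2},$$

and the log-likelihood sums $\ln b_i - b_i x_i$ over the inter-event
waiting times $x_i$ (the final interval to the present included). The null
model is a single process with hazard $\lambda_0 n_i^{p_0}$.

Fitting details, all deliberate:

* **Candidates.** Single-threshold candidates are the midpoints between
  consecutive distinct node heights, plus the degenerate threshold below the
  youngest node. Under the degenerate candidate every tip is its own entity
  and the likelihood collapses exactly to the null form, which guarantees
  the nesting property `logL(null) <= logL(single) <= logL(multiple)` that
  the likelihood-ratio tests assume. (The fit asserts this ordering on
  every run.)
* **Optimization.** For each candidate, rates and exponents are maximized
  with bounded L-BFGS-B from three fixed exponent starts (0.5, 1, 2), with
  rates initialized from method-of-moments event rates, plus the null
  solution and the previous candidate's optimum as warm starts. Rates are
  bounded to $[10^{-8}, 10^{6}]$.
* **Exponent bounds.** The scaling exponents are bounded to $[10^{-3}, 2]$.
  A wider upper bound lets the single-process term mimic the sharp rate
  increase of a coalescent burst ($k^{10}$ spans ten orders of magnitude
  over realistic lineage counts), which systematically over-splits clusters;
  restricting the exponents to the vicinity of the linear/quadratic
  behaviour of the underlying processes removes that failure mode while
  leaving the model its intended flexibility.
* **Multiple thresholds.** The multiple-threshold mode starts from the
  single-threshold optimum and greedily reclassifies one further node at a
  time as a diversification event (respecting the constraint that ancestors
  of diversification nodes are diversification nodes), keeping a move only
  if the log-likelihood improves, up to `max_thresholds`. Each accepted move
  adds one transition; refinement never merges entities. The degrees of
  freedom attributed to these models vary between software parameterizations,
  so `gmyc_lr_test` exposes `df` as an argument instead of hard-coding it.
* **Duplicates.** Zero-length pendant branches (identical haplotypes) are
  rejected with instructions to collapse first: they produce zero waiting
  times with unbounded likelihood contributions and are the classic cause of
  spurious over-partitioning.

`conspecificity_matrix` aggregates single-threshold delimitations over a
tree sample (a posterior sample, or nonparametric-bootstrap UPGMA trees) and
reports, per pair, the fraction of trees in which the pair is conspecific.
This is a maximum-likelihood surrogate with the same output contract as the
Bayesian variant of the model, which is deliberately not re-implemented.
Within each sampled tree, tips at effectively zero cophenetic distance are
collapsed to one representative before fitting and co-assigned afterwards.

## Population genetics

**Tajima's D** is computed from the segregating sites and the mean number of
pairwise differences with the standard normalizing constants. **Fu's Fs**
uses $\hat\theta = \hat\pi$ (the mean pairwise differences), evaluates
$S' = \Pr(K \ge k_{obs} \mid \hat\theta)$ under the Ewens sampling formula
with unsigned Stirling numbers of the first kind computed by the exact
recurrence in log space (to $n = 200$ without overflow), and returns
$F_s = \ln(S'/(1-S'))$. Significance for both comes from neutral
constant-size coalescent simulation conditioned on $(n, \hat\theta)$
(default 10,000 replicates): the p-value is the lower-tail fraction, the
direction sensitive to demographic expansion; by the usual convention Fs is
called significant at the 5% level only when $p < 0.02$. Simulated samples
that are monomorphic contribute the neutral value 0 to the reference
distribution.

**AMOVA** decomposes the squared pairwise distances into hierarchical sums
of squares (among groups, among populations within groups, within
populations, or the two-level reduction), solves the variance components
from expected mean squares with the standard unequal-sample-size
coefficients, and attaches permutation p-values by shuffling individuals
among populations (overall and within groups) and whole populations among
groups. Percentages are guaranteed to sum to 100 and are invariant to label
renaming.

**Mantel tests** correlate the upper triangles of two distance matrices
with joint row/column permutations; the default alternative is two-sided.
Geographic distances come from site coordinates as great-circle kilometres.

## Morphology

The analysis characters are the post-orbital head depth as a percentage of
head length, caudal peduncle depth and pre-dorsal length as percentages of
standard length, and the coded skin pattern (chevron blotches = 0,
none/unclear = 1). Dorsal spots and an elongated stomach are treated as
categorical diagnostics that identify the marine morphotype outright, short-
circuiting the discriminant; those individuals are excluded from
discriminant training.

Per-group kernel densities use a Gaussian kernel with Silverman's
rule-of-thumb bandwidth multiplied by 1.5 for extra smoothness, on a
512-point grid spanning the data range ± 3 bandwidths. Homogeneity of
multivariate dispersions is tested by a permutation ANOVA on each
individual's distance to its group centroid in standardized character
space.

The two overlapping morphospecies are separated with a smoothed
heteroscedastic discriminant model: a `dims`-dimensional projection (default
3 of the 4 characters) in which the classes keep distinct covariances while
the discarded directions carry only shared structure. The projection
maximizes the profile Gaussian log-likelihood over orthonormal bases,
initialized deterministically from the pooled-covariance linear discriminant
direction padded with principal components — no randomness, fully
reproducible. Class covariances are regularized before fitting as

$$\Sigma_k(\gamma, \lambda) = \gamma\left[(1-\lambda)\Sigma_k +
\lambda\Sigma_{pooled}\right] + (1-\gamma)\,\frac{tr(\Sigma_k)}{d}\,I,$$

so $\gamma = 1, \lambda = 0$ (the defaults) is pure unshrunk heteroscedastic
fitting, $\lambda = 1$ is the homoscedastic limit (where the classifier
agrees with standard LDA), and $\gamma = 0$ degrades gracefully to spherical
covariances. The exact regularization semantics of earlier software are not
published; this formula is the package's stated contract. Within the
retained subspace, the first component axis is the projected discriminant
direction and the remaining axes follow the eigenstructure of the projected
class-covariance difference, with signs fixed so the dominant loading of
each component is positive — classification is invariant to these
conventions. New individuals are classified by the larger Gaussian posterior
in component space; `hda_jackknife` reports leave-one-out accuracy, the
guard against overfitting used for the identification figures.

## The synthetic-data generator

Every stage above is validated against data with known truth. The generator
(`simulate_dataset`) draws a Yule species tree, runs a multispecies
coalescent along it (per-species constant size, exponential growth via the
usual time transformation, or a finite-island structured coalescent with
species-level theta split across demes), simulates sequences under the
two-rate transition/transversion model with branch lengths in expected
substitutions per site, lays populations on a one-dimensional coastline for
isolation-by-distance testing, and draws a morphology table from
class-specific multivariate normals plus Bernoulli colour patterns with a
cleanly diagnosable third class. The same configuration and seed give
byte-identical output.

The `aplochiton-like` preset encodes the study conditions the pipeline is
meant to resolve: three species sampled 24/24/12 across 3/5/2 populations;
species-tree root height drawn in [0.045, 0.055] substitutions/site with
internal splits at $\ge 0.75$ of the root, so all between-species K2P
distances fall in the 7–13% band; within-species theta of 0.008 (with
5-fold exponential growth, giving realized diversity near 0.002/site and a
clearly negative Tajima's D and Fu's Fs), 0.0012 and 0.001; scaled
migration 10 among demes (shallow structure, a few percent of variance
among populations). The morphology preset uses one compact deep-bodied
class, one highly variable slender class (unequal covariances, overlapping
ranges) and a separable third class, balanced 31/31 + 13, calibrated so
leave-one-out identification lands in the 0.75–0.92 band (around 0.84 on
average). What the generator does **not** emulate: recombination,
selection, indels, alignment error, sequencing ambiguity and migration
between species — so passing tests demonstrate correctness of the methods
under their own assumptions, not robustness to real-data artefacts.

Problem sizes used in the shipped tests and in `scripts/acceptance.R` — 100
replicate datasets for the species-recovery checks, 500 replicates for
nominal-level calibration of Tajima's D, the dispersion test and the Mantel
test, 20 replicates for the expansion signal, 5 for jackknife accuracy —
were chosen to give stable Monte-Carlo estimates at the package's own test
scale.

## The pipeline and its consensus rule

`run_pipeline` chains the stages and forms the consensus by strict
agreement: two individuals are conspecific only when every method
co-assigns them, so disagreement splits and is flagged, never silently
merged. The GMYC vote enters the consensus only when the threshold model
beats the null in the likelihood-ratio test (at 5%); otherwise its vote is
a single species — without this, a genealogy with no speciation signal
would still be cut at some threshold. Per-stage errors stop the run with a
stage tag. Reports echo all parameters and seeds and are bit-for-bit
reproducible.

## Known limitations

* The GMYC likelihood is evaluated per candidate threshold by numerical
  optimization; likelihood differences between neighbouring candidates are
  often well under one log unit, so entity counts on weakly structured data
  are intrinsically unstable — the reason the pipeline requires method
  agreement before promoting a grouping.
* UPGMA trees built from few segregating sites contain many tied node
  heights; the tie-jitter makes fitting possible but cannot create time
  resolution the data lack. A clock-calibrated genealogy is preferable
  input whenever available.
* The AMOVA permutation scheme permutes whole populations among groups for
  the among-group component; with few populations the achievable p-value
  resolution is coarse.
* Fu's Fs is clamped (with a warning) when the Ewens tail probability
  under- or overflows the unit interval at machine precision.
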