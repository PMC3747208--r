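# delimkit

Integrative species delimitation from DNA barcodes and morphology.

When a genus's nominal species are morphologically confusable — as in the
Patagonian galaxiid fishes where a slender and a deep-bodied morph overlap
broadly and a third, rarely caught form had been lost to synonymy — species
boundaries have to be built from several independent lines of evidence.
delimkit implements that workflow for a single mitochondrial barcode locus
(e.g. a 677-bp *COI* fragment) plus traditional morphometric characters:

* **Sequence statistics** — validated alignment handling, haplotype
  collapsing, segregating sites, nucleotide diversity π, and Kimura
  two-parameter distances
  `d = -½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)` with pairwise deletion.
* **ABGD** (Automatic Barcode Gap Discovery) — detects the gap between
  intra- and interspecific pairwise distances, partitions by single linkage
  below it with recursive refinement, and scans a log-spaced grid of prior
  intraspecific divergences for *stable* partitions.
* **GMYC** (general mixed Yule-coalescent) — maximum-likelihood fit of the
  threshold model on an ultrametric genealogy, with interval hazard
  `b_i = λ₁k_i^{p₁} + λ₂ Σ_j [n_ij(n_ij−1)]^{p₂}`, null/single/multiple
  modes, likelihood-ratio tests, and conspecificity aggregation over tree
  samples. A strict-clock UPGMA builder is included as plumbing for users
  without a calibrated tree.
* **Population genetics** — Tajima's D and Fu's F_S (Ewens sampling formula
  with exact log-space Stirling numbers) with coalescent-simulation
  p-values, hierarchical AMOVA with permutation tests, and Mantel
  isolation-by-distance tests with great-circle site distances.
* **Morphometrics** — ratio characters, oversmoothed kernel densities, a
  permutation test for homogeneity of multivariate dispersions, a smoothed
  heteroscedastic discriminant model (class-specific covariances, γ/λ
  regularization) with leave-one-out jackknife identification and a
  categorical short-circuit for diagnosable morphotypes.
* **Synthetic data** — a Yule + multispecies-coalescent + K2P-mutation
  generator (with expansion, population structure and a matched morphology
  sampler) so every stage is testable against known truth, offline.

The pipeline promotes a grouping to a species hypothesis only when ABGD and
GMYC agree (strict-agreement consensus); the GMYC vote counts only when the
threshold model beats the null in a likelihood-ratio test.

## Worked example

```r
library(delimkit)

ds  <- simulate_dataset("aplochiton-like", seed = 11)   # 60 seqs, 3 species
rep <- run_pipeline(ds$alignment, morphology = ds$morphology,
                    sites = ds$sites, reps = 1000, permutations = 199,
                    seed = 5)
rep
#> Integrative delimitation report
#>   haplotypes: 15 from 60 individuals
#>   ABGD: 3 groups (most stable)
#>   GMYC: 3 entities at T = 0.02585 ; LR chi2 = 24.645 , p = 1.83e-05
#>   consensus: 3 species (methods agree)
#>   G1: pi = 0.00158, D = -1.34, Fs = -2.9
#>   G2: pi = 0.00153, D = 0.729, Fs = 0.268
#>   G3: pi = 0.00253, D = 1.03, Fs = 0.559
#>   AMOVA among-group: 99.95 %
#>   morphology jackknife accuracy: 0.806
```

Reading the report: the 60 sequences collapse to 15 haplotypes; the ABGD
scan's most stable partition and the GMYC threshold model (transition at
T ≈ 0.026 substitutions/site, decisively preferred over the
constant-rate null) both delimit the same three species, so the strict
consensus has no disagreement flags. Per species, π is the nucleotide
diversity and D/F_S the neutrality statistics — the strongly negative pair
in G1 is the demographic-expansion signal built into that species by the
generator. AMOVA attributes ~99.9% of molecular variance to the species
level, and the morphological discriminant identifies ~81% of the two
overlapping morphotypes correctly under leave-one-out jackknifing (the
third morphotype is diagnosed categorically at 100%).

Between-species distance summaries come straight off the fitted partition:

```r
tab <- group_distance_summary(
  distance_matrix(collapse_haplotypes(ds$alignment)$alignment),
  rep$gmyc$partition)
tab[tab$group1 != tab$group2, ]
#>  group1 group2   mean     sd    se n_pairs
#>      G1     G2 0.0990 0.0011 2e-04      28
#>      G1     G3 0.1121 0.0016 3e-04      28
#>      G2     G3 0.0989 0.0012 3e-04      16
```

i.e. 9.9–11.2% K2P divergence between delimited species — comfortably above
any within-species diversity (≈0.2%), which is the barcode gap ABGD found.

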