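# shared fixtures: tiny alignments and matrices built in code

make_aln <- function(seqs, ...) seq_alignment(seqs, ...)

# random low-divergence alignment: common ancestor plus per-sequence
# substitutions (keeps K2P well away from saturation)
random_aln <- function(n, L, seed = 1, mut = 0.05) {
  set.seed(seed)
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  mat <- matrix(anc, nrow = n, ncol = L, byrow = TRUE)
  for (i in seq_len(n)) {
    k <- max(1L, stats::rbinom(1L, L, mut))
    at <- sample.int(L, k)
    for (s in at)
      mat[i, s] <- sample(setdiff(c("A", "C", "G", "T"), mat[i, s]), 1L)
  }
  rownames(mat) <- paste0("s", seq_len(n))
  seq_alignment(mat)
}

# two tight sequence clusters separated by a wide gap, as a distance matrix
two_cluster_dm <- function(n1 = 4, n2 = 4, within = 0.004, between = 0.12,
                           seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  labs <- paste0("x", seq_len(n))
  d <- matrix(between + runif(n * n, 0, 0.01), n, n,
              dimnames = list(labs, labs))
  d[seq_len(n1), seq_len(n1)] <- within * matrix(runif(n1 * n1), n1, n1)
  d[(n1 + 1):n, (n1 + 1):n] <- within * matrix(runif(n2 * n2), n2, n2)
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  diag(d) <- 0
  d
}

# haplotype-pruned true gene tree of a synthetic dataset
pruned_gene_tree <- function(ds) {
  h <- collapse_haplotypes(ds$alignment)
  reps <- names(h$membership)[match(unique(h$membership), h$membership)]
  ape::keep.tip(ds$gene_tree, reps)
}
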