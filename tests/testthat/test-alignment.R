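test_that("reading validates lengths, ids and alphabet", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTAC", ">c", "ACGAACGTAC"), fa)
  aln <- read_alignment(fa)
  expect_s3_class(aln, "seq_alignment")
  expect_equal(length(aln$ids), 3L)
  expect_equal(aln$length, 10L)
  expect_true(all(is.na(aln$metadata$population)))

  md <- tempfile(fileext = ".csv")
  writeLines(c("id,site,population,group", "a,S1,P1,G1", "b,S1,P1,G1"), md)
  aln2 <- read_alignment(fa, md)
  expect_equal(aln2$metadata$population, c("P1", "P1", NA))

  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTA"), fa)
  expect_error(read_alignment(fa), "length mismatch.*b")
  expect_error(seq_alignment(c(a = "ACGT", b = "ACXT")), "illegal character")
  expect_error(seq_alignment(c(a = "ACGT", a = "ACGT")), "unique")
})

test_that("haplotype collapsing conserves counts and matches exact grouping", {
  aln <- make_aln(setNames(rep("ACGTACGT", 5), paste0("i", 1:5)))
  h <- collapse_haplotypes(aln)
  expect_equal(length(h$haplotypes), 1L)
  expect_equal(sum(h$frequency), 5L)

  aln2 <- random_aln(8, 60, seed = 2)
  expect_equal(length(collapse_haplotypes(aln2)$haplotypes), 8L)

  # oracle: brute-force grouping of the raw strings on a simulated sample
  ds <- simulate_dataset("aplochiton-like", seed = 21)
  h3 <- collapse_haplotypes(ds$alignment)
  raw <- apply(ds$alignment$seq, 1L, paste, collapse = "")
  oracle_groups <- table(match(raw, unique(raw)))
  expect_equal(sort(as.integer(table(h3$membership))),
               sort(as.integer(oracle_groups)))
  expect_equal(sum(h3$frequency), length(ds$alignment$ids))
  # expanding membership reproduces the original multiset of sequences
  expect_equal(sort(unname(h3$haplotypes[h3$membership])), sort(unname(raw)))
})

test_that("missing-tolerant collapsing merges only across missing sites", {
  aln <- make_aln(c(a = "ACGT", b = "ACGN", c = "ACTT"))
  expect_equal(length(collapse_haplotypes(aln)$haplotypes), 3L)
  expect_equal(length(collapse_haplotypes(aln, missing_tolerant = TRUE)$haplotypes), 2L)
})

test_that("segregating sites counts polymorphic columns and ignores duplicates", {
  mono <- make_aln(setNames(rep("AAAA", 3), c("a", "b", "c")))
  expect_equal(segregating_sites(mono), 0L)
  two <- make_aln(c(a = "AAAAAAAAAA", b = "AATTAAAAGA"))
  expect_equal(segregating_sites(two), 3L)
  expect_error(segregating_sites(two, character(0)), "empty")

  # duplicate invariance over random alignments
  for (s in 1:5) {
    aln <- random_aln(6, 40, seed = 100 + s)
    S0 <- segregating_sites(aln)
    dup <- rbind(aln$seq, aln$seq[1, , drop = FALSE])
    rownames(dup) <- c(aln$ids, "copy")
    expect_equal(segregating_sites(seq_alignment(dup)), S0)
  }
})

test_that("nucleotide diversity equals the brute-force pair mean", {
  pair <- make_aln(c(a = "ACGT", b = "ACGT"))
  expect_equal(nucleotide_diversity(pair)$pi, 0)
  expect_error(nucleotide_diversity(pair, "a"), "at least 2")

  aln <- make_aln(c(a = "ACGTACGTGG", b = "ACGAACGTGG",
                    c = "TCGAACGTGC", d = "ACGTACTTGG"))
  # oracle: explicit loop over all 6 pairs
  seqs <- apply(aln$seq, 1, paste, collapse = "")
  tot <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    a <- strsplit(seqs[i], "")[[1]]; b <- strsplit(seqs[j], "")[[1]]
    tot <- tot + mean(a != b)
  }
  expect_equal(nucleotide_diversity(aln)$pi, tot / 6)
})

test_that("K2P distance matches the closed form and the ape oracle", {
  expect_equal(k2p_distance("ACGTACGTAC", "ACGTACGTAC"), 0)
  # one transition among ten comparable sites: P = 0.1, Q = 0
  expect_equal(k2p_distance("ACGTACGTAC", "GCGTACGTAC"),
               -0.5 * log(1 - 0.2), tolerance = 1e-12)
  expect_error(k2p_distance("AAAA", "GGGG"), "saturated")
  expect_error(k2p_distance("NNNN", "ACGT"), "comparable")

  aln <- random_aln(6, 200, seed = 3)
  dm <- distance_matrix(aln, "K2P")
  oracle <- as.matrix(ape::dist.dna(ape::as.DNAbin(
    strsplit(setNames(apply(aln$seq, 1, paste, collapse = ""), aln$ids), "")),
    model = "K80", pairwise.deletion = TRUE))
  expect_equal(unname(dm), unname(oracle[rownames(dm), rownames(dm)]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("K2P dominates p-distance and the matrix is permutation-equivariant", {
  aln <- random_aln(7, 120, seed = 4)
  k2p <- distance_matrix(aln, "K2P")
  pd <- distance_matrix(aln, "p-distance")
  off <- upper.tri(k2p)
  expect_true(all(k2p[off] >= pd[off]))
  expect_true(all((k2p[off] > pd[off]) == (pd[off] > 0)))

  perm <- c(3, 1, 7, 5, 2, 6, 4)
  shuffled <- seq_alignment(aln$seq[perm, , drop = FALSE])
  dm2 <- distance_matrix(shuffled, "K2P")
  expect_equal(dm2, k2p[perm, perm], ignore_attr = TRUE)

  one <- distance_matrix(make_aln(c(a = "ACGT")))
  expect_equal(unname(one), matrix(0, 1, 1), ignore_attr = TRUE)
})

test_that("group distance summaries equal explicit pair enumeration", {
  seqs <- c(g1a = "AAAAAAAAAA", g1b = "AAAAAAAAAA",
            g2a = "AAAAAGGGGG", g2b = "AAAAAGGGGG")
  dm <- distance_matrix(make_aln(seqs), "p-distance")
  part <- partition(c(g1a = "x", g1b = "x", g2a = "y", g2b = "y"))
  tab <- group_distance_summary(dm, part)
  within <- tab[tab$group1 == tab$group2, ]
  between <- tab[tab$group1 != tab$group2, ]
  expect_equal(within$mean, c(0, 0))
  expect_equal(between$mean, 0.5)

  # oracle on a random 6-label matrix with 3 groups
  set.seed(9)
  m <- matrix(runif(36), 6, 6); m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(letters[1:6], letters[1:6])
  grp <- setNames(c("A", "A", "B", "B", "C", "C"), letters[1:6])
  tab2 <- group_distance_summary(m, grp)
  ab <- as.vector(m[1:2, 3:4])
  expect_equal(tab2$mean[tab2$group1 == "A" & tab2$group2 == "B"], mean(ab))
  expect_equal(tab2$se[tab2$group1 == "A" & tab2$group2 == "B"],
               sd(ab) / sqrt(length(ab)))
  expect_equal(tab2$mean[tab2$group1 == "A" & tab2$group2 == "A"], m[1, 2])
  # singleton group flagged undefined
  grp2 <- setNames(c("A", "A", "B", "B", "C", "D"), letters[1:6])
  tab3 <- group_distance_summary(m, grp2)
  expect_equal(tab3$n_pairs[tab3$group1 == "C" & tab3$group2 == "C"], 0L)
  expect_true(is.na(tab3$mean[tab3$group1 == "C" & tab3$group2 == "C"]))
})
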