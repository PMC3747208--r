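test_that("Tajima's D matches an independent evaluation of the constants", {
  aln <- random_aln(6, 20, seed = 61)
  res <- tajimas_d(aln)
  # oracle: recompute every constant step by step from the alignment
  seqs <- apply(aln$seq, 1, paste, collapse = "")
  n <- 6L
  S <- sum(vapply(seq_len(20), function(j)
    length(unique(aln$seq[, j])) > 1, logical(1)))
  k <- 0
  for (i in 1:5) for (j in (i + 1):6)
    k <- k + sum(strsplit(seqs[i], "")[[1]] != strsplit(seqs[j], "")[[1]])
  k <- k / choose(6, 2)
  a1 <- sum(1 / (1:5)); a2 <- sum(1 / (1:5)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D_oracle <- (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(res$D, D_oracle, tolerance = 1e-12)
  expect_equal(res$S, S)
  expect_equal(res$pi_hat, k, tolerance = 1e-12)

  mono <- make_aln(setNames(rep("ACGTACGT", 4), paste0("m", 1:4)))
  resm <- tajimas_d(mono)
  expect_true(resm$undefined)
  expect_true(is.na(resm$D))
})

test_that("Ewens allele probabilities normalize and match cycle-type enumeration", {
  for (n in 2:8) for (theta in c(0.3, 1, 4.7))
    expect_equal(sum(ewens_allele_probs(n, theta)), 1, tolerance = 1e-12)

  # oracle: exhaustive enumeration over cycle types (integer partitions);
  # a permutation with cycle type (m_1, m_2, ...) occurs
  # n! / prod(j^m_j * m_j!) times and theta^k weights k = total cycles
  cycle_dist <- function(n, theta) {
    parts <- list()
    gen <- function(rem, maxpart, acc) {
      if (rem == 0) { parts[[length(parts) + 1]] <<- acc; return() }
      for (p in seq_len(min(rem, maxpart))) gen(rem - p, p, c(acc, p))
    }
    gen(n, n, integer(0))
    w <- numeric(n)
    for (pt in parts) {
      m <- tabulate(pt, n)
      count <- factorial(n) / prod(vapply(seq_len(n), function(j)
        j^m[j] * factorial(m[j]), numeric(1)))
      k <- length(pt)
      w[k] <- w[k] + count * theta^k
    }
    w / sum(w)
  }
  for (n in c(4L, 6L, 8L)) for (theta in c(1, 2.5))
    expect_equal(ewens_allele_probs(n, theta), cycle_dist(n, theta),
                 tolerance = 1e-10)
})

test_that("Fu's Fs follows the Ewens tail and flags degenerate input", {
  aln <- random_aln(8, 60, seed = 67)
  res <- fus_fs(aln)
  probs <- ewens_allele_probs(res$n, res$pi_hat)
  Sp <- sum(probs[res$k_obs:res$n])
  expect_equal(res$Fs, log(Sp / (1 - Sp)), tolerance = 1e-10)

  mono <- make_aln(setNames(rep("ACGTACGT", 4), paste0("m", 1:4)))
  expect_true(fus_fs(mono)$undefined)
})

test_that("coalescent p-values behave at the sentinels and under neutrality", {
  aln <- random_aln(8, 60, seed = 71)
  st <- fus_fs(aln)
  st$Fs <- -Inf
  st2 <- neutrality_pvalues(st, reps = 100, seed = 5)
  expect_equal(st2$p_Fs, 0)

  # neutral calibration: simulated D centred near zero (n = 20, theta = 5)
  set.seed(73)
  Ds <- replicate(800, {
    s <- delimkit:::.sim_coal_stats(20, 5)
    if (s$S > 0) delimkit:::.tajima_D_stat(20, s$S, s$pi_hat) else 0
  })
  expect_lt(abs(mean(Ds)), 0.15)

  # expansion makes Fs strongly negative relative to constant size
  set.seed(79)
  fs_pair <- replicate(150, {
    g <- delimkit:::.sim_coal_stats(15, 3, growth = 10)
    c0 <- delimkit:::.sim_coal_stats(15, 3)
    fg <- if (g$pi_hat > 0) delimkit:::.fu_fs_stat(15, g$pi_hat, g$k_obs)$Fs else 0
    fc <- if (c0$pi_hat > 0) delimkit:::.fu_fs_stat(15, c0$pi_hat, c0$k_obs)$Fs else 0
    c(fg, fc)
  })
  expect_lt(mean(fs_pair[1, ]), mean(fs_pair[2, ]))
})

test_that("AMOVA recovers forced partitions and matches brute-force SSDs", {
  # two internally monomorphic populations fixed for distinct haplotypes
  seqs <- c(p1a = "AAAAAAAAAA", p1b = "AAAAAAAAAA", p1c = "AAAAAAAAAA",
            p2a = "AAAAAGGGGG", p2b = "AAAAAGGGGG", p2c = "AAAAAGGGGG")
  dm <- distance_matrix(make_aln(seqs), "p-distance")
  hier <- data.frame(id = names(seqs),
                     population = rep(c("P1", "P2"), each = 3))
  res <- amova(dm, hier, permutations = 99, seed = 1)
  expect_equal(res$table$percent[1], 100, tolerance = 1e-9)
  expect_equal(res$phi[["phi_ST"]], 1, tolerance = 1e-9)

  # random 12-sequence, 3-population data against an independent SSD oracle
  aln <- random_aln(12, 50, seed = 83)
  dmr <- distance_matrix(aln, "p-distance")
  pops <- rep(c("A", "B", "C"), c(3, 4, 5))
  hier2 <- data.frame(id = aln$ids, population = pops)
  res2 <- amova(dmr, hier2, permutations = 0)
  d2 <- dmr^2
  ssd_tot <- sum(d2[upper.tri(d2)]) / 12
  ssd_wp <- 0
  for (p in c("A", "B", "C")) {
    idx <- which(pops == p)
    acc <- 0
    for (i in idx) for (j in idx) if (i < j) acc <- acc + d2[i, j]
    ssd_wp <- ssd_wp + acc / length(idx)
  }
  ms_ap <- (ssd_tot - ssd_wp) / 2
  ms_wp <- ssd_wp / 9
  ncoef <- (12 - (9 + 16 + 25) / 12) / 2
  sig_c <- ms_wp
  sig_b <- (ms_ap - sig_c) / ncoef
  expect_equal(res2$table$sigma2, c(sig_b, sig_c), tolerance = 1e-12)
  expect_equal(sum(res2$table$percent), 100, tolerance = 1e-9)
  expect_equal(sum(res2$table$df), 11)
})

test_that("three-level AMOVA percentages are relabel-invariant and sum to 100", {
  ds <- simulate_dataset("aplochiton-like", seed = 89)
  dm <- distance_matrix(ds$alignment, "p-distance")
  hier <- data.frame(id = ds$alignment$ids,
                     population = ds$alignment$metadata$population,
                     group = ds$alignment$metadata$group)
  res <- amova(dm, hier, permutations = 49, seed = 7)
  expect_equal(sum(res$table$percent), 100, tolerance = 0.01)
  expect_equal(sum(res$table$df), length(ds$alignment$ids) - 1L)
  expect_gt(res$table$percent[1], 80)       # species dominate the variance

  relab <- hier
  relab$group <- paste0("grp_", relab$group)
  relab$population <- toupper(relab$population)
  res_r <- amova(dm, relab, permutations = 0)
  expect_equal(res_r$table$percent, res$table$percent, tolerance = 1e-9)
})

test_that("Mantel statistics behave on affine, identical and constant matrices", {
  set.seed(97)
  m <- matrix(runif(64), 8, 8); m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(paste0("q", 1:8), paste0("q", 1:8))
  aff <- 3 * m + 2; diag(aff) <- 0
  r1 <- mantel_test(m, aff, permutations = 99, seed = 3)
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_lt(r1$p.value, 0.05)
  expect_equal(mantel_test(m, m, permutations = 49, seed = 3)$r, 1)

  const <- matrix(1, 8, 8); diag(const) <- 0
  dimnames(const) <- dimnames(m)
  expect_true(mantel_test(m, const, permutations = 49)$undefined)

  # agreement with the vegan implementation (one-sided)
  vg <- vegan::mantel(as.dist(m), as.dist(aff), permutations = 99)
  expect_equal(r1$r, unname(vg$statistic), tolerance = 1e-12)
})

test_that("great-circle site distances are symmetric and plausible", {
  sites <- data.frame(site = c("s1", "s2", "s3"),
                      lat = c(-39, -40, -41), lon = c(-73, -73, -73))
  g <- geo_distance_matrix(sites)
  expect_equal(g, t(g))
  expect_equal(diag(g), c(s1 = 0, s2 = 0, s3 = 0))
  # one degree of latitude is roughly 111 km
  expect_equal(g["s1", "s2"], 111, tolerance = 0.01)
})
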