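test_that("interval log-likelihood matches analytic and brute-force values", {
  # two tips: a single interval with constant hazard b gives ln b - b x
  tr2 <- ape::read.tree(text = "(a:0.7,b:0.7);")
  s <- branching_schedule(tr2)
  b <- 3 * 2^1.2
  expect_equal(gmyc_loglik(s, list(lambda0 = 3, p0 = 1.2), mode = "null"),
               log(b) - b * 0.7, tolerance = 1e-12)

  # null model with p0 = 1 on a 5-tip tree: oracle = explicit per-interval
  # product of exponential densities
  set.seed(23)
  tr5 <- ape::rcoal(5)
  s5 <- branching_schedule(tr5)
  lam <- 1.7
  oracle <- 0
  for (i in seq_along(s5$waits)) {
    bi <- lam * s5$n_lineages[i]
    oracle <- oracle + log(bi) - bi * s5$waits[i]
  }
  expect_equal(gmyc_loglik(s5, list(lambda0 = lam, p0 = 1), mode = "null"),
               oracle, tolerance = 1e-12)

  # threshold mode with all-singleton classification reduces to the null form
  thr <- min(s5$heights) / 2
  st <- branching_schedule(tr5, threshold = thr)
  expect_equal(gmyc_loglik(st, list(lambda1 = lam, lambda2 = 1e-9,
                                    p1 = 1, p2 = 1)),
               oracle, tolerance = 1e-6)
  expect_error(gmyc_loglik(s5, list(lambda0 = -1, p0 = 1), mode = "null"),
               "positive")
})

test_that("likelihood-ratio arithmetic is exact", {
  eq <- gmyc_lr_test(10, 10, df = 2)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p.value, 1)
  expect_error(gmyc_lr_test(9, 10, df = 2), "optimizer failure")

  lr <- gmyc_lr_test(73.08939, 65.74721, df = 2)
  expect_equal(lr$statistic, 14.6844, tolerance = 1e-5)
  lr2 <- gmyc_lr_test(74.68891, 65.74721, df = 5)
  expect_equal(lr2$statistic, 17.8834, tolerance = 1e-5)
  lr3 <- gmyc_lr_test(74.68891, 73.08939, df = 3)
  expect_equal(lr3$statistic, 3.19904, tolerance = 1e-6)
  expect_equal(lr3$p.value, 0.3619, tolerance = 2e-4)
})

test_that("fitted log-likelihoods are monotone across nested modes", {
  set.seed(29)
  trees <- list(ape::rcoal(12),
                pruned_gene_tree(simulate_dataset("aplochiton-like", 41)),
                simulate_species_tree(15, lambda = 3))
  for (tr in trees) {
    f0 <- gmyc_fit(tr, "null")
    f1 <- gmyc_fit(tr, "single")
    fm <- gmyc_fit(tr, "multiple", max_thresholds = 3)
    expect_lte(f0$logL, f1$logL + 1e-6)
    expect_lte(f1$logL, fm$logL + 1e-6)
  }
})

test_that("the threshold delimitation matches an independent tree cut", {
  ds <- simulate_dataset("aplochiton-like", seed = 43)
  tr <- pruned_gene_tree(ds)
  f <- gmyc_fit(tr, "single")
  expect_equal(f$entities, 3L)
  # oracle: count edges crossing the fitted threshold
  depth <- ape::node.depth.edgelength(f$tree)
  hts <- max(depth) - depth
  crossing <- sum(hts[f$tree$edge[, 1]] > f$threshold &
                  hts[f$tree$edge[, 2]] <= f$threshold)
  expect_equal(f$entities, crossing)
  # delimited entities equal the generating species
  truth <- ds$truth$species[names(f$partition$assignment)]
  expect_equal(unname(match(f$partition$assignment,
                            unique(f$partition$assignment))),
               unname(match(truth, unique(truth))))
})

test_that("pure-Yule trees rarely reject the null", {
  set.seed(31)
  rejections <- 0L
  n_rep <- 15L
  for (i in seq_len(n_rep)) {
    tr <- simulate_species_tree(25, lambda = 2)
    f1 <- gmyc_fit(tr, "single")
    lr <- gmyc_lr_test(f1$logL, f1$null_logL, df = 3)
    rejections <- rejections + (lr$p.value < 0.05)
  }
  expect_lte(rejections, 4L)
})

test_that("duplicate haplotypes and too-small trees are rejected", {
  dup <- ape::read.tree(text = "((a:0,b:0):1,c:1);")
  expect_error(gmyc_fit(dup), "zero-length pendant")
  two <- ape::read.tree(text = "(a:1,b:1);")
  expect_error(gmyc_fit(two), "at least 3 tips")
})

test_that("conspecificity over a tree sample reflects the clusters", {
  ds <- simulate_dataset("aplochiton-like", seed = 47)
  tr <- pruned_gene_tree(ds)
  # identical trees give 0/1 entries only
  cm0 <- conspecificity_matrix(list(tr, tr, tr))
  expect_true(all(cm0$prob %in% c(0, 1)))
  expect_true(all(diag(cm0$prob) == 1))

  # bootstrap-UPGMA sample: resample alignment columns, rebuild trees
  h <- collapse_haplotypes(ds$alignment)
  set.seed(53)
  boots <- lapply(1:12, function(i) {
    cols <- sample.int(h$alignment$length, replace = TRUE)
    baln <- seq_alignment(h$alignment$seq[, cols, drop = FALSE])
    upgma_clock_tree(distance_matrix(baln, "p-distance"))
  })
  cm <- conspecificity_matrix(boots)
  truth <- ds$truth$species[names(h$membership)[match(cm$labels,
                                                      h$membership)]]
  same <- outer(truth, truth, "==")
  off <- upper.tri(same)
  expect_gte(mean(cm$prob[off][same[off]]), 0.9)
  expect_lte(max(cm$prob[off][!same[off]]), 0.1)
})
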