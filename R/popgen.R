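# Neutrality tests, AMOVA, Mantel --------------------------------------------

.delimkit_cache <- new.env(parent = emptyenv())

# log unsigned Stirling numbers of the first kind, |s(n, k)| for k = 1..n,
# by the exact recurrence |s(n+1,k)| = n|s(n,k)| + |s(n,k-1)| in log space
.log_stirling1 <- function(n) {
  key <- as.character(n)
  if (!is.null(.delimkit_cache[[key]])) return(.delimkit_cache[[key]])
  if (n > 200L) stop("Stirling table limited to n <= 200")
  lse2 <- function(a, b) {
    if (a == -Inf) return(b); if (b == -Inf) return(a)
    m <- max(a, b); m + log(exp(a - m) + exp(b - m))
  }
  row <- 0                                   # n = 1: |s(1,1)| = 1
  for (nn in seq_len(n - 1L)) {              # build row nn+1 from row nn
    new <- numeric(nn + 1L)
    for (k in seq_len(nn + 1L)) {
      a <- if (k <= nn) log(nn) + row[k] else -Inf
      b <- if (k >= 2L) row[k - 1L] else -Inf
      new[k] <- lse2(a, b)
    }
    row <- new
  }
  .delimkit_cache[[key]] <- row
  row
}

#' Ewens sampling distribution of the allele count
#'
#' Probability `Pr(K = k)` of observing `k` distinct alleles in a sample of
#' `n` under the Ewens sampling formula,
#' `Pr(K = k) = |s(n,k)| theta^k / (theta (theta+1) ... (theta+n-1))`,
#' with unsigned Stirling numbers of the first kind computed exactly in log
#' space.
#'
#' @param n Sample size.
#' @param theta Scaled mutation parameter (> 0).
#' @return Numeric vector of probabilities for k = 1..n (sums to 1).
#' @export
ewens_allele_probs <- function(n, theta) {
  stopifnot(n >= 1L, theta > 0)
  ls <- .log_stirling1(n)
  logp <- ls + seq_len(n) * log(theta) - sum(log(theta + 0:(n - 1L)))
  exp(logp)
}

# Tajima's D from summary statistics (n sequences, S segregating sites,
# k mean pairwise differences per sequence)
.tajima_D_stat <- function(n, S, k) {
  if (S == 0L || n < 2L) return(NA_real_)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Fu's Fs from (n, theta-hat = mean pairwise differences, observed allele
# count). Returns list(Fs, Sprime, clamped)
.fu_fs_stat <- function(n, theta, k_obs) {
  if (theta <= 0) return(list(Fs = NA_real_, Sprime = NA_real_, clamped = FALSE))
  p <- ewens_allele_probs(n, theta)
  Sp <- sum(p[k_obs:n])
  clamped <- FALSE
  eps <- 1e-15
  if (Sp <= 0) { Sp <- eps; clamped <- TRUE }
  if (Sp >= 1) { Sp <- 1 - eps; clamped <- TRUE }
  list(Fs = log(Sp / (1 - Sp)), Sprime = Sp, clamped = clamped)
}

.neutrality_base <- function(aln, subset, complete_deletion = FALSE) {
  ids <- if (is.null(subset)) aln$ids else subset
  div <- nucleotide_diversity(aln, ids, complete_deletion = complete_deletion)
  haps <- collapse_haplotypes(
    seq_alignment(setNames(apply(aln$seq[.aln_rows(aln, ids), , drop = FALSE],
                                 1L, paste, collapse = ""), ids)))
  list(n = div$n, S = div$S, pi_hat = div$k, k_obs = length(haps$haplotypes))
}

#' Tajima's D neutrality test
#'
#' Computes Tajima's D from the number of segregating sites and the mean
#' number of pairwise differences. `D` is undefined (flagged, `NA`) for
#' monomorphic samples. Significance can be attached afterwards with
#' [neutrality_pvalues].
#'
#' @param aln A [seq_alignment].
#' @param subset Optional character vector of ids.
#' @param complete_deletion Deletion policy (default pairwise).
#' @return Object of class `neutrality_stats` with fields `n`, `S`,
#'   `pi_hat` (mean pairwise differences per sequence), `k_obs` (haplotype
#'   count), `D`, `Fs`, `p_D`, `p_Fs`, `undefined`.
#' @export
tajimas_d <- function(aln, subset = NULL, complete_deletion = FALSE) {
  base <- .neutrality_base(aln, subset, complete_deletion)
  fs <- .fu_fs_stat(base$n, base$pi_hat, base$k_obs)
  structure(c(base, list(D = .tajima_D_stat(base$n, base$S, base$pi_hat),
                         Fs = fs$Fs, p_D = NA_real_, p_Fs = NA_real_,
                         undefined = base$S == 0L,
                         reps = NA_integer_, seed = NA_integer_)),
            class = "neutrality_stats")
}

#' Fu's Fs neutrality test
#'
#' Estimates `theta` by the mean number of pairwise differences, evaluates
#' `S' = Pr(K >= k_obs | theta)` under the Ewens sampling formula and
#' returns `Fs = ln(S' / (1 - S'))`. Numerically degenerate `S'` values are
#' clamped with a warning; `theta = 0` yields an undefined-flagged result.
#'
#' @inheritParams tajimas_d
#' @return A `neutrality_stats` object (see [tajimas_d]).
#' @export
fus_fs <- function(aln, subset = NULL, complete_deletion = FALSE) {
  out <- tajimas_d(aln, subset, complete_deletion)
  if (out$pi_hat <= 0) {
    out$undefined <- TRUE
    return(out)
  }
  fs <- .fu_fs_stat(out$n, out$pi_hat, out$k_obs)
  if (fs$clamped) warning("S' numerically degenerate; Fs clamped")
  out$Fs <- fs$Fs
  out
}

#' @export
print.neutrality_stats <- function(x, ...) {
  cat("n =", x$n, " S =", x$S, " mean pairwise diff =",
      format(x$pi_hat, digits = 4), " haplotypes =", x$k_obs, "\n")
  cat("Tajima's D =", format(x$D, digits = 4),
      if (!is.na(x$p_D)) paste0("(p = ", format(x$p_D, digits = 3), ")"), "\n")
  cat("Fu's Fs    =", format(x$Fs, digits = 4),
      if (!is.na(x$p_Fs)) paste0("(p = ", format(x$p_Fs, digits = 3), ")"), "\n")
  invisible(x)
}

# one neutral (or exponentially growing) coalescent sample; returns summary
# statistics. Time in units of 2N generations, mutation rate theta/2 per
# lineage; growth > 0 compresses old time as t = log(1 + growth*tau)/growth.
.sim_coal_stats <- function(n, theta, growth = 0) {
  members <- as.list(seq_len(n))
  sig <- character(n)
  S <- 0L
  pi_num <- 0
  tau <- 0
  t_prev <- 0
  marker <- 0L
  for (k in seq(n, 2L)) {
    tau <- tau + stats::rexp(1L, k * (k - 1) / 2)
    t_now <- if (growth > 0) log(1 + growth * tau) / growth else tau
    dt <- t_now - t_prev
    t_prev <- t_now
    muts <- stats::rpois(k, theta / 2 * dt)
    for (l in which(muts > 0L)) {
      m <- muts[l]
      sz <- length(members[[l]])
      S <- S + m
      pi_num <- pi_num + m * sz * (n - sz)
      marker <- marker + 1L
      sig[members[[l]]] <- paste0(sig[members[[l]]], ",", marker)
    }
    pair <- sample.int(k, 2L)
    a <- min(pair); b <- max(pair)
    members[[a]] <- c(members[[a]], members[[b]])
    members[[b]] <- NULL
  }
  k_hat <- 2 * pi_num / (n * (n - 1))
  list(S = S, pi_hat = k_hat, k_obs = length(unique(sig)))
}

#' Coalescent significance for neutrality statistics
#'
#' Simulates neutral constant-size coalescent samples of the observed size
#' conditioned on the observed `theta` (estimated by the mean pairwise
#' differences) and attaches lower-tail simulation p-values: `p_D` is the
#' fraction of simulated D values at or below the observed D (the
#' expansion-sensitive direction) and `p_Fs` likewise for Fs. Simulated
#' samples whose statistic is undefined (monomorphic) contribute the neutral
#' value 0. By the usual convention, Fs is called significant at the 5%
#' level only when `p_Fs < 0.02`.
#'
#' @param stats A `neutrality_stats` object (from [tajimas_d] or [fus_fs]).
#' @param reps Number of coalescent replicates (default 10000; >= 100).
#' @param seed Optional integer seed.
#' @return The updated `neutrality_stats` with `p_D`, `p_Fs`, `reps`,
#'   `seed` filled in.
#' @export
neutrality_pvalues <- function(stats, reps = 10000L, seed = NULL) {
  stopifnot(inherits(stats, "neutrality_stats"), reps >= 100L)
  if (!is.null(seed)) set.seed(seed)
  theta <- stats$pi_hat
  if (theta <= 0) {
    stats$p_D <- NA_real_; stats$p_Fs <- NA_real_
    return(stats)
  }
  D_sim <- numeric(reps)
  Fs_sim <- numeric(reps)
  for (r in seq_len(reps)) {
    s <- .sim_coal_stats(stats$n, theta)
    D_sim[r] <- if (s$S > 0L) .tajima_D_stat(stats$n, s$S, s$pi_hat) else 0
    Fs_sim[r] <- if (s$pi_hat > 0) .fu_fs_stat(stats$n, s$pi_hat, s$k_obs)$Fs else 0
  }
  if (!is.na(stats$D)) stats$p_D <- mean(D_sim <= stats$D)
  if (!is.na(stats$Fs)) stats$p_Fs <- mean(Fs_sim <= stats$Fs)
  stats$reps <- as.integer(reps)
  stats$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  stats
}

# ---------------------------------------------------------------------------
# AMOVA

# sum over all within-set pairs of squared distances, divided by set size
.ssd_within <- function(d2, idx) {
  if (length(idx) < 2L) return(0)
  sum(d2[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]) / length(idx)
}

.amova_components <- function(d2, pop, grp) {
  N <- length(pop)
  pops <- unique(pop)
  P <- length(pops)
  ssd_total <- sum(d2[upper.tri(d2)]) / N
  ssd_wp <- sum(vapply(pops, function(p) .ssd_within(d2, which(pop == p)),
                       numeric(1L)))
  n_p <- as.vector(table(pop)[pops])
  if (is.null(grp)) {                       # two-level design
    df_ap <- P - 1L; df_wp <- N - P
    ssd_ap <- ssd_total - ssd_wp
    ms_ap <- ssd_ap / df_ap; ms_wp <- ssd_wp / df_wp
    ncoef <- (N - sum(n_p^2) / N) / df_ap
    sig_c <- ms_wp
    sig_b <- (ms_ap - sig_c) / ncoef
    tab <- data.frame(
      level = c("among populations", "within populations"),
      df = c(df_ap, df_wp), SSD = c(ssd_ap, ssd_wp), MS = c(ms_ap, ms_wp),
      sigma2 = c(sig_b, sig_c))
    phi <- c(phi_ST = sig_b / (sig_b + sig_c))
  } else {                                  # three-level design
    groups <- unique(grp)
    G <- length(groups)
    ssd_wg <- sum(vapply(groups, function(g) .ssd_within(d2, which(grp == g)),
                         numeric(1L)))
    ssd_ag <- ssd_total - ssd_wg
    ssd_ap <- ssd_wg - ssd_wp
    df_ag <- G - 1L; df_ap <- P - G; df_wp <- N - P
    ms_ag <- ssd_ag / df_ag
    ms_ap <- if (df_ap > 0L) ssd_ap / df_ap else NA_real_
    ms_wp <- ssd_wp / df_wp
    grp_of_pop <- vapply(pops, function(p) grp[match(p, pop)], grp[1L])
    n_g <- vapply(groups, function(g) sum(grp == g), numeric(1L))
    sum_np2_over_ng <- sum(vapply(groups, function(g) {
      pp <- pops[grp_of_pop == g]
      sum(n_p[match(pp, pops)]^2) / sum(pop %in% pp)
    }, numeric(1L)))
    n1 <- (N - sum_np2_over_ng) / df_ap
    n2 <- (sum_np2_over_ng - sum(n_p^2) / N) / df_ag
    n3 <- (N - sum(n_g^2) / N) / df_ag
    sig_c <- ms_wp
    sig_b <- if (df_ap > 0L) (ms_ap - sig_c) / n1 else 0
    sig_a <- (ms_ag - sig_c - n2 * sig_b) / n3
    tab <- data.frame(
      level = c("among groups", "among populations within groups",
                "within populations"),
      df = c(df_ag, df_ap, df_wp), SSD = c(ssd_ag, ssd_ap, ssd_wp),
      MS = c(ms_ag, ms_ap, ms_wp), sigma2 = c(sig_a, sig_b, sig_c))
    phi <- c(phi_CT = sig_a / sum(tab$sigma2),
             phi_SC = sig_b / (sig_b + sig_c),
             phi_ST = (sig_a + sig_b) / sum(tab$sigma2))
  }
  tab$percent <- 100 * tab$sigma2 / sum(tab$sigma2)
  list(table = tab, phi = phi)
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions the genetic variance computed from squared pairwise distances
#' into hierarchical components (among groups, among populations within
#' groups, within populations -- or the two-level reduction without groups),
#' solving the variance components from the expected mean squares with
#' unequal-sample-size coefficients. Significance is assessed by permuting
#' units at the appropriate level: individuals among populations (overall
#' and within groups) and whole populations among groups.
#'
#' @param dm Distance matrix over individuals (e.g. K2P); distances are
#'   squared as-is.
#' @param hierarchy `data.frame` with columns `id`, `population` and
#'   optionally `group`, covering all matrix labels.
#' @param levels 2 or 3; default inferred from the presence of >1 group.
#' @param permutations Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return Object of class `amova_result`: `table` (df, SSD, MS, sigma2,
#'   percent per level), `phi`, `p.values`, `permutations`, `seed`.
#' @export
amova <- function(dm, hierarchy, levels = NULL, permutations = 999L,
                  seed = NULL) {
  stopifnot(is.matrix(dm))
  ids <- rownames(dm)
  m <- match(ids, as.character(hierarchy$id))
  if (anyNA(m)) stop("hierarchy does not cover all ids")
  pop <- as.character(hierarchy$population)[m]
  grp <- if ("group" %in% names(hierarchy))
    as.character(hierarchy$group)[m] else NULL
  if (is.null(levels))
    levels <- if (!is.null(grp) && length(unique(grp)) > 1L) 3L else 2L
  if (levels == 2L) grp <- NULL
  if (length(unique(pop)) < 2L) stop("need at least two populations")
  if (!is.null(grp) && length(unique(grp)) < 2L)
    stop("three-level design needs at least two groups")
  d2 <- dm^2
  obs <- .amova_components(d2, pop, grp)
  if (!is.null(seed)) set.seed(seed)
  pv <- setNames(rep(NA_real_, length(obs$phi)), names(obs$phi))
  if (permutations > 0L) {
    cnt <- setNames(numeric(length(obs$phi)), names(obs$phi))
    N <- length(pop)
    pops <- unique(pop)
    for (b in seq_len(permutations)) {
      # phi_ST: permute individuals among populations (whole design)
      perm <- sample.int(N)
      st <- .amova_components(d2[perm, perm], pop, grp)
      cnt["phi_ST"] <- cnt["phi_ST"] +
        (st$phi["phi_ST"] >= obs$phi["phi_ST"] - 1e-12)
      if (!is.null(grp)) {
        # phi_SC: permute individuals among populations within groups
        perm2 <- seq_len(N)
        for (g in unique(grp)) {
          idx <- which(grp == g)
          perm2[idx] <- idx[sample.int(length(idx))]
        }
        sc <- .amova_components(d2[perm2, perm2], pop, grp)
        cnt["phi_SC"] <- cnt["phi_SC"] +
          (sc$phi["phi_SC"] >= obs$phi["phi_SC"] - 1e-12)
        # phi_CT: permute whole populations among groups
        grp_of_pop <- vapply(pops, function(p) grp[match(p, pop)], grp[1L])
        shuf <- grp_of_pop[sample.int(length(pops))]
        grp_perm <- shuf[match(pop, pops)]
        ct <- .amova_components(d2, pop, grp_perm)
        cnt["phi_CT"] <- cnt["phi_CT"] +
          (ct$phi["phi_CT"] >= obs$phi["phi_CT"] - 1e-12)
      }
      if (is.null(grp)) next
    }
    pv <- cnt / permutations
  }
  structure(list(table = obs$table, phi = obs$phi, p.values = pv,
                 permutations = as.integer(permutations),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (", x$permutations, "permutations )\n")
  print(cbind(x$table[, c("level", "df")],
              round(x$table[, c("SSD", "MS", "sigma2", "percent")], 4)))
  cat("Phi statistics:\n")
  for (nm in names(x$phi))
    cat(" ", nm, "=", format(x$phi[[nm]], digits = 4),
        " p =", format(x$p.values[[nm]], digits = 3), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Mantel test

#' Mantel matrix-correlation test
#'
#' Pearson correlation of the upper-triangle entries of two distance
#' matrices, with significance by joint row/column permutation of one
#' matrix. The default alternative is two-sided: the p-value is the
#' fraction of permutations with `|r|` at least the observed `|r|`.
#'
#' @param dm_a,dm_b Symmetric matrices over the same labels.
#' @param permutations Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return Object of class `mantel_result`: `r`, `p.value`, `permutations`,
#'   `seed`, `alternative`.
#' @export
mantel_test <- function(dm_a, dm_b, permutations = 999L, seed = NULL,
                        alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(dm_a), is.matrix(dm_b), all(dim(dm_a) == dim(dm_b)))
  if (!is.null(rownames(dm_a)) && !is.null(rownames(dm_b))) {
    if (!setequal(rownames(dm_a), rownames(dm_b)))
      stop("matrices have different labels")
    dm_b <- dm_b[rownames(dm_a), rownames(dm_a)]
  }
  ut <- upper.tri(dm_a)
  a <- dm_a[ut]; b <- dm_b[ut]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(structure(list(r = NA_real_, p.value = NA_real_,
                          permutations = 0L, seed = NA_integer_,
                          alternative = alternative, undefined = TRUE),
                     class = "mantel_result"))
  }
  r_obs <- stats::cor(a, b)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(dm_a)
  hits <- 0L
  for (i in seq_len(permutations)) {
    perm <- sample.int(n)
    r_p <- stats::cor(a, dm_b[perm, perm][ut])
    hits <- hits + if (alternative == "two.sided")
      (abs(r_p) >= abs(r_obs) - 1e-12) else (r_p >= r_obs - 1e-12)
  }
  structure(list(r = r_obs, p.value = hits / permutations,
                 permutations = as.integer(permutations),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 alternative = alternative, undefined = FALSE),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  if (isTRUE(x$undefined)) cat("Mantel test: undefined (constant matrix)\n")
  else cat("Mantel r =", format(x$r, digits = 4), " p =",
           format(x$p.value, digits = 3), "(", x$alternative, ",",
           x$permutations, "permutations )\n")
  invisible(x)
}

#' Great-circle distance matrix from site coordinates
#'
#' @param sites `data.frame` with columns `site`, `lat`, `lon` (degrees).
#' @return Symmetric matrix of distances in kilometres, labelled by site.
#' @export
geo_distance_matrix <- function(sites) {
  stopifnot(all(c("site", "lat", "lon") %in% names(sites)))
  n <- nrow(sites)
  d <- matrix(0, n, n, dimnames = list(sites$site, sites$site))
  for (i in seq_len(n)) {
    d[i, ] <- geosphere::distHaversine(
      c(sites$lon[i], sites$lat[i]), cbind(sites$lon, sites$lat)) / 1000
  }
  d
}
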