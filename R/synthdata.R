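# Synthetic sequence and morphology data ------------------------------------

#' Simulation presets
#'
#' Named parameter bundles emulating the statistical structure the analysis
#' pipeline expects:
#' \describe{
#'   \item{`aplochiton-like`}{Three species sampled 24/24/12 with 3/5/2
#'     populations, deep near-simultaneous divergences (pairwise species
#'     distances in the 7--13\% band), within-species diversity around
#'     0.001--0.002/site, shallow geographic structure, and a recent
#'     demographic expansion in the first species.}
#'   \item{`null-neutral`}{A single neutral constant-size species (n = 20,
#'     theta = 0.002/site).}
#'   \item{`single-species-yule`}{A 40-tip pure-Yule tree used directly as
#'     the genealogy (no speciation-coalescent transition).}
#' }
#'
#' @param name Preset name.
#' @return A list of class `sim_config`.
#' @export
sim_preset <- function(name = c("aplochiton-like", "null-neutral",
                                "single-species-yule")) {
  name <- match.arg(name)
  cfg <- switch(name,
    "aplochiton-like" = list(
      n_species = 3L, lambda = 20, height_range = c(0.045, 0.055),
      min_split_frac = 0.75,
      n_samples = c(24L, 24L, 12L), demes = c(3L, 5L, 2L),
      theta = c(0.008, 0.0012, 0.0010), growth = c(5, 0, 0),
      migration = 10, theta_anc = 0.002,
      seq_length = 677L, kappa = 4,
      morphology = .default_morpho_config()),
    "null-neutral" = list(
      n_species = 1L, lambda = 1, height_range = NULL, min_split_frac = NULL,
      n_samples = 20L, demes = 1L, theta = 0.002, growth = 0,
      migration = 30, theta_anc = 0.002, seq_length = 677L, kappa = 4,
      morphology = NULL),
    "single-species-yule" = list(
      n_species = 40L, lambda = 1, height_range = NULL, min_split_frac = NULL,
      n_samples = 1L, demes = 1L, theta = 0, growth = 0, migration = 0,
      theta_anc = 0, seq_length = 677L, kappa = 4, morphology = NULL))
  cfg$preset <- name
  structure(cfg, class = "sim_config")
}

# morphology generator defaults: one cleanly separable class (AM) and two
# overlapping classes with unequal covariances (AT more variable)
.default_morpho_config <- function() {
  list(
    classes = list(
      AZ = list(n = 31L, mean = c(60, 9.8, 57),
                cov = diag(c(9, 0.5, 4)), p_pattern1 = 0.15),
      AT = list(n = 31L, mean = c(54, 8.8, 58),
                cov = matrix(c(25, 1.5, 2, 1.5, 1.1, 0.3, 2, 0.3, 9),
                             3, 3), p_pattern1 = 0.55)),
    am = list(n = 13L, mean = c(48, 8.0, 60), cov = diag(c(6, 0.4, 4))))
}

#' Simulate a Yule species tree
#'
#' Forward pure-birth simulation: starting from one lineage, each lineage
#' splits at rate `lambda`, so the waiting time with k lineages is
#' exponential with rate `k * lambda`; after the n-th species appears one
#' further exponential waiting time elapses before the present. Heights are
#' in expected substitutions per site. Optionally the root height is
#' rescaled into `height_range` and shallow splits are raised to
#' `min_split_frac` of the root height (a preset calibration that keeps all
#' between-species divergences inside a target band).
#'
#' @param n_species Number of species (tips).
#' @param lambda Speciation rate (events per lineage per unit height).
#' @param height_range Optional `c(lo, hi)`; root height drawn uniformly.
#' @param min_split_frac Optional minimum internal-node height as a
#'   fraction of the root height.
#' @param seed Optional integer seed.
#' @return An ape `phylo` (ultrametric); for `n_species = 1` a one-tip
#'   stand-in list with elements `tip.label` and `height = 0`.
#' @export
simulate_species_tree <- function(n_species, lambda = 1, height_range = NULL,
                                  min_split_frac = NULL, seed = NULL) {
  stopifnot(n_species >= 1L, lambda > 0)
  if (!is.null(seed)) set.seed(seed)
  if (n_species == 1L)
    return(structure(list(tip.label = "sp1", height = 0),
                     class = "singleton_tree"))
  born <- c(0)                 # birth time of each lineage record
  split_t <- c(NA_real_)
  kids <- list(NULL)
  active <- 1L
  t <- 0
  repeat {
    k <- length(active)
    t <- t + stats::rexp(1L, k * lambda)
    if (k == n_species) break                    # final waiting time elapsed
    pick <- active[sample.int(k, 1L)]
    id1 <- length(born) + 1L; id2 <- length(born) + 2L
    born <- c(born, t, t)
    split_t <- c(split_t, NA_real_, NA_real_)
    kids[[pick]] <- c(id1, id2)
    length(kids) <- length(born)       # new lineages are leaves (NULL kids)
    split_t[pick] <- t
    active <- c(setdiff(active, pick), id1, id2)
  }
  present <- t
  nwk <- function(i) {
    if (is.null(kids[[i]]))
      paste0("t", i, ":", format(present - born[i], digits = 15))
    else paste0("(", nwk(kids[[i]][1L]), ",", nwk(kids[[i]][2L]), "):",
                format(split_t[i] - born[i], digits = 15))
  }
  root_kids <- kids[[1L]]
  tree <- ape::read.tree(text = paste0("(", nwk(root_kids[1L]), ",",
                                       nwk(root_kids[2L]), ");"))
  tree$tip.label <- paste0("sp", seq_along(tree$tip.label))
  h <- .node_heights(tree)
  root_h <- max(h)
  if (!is.null(height_range)) {
    target <- stats::runif(1L, height_range[1L], height_range[2L])
    tree$edge.length <- tree$edge.length * target / root_h
    h <- h * target / root_h
    root_h <- target
  }
  if (!is.null(min_split_frac)) {
    n <- ape::Ntip(tree)
    idx <- order(h[(n + 1L):(n + tree$Nnode)], decreasing = TRUE) + n
    h2 <- h
    for (v in idx[-1L]) {
      parent <- tree$edge[tree$edge[, 2L] == v, 1L]
      h2[v] <- min(max(h[v], min_split_frac * root_h),
                   h2[parent] * (1 - 1e-6))
    }
    tree$edge.length <- h2[tree$edge[, 1L]] - h2[tree$edge[, 2L]]
  }
  tree
}

# ---------------------------------------------------------------------------
# multispecies coalescent gene tree

# registry-based merger: nodes 1..n are tips; merges append times/children
.new_registry <- function(n, labels) {
  env <- new.env(parent = emptyenv())
  env$time <- rep(0, n)
  env$kids <- vector("list", n)
  env$labels <- labels
  env
}

.reg_merge <- function(reg, a, b, t) {
  id <- length(reg$time) + 1L
  reg$time[id] <- t
  reg$kids[[id]] <- c(a, b)
  id
}

.reg_to_phylo <- function(reg, root) {
  nwk <- function(i, parent_t) {
    len <- format(parent_t - reg$time[i], digits = 15)
    if (is.null(reg$kids[[i]])) paste0(reg$labels[i], ":", len)
    else paste0("(", nwk(reg$kids[[i]][1L], reg$time[i]), ",",
                nwk(reg$kids[[i]][2L], reg$time[i]), "):", len)
  }
  k <- reg$kids[[root]]
  ape::read.tree(text = paste0("(", nwk(k[1L], reg$time[root]), ",",
                               nwk(k[2L], reg$time[root]), ");"))
}

# coalesce a panmictic pool between t_start and t_end; constant size theta,
# or exponential growth (growth > 0): old coalescences compressed through
# u -> t_start + (theta/2) * log(1 + growth * u) / growth
.coalesce_panmictic <- function(reg, pool, theta, t_start, t_end,
                                growth = 0) {
  if (theta <= 0) return(pool)
  u <- 0
  repeat {
    k <- length(pool)
    if (k <= 1L) break
    u <- u + stats::rexp(1L, k * (k - 1) / 2)
    t <- if (growth > 0) t_start + (theta / 2) * log(1 + growth * u) / growth
         else t_start + (theta / 2) * u
    if (t >= t_end) break
    pair <- sample.int(k, 2L)
    id <- .reg_merge(reg, pool[pair[1L]], pool[pair[2L]], t)
    pool <- c(pool[-pair], id)
  }
  pool
}

# structured (finite-island) coalescent with per-lineage scaled migration M;
# theta here is PER DEME (species-level theta divided by the deme count),
# within-deme pair coalescence rate 2/theta, migration rate M*2/theta
.coalesce_structured <- function(reg, pool, deme, n_demes, theta, M,
                                 t_start, t_end) {
  t <- t_start
  repeat {
    k <- length(pool)
    if (k <= 1L) break
    kd <- tabulate(deme, n_demes)
    coal_rates <- kd * (kd - 1) / theta           # = C(kd,2) * 2/theta
    mig_rate <- k * M * 2 / theta
    total <- sum(coal_rates) + mig_rate
    t <- t + stats::rexp(1L, total)
    if (t >= t_end) break
    if (stats::runif(1L) < sum(coal_rates) / total) {
      d <- sample.int(n_demes, 1L, prob = coal_rates)
      here <- which(deme == d)
      pair <- here[sample.int(length(here), 2L)]
      id <- .reg_merge(reg, pool[pair[1L]], pool[pair[2L]], t)
      keep <- setdiff(seq_len(k), pair)
      pool <- c(pool[keep], id)
      deme <- c(deme[keep], d)
    } else {
      l <- sample.int(k, 1L)
      deme[l] <- sample(setdiff(seq_len(n_demes), deme[l]), 1L)
    }
  }
  list(pool = pool, deme = deme)
}

#' Simulate a gene tree along a species tree
#'
#' Runs independent within-species coalescents (constant size, exponential
#' growth, or a finite-island structured coalescent when a species has more
#' than one deme), passes the surviving lineages up the species tree, and
#' continues a constant-size coalescent with the ancestral theta between and
#' above species divergences. All times are in expected substitutions per
#' site; `theta` is the per-site population-scaled mutation parameter, so a
#' constant-size species has expected pairwise diversity `theta`.
#'
#' @param species_tree Output of [simulate_species_tree].
#' @param cfg A `sim_config` (fields `n_samples`, `demes`, `theta`,
#'   `growth`, `migration`, `theta_anc` are used; scalar values are
#'   recycled across species).
#' @param seed Optional integer seed.
#' @return List with `tree` (ultrametric `phylo`; tips `sp<i>_<j>`) and
#'   `meta` (`data.frame` id, species, population).
#' @export
simulate_gene_tree <- function(species_tree, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  single <- inherits(species_tree, "singleton_tree")
  n_sp <- if (single) 1L else ape::Ntip(species_tree)
  rec <- function(v) rep_len(v, n_sp)
  n_samples <- rec(cfg$n_samples)
  demes <- rec(cfg$demes)
  theta <- rec(cfg$theta)
  growth <- rec(cfg$growth)
  labels <- unlist(lapply(seq_len(n_sp), function(i)
    paste0("sp", i, "_", seq_len(n_samples[i]))))
  species <- rep(paste0("sp", seq_len(n_sp)), n_samples)
  deme_of <- unlist(lapply(seq_len(n_sp), function(i)
    rep_len(seq_len(demes[i]), n_samples[i])))
  meta <- data.frame(id = labels, species = species,
                     population = paste0(species, "_d", deme_of),
                     stringsAsFactors = FALSE)
  reg <- .new_registry(length(labels), labels)

  if (single) {
    pool <- seq_len(n_samples[1L])
    if (demes[1L] > 1L && growth[1L] <= 0) {
      st <- .coalesce_structured(reg, pool, deme_of, demes[1L],
                                 theta[1L] / demes[1L], cfg$migration, 0, Inf)
      pool <- st$pool
      if (length(pool) > 1L)  # migration can strand lineages only at t_end=Inf
        pool <- .coalesce_panmictic(reg, pool, theta[1L], max(reg$time), Inf)
    } else {
      pool <- .coalesce_panmictic(reg, pool, theta[1L], 0, Inf, growth[1L])
    }
    return(list(tree = .reg_to_phylo(reg, pool[1L]), meta = meta))
  }

  h <- .node_heights(species_tree)
  tip_idx <- match(paste0("sp", seq_len(n_sp)), species_tree$tip.label)
  n <- ape::Ntip(species_tree)
  parent <- integer(n + species_tree$Nnode)
  parent[species_tree$edge[, 2L]] <- species_tree$edge[, 1L]
  # pools per active species-tree node
  pools <- list()
  offset <- c(0L, cumsum(n_samples))
  for (i in seq_len(n_sp)) {
    pool <- (offset[i] + 1L):offset[i + 1L]
    dm <- deme_of[pool]
    t_end <- h[parent[tip_idx[i]]]
    if (demes[i] > 1L && growth[i] <= 0 && length(pool) > 1L) {
      st <- .coalesce_structured(reg, pool, dm, demes[i],
                                 theta[i] / demes[i], cfg$migration, 0, t_end)
      pool <- st$pool
    } else if (length(pool) > 1L) {
      pool <- .coalesce_panmictic(reg, pool, theta[i], 0, t_end, growth[i])
    }
    pools[[as.character(tip_idx[i])]] <- pool
  }
  internal <- order(h[(n + 1L):(n + species_tree$Nnode)]) + n
  for (v in internal) {
    ch <- species_tree$edge[species_tree$edge[, 1L] == v, 2L]
    pool <- c(pools[[as.character(ch[1L])]], pools[[as.character(ch[2L])]])
    t_end <- if (parent[v] == 0L) Inf else h[parent[v]]
    pool <- .coalesce_panmictic(reg, pool, cfg$theta_anc, h[v], t_end)
    pools[[as.character(v)]] <- pool
  }
  root_pool <- pools[[as.character(internal[length(internal)])]]
  list(tree = .reg_to_phylo(reg, root_pool[1L]), meta = meta)
}

#' Simulate sequences along a tree under the K2P mutation model
#'
#' Two-rate (transition/transversion) Markov substitution along the tree
#' with equal base frequencies and transition weight `kappa`; branch lengths
#' are expected substitutions per site. A zero-length tree reproduces the
#' root sequence in every tip.
#'
#' @param tree Ape `phylo` with branch lengths in substitutions/site.
#' @param length Number of sites (default 677).
#' @param kappa Transition/transversion rate ratio (default 4).
#' @param seed Optional integer seed.
#' @param metadata Optional metadata `data.frame` joined by id.
#' @return A [seq_alignment].
#' @export
simulate_sequences <- function(tree, length = 677L, kappa = 4, seed = NULL,
                               metadata = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- c(1, kappa, 1, 1, kappa, 1)   # AC, AG, AT, CG, CT, GT
  sim <- phangorn::simSeq(tree, l = length, Q = Q, bf = rep(0.25, 4L),
                          type = "DNA")
  mat <- toupper(as.character(sim))
  rownames(mat) <- names(sim)
  seq_alignment(mat, metadata)
}

#' Simulate a morphology table
#'
#' Draws the two overlapping classes from multivariate normal ratio
#' distributions with class-specific covariances and Bernoulli colour
#' patterns, plus a cleanly diagnosable class (spots, elongated stomach).
#'
#' @param config Morphology block of a `sim_config` (see
#'   [sim_preset]); `NULL` uses the defaults.
#' @param seed Optional integer seed.
#' @return A `morpho_table` with true labels.
#' @export
simulate_morphology <- function(config = NULL, seed = NULL) {
  if (is.null(config)) config <- .default_morpho_config()
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (cl in names(config$classes)) {
    p <- config$classes[[cl]]
    ok <- tryCatch({chol(p$cov); TRUE}, error = function(e) FALSE)
    if (!ok) stop("covariance for class ", cl, " is not positive definite")
    ratios <- MASS::mvrnorm(p$n, p$mean, p$cov)
    code <- stats::rbinom(p$n, 1L, p$p_pattern1)
    rows[[cl]] <- data.frame(
      id = paste0(cl, seq_len(p$n)),
      head_depth_ratio = ratios[, 1L], peduncle_ratio = ratios[, 2L],
      predorsal_ratio = ratios[, 3L], pattern_code = as.numeric(code),
      pattern = ifelse(code == 1L, "none", "chevron"),
      stomach = "bulbous", label = cl, stringsAsFactors = FALSE)
  }
  if (!is.null(config$am)) {
    p <- config$am
    ratios <- MASS::mvrnorm(p$n, p$mean, p$cov)
    rows$AM <- data.frame(
      id = paste0("AM", seq_len(p$n)),
      head_depth_ratio = ratios[, 1L], peduncle_ratio = ratios[, 2L],
      predorsal_ratio = ratios[, 3L], pattern_code = NA_real_,
      pattern = "spots", stomach = "elongated", label = "AM",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("morpho_table", "data.frame")
  out
}

#' Generate a complete synthetic dataset
#'
#' Simulates a species tree, a multispecies-coalescent gene tree, a sequence
#' alignment, per-individual metadata with populations placed on a 1-D
#' coastline (site coordinates for isolation-by-distance testing) and a
#' morphology table, together with the generating truth. Identical
#' configuration and seed give identical output.
#'
#' @param preset Preset name or a `sim_config` (see [sim_preset]).
#' @param seed Integer seed (default 1).
#' @return Object of class `synthetic_dataset`: list with `alignment`,
#'   `gene_tree`, `species_tree`, `morphology`, `sites`, `truth`, `config`,
#'   `seed`.
#' @export
simulate_dataset <- function(preset = "aplochiton-like", seed = 1L) {
  cfg <- if (inherits(preset, "sim_config")) preset else sim_preset(preset)
  set.seed(seed)
  sp_tree <- simulate_species_tree(cfg$n_species, cfg$lambda,
                                   cfg$height_range, cfg$min_split_frac)
  gt <- simulate_gene_tree(sp_tree, cfg)
  meta <- gt$meta
  # 1-D coastline: one latitude step per population, fixed longitude
  sites <- unique(meta$population)
  site_df <- data.frame(site = sites,
                        lat = -39 - 0.8 * (seq_along(sites) - 1L),
                        lon = rep(-73, length(sites)))
  metadata <- data.frame(id = meta$id, site = meta$population,
                         population = meta$population, group = meta$species,
                         stringsAsFactors = FALSE)
  aln <- simulate_sequences(gt$tree, cfg$seq_length, cfg$kappa,
                            metadata = metadata)
  morpho <- if (!is.null(cfg$morphology))
    simulate_morphology(cfg$morphology) else NULL
  structure(list(alignment = aln, gene_tree = gt$tree,
                 species_tree = sp_tree, morphology = morpho,
                 sites = site_df,
                 truth = list(species = setNames(meta$species, meta$id),
                              population = setNames(meta$population, meta$id)),
                 config = cfg, seed = seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset (preset ", x$config$preset, ", seed ", x$seed,
      "):\n", sep = "")
  cat(" ", length(x$alignment$ids), "sequences x", x$alignment$length,
      "sites;", length(unique(x$truth$species)), "species\n")
  if (!is.null(x$morphology))
    cat(" ", nrow(x$morphology), "morphology rows\n")
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `alignment.fasta`, `metadata.csv`, `sites.csv`,
#' `gene_tree.nwk`, `species_tree.nwk` (when present), `morphology.csv`
#' and `truth.json`.
#'
#' @param dataset A [simulate_dataset] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_alignment(dataset$alignment, file.path(dir, "alignment.fasta"))
  utils::write.csv(dataset$alignment$metadata,
                   file.path(dir, "metadata.csv"), row.names = FALSE)
  utils::write.csv(dataset$sites, file.path(dir, "sites.csv"),
                   row.names = FALSE)
  write_newick(dataset$gene_tree, file.path(dir, "gene_tree.nwk"))
  if (inherits(dataset$species_tree, "phylo"))
    write_newick(dataset$species_tree, file.path(dir, "species_tree.nwk"))
  if (!is.null(dataset$morphology))
    utils::write.csv(dataset$morphology, file.path(dir, "morphology.csv"),
                     row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE)
  }
  invisible(dir)
}
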