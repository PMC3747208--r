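# Newick I/O, UPGMA building and branching schedules -------------------------

#' Read a Newick tree file
#'
#' Thin wrapper around the ape parser that insists on branch lengths and
#' reports malformed input as an error. `read_nexus_trees` reads trees
#' embedded in a NEXUS file (translate table supported by the parser).
#'
#' @param path Path to a Newick file (one or more trees).
#' @return An ape `phylo` object (or `multiPhylo` when the file holds
#'   several trees).
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) stop("Newick parse error in '", path,
                                          "': ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in '", path, "'")
  check <- function(t) {
    if (is.null(t$edge.length) || anyNA(t$edge.length))
      stop("tree in '", path, "' is missing branch lengths")
    t
  }
  if (inherits(tr, "multiPhylo")) { for (t in tr) check(t); tr } else check(tr)
}

#' @rdname read_newick
#' @export
read_nexus_trees <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ape::read.nexus(path)
}

#' Write a tree in Newick format
#'
#' @param tree An ape `phylo` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# node heights (time before present): tips at 0, root at max
.node_heights <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth) - depth
  h[h < 0] <- 0
  h
}

#' Check that a tree is ultrametric within tolerance
#'
#' All root-to-tip path lengths must agree to a relative tolerance of 1e-6
#' (relative to tree height). On failure the worst-deviating tip is named.
#'
#' @param tree An ape `phylo` object with branch lengths.
#' @param tol Relative tolerance (default `1e-6`).
#' @return Invisibly `TRUE`; error otherwise.
#' @export
assert_ultrametric <- function(tree, tol = 1e-6) {
  depth <- ape::node.depth.edgelength(tree)
  tip_depth <- depth[seq_len(ape::Ntip(tree))]
  span <- max(tip_depth) - min(tip_depth)
  if (max(tip_depth) <= 0) stop("tree has zero height")
  if (span / max(tip_depth) > tol) {
    worst <- tree$tip.label[which.min(tip_depth)]
    stop("tree is not ultrametric: tip '", worst, "' deviates by ",
         format(span), " (relative ", format(span / max(tip_depth)), ")")
  }
  invisible(TRUE)
}

#' UPGMA strict-clock tree from a distance matrix
#'
#' Standard UPGMA agglomeration (average linkage); node heights are half the
#' average inter-cluster distance, so the output is exactly ultrametric with
#' heights in the same units as the input distances (substitutions/site).
#' Labels are sorted lexicographically before clustering so that ties are
#' broken deterministically.
#'
#' @param dm Symmetric distance matrix with labels.
#' @return A rooted ultrametric ape `phylo` object.
#' @export
upgma_clock_tree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) >= 2L)
  if (any(!is.finite(dm))) stop("distance matrix has non-finite entries")
  ord <- order(rownames(dm))
  dm <- dm[ord, ord, drop = FALSE]
  phangorn::upgma(stats::as.dist(dm))
}

# resolve polytomies and tie heights so that event times are distinct
.prepare_binary <- function(tree, jitter = 1e-10) {
  if (!ape::is.binary(tree)) {
    warning("polytomies resolved into zero-length bifurcations")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  h <- .node_heights(tree)
  n <- ape::Ntip(tree)
  internal <- h[(n + 1L):(n + tree$Nnode)]
  if (anyDuplicated(signif(internal, 12))) {
    # perturb tied event times minimally (documented: GMYC needs distinct
    # event times); applied on the returned height vector only
    o <- order(internal, decreasing = TRUE)
    for (i in seq_along(o)[-1L]) {
      if (internal[o[i]] >= internal[o[i - 1L]])
        internal[o[i]] <- internal[o[i - 1L]] - jitter
    }
    h[(n + 1L):(n + tree$Nnode)] <- internal
  }
  list(tree = tree, heights = h)
}

#' Branching schedule of an ultrametric tree
#'
#' Orders the internal-node (branching) events from the root towards the
#' present and records, for each inter-event interval, the waiting time and
#' the number of lineages. With a threshold time `T`, nodes older than `T`
#' are diversification (speciation) events and the lineages crossing `T`
#' define the delimited entities (clusters and singletons); the schedule then
#' also carries, per interval, the count of species-level lineages and the
#' per-cluster coalescent lineage counts needed by the GMYC likelihood.
#'
#' @param tree Ultrametric ape `phylo` object (within tolerance `1e-6`).
#' @param threshold Optional threshold height (time before present, same
#'   units as the branch lengths). `NULL` means no classification.
#' @return Object of class `branching_schedule`: list with `heights` (event
#'   heights, descending; the root first), `waits` (interval waiting times,
#'   one per interval from each event down to the next event or the
#'   present), `n_lineages` (per interval), and, when a threshold is given,
#'   `threshold`, `k` (species-level lineage count per interval), `coal`
#'   (interval x entity matrix of within-entity lineage counts),
#'   `entities` (count) and `partition` (tip assignment).
#' @export
branching_schedule <- function(tree, threshold = NULL) {
  assert_ultrametric(tree)
  prep <- .prepare_binary(tree)
  tree <- prep$tree
  h <- prep$heights
  n <- ape::Ntip(tree)
  node_ids <- (n + 1L):(n + tree$Nnode)
  ev <- node_ids[order(h[node_ids], decreasing = TRUE)]
  evh <- h[ev]
  waits <- c(-diff(evh), evh[length(evh)])
  out <- list(heights = evh, waits = waits,
              n_lineages = seq_along(evh) + 1L, tree = tree)
  if (!is.null(threshold)) {
    cls <- .classify_by_threshold(tree, h, ev, threshold)
    out <- c(out, cls, list(threshold = threshold))
  }
  structure(out, class = "branching_schedule")
}

# Build the GMYC interval bookkeeping from a speciation/coalescent node
# classification. `spec` is a logical vector over `ev` (ordered events):
# TRUE = speciation (diversification) event.
.schedule_from_classification <- function(tree, h, ev, spec) {
  n <- ape::Ntip(tree)
  m <- length(ev)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  is_spec_node <- logical(n + tree$Nnode)
  is_spec_node[ev] <- spec
  # entity of a node: walk up until the parent is a speciation node (or root
  # reached). Entity root = highest non-speciation ancestor (or the tip).
  ent_root <- integer(n + tree$Nnode)
  root <- n + 1L
  find_root <- function(v) {
    while (parent[v] != 0L && !is_spec_node[parent[v]]) v <- parent[v]
    v
  }
  tip_entity <- vapply(seq_len(n), find_root, integer(1L))
  ents <- unique(tip_entity)
  n_ent <- length(ents)
  # founding interval of entity j: index of its parent speciation event
  ev_index <- setNames(seq_len(m), ev)
  founded <- vapply(ents, function(v) {
    if (parent[v] == 0L) 0L                      # entity root is the tree root
    else ev_index[[as.character(parent[v])]]
  }, integer(1L))
  # entity of each coalescent event
  ev_entity <- rep(NA_integer_, m)
  for (i in seq_len(m)) {
    if (!spec[i]) ev_entity[i] <- match(find_root(ev[i]), ents)
  }
  # interval i follows event i; an entity's stem exists from the interval of
  # its founding speciation event, and each of the entity's own coalescent
  # events at global position i adds a lineage from interval i on.
  k <- cumsum(spec) + 1L                          # species lineages, interval i
  coal <- matrix(0L, nrow = m, ncol = n_ent)
  for (j in seq_len(n_ent)) {
    v <- integer(m)
    start <- max(founded[j], 1L)
    v[start:m] <- 1L
    own <- which(!spec & ev_entity == j)
    for (i in own) v[i:m] <- v[i:m] + 1L
    coal[, j] <- v
  }
  part <- partition(setNames(match(tip_entity, ents), tree$tip.label),
                    method = "gmyc")
  list(k = k, coal = coal, entities = n_ent, partition = part,
       speciation = spec)
}

.classify_by_threshold <- function(tree, h, ev, threshold) {
  spec <- h[ev] > threshold
  .schedule_from_classification(tree, h, ev, spec)
}

#' @export
print.branching_schedule <- function(x, ...) {
  cat("Branching schedule:", length(x$heights), "events, root height",
      format(max(x$heights), digits = 6), "\n")
  if (!is.null(x$entities))
    cat("Threshold", format(x$threshold, digits = 6), "->", x$entities,
        "entities\n")
  invisible(x)
}

# number of lineages crossing height t (independent tree-cutting routine)
.lineages_at <- function(tree, t) {
  h <- .node_heights(tree)
  par_h <- h[tree$edge[, 1L]]
  chi_h <- h[tree$edge[, 2L]]
  if (t >= max(h)) return(1L)
  sum(par_h > t & chi_h <= t)
}
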