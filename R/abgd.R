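# Automatic Barcode Gap Discovery -------------------------------------------

#' ABGD configuration
#'
#' Parameters controlling the barcode-gap scan: the range and number of prior
#' intraspecific divergences, the relative gap width, and the recursion
#' depth of the within-group re-partitioning.
#'
#' @param p_min,p_max Prior intraspecific divergence range (proportions,
#'   defaults 0.001 and 0.1). The scan grid is logarithmic between them.
#' @param steps Number of priors in the scan grid (default 100).
#' @param x Relative gap width: a gap is significant when it exceeds `x`
#'   times the local slope of the ranked-distance curve (default 1.5).
#' @param max_depth Maximum recursion depth of within-group splitting
#'   (default 10).
#' @return A list of class `abgd_config`.
#' @export
abgd_config <- function(p_min = 0.001, p_max = 0.1, steps = 100L, x = 1.5,
                        max_depth = 10L) {
  stopifnot(p_min > 0, p_min < p_max, p_max < 1, steps >= 2L, x > 0,
            max_depth >= 1L)
  structure(list(p_min = p_min, p_max = p_max, steps = as.integer(steps),
                 x = x, max_depth = as.integer(max_depth)),
            class = "abgd_config")
}

#' Locate the barcode gap in a ranked distance distribution
#'
#' Scans the sorted pairwise distances for the first significant gap beyond
#' the prior intraspecific divergence `P`. The slope of the ranked-distance
#' curve at rank i is estimated as the mean of consecutive differences over a
#' trailing window of `w = max(3, ceiling(0.1 m))` ranked distances; the gap
#' between ranks i and i+1 is significant when its width exceeds `x` times
#' that local slope and the right edge exceeds `P`. The returned threshold is
#' the midpoint of the first significant gap (a value strictly inside the
#' gap, so that "distance below threshold" captures the whole left mode).
#'
#' @param distances Numeric vector of pairwise distances sorted ascending.
#' @param p Prior maximum intraspecific divergence.
#' @param x Relative gap width (default 1.5).
#' @return The gap threshold (numeric), or `NULL` when no significant gap
#'   exists.
#' @export
find_barcode_gap <- function(distances, p, x = 1.5) {
  if (length(distances) == 0L) stop("empty distance list")
  if (is.unsorted(distances)) stop("distances must be sorted ascending")
  if (any(!is.finite(distances))) stop("distances must be finite")
  m <- length(distances)
  if (m < 2L) return(NULL)
  g <- diff(distances)                      # g[i] = d[i+1] - d[i]
  w <- max(3L, ceiling(0.1 * m))
  for (i in seq_len(m - 1L)) {
    lo <- max(1L, i - w)
    slope <- if (i >= 2L) mean(g[lo:(i - 1L)]) else mean(g[seq_len(min(w, m - 1L))])
    if (distances[i + 1L] > p && g[i] > x * slope && g[i] > 0)
      return((distances[i] + distances[i + 1L]) / 2)
  }
  NULL
}

# single-linkage components of the graph with edges d < threshold
.sl_components <- function(dm, threshold) {
  n <- nrow(dm)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (dm[i, j] < threshold && comp[i] != comp[j]) {
          old <- max(comp[i], comp[j]); new <- min(comp[i], comp[j])
          comp[comp == old] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

.abgd_recurse <- function(dm, p, x, depth) {
  n <- nrow(dm)
  if (n <= 1L) return(rep(1L, n))
  dvals <- dm[upper.tri(dm)]
  dvals <- sort(dvals[dvals > 0])           # duplicate haplotypes excluded
  thr <- find_barcode_gap(dvals, p, x)
  if (is.null(thr)) return(rep(1L, n))
  comp <- .sl_components(dm, thr)
  if (max(comp) == 1L || depth <= 1L) return(comp)
  out <- integer(n)
  nxt <- 0L
  for (k in seq_len(max(comp))) {
    idx <- which(comp == k)
    sub <- .abgd_recurse(dm[idx, idx, drop = FALSE], p, x, depth - 1L)
    out[idx] <- sub + nxt
    nxt <- nxt + max(sub)
  }
  out
}

#' ABGD partition at a single prior divergence
#'
#' Partitions sequences into candidate species: single-linkage components of
#' the graph joining pairs closer than the detected barcode gap, re-applied
#' recursively within each component until no component splits further. When
#' no significant gap exists all sequences form one group.
#'
#' @param dm Distance matrix (as from [distance_matrix]).
#' @param p Prior maximum intraspecific divergence.
#' @param config An [abgd_config] (supplies `x` and `max_depth`).
#' @return A [partition] with provenance `method = "abgd"`.
#' @export
abgd_partition <- function(dm, p, config = abgd_config()) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  comp <- .abgd_recurse(dm, p, config$x, config$max_depth)
  partition(setNames(comp, rownames(dm)), method = "abgd",
            parameters = list(p = p, x = config$x))
}

#' ABGD scan over a grid of prior divergences
#'
#' Runs [abgd_partition] at every prior of a logarithmic grid between
#' `p_min` and `p_max` and identifies stable partitions: groupings that are
#' identical (up to relabelling) over at least three consecutive priors.
#' The number of groups is expected to be non-increasing in the prior;
#' violations are recorded (`monotone` flag) as algorithmic defects rather
#' than silently accepted.
#'
#' @param dm Distance matrix.
#' @param config An [abgd_config].
#' @return Object of class `abgd_scan`: list with `priors`, `n_groups`
#'   (per prior), `partitions` (list of [partition]), `stable`
#'   (`data.frame` describing each maximal stable run: group count, prior
#'   range, run length, index of a representative partition), and
#'   `monotone` (logical).
#' @export
abgd_scan <- function(dm, config = abgd_config()) {
  priors <- exp(seq(log(config$p_min), log(config$p_max),
                    length.out = config$steps))
  parts <- lapply(priors, function(p) abgd_partition(dm, p, config))
  ng <- vapply(parts, function(p) p$n_groups, integer(1L))
  monotone <- !is.unsorted(rev(ng))
  # maximal runs of identical partitions
  run_id <- integer(length(parts))
  run_id[1L] <- 1L
  for (i in seq_along(parts)[-1L]) {
    run_id[i] <- if (partitions_equal(parts[[i]], parts[[i - 1L]]))
      run_id[i - 1L] else run_id[i - 1L] + 1L
  }
  runs <- split(seq_along(parts), run_id)
  stable <- do.call(rbind, lapply(runs, function(idx) {
    data.frame(n_groups = ng[idx[1L]], p_from = priors[idx[1L]],
               p_to = priors[idx[length(idx)]], run_length = length(idx),
               partition_index = idx[1L])
  }))
  stable <- stable[stable$run_length >= 3L, , drop = FALSE]
  rownames(stable) <- NULL
  structure(list(priors = priors, n_groups = ng, partitions = parts,
                 stable = stable, monotone = monotone, config = config),
            class = "abgd_scan")
}

#' @export
print.abgd_scan <- function(x, ...) {
  cat("ABGD scan over", length(x$priors), "priors in [",
      format(x$config$p_min), ",", format(x$config$p_max), "]\n")
  if (nrow(x$stable)) {
    cat("Stable partitions (>= 3 consecutive priors):\n")
    print(x$stable, digits = 3)
  } else cat("No stable partition found.\n")
  if (!x$monotone)
    cat("WARNING: group count not monotone in the prior (see $n_groups)\n")
  invisible(x)
}

#' Most stable ABGD partition
#'
#' The stable partition persisting over the longest run of consecutive
#' priors (ties: the one reaching the largest prior).
#'
#' @param scan An [abgd_scan] result.
#' @return A [partition], or `NULL` when no run reached length 3.
#' @export
abgd_best <- function(scan) {
  s <- scan$stable
  if (!nrow(s)) return(NULL)
  s <- s[order(-s$run_length, -s$p_to), , drop = FALSE]
  scan$partitions[[s$partition_index[1L]]]
}

#' @export
plot.abgd_scan <- function(x, ...) {
  graphics::plot(x$priors, x$n_groups, log = "x", type = "s",
                 xlab = "prior intraspecific divergence (P)",
                 ylab = "number of groups", ...)
  invisible(x)
}
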