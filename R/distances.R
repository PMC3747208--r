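# Pairwise genetic distances ------------------------------------------------

# split a sequence string into comparable-base logical mask + uppercase chars
.k2p_pair_counts <- function(a, b) {
  comp <- (a %in% .DNA_BASES) & (b %in% .DNA_BASES)
  n <- sum(comp)
  if (n == 0L) stop("no comparable sites")
  ai <- a[comp]; bi <- b[comp]
  diff <- ai != bi
  ts <- diff & ((ai %in% .PURINES) == (bi %in% .PURINES))
  list(n = n, P = sum(ts) / n, Q = sum(diff & !ts) / n)
}

#' Kimura two-parameter (K2P) distance between two aligned sequences
#'
#' Corrects the observed proportions of transitions (`P`) and transversions
#' (`Q`) separately:
#' \deqn{d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q)}
#' Sites where either sequence carries a gap, `N` or an ambiguity code are
#' excluded (pairwise deletion). Saturated pairs (a logarithm argument
#' reaching zero or below) raise an error rather than returning `Inf`.
#'
#' @param a,b Character vectors of single characters, or single strings, of
#'   equal length (aligned sequences).
#' @return K2P distance in substitutions per site.
#' @export
k2p_distance <- function(a, b) {
  if (length(a) == 1L && nchar(a) > 1L) a <- strsplit(a, "")[[1L]]
  if (length(b) == 1L && nchar(b) > 1L) b <- strsplit(b, "")[[1L]]
  if (length(a) != length(b)) stop("sequences differ in length")
  cnt <- .k2p_pair_counts(toupper(a), toupper(b))
  w1 <- 1 - 2 * cnt$P - cnt$Q
  w2 <- 1 - 2 * cnt$Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P distance saturated (P = ", signif(cnt$P, 4),
         ", Q = ", signif(cnt$Q, 4), ")")
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among pairwise-comparable sites.
#'
#' @inheritParams k2p_distance
#' @return p-distance (proportion in \[0, 1\]).
#' @export
p_distance <- function(a, b) {
  if (length(a) == 1L && nchar(a) > 1L) a <- strsplit(a, "")[[1L]]
  if (length(b) == 1L && nchar(b) > 1L) b <- strsplit(b, "")[[1L]]
  if (length(a) != length(b)) stop("sequences differ in length")
  cnt <- .k2p_pair_counts(toupper(a), toupper(b))
  cnt$P + cnt$Q
}

#' Pairwise distance matrix for an alignment
#'
#' Computes all pairwise distances under the K2P or p-distance model with
#' pairwise deletion of missing data. Distances are stored as proportions
#' (substitutions per site), zero diagonal, symmetric.
#'
#' @param aln A [seq_alignment].
#' @param model `"K2P"` (default) or `"p-distance"`.
#' @return A symmetric numeric matrix with `dimnames` = ids and attribute
#'   `model`.
#' @export
distance_matrix <- function(aln, model = c("K2P", "p-distance")) {
  stopifnot(inherits(aln, "seq_alignment"))
  model <- match.arg(model)
  n <- nrow(aln$seq)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  f <- if (model == "K2P") k2p_distance else p_distance
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        dij <- tryCatch(f(aln$seq[i, ], aln$seq[j, ]), error = function(e)
          stop("distance failed for pair (", aln$ids[i], ", ", aln$ids[j],
               "): ", conditionMessage(e)))
        d[i, j] <- d[j, i] <- dij
      }
    }
  }
  attr(d, "model") <- model
  d
}

#' Within/between-group summary of a distance matrix
#'
#' For each group and each pair of groups, reports the mean pairwise
#' distance, its standard deviation and standard error over the set of
#' pairs, and the number of pairs. Within-group entries for singleton groups
#' are flagged undefined (`NA` with `n_pairs = 0`).
#'
#' @param dm Distance matrix (as from [distance_matrix]).
#' @param partition A [partition] or a named vector id -> group label
#'   covering all matrix labels.
#' @return `data.frame` with columns `group1`, `group2` (equal on the
#'   diagonal entries), `mean`, `sd`, `se`, `n_pairs`.
#' @export
group_distance_summary <- function(dm, partition) {
  grp <- .as_assignment(partition)
  labels <- rownames(dm)
  if (!all(labels %in% names(grp)))
    stop("partition does not cover all labels")
  grp <- grp[labels]
  groups <- sort(unique(grp))
  res <- list()
  for (gi in seq_along(groups)) {
    for (gj in gi:length(groups)) {
      a <- which(grp == groups[gi])
      b <- which(grp == groups[gj])
      if (gi == gj) {
        if (length(a) < 2L) {
          vals <- numeric(0)
        } else {
          pairs <- utils::combn(a, 2L)
          vals <- dm[cbind(pairs[1L, ], pairs[2L, ])]
        }
      } else {
        vals <- as.vector(dm[a, b, drop = FALSE])
      }
      res[[length(res) + 1L]] <- data.frame(
        group1 = groups[gi], group2 = groups[gj],
        mean = if (length(vals)) mean(vals) else NA_real_,
        sd = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
        se = if (length(vals) > 1L) stats::sd(vals) / sqrt(length(vals)) else NA_real_,
        n_pairs = length(vals), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Write a distance matrix as square TSV
#'
#' @param dm Distance matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(dm, path) {
  utils::write.table(as.data.frame(dm), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
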