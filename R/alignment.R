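#' @importFrom stats optim rexp rpois runif rbinom rnorm sd quantile dist
#'   cutree hclust as.dist pchisq var cor density setNames
#' @importFrom utils read.csv write.csv combn head tail
NULL

# nucleotide alphabet ---------------------------------------------------------

.DNA_BASES <- c("A", "C", "G", "T")
.DNA_IUPAC <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N", "-", "?")
.PURINES <- c("A", "G")

#' Aligned DNA sequences with per-individual metadata
#'
#' Container for an aligned set of DNA sequences (one locus, equal lengths)
#' together with optional per-individual metadata (sampling site, population
#' and group labels). Sequences may contain IUPAC ambiguity codes, `N`, `?`
#' and the gap character `-`; everything that is not an unambiguous
#' `A`/`C`/`G`/`T` is treated as missing by downstream statistics.
#'
#' @param sequences Named character vector of aligned sequences (all the same
#'   length), or a character matrix with one row per individual and one column
#'   per site (rownames = ids).
#' @param metadata Optional `data.frame` with an `id` column and any of
#'   `site`, `population`, `group`; joined to the sequences by id.
#'
#' @return An object of class `seq_alignment`: a list with elements `seq`
#'   (character matrix, rows = individuals, columns = sites), `ids`, `length`
#'   (number of sites) and `metadata`.
#' @export
seq_alignment <- function(sequences, metadata = NULL) {
  if (is.matrix(sequences)) {
    mat <- toupper(sequences)
    ids <- rownames(mat)
  } else {
    if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
      stop("sequences must be uniquely named")
    ids <- names(sequences)
    lens <- nchar(sequences)
    if (length(unique(lens)) > 1L) {
      bad <- ids[lens != lens[1L]][1L]
      stop("length mismatch: sequence '", bad, "' has ", nchar(sequences[bad]),
           " sites, expected ", lens[1L])
    }
    mat <- matrix(toupper(unlist(strsplit(unname(sequences), ""), use.names = FALSE)),
                  nrow = length(sequences), byrow = TRUE)
    rownames(mat) <- ids
  }
  if (is.null(ids) || anyDuplicated(ids)) stop("sequence ids must be unique")
  bad <- !(mat %in% .DNA_IUPAC)
  if (any(bad)) {
    idx <- which(bad, arr.ind = FALSE)[1L]
    stop("illegal character '", mat[idx], "' in sequence '",
         rownames(mat)[(idx - 1L) %% nrow(mat) + 1L], "'")
  }
  md <- data.frame(id = ids, site = NA_character_, population = NA_character_,
                   group = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    if (!"id" %in% names(metadata)) stop("metadata must have an 'id' column")
    metadata$id <- as.character(metadata$id)
    for (field in c("site", "population", "group")) {
      if (field %in% names(metadata)) {
        m <- match(ids, metadata$id)
        md[[field]] <- as.character(metadata[[field]][m])
      }
    }
  }
  structure(list(seq = mat, ids = ids, length = ncol(mat), metadata = md),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat("Aligned DNA sequences:", nrow(x$seq), "records x", x$length, "sites\n")
  n_meta <- sum(!is.na(x$metadata$population))
  if (n_meta > 0) cat("  population labels for", n_meta, "records\n")
  invisible(x)
}

#' Read an aligned FASTA file (with optional metadata CSV)
#'
#' Reads a multi-record aligned FASTA file and validates it (equal lengths,
#' unique ids, nucleotide alphabet). An optional metadata CSV with header
#' `id,site,population,group` is joined by id; missing fields are allowed.
#'
#' @param path Path to the FASTA file.
#' @param metadata Optional path to a metadata CSV file, or a `data.frame`.
#' @return A [seq_alignment] object.
#' @export
read_alignment <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), paste, character(1L), collapse = "")
  names(seqs) <- names(dna)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    bad <- names(seqs)[lens != lens[1L]][1L]
    stop("length mismatch: sequence '", bad, "' has ", nchar(seqs[bad]),
         " sites, expected ", lens[1L])
  }
  if (is.character(metadata)) metadata <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  seq_alignment(seqs, metadata)
}

#' Write an alignment to FASTA
#'
#' @param aln A [seq_alignment].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "seq_alignment"))
  lines <- character(2L * length(aln$ids))
  lines[seq(1L, by = 2L, length.out = length(aln$ids))] <- paste0(">", aln$ids)
  lines[seq(2L, by = 2L, length.out = length(aln$ids))] <-
    apply(aln$seq, 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

# subset helper: returns row indices for a subset of ids (NULL = all)
.aln_rows <- function(aln, subset) {
  if (is.null(subset)) return(seq_along(aln$ids))
  idx <- match(subset, aln$ids)
  if (anyNA(idx)) stop("unknown ids: ", paste(subset[is.na(idx)], collapse = ", "))
  idx
}

#' Collapse identical sequences into haplotypes
#'
#' Groups identical sequences into haplotypes and records per-population
#' haplotype frequencies. Under the default (strict) policy two sequences are
#' the same haplotype only when they match exactly, missing characters
#' included; in `missing_tolerant` mode sequences are merged when they agree
#' at every site where both carry an unambiguous base.
#'
#' @param aln A [seq_alignment].
#' @param missing_tolerant Logical; merge sequences that differ only at
#'   missing/ambiguous sites (default `FALSE`).
#' @return An object of class `haplotype_set`: list with `haplotypes` (named
#'   character vector haplotype-id -> sequence), `membership` (named character
#'   vector individual-id -> haplotype-id), `frequency` (haplotype x
#'   population count table) and `alignment` (a [seq_alignment] of one
#'   representative per haplotype).
#' @export
collapse_haplotypes <- function(aln, missing_tolerant = FALSE) {
  stopifnot(inherits(aln, "seq_alignment"))
  seqs <- apply(aln$seq, 1L, paste, collapse = "")
  if (!missing_tolerant) {
    key <- match(seqs, unique(seqs))
  } else {
    n <- length(seqs)
    key <- integer(n)
    reps <- integer(0) # indices of current representatives
    comparable <- aln$seq %in% .DNA_BASES
    dim(comparable) <- dim(aln$seq)
    for (i in seq_len(n)) {
      hit <- 0L
      for (r in reps) {
        ok <- comparable[i, ] & comparable[r, ]
        if (all(aln$seq[i, ok] == aln$seq[r, ok])) { hit <- r; break }
      }
      if (hit == 0L) { reps <- c(reps, i); key[i] <- length(reps) }
      else key[i] <- key[hit]
    }
  }
  hap_ids <- paste0("H", seq_len(max(key)))
  membership <- setNames(hap_ids[key], aln$ids)
  first <- match(seq_len(max(key)), key)
  haplotypes <- setNames(seqs[first], hap_ids)
  pop <- aln$metadata$population
  pop[is.na(pop)] <- "unassigned"
  frequency <- table(haplotype = membership, population = pop)
  hap_md <- aln$metadata[first, , drop = FALSE]
  hap_md$id <- hap_ids
  structure(list(haplotypes = haplotypes, membership = membership,
                 frequency = frequency,
                 alignment = seq_alignment(haplotypes, hap_md)),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(length(x$haplotypes), "haplotypes among", length(x$membership),
      "individuals\n")
  invisible(x)
}

#' Count segregating (polymorphic) sites
#'
#' A site is segregating when it carries at least two distinct unambiguous
#' bases among the selected sequences. With `complete_deletion = TRUE`, sites
#' with any missing/ambiguous state in the subset are discarded first.
#'
#' @param aln A [seq_alignment].
#' @param subset Optional character vector of ids (default: all).
#' @param complete_deletion Logical (default `FALSE`): drop columns containing
#'   any missing data before counting.
#' @return Integer count of segregating sites.
#' @export
segregating_sites <- function(aln, subset = NULL, complete_deletion = FALSE) {
  rows <- .aln_rows(aln, subset)
  if (length(rows) == 0L) stop("empty subset")
  m <- aln$seq[rows, , drop = FALSE]
  good <- m %in% .DNA_BASES
  dim(good) <- dim(m)
  if (complete_deletion) {
    keep <- colSums(good) == nrow(m)
    m <- m[, keep, drop = FALSE]
    good <- good[, keep, drop = FALSE]
  }
  seg <- vapply(seq_len(ncol(m)), function(j) {
    states <- unique(m[good[, j], j])
    length(states) >= 2L
  }, logical(1L))
  sum(seg)
}

#' Nucleotide diversity (pi) and related statistics
#'
#' Computes nucleotide diversity as the average over all unordered pairs of
#' the per-site difference proportion (pairwise deletion: each pair is
#' compared only at sites where both carry an unambiguous base), together
#' with the number of segregating sites and the mean number of pairwise
#' differences per sequence.
#'
#' @param aln A [seq_alignment].
#' @param subset Optional character vector of ids.
#' @param complete_deletion Logical; deletion policy for `S` and the per-pair
#'   comparisons (default `FALSE` = pairwise deletion).
#' @return Object of class `diversity_stats`: list with `n`, `S`, `pi`
#'   (per site) and `k` (mean pairwise differences per sequence).
#' @export
nucleotide_diversity <- function(aln, subset = NULL, complete_deletion = FALSE) {
  rows <- .aln_rows(aln, subset)
  n <- length(rows)
  if (n < 2L) stop("need at least 2 sequences")
  m <- aln$seq[rows, , drop = FALSE]
  good <- m %in% .DNA_BASES
  dim(good) <- dim(m)
  if (complete_deletion) {
    keep <- colSums(good) == n
    m <- m[, keep, drop = FALSE]
    good <- good[, keep, drop = FALSE]
  }
  pair_prop <- 0
  pair_diff <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      comp <- good[i, ] & good[j, ]
      nc <- sum(comp)
      if (nc == 0L) stop("no comparable sites between '", rownames(m)[i],
                         "' and '", rownames(m)[j], "'")
      nd <- sum(m[i, comp] != m[j, comp])
      pair_prop <- pair_prop + nd / nc
      pair_diff <- pair_diff + nd
    }
  }
  npairs <- n * (n - 1L) / 2
  structure(list(n = n,
                 S = segregating_sites(aln, if (is.null(subset)) aln$ids else subset,
                                       complete_deletion = complete_deletion),
                 pi = pair_prop / npairs,
                 k = pair_diff / npairs),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat("n =", x$n, " S =", x$S, " pi =", format(x$pi, digits = 4),
      " mean pairwise differences =", format(x$k, digits = 4), "\n")
  invisible(x)
}
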