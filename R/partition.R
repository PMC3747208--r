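# Candidate-species partitions ----------------------------------------------

#' Assignment of individuals to candidate species
#'
#' A partition records which delimited group every sequence belongs to, with
#' provenance (the method and parameters that produced it). Group labels are
#' dense integers rendered as `"G1"`, `"G2"`, ... in first-appearance order.
#'
#' @param assignment Named vector (id -> group); any label type, relabelled
#'   densely.
#' @param method Character tag for provenance (e.g. `"abgd"`, `"gmyc"`).
#' @param parameters Optional named list echoed into the object.
#' @return Object of class `partition`: list with `assignment` (named
#'   character), `n_groups`, `method`, `parameters`.
#' @export
partition <- function(assignment, method = "manual", parameters = list()) {
  if (is.null(names(assignment))) stop("assignment must be named by id")
  key <- match(assignment, unique(assignment))
  out <- setNames(paste0("G", key), names(assignment))
  structure(list(assignment = out, n_groups = max(key), method = method,
                 parameters = parameters), class = "partition")
}

.as_assignment <- function(x) {
  if (inherits(x, "partition")) x$assignment
  else if (!is.null(names(x))) setNames(as.character(x), names(x))
  else stop("expected a partition or a named vector")
}

#' @export
print.partition <- function(x, ...) {
  cat("Partition (", x$method, "): ", x$n_groups, " groups, ",
      length(x$assignment), " individuals\n", sep = "")
  tab <- table(x$assignment)
  cat(paste0("  ", names(tab), ": ", as.integer(tab), collapse = "\n"), "\n")
  invisible(x)
}

# TRUE when two partitions induce the same grouping (up to relabelling)
partitions_equal <- function(a, b) {
  a <- .as_assignment(a); b <- .as_assignment(b)
  if (!setequal(names(a), names(b))) return(FALSE)
  b <- b[names(a)]
  all(match(a, unique(a)) == match(b, unique(b)))
}

#' Strict-agreement consensus of several partitions
#'
#' Two individuals are co-assigned in the consensus only when every input
#' partition co-assigns them (the intersection of the co-assignment
#' relations). Method disagreement therefore splits groups; the result is
#' flagged when the inputs were not identical.
#'
#' @param parts List of [partition] objects over the same id set.
#' @return A [partition] with `method = "consensus"`; its `parameters`
#'   carry `disagreement` (logical) and the input methods.
#' @export
consensus_partition <- function(parts) {
  stopifnot(length(parts) >= 1L)
  asg <- lapply(parts, .as_assignment)
  ids <- names(asg[[1L]])
  for (a in asg) {
    if (!setequal(names(a), ids)) stop("partitions have mismatched label sets")
  }
  key <- do.call(paste, c(lapply(asg, function(a) match(a[ids], unique(a[ids]))),
                          sep = "/"))
  out <- partition(setNames(key, ids), method = "consensus",
                   parameters = list(
                     methods = vapply(parts, function(p)
                       if (inherits(p, "partition")) p$method else "unknown",
                       character(1L))))
  out$parameters$disagreement <-
    !all(vapply(asg, function(a) partitions_equal(a, asg[[1L]]), logical(1L)))
  out
}
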