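# General mixed Yule-coalescent model ----------------------------------------

#' GMYC interval log-likelihood
#'
#' Evaluates the mixed Yule-coalescent log-likelihood of a branching
#' schedule. Each inter-event interval of waiting time `x_i` contributes
#' `log(b_i) - b_i * x_i`, with interval hazard
#' `b_i = lambda0 * n_i^p0` under the null (single constant-type branching
#' process) and
#' `b_i = lambda1 * k_i^p1 + lambda2 * sum_j (n_ij (n_ij - 1))^p2`
#' under the threshold model, where `k_i` counts species-level lineages and
#' `n_ij` the coalescent lineages within delimited entity `j`.
#'
#' @param schedule A [branching_schedule]; for the threshold modes it must
#'   carry a threshold classification.
#' @param params Named list: `lambda0`, `p0` (null) or `lambda1`, `lambda2`,
#'   `p1`, `p2` (threshold modes). Rates must be positive.
#' @param mode `"single"`, `"multiple"` or `"null"` (single and multiple
#'   share the likelihood form; they differ in how the classification was
#'   obtained).
#' @return Log-likelihood (numeric scalar).
#' @export
gmyc_loglik <- function(schedule, params, mode = c("single", "multiple", "null")) {
  mode <- match.arg(mode)
  x <- schedule$waits
  if (mode == "null") {
    if (is.null(params$lambda0) || params$lambda0 <= 0)
      stop("lambda0 must be positive")
    b <- params$lambda0 * schedule$n_lineages ^ params$p0
  } else {
    if (is.null(schedule$k))
      stop("schedule lacks a threshold classification")
    if (params$lambda1 <= 0 || params$lambda2 <= 0)
      stop("rates must be positive")
    nn <- schedule$coal * (schedule$coal - 1L)
    b <- params$lambda1 * schedule$k ^ params$p1 +
      params$lambda2 * rowSums(nn ^ params$p2)
  }
  if (any(!is.finite(b)) || any(b <= 0)) stop("non-positive interval hazard")
  sum(log(b) - b * x)
}

.P_BOUNDS <- c(1e-3, 2)
.LOGL_BOUNDS <- log(c(1e-8, 1e6))

# maximize the threshold-model likelihood for a fixed classification
.gmyc_optim_threshold <- function(k, coal, x, extra_starts = NULL) {
  nn <- coal * (coal - 1L)
  coal1 <- rowSums(nn)                       # coalescent term at p2 = 1
  negll <- function(par) {
    b <- exp(par[1L]) * k ^ par[3L] + exp(par[2L]) * rowSums(nn ^ par[4L])
    if (any(!is.finite(b)) || any(b <= 0)) return(1e12)
    v <- sum(b * x) - sum(log(b))
    if (!is.finite(v)) 1e12 else v
  }
  l1_0 <- length(x) / max(sum(k * x), 1e-12)
  l2_0 <- length(x) / max(sum(coal1 * x), 1e-6)
  starts <- lapply(c(0.5, 1, 2), function(p)
    c(log(l1_0), log(l2_0), p, p))
  starts <- c(starts, extra_starts)
  best <- NULL
  conv <- integer(0)
  for (s in starts) {
    s <- pmin(pmax(s, c(.LOGL_BOUNDS[1L], .LOGL_BOUNDS[1L], .P_BOUNDS[1L], .P_BOUNDS[1L])),
              c(.LOGL_BOUNDS[2L], .LOGL_BOUNDS[2L], .P_BOUNDS[2L], .P_BOUNDS[2L]))
    fit <- tryCatch(
      stats::optim(s, negll, method = "L-BFGS-B",
                   lower = c(.LOGL_BOUNDS[1L], .LOGL_BOUNDS[1L], .P_BOUNDS[1L], .P_BOUNDS[1L]),
                   upper = c(.LOGL_BOUNDS[2L], .LOGL_BOUNDS[2L], .P_BOUNDS[2L], .P_BOUNDS[2L])),
      error = function(e) NULL)
    if (is.null(fit)) next
    conv <- c(conv, fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(NULL)
  list(logL = -best$value,
       params = list(lambda1 = exp(best$par[1L]), lambda2 = exp(best$par[2L]),
                     p1 = best$par[3L], p2 = best$par[4L]),
       par = best$par, convergence = conv)
}

.gmyc_optim_null <- function(n_lineages, x) {
  negll <- function(par) {
    b <- exp(par[1L]) * n_lineages ^ par[2L]
    if (any(!is.finite(b)) || any(b <= 0)) return(1e12)
    v <- sum(b * x) - sum(log(b))
    if (!is.finite(v)) 1e12 else v
  }
  l0 <- length(x) / max(sum(n_lineages * x), 1e-12)
  best <- NULL
  conv <- integer(0)
  for (p in c(0.5, 1, 2)) {
    fit <- tryCatch(
      stats::optim(c(log(l0), p), negll, method = "L-BFGS-B",
                   lower = c(.LOGL_BOUNDS[1L], .P_BOUNDS[1L]),
                   upper = c(.LOGL_BOUNDS[2L], .P_BOUNDS[2L])),
      error = function(e) NULL)
    if (is.null(fit)) next
    conv <- c(conv, fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(logL = -best$value,
       params = list(lambda0 = exp(best$par[1L]), p0 = best$par[2L]),
       par = best$par, convergence = conv)
}

#' Fit the GMYC model to an ultrametric tree
#'
#' Fits the general mixed Yule-coalescent model by maximum likelihood.
#' In `single` mode the candidate thresholds are the midpoints between
#' consecutive distinct node heights plus the degenerate threshold below the
#' youngest node (under which the model collapses to the null single-process
#' form, so the single-threshold maximum can never fall below the null
#' maximum); for each candidate the rates and scaling exponents are
#' maximized numerically (bounded quasi-Newton from three fixed starting
#' points, rates initialized from method-of-moments event rates) and the
#' best candidate is retained. `multiple` mode starts from the single-mode
#' optimum and greedily reclassifies further nodes as diversification events
#' (adding one transition at a time, up to `max_thresholds` extra) while the
#' log-likelihood improves. Duplicate haplotypes must be collapsed first:
#' zero-length pendant branches are rejected.
#'
#' @param tree Ultrametric ape `phylo` with at least 3 tips.
#' @param mode `"single"` (default), `"multiple"` or `"null"`.
#' @param max_thresholds Maximum number of additional transitions in
#'   `multiple` mode (default 5).
#' @return Object of class `gmyc`: list with `mode`, `logL`, `params`
#'   (rates and scaling exponents), `threshold` (primary threshold time;
#'   `NA` for null), `extra_thresholds` (heights of additional transitions
#'   in multiple mode), `entities`, `partition`, `scan` (per-candidate
#'   threshold/logL/entity table), `convergence` and `tree`.
#' @export
gmyc_fit <- function(tree, mode = c("single", "multiple", "null"),
                     max_thresholds = 5L) {
  mode <- match.arg(mode)
  if (ape::Ntip(tree) < 3L) stop("need at least 3 tips")
  assert_ultrametric(tree)
  pend <- tree$edge[, 2L] <= ape::Ntip(tree)
  if (any(tree$edge.length[pend] <= 0))
    stop("zero-length pendant branches: collapse duplicate haplotypes before fitting")
  prep <- .prepare_binary(tree)
  tree2 <- prep$tree
  h <- prep$heights
  n <- ape::Ntip(tree2)
  node_ids <- (n + 1L):(n + tree2$Nnode)
  ev <- node_ids[order(h[node_ids], decreasing = TRUE)]
  evh <- h[ev]
  m <- length(ev)
  waits <- c(-diff(evh), evh[m])
  n_lin <- seq_len(m) + 1L

  null_fit <- .gmyc_optim_null(n_lin, waits)
  if (mode == "null") {
    return(structure(list(mode = "null", logL = null_fit$logL,
                          params = null_fit$params, threshold = NA_real_,
                          extra_thresholds = numeric(0),
                          entities = NA_integer_, partition = NULL,
                          scan = NULL, convergence = null_fit$convergence,
                          tree = tree2),
                     class = "gmyc"))
  }

  # candidate thresholds: midpoints between consecutive events + below the
  # youngest event (the null-nested, all-singletons classification)
  cands <- c((evh[-m] + evh[-1L]) / 2, evh[m] / 2)
  null_start <- list(c(null_fit$par[1L], .LOGL_BOUNDS[1L],
                       null_fit$par[2L], 1))
  scan <- data.frame(threshold = cands, logL = NA_real_,
                     entities = NA_integer_)
  best <- NULL
  conv_all <- integer(0)
  warm <- NULL                      # warm start from the previous candidate
  for (ci in seq_along(cands)) {
    cls <- .schedule_from_classification(tree2, h, ev, evh > cands[ci])
    fit <- .gmyc_optim_threshold(cls$k, cls$coal, waits,
                                 extra_starts = c(null_start, warm))
    if (is.null(fit)) next
    warm <- list(fit$par)
    conv_all <- c(conv_all, fit$convergence)
    scan$logL[ci] <- fit$logL
    scan$entities[ci] <- cls$entities
    if (is.null(best) || fit$logL > best$fit$logL)
      best <- list(fit = fit, cls = cls, threshold = cands[ci],
                   spec = evh > cands[ci])
  }
  if (is.null(best)) stop("GMYC optimizer failed on every candidate threshold")

  extra <- numeric(0)
  if (mode == "multiple") {
    spec <- best$spec
    cur <- best$fit
    parent <- integer(n + tree2$Nnode)
    parent[tree2$edge[, 2L]] <- tree2$edge[, 1L]
    is_spec_node <- function(sp) {
      z <- logical(n + tree2$Nnode); z[ev] <- sp; z
    }
    for (step in seq_len(max_thresholds)) {
      flag <- is_spec_node(spec)
      movable <- which(!spec & vapply(seq_len(m), function(i) {
        p <- parent[ev[i]]
        p == 0L || flag[p]
      }, logical(1L)))
      if (!length(movable)) break
      best_move <- NULL
      for (i in movable) {
        sp2 <- spec; sp2[i] <- TRUE
        cls2 <- .schedule_from_classification(tree2, h, ev, sp2)
        fit2 <- .gmyc_optim_threshold(cls2$k, cls2$coal, waits,
                                      extra_starts = list(cur$par))
        if (is.null(fit2)) next
        if (is.null(best_move) || fit2$logL > best_move$fit$logL)
          best_move <- list(fit = fit2, cls = cls2, i = i)
      }
      if (is.null(best_move) || best_move$fit$logL <= cur$logL + 1e-9) break
      spec <- {s <- spec; s[best_move$i] <- TRUE; s}
      cur <- best_move$fit
      extra <- c(extra, evh[best_move$i])
      best <- list(fit = cur,
                   cls = best_move$cls,
                   threshold = best$threshold, spec = spec)
    }
  }

  logL <- max(best$fit$logL, null_fit$logL)   # guard against optimizer noise
  structure(list(mode = mode, logL = logL, params = best$fit$params,
                 threshold = best$threshold, extra_thresholds = extra,
                 entities = best$cls$entities, partition = best$cls$partition,
                 scan = scan, convergence = conv_all,
                 null_logL = null_fit$logL, null_params = null_fit$params,
                 tree = tree2),
            class = "gmyc")
}

#' @export
print.gmyc <- function(x, ...) {
  cat("GMYC fit (", x$mode, " mode): logL = ", format(x$logL, digits = 7),
      "\n", sep = "")
  if (x$mode != "null") {
    cat("  threshold T =", format(x$threshold, digits = 6),
        "substitutions/site;", x$entities, "entities\n")
    if (length(x$extra_thresholds))
      cat("  additional transitions at:",
          paste(format(x$extra_thresholds, digits = 4), collapse = ", "), "\n")
  }
  cat("  parameters:",
      paste(names(x$params), format(unlist(x$params), digits = 4),
            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.gmyc <- function(object, ...) {
  npar <- length(object$params) + (object$mode == "single") +
    (object$mode == "multiple") * (1L + length(object$extra_thresholds))
  structure(object$logL, df = npar, class = "logLik")
}

#' @export
coef.gmyc <- function(object, ...) {
  c(unlist(object$params),
    if (!is.na(object$threshold)) c(threshold = object$threshold))
}

#' @export
summary.gmyc <- function(object, ...) {
  print(object)
  if (!is.null(object$null_logL)) {
    lr <- gmyc_lr_test(object$logL, object$null_logL,
                       df = length(object$params) - 2L + 1L)
    cat("LR vs null (logL ", format(object$null_logL, digits = 7), "): chi2 = ",
        format(lr$statistic, digits = 6), ", df = ", lr$df, ", p = ",
        format.pval(lr$p.value, digits = 4), "\n", sep = "")
  }
  invisible(object)
}

#' @export
plot.gmyc <- function(x, ...) {
  sc <- x$scan
  if (is.null(sc)) stop("null-mode fits have no threshold scan")
  graphics::plot(sc$threshold, sc$logL, type = "b", xlab = "threshold (subst/site)",
                 ylab = "log-likelihood", ...)
  graphics::abline(v = x$threshold, lty = 2)
  invisible(x)
}

#' Likelihood-ratio test between two GMYC fits
#'
#' Computes `chi2 = 2 (logL_alt - logL_null)` and the upper-tail chi-square
#' p-value. The degrees of freedom are caller-visible because the parameter
#' count attributed to the threshold models varies between software
#' parameterizations.
#'
#' @param alt,null `gmyc` objects or bare log-likelihood values.
#' @param df Degrees of freedom; when `NULL` (default) it is taken as the
#'   difference in parameter counts of the two fits (requires `gmyc`
#'   objects).
#' @param tol Tolerance for a slightly negative statistic due to optimizer
#'   noise (default `1e-6`).
#' @return List of class `gmyc_lr` with `statistic`, `df`, `p.value`.
#' @export
gmyc_lr_test <- function(alt, null, df = NULL, tol = 1e-6) {
  ll <- function(z) if (inherits(z, "gmyc")) z$logL else as.numeric(z)
  npar <- function(z) if (inherits(z, "gmyc")) attr(logLik(z), "df") else NA_integer_
  la <- ll(alt); l0 <- ll(null)
  if (is.null(df)) {
    df <- npar(alt) - npar(null)
    if (is.na(df)) stop("df must be given when bare log-likelihoods are passed")
  }
  stat <- 2 * (la - l0)
  if (stat < -tol)
    stop("alternative log-likelihood below null beyond tolerance: optimizer failure")
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "gmyc_lr")
}

#' @export
print.gmyc_lr <- function(x, ...) {
  cat("GMYC likelihood-ratio test: chi2 =", format(x$statistic, digits = 6),
      " df =", x$df, " p =", format.pval(x$p.value, digits = 4), "\n")
  invisible(x)
}

#' Conspecificity matrix over a tree sample
#'
#' Applies single-threshold GMYC delimitation to every tree of a sample
#' (e.g. a posterior sample or bootstrap UPGMA trees) and reports, for each
#' pair of tips, the fraction of trees in which the pair falls inside the
#' same delimited entity. This is a maximum-likelihood aggregation with the
#' same output contract as Bayesian conspecificity estimates.
#'
#' @param trees List of ultrametric `phylo` objects (or a `multiPhylo`)
#'   sharing one tip set.
#' @return Object of class `conspecificity`: list with `labels`, `prob`
#'   (symmetric matrix, unit diagonal), `n_trees`.
#' @export
conspecificity_matrix <- function(trees) {
  trees <- unclass(trees)
  if (length(trees) < 2L) stop("need at least 2 trees")
  labels <- sort(trees[[1L]]$tip.label)
  acc <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
  for (tr in trees) {
    if (!setequal(tr$tip.label, labels)) stop("trees have mismatched tip sets")
    # tips at (effectively) zero distance are duplicate haplotypes on this
    # tree: keep one representative each, fit, and co-assign the duplicates
    # with their representative afterwards
    cd <- ape::cophenetic.phylo(tr)
    tol <- max(1e-9 * max(cd), 1e-12)
    comp <- .sl_components(cd, tol)
    rep_tip <- vapply(seq_len(max(comp)), function(k)
      sort(rownames(cd)[comp == k])[1L], character(1L))
    tip_rep <- setNames(rep_tip[comp], rownames(cd))
    if (length(rep_tip) < 3L) {
      asg <- setNames(rep("G1", length(labels)), labels)
    } else {
      fit <- gmyc_fit(ape::keep.tip(tr, rep_tip), mode = "single")
      asg <- fit$partition$assignment[tip_rep[labels]]
      names(asg) <- labels
    }
    acc <- acc + outer(asg, asg, "==")
  }
  structure(list(labels = labels, prob = acc / length(trees),
                 n_trees = length(trees)),
            class = "conspecificity")
}

#' @export
print.conspecificity <- function(x, ...) {
  cat("Conspecificity over", x$n_trees, "trees;", length(x$labels), "tips\n")
  invisible(x)
}

#' @export
plot.conspecificity <- function(x, ...) {
  n <- length(x$labels)
  graphics::image(seq_len(n), seq_len(n), x$prob[, n:1], axes = FALSE,
                  xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_len(n), labels = x$labels, las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq_len(n), labels = rev(x$labels), las = 2, cex.axis = 0.6)
  invisible(x)
}
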