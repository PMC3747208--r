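# Morphological characters and heteroscedastic discriminant analysis --------

.MORPHO_FEATURES <- c("pattern_code", "head_depth_ratio", "peduncle_ratio",
                      "predorsal_ratio")

#' Derive analysis characters from raw morphometric measurements
#'
#' Converts raw linear measurements into the analysis characters: the
#' post-orbital head depth as a percentage of head length, the caudal
#' peduncle depth and pre-dorsal length as percentages of standard length,
#' and the coded skin pattern (chevron blotches = 0, none/unclear = 1;
#' dorsal spots are kept as the categorical value `"spots"` with no numeric
#' code since they are diagnostic on their own). Rows with non-positive
#' lengths are rejected with a message.
#'
#' @param measurements `data.frame` with columns `head_length`,
#'   `postorbital_head_depth`, `peduncle_depth`, `predorsal_length`,
#'   `standard_length`, `pattern`, `stomach` and optionally `id`, `label`.
#' @return A `data.frame` (class `morpho_table`) with columns `id`,
#'   `head_depth_ratio`, `peduncle_ratio`, `predorsal_ratio`,
#'   `pattern_code`, `pattern`, `stomach`, `label`.
#' @export
compute_characters <- function(measurements) {
  req <- c("head_length", "postorbital_head_depth", "peduncle_depth",
           "predorsal_length", "standard_length", "pattern", "stomach")
  missing_cols <- setdiff(req, names(measurements))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  df <- measurements
  if (!"id" %in% names(df)) df$id <- paste0("ind", seq_len(nrow(df)))
  if (!"label" %in% names(df)) df$label <- "unknown"
  num <- c("head_length", "postorbital_head_depth", "peduncle_depth",
           "predorsal_length", "standard_length")
  ok <- rowSums(sapply(df[num], function(v) is.finite(v) & v > 0)) == length(num)
  if (any(!ok))
    message(sum(!ok), " row(s) rejected for non-positive or missing lengths: ",
            paste(df$id[!ok], collapse = ", "))
  df <- df[ok, , drop = FALSE]
  pattern <- tolower(as.character(df$pattern))
  code <- ifelse(pattern %in% c("chevron", "chevrons", "blotches"), 0,
                 ifelse(pattern %in% c("none", "unclear", "no", "plain"), 1,
                        NA_real_))
  out <- data.frame(
    id = as.character(df$id),
    head_depth_ratio = 100 * df$postorbital_head_depth / df$head_length,
    peduncle_ratio = 100 * df$peduncle_depth / df$standard_length,
    predorsal_ratio = 100 * df$predorsal_length / df$standard_length,
    pattern_code = code,
    pattern = pattern,
    stomach = tolower(as.character(df$stomach)),
    label = as.character(df$label),
    stringsAsFactors = FALSE)
  class(out) <- c("morpho_table", "data.frame")
  out
}

#' Gaussian kernel density with oversmoothed Silverman bandwidth
#'
#' Bandwidth `h = 1.5 * 0.9 * min(sd, IQR/1.34) * n^(-1/5)` (Silverman's
#' rule of thumb times 1.5 for extra smoothness), evaluated on a 512-point
#' grid spanning the data range plus/minus `3h`.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return Object of class `density_estimate`: list with `x` (grid), `y`
#'   (density), `bw`.
#' @export
kernel_density <- function(values) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L) stop("need at least 2 distinct values")
  n <- length(values)
  iqr <- stats::IQR(values) / 1.34
  s <- stats::sd(values)
  spread <- if (iqr > 0) min(s, iqr) else s
  h <- 1.5 * 0.9 * spread * n^(-1 / 5)
  d <- stats::density(values, bw = h, n = 512L,
                      from = min(values) - 3 * h, to = max(values) + 3 * h)
  structure(list(x = d$x, y = d$y, bw = h), class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat("Kernel density on", length(x$x), "grid points, bandwidth",
      format(x$bw, digits = 4), "\n")
  invisible(x)
}

#' @export
plot.density_estimate <- function(x, ...) {
  graphics::plot(x$x, x$y, type = "l", xlab = "value", ylab = "density", ...)
  invisible(x)
}

#' Permutation test for homogeneity of multivariate dispersions
#'
#' Characters are standardized, each individual's Euclidean distance to its
#' group centroid is computed, and a one-way ANOVA F statistic on these
#' distances (df1 = groups - 1, df2 = N - groups) is compared with its
#' permutation distribution under shuffled group labels.
#'
#' @param x Feature matrix, or a `morpho_table` (its four analysis
#'   characters are used).
#' @param labels Group labels (2+ groups, each of size >= 2).
#' @param permutations Number of label permutations (default 999).
#' @param seed Optional integer seed.
#' @return List of class `dispersion_test` with `F`, `df`, `p.value`,
#'   `permutations`.
#' @export
dispersion_test <- function(x, labels, permutations = 999L, seed = NULL) {
  x <- .morpho_features(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  if (any(table(labels) < 2L)) stop("every group needs at least 2 members")
  if (length(unique(labels)) < 2L) stop("need at least 2 groups")
  z <- scale(x)
  fstat <- function(lab) {
    d <- numeric(nrow(z))
    for (g in unique(lab)) {
      idx <- lab == g
      ctr <- colMeans(z[idx, , drop = FALSE])
      d[idx] <- sqrt(rowSums(sweep(z[idx, , drop = FALSE], 2L, ctr)^2))
    }
    grand <- mean(d)
    gm <- tapply(d, lab, mean)
    ng <- tapply(d, lab, length)
    ssb <- sum(ng * (gm - grand)^2)
    ssw <- sum((d - gm[lab])^2)
    k <- length(gm)
    (ssb / (k - 1)) / (ssw / (length(d) - k))
  }
  f_obs <- fstat(labels)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (i in seq_len(permutations))
    hits <- hits + (fstat(sample(labels)) >= f_obs - 1e-12)
  structure(list(F = f_obs,
                 df = c(length(unique(labels)) - 1L,
                        length(labels) - length(unique(labels))),
                 p.value = hits / permutations,
                 permutations = as.integer(permutations)),
            class = "dispersion_test")
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat("Dispersion homogeneity: F(", x$df[1L], ",", x$df[2L], ") = ",
      format(x$F, digits = 5), ", permutation p = ",
      format(x$p.value, digits = 3), "\n", sep = "")
  invisible(x)
}

.morpho_features <- function(x) {
  if (inherits(x, "morpho_table") ||
      (is.data.frame(x) && all(.MORPHO_FEATURES %in% names(x)))) {
    as.matrix(x[, .MORPHO_FEATURES])
  } else as.matrix(x)
}

# regularized class covariance: gamma*[(1-lambda)*S_k + lambda*S_pooled] +
# (1-gamma)*(tr(S_k)/d)*I
.reg_cov <- function(S_k, S_pool, gamma, lambda) {
  d <- nrow(S_k)
  gamma * ((1 - lambda) * S_k + lambda * S_pool) +
    (1 - gamma) * (sum(diag(S_k)) / d) * diag(d)
}

#' Fit a smoothed heteroscedastic discriminant model
#'
#' Finds a `dims`-dimensional projection of the (standardized) characters in
#' which the two classes keep distinct covariance structures while the
#' discarded directions carry only shared structure, by maximizing the
#' profile Gaussian log-likelihood over orthonormal projections
#' (deterministically initialized from the pooled-covariance linear
#' discriminant direction padded with principal components, then refined by
#' quasi-Newton). Class covariances are regularized before fitting as
#' `gamma * ((1-lambda) * S_k + lambda * S_pooled) +
#'  (1-gamma) * (tr(S_k)/d) * I`, so `gamma = 1, lambda = 0` is pure
#' unshrunk heteroscedastic fitting. Individuals are classified in the
#' component space by the larger Gaussian posterior.
#'
#' @param x Feature matrix or `morpho_table` (4 characters).
#' @param labels Two-class label vector.
#' @param dims Number of discriminative components (default 3).
#' @param gamma,lambda Regularization weights (defaults 1 and 0).
#' @return Object of class `hda_model`: `loadings` (feature -> component
#'   matrix on the standardized scale), `means`/`covs` per class in
#'   component space, `priors`, `correlations` (component-feature Pearson),
#'   `center`/`scale` of the training standardization, `classes`,
#'   `training_accuracy`, `dims`, `gamma`, `lambda`.
#' @export
hda_fit <- function(x, labels, dims = 3L, gamma = 1, lambda = 0) {
  X <- .morpho_features(x)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("exactly two classes required")
  if (anyNA(X)) stop("features contain missing values")
  d <- ncol(X)
  if (dims < 1L || dims > d) stop("dims must be in 1..", d)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  if (any(scl == 0)) stop("constant feature; cannot standardize")
  Z <- scale(X, ctr, scl)
  n_k <- table(labels)[classes]
  S_k <- lapply(classes, function(cl) stats::cov(Z[labels == cl, , drop = FALSE]))
  S_pool <- Reduce(`+`, Map(function(S, nk) (nk - 1) * S, S_k, as.list(n_k))) /
    (nrow(Z) - 2)
  S_reg <- lapply(S_k, .reg_cov, S_pool = S_pool, gamma = gamma, lambda = lambda)
  for (S in S_reg) {
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-10)
      stop("singular class covariance after regularization; try gamma < 1")
  }
  S_tot <- stats::cov(Z)
  mu_k <- lapply(classes, function(cl) colMeans(Z[labels == cl, , drop = FALSE]))

  # deterministic initial basis: LDA direction, then principal components
  w_lda <- tryCatch(solve(S_pool, mu_k[[2L]] - mu_k[[1L]]),
                    error = function(e) mu_k[[2L]] - mu_k[[1L]])
  pcs <- eigen(S_tot, symmetric = TRUE)$vectors
  W0 <- qr.Q(qr(cbind(w_lda, pcs)))[, seq_len(d), drop = FALSE]

  if (dims < d) {
    q <- dims
    nfree <- d * (d - q)
    obj <- function(par) {
      V <- matrix(par, nrow = d)
      qrv <- qr(V)
      if (qrv$rank < (d - q)) return(1e12)
      Vq <- qr.Q(qrv)
      # orthonormal complement = retained subspace
      Us <- qr.Q(qr(cbind(Vq, diag(d))))[, (d - q + 1L):d, drop = FALSE]
      val <- 0
      for (ki in seq_along(classes)) {
        M <- crossprod(Us, S_reg[[ki]] %*% Us)
        dt <- determinant(M, logarithm = TRUE)$modulus
        val <- val + as.numeric(n_k[ki]) / 2 * as.numeric(dt)
      }
      Md <- crossprod(Vq, S_tot %*% Vq)
      val <- val + nrow(Z) / 2 *
        as.numeric(determinant(Md, logarithm = TRUE)$modulus)
      if (!is.finite(val)) 1e12 else val
    }
    v0 <- as.vector(W0[, (q + 1L):d, drop = FALSE])
    opt <- stats::optim(v0, obj, method = "BFGS",
                        control = list(maxit = 200L, reltol = 1e-10))
    V <- qr.Q(qr(matrix(opt$par, nrow = d)))
    Us <- qr.Q(qr(cbind(V, diag(d))))[, (d - q + 1L):d, drop = FALSE]
  } else {
    Us <- diag(d)
  }

  # interpretable axes inside the retained subspace: first the projected LDA
  # direction, then eigenvectors of the projected class-covariance
  # difference (the heteroscedastic structure), orthogonalized sequentially
  b1 <- crossprod(Us, w_lda)
  b1 <- b1 / sqrt(sum(b1^2))
  B <- b1
  if (dims > 1L) {
    Dhet <- crossprod(Us, (S_reg[[1L]] - S_reg[[2L]]) %*% Us)
    ev <- eigen((Dhet + t(Dhet)) / 2, symmetric = TRUE)
    cand <- ev$vectors[, order(-abs(ev$values)), drop = FALSE]
    for (j in seq_len(ncol(cand))) {
      v <- cand[, j] - B %*% crossprod(B, cand[, j])
      nv <- sqrt(sum(v^2))
      if (nv > 1e-8) B <- cbind(B, v / nv)
      if (ncol(B) == dims) break
    }
    j <- 1L
    while (ncol(B) < dims && j <= dims) {  # degenerate fallback: pad from
      v <- diag(dims)[, j]                 # the coordinate axes
      v <- v - B %*% crossprod(B, v)
      nv <- sqrt(sum(v^2))
      if (nv > 1e-8) B <- cbind(B, v / nv)
      j <- j + 1L
    }
  }
  loadings <- Us %*% B                       # d x dims, standardized scale
  # sign convention: largest-magnitude loading of each component positive
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  dimnames(loadings) <- list(colnames(X),
                             paste0("component", seq_len(ncol(loadings))))
  scores <- Z %*% loadings
  means <- lapply(classes, function(cl)
    colMeans(scores[labels == cl, , drop = FALSE]))
  covs <- lapply(seq_along(classes), function(ki)
    crossprod(loadings, S_reg[[ki]] %*% loadings))
  names(means) <- names(covs) <- classes
  correlations <- stats::cor(scores, X)      # dims x d
  model <- structure(list(loadings = loadings, means = means, covs = covs,
                          priors = as.numeric(n_k) / nrow(Z),
                          correlations = t(correlations),
                          center = ctr, scale = scl, classes = classes,
                          dims = dims, gamma = gamma, lambda = lambda),
                     class = "hda_model")
  pred <- predict(model, X, type = "class")
  model$training_accuracy <- mean(pred == labels)
  model
}

#' @export
print.hda_model <- function(x, ...) {
  cat("Heteroscedastic discriminant model: classes",
      paste(x$classes, collapse = " vs "), "|", x$dims, "components\n")
  cat("gamma =", x$gamma, " lambda =", x$lambda,
      " training accuracy =", format(x$training_accuracy, digits = 3), "\n")
  cat("Loadings (standardized features):\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' @export
coef.hda_model <- function(object, ...) object$loadings

#' Classify new individuals with a fitted discriminant model
#'
#' @param object An [hda_fit] model.
#' @param newdata Feature matrix or `morpho_table`.
#' @param type `"class"`, `"posterior"` or `"score"`.
#' @param ... Unused.
#' @return Class vector, posterior matrix, or component scores.
#' @export
predict.hda_model <- function(object, newdata,
                              type = c("class", "posterior", "score"), ...) {
  type <- match.arg(type)
  X <- .morpho_features(newdata)
  Z <- scale(X, object$center, object$scale)
  scores <- Z %*% object$loadings
  if (type == "score") return(scores)
  logd <- vapply(seq_along(object$classes), function(ki) {
    S <- object$covs[[ki]]
    mu <- object$means[[ki]]
    L <- chol(S)
    dev <- forwardsolve(t(L), t(scores) - mu)
    -0.5 * colSums(dev^2) - sum(log(diag(L))) + log(object$priors[ki])
  }, numeric(nrow(scores)))
  if (nrow(X) == 1L) logd <- matrix(logd, nrow = 1L)
  mx <- apply(logd, 1L, max)
  post <- exp(logd - mx)
  post <- post / rowSums(post)
  colnames(post) <- object$classes
  rownames(post) <- rownames(X)
  if (type == "posterior") post
  else object$classes[max.col(post, ties.method = "first")]
}

#' Jackknife (leave-one-out) identification accuracy
#'
#' Refits the discriminant model with each individual excluded and predicts
#' that individual's class from the reduced model. Fold failures are
#' recorded as misidentifications with a diagnostic rather than stopping
#' the run.
#'
#' @inheritParams hda_fit
#' @return List of class `hda_jackknife`: `accuracy`, `predictions`
#'   (`data.frame` with truth, prediction, posterior), `failures`.
#' @export
hda_jackknife <- function(x, labels, dims = 3L, gamma = 1, lambda = 0) {
  X <- .morpho_features(x)
  labels <- as.character(labels)
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 individuals")
  pred <- character(n)
  post <- numeric(n)
  failures <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      m <- hda_fit(X[-i, , drop = FALSE], labels[-i], dims = dims,
                   gamma = gamma, lambda = lambda)
      p <- predict(m, X[i, , drop = FALSE], type = "posterior")
      list(class = colnames(p)[which.max(p)], post = max(p))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0("fold ", i, ": ", conditionMessage(res)))
      pred[i] <- NA_character_
      post[i] <- NA_real_
    } else {
      pred[i] <- res$class
      post[i] <- res$post
    }
  }
  correct <- !is.na(pred) & pred == labels
  structure(list(accuracy = mean(correct),
                 predictions = data.frame(truth = labels, prediction = pred,
                                          posterior = post),
                 failures = failures),
            class = "hda_jackknife")
}

#' @export
print.hda_jackknife <- function(x, ...) {
  n <- nrow(x$predictions)
  cat("Jackknife identification:", sum(x$predictions$truth ==
        x$predictions$prediction, na.rm = TRUE), "/", n, "correct (",
      format(100 * x$accuracy, digits = 3), "% )\n")
  if (length(x$failures)) cat(length(x$failures), "fold failure(s)\n")
  invisible(x)
}

#' Identify specimens from morphology
#'
#' Applies the diagnostic short-circuit first -- an elongated stomach or a
#' dorsal-spot pattern identifies the marine morphotype directly, without
#' discriminant scoring -- then classifies the remaining individuals with
#' the fitted two-class discriminant model. Rows with missing features are
#' flagged unidentifiable.
#'
#' @param table A `morpho_table` (see [compute_characters]).
#' @param model A fitted [hda_fit] model.
#' @param diagnostic_label Label assigned by the categorical short-circuit
#'   (default `"AM"`).
#' @return `data.frame` with `id`, `predicted`, `posterior`, `basis`
#'   (`"diagnostic"`, `"discriminant"` or `"unidentifiable"`).
#' @export
identify_specimens <- function(table, model, diagnostic_label = "AM") {
  stopifnot(inherits(model, "hda_model"))
  n <- nrow(table)
  out <- data.frame(id = table$id, predicted = NA_character_,
                    posterior = NA_real_, basis = NA_character_,
                    stringsAsFactors = FALSE)
  diag_hit <- (!is.na(table$stomach) & table$stomach == "elongated") |
    (!is.na(table$pattern) & table$pattern == "spots")
  out$predicted[diag_hit] <- diagnostic_label
  out$posterior[diag_hit] <- 1
  out$basis[diag_hit] <- "diagnostic"
  rest <- which(!diag_hit)
  if (length(rest)) {
    feats <- .morpho_features(table[rest, , drop = FALSE])
    complete <- stats::complete.cases(feats)
    idx <- rest[complete]
    if (length(idx)) {
      p <- predict(model, table[idx, , drop = FALSE], type = "posterior")
      out$predicted[idx] <- colnames(p)[max.col(p, ties.method = "first")]
      out$posterior[idx] <- apply(p, 1L, max)
      out$basis[idx] <- "discriminant"
    }
    out$basis[rest[!complete]] <- "unidentifiable"
  }
  out
}
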