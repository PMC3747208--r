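test_that("character computation reproduces row-wise arithmetic and coding", {
  raw <- data.frame(
    id = c("f1", "f2", "f3"),
    head_length = c(4, 5, 4), postorbital_head_depth = c(2, 3, 2.4),
    peduncle_depth = c(1, 1.2, 0.9), predorsal_length = c(11, 12, 10),
    standard_length = c(20, 22, 19),
    pattern = c("chevron", "none", "spots"),
    stomach = c("bulbous", "bulbous", "elongated"))
  tab <- compute_characters(raw)
  expect_equal(tab$head_depth_ratio, 100 * raw$postorbital_head_depth / raw$head_length)
  expect_equal(tab$peduncle_ratio, 100 * raw$peduncle_depth / raw$standard_length)
  expect_equal(tab$predorsal_ratio, 100 * raw$predorsal_length / raw$standard_length)
  expect_equal(tab$pattern_code, c(0, 1, NA))

  raw$head_length[2] <- -1
  expect_message(tab2 <- compute_characters(raw), "rejected.*f2")
  expect_equal(nrow(tab2), 2L)
})

test_that("kernel densities integrate to one and match the analytic mixture", {
  set.seed(101)
  d <- kernel_density(rnorm(100))
  area <- sum(diff(d$x) * (head(d$y, -1) + tail(d$y, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-3)

  # two-point sample: density is the mean of two normal kernels
  v <- c(0, 1)
  d2 <- kernel_density(v)
  h <- 1.5 * 0.9 * min(sd(v), IQR(v) / 1.34) * 2^(-1 / 5)
  expect_equal(d2$bw, h, tolerance = 1e-12)
  analytic <- (dnorm(d2$x, 0, h) + dnorm(d2$x, 1, h)) / 2
  expect_equal(d2$y, analytic, tolerance = 0.02)

  expect_error(kernel_density(rep(3, 10)), "distinct")
})

test_that("dispersion test is symmetric under mirrored groups and calibrated", {
  set.seed(103)
  g1 <- matrix(rnorm(40), 10, 4)
  g2 <- -g1                       # mirror copy: identical dispersion
  x <- rbind(g1, g2)
  res <- dispersion_test(x, rep(c("a", "b"), each = 10),
                         permutations = 99, seed = 1)
  expect_lt(res$F, 1e-20)
  expect_equal(res$df, c(1L, 18L))

  # agreement with the vegan oracle on heteroscedastic data
  set.seed(107)
  y <- rbind(matrix(rnorm(60), 15, 4), matrix(rnorm(60, sd = 2.2), 15, 4))
  lab <- rep(c("a", "b"), each = 15)
  mine <- dispersion_test(y, lab, permutations = 99, seed = 2)
  bd <- vegan::betadisper(dist(scale(y)), lab, type = "centroid")
  expect_equal(mine$F, anova(bd)[1, "F value"], tolerance = 1e-9)
  expect_lt(mine$p.value, 0.05)

  # nominal-level calibration under the null (light version)
  set.seed(109)
  rej <- 0L
  for (i in 1:60) {
    z <- matrix(rnorm(80), 20, 4)
    r <- dispersion_test(z, rep(c("a", "b"), each = 10), permutations = 59)
    rej <- rej + (r$p.value < 0.05)
  }
  expect_lte(rej, 10L)
  expect_error(dispersion_test(matrix(rnorm(12), 3, 4), c("a", "a", "b")),
               "at least 2")
})

test_that("HDA agrees with standard LDA in the homoscedastic limit", {
  set.seed(113)
  S <- matrix(c(1, 0.3, 0.1, 0, 0.3, 1, 0.2, 0, 0.1, 0.2, 1, 0.15,
                0, 0, 0.15, 1), 4, 4)
  x <- rbind(MASS::mvrnorm(40, c(0, 0, 0, 0), S),
             MASS::mvrnorm(40, c(1.4, 1, 0.5, 0.2), S))
  lab <- rep(c("u", "v"), each = 40)
  m <- hda_fit(x, lab, lambda = 1)   # pooled covariance: homoscedastic limit
  lda <- MASS::lda(x, grouping = lab)
  agree <- mean(predict(m, x, type = "class") ==
                as.character(predict(lda, x)$class))
  expect_gte(agree, 0.95)
})

test_that("HDA separates clean classes and handles regularization limits", {
  set.seed(127)
  x <- rbind(matrix(rnorm(40, 0, 0.2), 10, 4),
             matrix(rnorm(40, 8, 0.2), 10, 4))
  lab <- rep(c("u", "v"), each = 10)
  m <- hda_fit(x, lab)
  expect_equal(m$training_accuracy, 1)
  expect_equal(dim(m$loadings), c(4L, 3L))
  # gamma = 0 degrades gracefully to spherical covariances
  m0 <- hda_fit(x, lab, gamma = 0)
  expect_equal(m0$training_accuracy, 1)
  expect_error(hda_fit(x, c(lab[-1], "w")), "two classes")
})

test_that("component sign flips leave the classification unchanged", {
  m <- simulate_morphology(seed = 131)
  tr <- m[m$label %in% c("AT", "AZ"), ]
  fit <- hda_fit(tr, tr$label)
  base <- predict(fit, tr, type = "class")
  for (j in 1:3) {
    flipped <- fit
    flipped$loadings[, j] <- -flipped$loadings[, j]
    flipped$means <- lapply(fit$means, function(mu) { mu[j] <- -mu[j]; mu })
    flipped$covs <- lapply(fit$covs, function(S) {
      S[j, ] <- -S[j, ]; S[, j] <- -S[, j]; S
    })
    expect_equal(predict(flipped, tr, type = "class"), base)
  }
})

test_that("jackknife is pessimistic relative to training accuracy", {
  set.seed(137)
  diff_acc <- replicate(8, {
    m <- simulate_morphology()
    tr <- m[m$label %in% c("AT", "AZ"), ]
    fit <- hda_fit(tr, tr$label)
    jk <- hda_jackknife(tr, tr$label)
    fit$training_accuracy - jk$accuracy
  })
  expect_gte(mean(diff_acc), 0)
  expect_error(hda_jackknife(matrix(rnorm(16), 4, 4), c("a", "a", "b", "b")),
               "at least 10")
})

test_that("identification short-circuits diagnostic characters", {
  m <- simulate_morphology(seed = 139)
  tr <- m[m$label %in% c("AT", "AZ"), ]
  fit <- hda_fit(tr, tr$label)
  out <- identify_specimens(m, fit)
  am_rows <- m$label == "AM"
  expect_true(all(out$predicted[am_rows] == "AM"))
  expect_true(all(out$basis[am_rows] == "diagnostic"))
  expect_true(all(out$basis[!am_rows] == "discriminant"))
  # batch predictions equal row-wise posterior evaluation
  post <- predict(fit, m[!am_rows, ], type = "posterior")
  expect_equal(out$predicted[!am_rows],
               colnames(post)[max.col(post, ties.method = "first")])

  # a row at a training centroid is assigned to its own class
  ctr <- tr[tr$label == "AZ", ]
  centroid <- ctr[1, ]
  for (f in c("head_depth_ratio", "peduncle_ratio", "predorsal_ratio",
              "pattern_code"))
    centroid[[f]] <- mean(ctr[[f]])
  p <- predict(fit, centroid, type = "posterior")
  expect_gt(p[1, "AZ"], 0.5)

  # missing features flagged unidentifiable
  broken <- m[1:2, ]
  broken$head_depth_ratio[1] <- NA
  broken$pattern[1] <- "none"; broken$stomach[1] <- "bulbous"
  out2 <- identify_specimens(broken, fit)
  expect_equal(out2$basis[1], "unidentifiable")
})

test_that("class-conditional errors are balanced on the default design", {
  m <- simulate_morphology(seed = 149)
  tr <- m[m$label %in% c("AT", "AZ"), ]
  jk <- hda_jackknife(tr, tr$label)
  errs <- with(jk$predictions, tapply(truth != prediction, truth, sum))
  expect_lte(abs(diff(errs)), 3L)
})
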