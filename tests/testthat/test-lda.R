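test_that("two equal 1-D classes put the decision boundary at the midpoint", {
  # symmetric classes around 0 and 10, equal sizes
  x <- matrix(c(-1, 0, 1, 9, 10, 11), ncol = 1,
              dimnames = list(NULL, "f"))
  g <- rep(c("A", "B"), each = 3)
  m <- fit_lda(x, groups = g, priors = "equal")
  at5 <- classify(m, 5)
  expect_equal(unname(as.numeric(at5[1, c("A", "B")])), c(0.5, 0.5),
               tolerance = 1e-12)
  expect_equal(classify(m, 4.9)$predicted, "A")
  expect_equal(classify(m, 5.1)$predicted, "B")
  # exact posterior tie goes to the first class in declared order
  expect_equal(at5$predicted, "A")
})

test_that("pooled covariance equals the common within-class matrix", {
  set.seed(8)
  base <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("x", "y")))
  base <- scale(base, scale = FALSE)          # centred block
  X <- rbind(base, sweep(base, 2, c(5, -3), "+"),
             sweep(base, 2, c(-2, 7), "+"))   # identical within-class shape
  g <- rep(c("A", "B", "C"), each = 10)
  m <- fit_lda(X, groups = g)
  expect_equal(unname(m$pooled_cov), unname(cov(base) * 9 * 3 / 27),
               tolerance = 1e-12)
})

test_that("a 3-class fit yields exactly K - 1 discriminant axes", {
  tab <- generate_cohort(two_marker_config(2, n_metabolites = 6))
  m <- fit_lda(tab)
  expect_equal(ncol(m$axes), 2)
  expect_equal(colnames(m$axes), c("LD1", "LD2"))
  # axes ordered by decreasing between/within eigenvalue
  expect_true(all(diff(m$svd) <= 1e-10))
  # unit pooled within-class variance per axis
  expect_equal(unname(diag(t(m$axes) %*% m$pooled_cov %*% m$axes)),
               rep(1, 2), tolerance = 1e-8)
  # sign convention: largest-magnitude loading positive
  for (j in 1:2) expect_gt(m$axes[which.max(abs(m$axes[, j])), j], 0)
  # 2-class fit: a single axis
  m2 <- fit_lda(tab$concentrations[tab$group != "C", 1:3],
                groups = droplevels(tab$group[tab$group != "C"]))
  expect_equal(ncol(m2$axes), 1)
})

test_that("posteriors normalize, and a far-away centroid dominates", {
  tab <- generate_cohort(two_marker_config(6))
  m <- fit_lda(tab, features = c("M001", "M002"))
  P <- classify(m, tab$concentrations[, 1:2])
  expect_equal(rowSums(as.matrix(P[, m$class_names])), rep(1, nrow(P)),
               tolerance = 1e-9)
  # argmax consistency
  expect_equal(P$predicted,
               m$class_names[max.col(as.matrix(P[, m$class_names]),
                                     ties.method = "first")])
  # x at a centroid with the others >= 10 Mahalanobis units away:
  # posterior ratio bounded by exp(-50), so posterior_A >= 1 - 1e-9
  m3 <- fit_lda(matrix(c(rnorm(20, 0, 1), rnorm(20, 30, 1)), ncol = 1,
                       dimnames = list(NULL, "f")),
                groups = rep(c("A", "B"), each = 20), priors = "equal")
  pa <- classify(m3, unname(m3$means["A", ]))
  expect_gte(pa$A, 1 - 1e-9)
})

test_that("fit errors are explicit: small class, constant feature, bad x", {
  X <- matrix(runif(12), 6, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_lda(X, groups = c("A", "A", "A", "A", "A", "B")),
               "fewer than 2")
  Xc <- X; Xc[, 2] <- 3
  expect_error(fit_lda(Xc, groups = rep(c("A", "B"), 3)), "'b'")
  m <- fit_lda(X, groups = rep(c("A", "B"), 3))
  expect_error(classify(m, c(1, NA)), "non-finite")
  expect_error(classify(m, c(1, 2, 3)), "features")
})

test_that("equal-priors classification is invariant to affine re-scaling", {
  for (s in 1:20) {
    inst <- random_instance(s)
    if (ncol(inst$X) < 2) next
    m1 <- fit_lda(inst$X, groups = inst$g, priors = "equal")
    scale <- diag(runif(ncol(inst$X), 0.1, 10))
    shift <- rnorm(ncol(inst$X), sd = 5)
    X2 <- sweep(inst$X %*% scale, 2, shift, "+")
    colnames(X2) <- colnames(inst$X)
    m2 <- fit_lda(X2, groups = inst$g, priors = "equal")
    p1 <- classify(m1, inst$X)
    p2 <- classify(m2, X2)
    expect_identical(p1$predicted, p2$predicted)
    expect_equal(as.matrix(p1[, m1$class_names]),
                 as.matrix(p2[, m2$class_names]), tolerance = 1e-6)
  }
})

unname2 <- function(m) { dimnames(m) <- list(NULL, colnames(m)); m }

test_that("posteriors and predictions match an independent reference LDA", {
  skip_if_not_installed("MASS")
  for (s in 1:50) {
    inst <- random_instance(1000 + s)
    m <- fit_lda(inst$X, groups = inst$g)
    expect_equal(m$ridge_used, 0)
    ref <- MASS::lda(inst$X, grouping = inst$g)
    pref <- predict(ref, inst$X)
    mine <- classify(m, inst$X)
    expect_equal(as.matrix(mine[, m$class_names]),
                 unname2(pref$posterior), tolerance = 1e-8)
    expect_identical(mine$predicted, as.character(pref$class))
  }
})

test_that("leave-one-out matches per-fold refits and the reference CV", {
  skip_if_not_installed("MASS")
  tab <- generate_cohort(two_marker_config(9))
  loo <- loo_evaluate(tab, features = c("M001", "M002", "M003"))
  # naive oracle: refit from scratch per fold with the reference LDA
  X <- tab$concentrations[, 1:3]
  for (i in seq_len(nrow(X))) {
    ref <- MASS::lda(X[-i, ], grouping = tab$group[-i])
    expect_identical(loo$records$predicted[i],
                     as.character(predict(ref, X[i, ])$class))
  }
  # and against the reference implementation's own CV mode (equal priors:
  # its CV reuses full-data priors, so only then are the folds identical)
  looe <- loo_evaluate(tab, features = c("M001", "M002", "M003"),
                       priors = "equal")
  cv <- MASS::lda(X, grouping = tab$group, CV = TRUE,
                  prior = rep(1 / 3, 3))
  expect_identical(looe$records$predicted, as.character(cv$class))
  expect_equal(as.matrix(looe$records[, levels(tab$group)]),
               unname2(cv$posterior), tolerance = 1e-8)
})

test_that("well-separated classes reach 100% leave-one-out accuracy", {
  accs <- vapply(1:20, function(s) {
    cfg <- synthetic_config(n_per_group = c(12, 9), n_metabolites = 2,
                            class_names = c("A", "B"),
                            markers = list(list(index = 1,
                                                shift = c(1, 4))),
                            noise_sigma = 0.1, seed = s)
    loo_evaluate(generate_cohort(cfg), features = "M001")$accuracy
  }, numeric(1))
  # log-shift log(4) = 1.39 is ~14 within-class log-SDs (0.1): clean margin
  expect_true(all(accs == 1))
})

test_that("degenerate leave-one-out folds are refused", {
  X <- matrix(runif(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(loo_evaluate(X, groups = c("A", "A", "A", "B", "B")),
               "degenerate")
})

test_that("leave-one-out is independent of subject order", {
  tab <- generate_cohort(two_marker_config(12))
  perm <- sample(n_subjects(tab))
  loo1 <- loo_evaluate(tab, features = c("M001", "M002"))
  loo2 <- loo_evaluate(subset_subjects(tab, perm),
                       features = c("M001", "M002"))
  ord <- match(tab$subject_id, tab$subject_id[perm])
  expect_identical(loo2$records$predicted[ord], loo1$records$predicted)
  expect_equal(loo1$accuracy, loo2$accuracy)
})

test_that("class means recover generator means as n grows", {
  cfg <- synthetic_config(n_per_group = c(1000, 1000, 1000),
                          n_metabolites = 5,
                          class_names = c("A", "B", "C"),
                          markers = list(list(index = 1,
                                              shift = c(1, 2, 0.5))),
                          noise_sigma = 0.5, seed = 31)
  tab <- generate_cohort(cfg)
  m <- fit_lda(tab)
  base <- with_seed_mu(cfg)
  # expected class mean of metabolite j: exp(mu_j + log shift + sigma^2/2)
  rel <- sapply(1:3, function(k) {
    sh <- c(log(cfg$markers[[1]]$shift[k]), 0, 0, 0, 0)
    expected <- exp(base + sh + cfg$noise_sigma^2 / 2)
    abs(m$means[k, ] - expected) / expected
  })
  expect_lt(mean(rel), 0.02)
  expect_lt(max(rel), 0.1)
})

test_that("singular designs fall back to a recorded ridge", {
  set.seed(2)
  x <- runif(20, 1, 2)
  X <- cbind(a = x, b = 2 * x)         # exactly collinear
  g <- rep(c("A", "B"), 10)
  m <- fit_lda(X, groups = g)
  expect_gt(m$ridge_used, 0)
  p <- classify(m, X)
  expect_equal(rowSums(as.matrix(p[, c("A", "B")])), rep(1, 20),
               tolerance = 1e-9)
})

test_that("models survive a JSON round-trip exactly", {
  tab <- generate_cohort(two_marker_config(14))
  m <- fit_lda(tab, features = c("M001", "M002", "M003"))
  f <- withr::local_tempfile(fileext = ".json")
  write_lda_json(m, f)
  m2 <- read_lda_json(f)
  x <- tab$concentrations[5, 1:3]
  expect_identical(m2$class_names, m$class_names)
  expect_equal(m2$means, m$means)
  expect_equal(as.matrix(classify(m2, x)[, m$class_names]),
               as.matrix(classify(m, x)[, m$class_names]),
               tolerance = 1e-12)
})
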