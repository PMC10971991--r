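test_that("a perfect three-class stratification scores 100% everywhere", {
  real <- rep(c("Control", "Glaucoma", "Diabetes"), c(31, 8, 7))
  rep_ <- classification_report(real, real,
                                class_order = c("Control", "Glaucoma",
                                                "Diabetes"))
  expect_equal(unname(diag(rep_$confusion)), c(31, 8, 7))
  expect_equal(sum(rep_$confusion) - sum(diag(rep_$confusion)), 0)
  expect_equal(rep_$overall_accuracy, 1)
  expect_true(all(as.matrix(rep_$per_class) == 1))
  expect_equal(unname(rep_$macro), rep(1, 4))
})

test_that("a single misclassified control shifts the metrics as expected", {
  real <- rep(c("Control", "Glaucoma", "Diabetes"), c(20, 8, 7))
  pred <- real
  pred[1] <- "Diabetes"   # one control called diabetes
  rep_ <- classification_report(real, pred,
                                class_order = unique(real))
  expect_equal(sum(rep_$confusion) - sum(diag(rep_$confusion)), 1)
  expect_equal(rep_$confusion["Control", "Diabetes"], 1)
  expect_equal(rep_$overall_accuracy, 34 / 35)
  expect_equal(rep_$per_class["Control", "sensitivity"], 19 / 20)
  expect_equal(rep_$per_class["Diabetes", "ppv"], 7 / 8)
  # row sums conserve the real class sizes
  expect_equal(unname(rowSums(rep_$confusion)), c(20, 8, 7))
})

test_that("a reversed two-class assignment scores zero", {
  real <- rep(c("A", "B"), each = 4)
  pred <- rep(c("B", "A"), each = 4)
  rep_ <- classification_report(real, pred)
  expect_equal(rep_$overall_accuracy, 0)
  expect_equal(rep_$per_class$sensitivity, c(0, 0))
})

test_that("0/0 metric cells surface as flagged NaN, not silent zeros", {
  # class C never occurs and is never predicted: its sensitivity and PPV
  # are undefined
  rep_ <- classification_report(c("A", "A", "B", "B"),
                                c("A", "A", "B", "B"),
                                class_order = c("A", "B", "C"))
  expect_true(is.nan(rep_$per_class["C", "sensitivity"]))
  expect_true(is.nan(rep_$per_class["C", "ppv"]))
  expect_true(rep_$undefined["C", "sensitivity"])
  # macro averages skip undefined cells instead of counting them as 0
  expect_equal(unname(rep_$macro["sensitivity"]), 1)
  expect_error(classification_report(c("A"), c("A", "B")), "length")
  expect_error(classification_report("A", "Z", class_order = "A"),
               "unknown")
})

test_that("posterior tables conserve records and apply a strict 0.5 rule", {
  tab <- generate_cohort(two_marker_config(15))
  loo <- loo_evaluate(tab, features = c("M001", "M002"))
  pt <- posterior_table(loo$records, as.character(tab$group))
  expect_equal(pt$n, n_subjects(tab))
  expect_equal(pt$n_true_posterior_gt_half +
                 sum(pt$table$true_posterior <= 0.5), pt$n)
  expect_equal(rowSums(as.matrix(pt$table[, levels(tab$group)])),
               rep(1, pt$n), tolerance = 1e-9)
  # a posterior of exactly 0.5 does not count as exceeding
  rec <- loo$records[1, ]
  rec[, levels(tab$group)] <- c(0.5, 0.5, 0)
  pt2 <- posterior_table(rec, levels(tab$group)[1])
  expect_equal(pt2$n_true_posterior_gt_half, 0)
})

test_that("pearson correlation handles exact and degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  # orthogonal zero-mean construction
  a <- c(-1, 1, -1, 1)
  b <- c(-1, -1, 1, 1)
  expect_equal(pearson_cor(a, b)$r, 0)
  expect_error(pearson_cor(x, rep(3, 5)), "variance")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("pearson matches the reference implementation to 1e-10", {
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    x <- rnorm(n)
    y <- rnorm(n) + 0.3 * x
    mine <- pearson_cor(x, y)
    ref <- cor.test(x, y)
    expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("correlation matrices have the pairwise layout", {
  tab <- generate_cohort(two_marker_config(20, n_metabolites = 6))
  cm4 <- correlation_matrix(tab, features = paste0("M00", 1:4))
  expect_equal(nrow(cm4$pairs), choose(4, 2))
  cm6 <- correlation_matrix(tab)
  expect_equal(nrow(cm6$pairs), choose(6, 2))
  expect_equal(cm6$r, t(cm6$r))
  # identical features correlate perfectly
  X <- cbind(a = tab$concentrations[, 1], b = tab$concentrations[, 1])
  expect_equal(correlation_matrix(X)$pairs$r, 1)
  expect_error(correlation_matrix(tab, features = "M001"), "at least 2")
})

test_that("one-way ANOVA reduces to t^2 and matches the reference", {
  set.seed(5)
  # two-group identity F = t^2
  x <- rnorm(20)
  g <- rep(c("A", "B"), 10)
  mine <- anova_oneway(x, g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(mine$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(mine$p, tt$p.value, tolerance = 1e-10)
  # identical groups: F exactly 0
  y <- rep(c(1, 2, 3), 2)
  expect_lte(anova_oneway(y, rep(c("A", "B"), each = 3))$F, 1e-20)
  # reference equivalence on random 3-group instances
  for (i in 1:1000) {
    n <- sample(c(3, 4, 5, 8), 3, replace = TRUE)
    v <- rnorm(sum(n), mean = rep(rnorm(3), n))
    gg <- factor(rep(c("a", "b", "c"), n))
    m <- anova_oneway(v, gg)
    ref <- anova(lm(v ~ gg))
    expect_equal(m$F, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(m$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(m$df_between, ref$Df[1])
    expect_equal(m$df_within, ref$Df[2])
  }
})

test_that("group summaries follow the linear-interpolation quartiles", {
  X <- matrix(c(1:5, rep(7, 5)), 5, 2,
              dimnames = list(NULL, c("v", "const")))
  tab <- sample_table(rbind(X, X), rep(c("g1", "g2"), each = 5))
  s <- summarize_by_group(tab)
  v1 <- s[s$group == "g1" & s$feature == "v", ]
  expect_equal(c(v1$min, v1$q1, v1$median, v1$q3, v1$max),
               c(1, 2, 3, 4, 5))
  cst <- s[s$group == "g1" & s$feature == "const", ]
  expect_true(all(c(cst$min, cst$q1, cst$median, cst$q3, cst$max) == 7))
  # monotone invariant
  expect_true(all(s$min <= s$q1 & s$q1 <= s$median &
                    s$median <= s$q3 & s$q3 <= s$max))
})

test_that("planted shifts order the group medians accordingly", {
  tab <- generate_cohort(synthetic_config(
    n_per_group = c(40, 40, 40), n_metabolites = 2,
    class_names = c("low", "mid", "high"),
    markers = list(list(index = 1, shift = c(1, 3, 9))),
    noise_sigma = 0.3, seed = 23))
  s <- summarize_by_group(tab, features = "M001")
  med <- s$median[match(c("low", "mid", "high"), s$group)]
  expect_true(all(diff(med) > 0))
})
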