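#' Confusion matrix and multi-class classification report
#'
#' Builds the K x K confusion matrix (rows = real class, columns = predicted
#' class; the orientation is also stated in the printed header) and derives
#' overall accuracy plus one-vs-rest sensitivity, specificity, positive and
#' negative predictive value per class, with macro-averages.
#'
#' One-vs-rest definitions per class k: sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), PPV = TP/(TP+FP), NPV = TN/(TN+FN). A 0/0
#' ratio (for example PPV of a class never predicted) is reported as `NaN`
#' and flagged in `undefined`; macro-averages are taken over defined values
#' only, never treating an undefined cell as zero.
#'
#' @param real true class labels.
#' @param predicted predicted class labels, same length.
#' @param class_order class order used for rows/columns; defaults to order
#'   of first appearance in `real`.
#' @return object of class `classification_report`: `confusion`,
#'   `overall_accuracy`, `per_class` (data frame of the four metrics),
#'   `undefined` (logical matrix), `macro` (named numeric), `n`.
#' @examples
#' r <- classification_report(rep(c("A", "B"), c(3, 2)),
#'                            c("A", "A", "A", "B", "B"))
#' r$overall_accuracy
#' @export
classification_report <- function(real, predicted, class_order = NULL) {
  real <- as.character(real)
  predicted <- as.character(predicted)
  if (length(real) != length(predicted))
    stop("real and predicted must have the same length", call. = FALSE)
  if (is.null(class_order)) class_order <- unique(real)
  bad <- setdiff(unique(c(real, predicted)), class_order)
  if (length(bad))
    stop("unknown class label '", bad[1], "'", call. = FALSE)
  fr <- factor(real, levels = class_order)
  fp <- factor(predicted, levels = class_order)
  cm <- table(real = fr, predicted = fp)
  cm <- matrix(as.integer(cm), nrow(cm), ncol(cm), dimnames = dimnames(cm))
  n <- length(real)
  K <- length(class_order)
  metrics <- matrix(NA_real_, K, 4,
                    dimnames = list(class_order,
                                    c("sensitivity", "specificity",
                                      "ppv", "npv")))
  undef <- matrix(FALSE, K, 4, dimnames = dimnames(metrics))
  for (k in seq_len(K)) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp_ <- sum(cm[, k]) - tp
    tn <- n - tp - fn - fp_
    ratios <- c(sensitivity = tp / (tp + fn),
                specificity = tn / (tn + fp_),
                ppv = tp / (tp + fp_),
                npv = tn / (tn + fn))
    metrics[k, ] <- ratios
    undef[k, ] <- is.nan(ratios)
  }
  macro <- apply(metrics, 2, function(v) mean(v[!is.nan(v)]))
  structure(list(confusion = cm,
                 overall_accuracy = sum(diag(cm)) / n,
                 per_class = as.data.frame(metrics),
                 undefined = undef,
                 macro = macro, n = n,
                 class_order = class_order),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Confusion matrix (rows = real class, columns = predicted class):\n")
  print(x$confusion)
  cat(sprintf("Overall accuracy: %.4f (n = %d)\n", x$overall_accuracy, x$n))
  print(round(x$per_class, 4))
  if (any(x$undefined))
    cat("note: NaN marks undefined (0/0) metrics; excluded from macro",
        "averages\n")
  cat("Macro:",
      paste(sprintf("%s=%.4f", names(x$macro), x$macro), collapse = " "),
      "\n")
  invisible(x)
}

#' Per-subject posterior table and threshold summary
#'
#' Lists every subject's posterior class probabilities and predicted class
#' from a leave-one-out evaluation, together with a count of subjects whose
#' posterior for their *true* class strictly exceeds 0.5 (a posterior of
#' exactly 0.5 does not count as exceeding).
#'
#' @param records a `posterior_record` data frame (from [loo_evaluate()] or
#'   [classify()]).
#' @param truth true class label per record.
#' @return list of class `posterior_table`: `table` (records with `true`
#'   column appended), `n`, `n_true_posterior_gt_half`.
#' @export
posterior_table <- function(records, truth) {
  stopifnot(inherits(records, "posterior_record"))
  truth <- as.character(truth)
  if (length(truth) != nrow(records))
    stop("truth must have one label per record", call. = FALSE)
  cls <- setdiff(names(records), c("subject_id", "predicted", "held_out"))
  if (!all(truth %in% cls))
    stop("unknown true class label '", setdiff(truth, cls)[1], "'",
         call. = FALSE)
  ptrue <- vapply(seq_len(nrow(records)),
                  function(i) records[[truth[i]]][i], numeric(1))
  tab <- cbind(as.data.frame(records), true = truth,
               true_posterior = ptrue)
  structure(list(table = tab, n = nrow(tab),
                 n_true_posterior_gt_half = sum(ptrue > 0.5)),
            class = "posterior_table")
}

#' @export
print.posterior_table <- function(x, ...) {
  cat("Posterior table:", x$n, "subjects;",
      x$n_true_posterior_gt_half, "with true-class posterior > 0.5\n")
  print(utils::head(x$table, 10))
  if (x$n > 10) cat("...\n")
  invisible(x)
}

#' Pearson correlation with two-sided t-test
#'
#' Product-moment correlation coefficient with the classical t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom,
#' two-sided, uncorrected for multiple testing.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list of class `correlation_result`: `r`, `p`, `n`, `df`, `t`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in input", call. = FALSE)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sqrt(sum(xc^2))
  sy <- sqrt(sum(yc^2))
  if (sx == 0) stop("x has zero variance", call. = FALSE)
  if (sy == 0) stop("y has zero variance", call. = FALSE)
  r <- sum(xc * yc) / (sx * sy)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    t <- Inf * sign(r)
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  structure(list(r = r, p = p, n = n, df = n - 2, t = t),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d, p = %.3g)\n", x$r, x$n, x$p))
  invisible(x)
}

#' Pairwise Pearson correlation matrix
#'
#' All pairwise correlations among the selected feature columns, in the
#' upper-triangular layout used to report metabolite and term-variable
#' correlation tables.
#'
#' @param x a [sample_table()] or numeric matrix.
#' @param features columns to correlate (default all; at least 2).
#' @return list of class `correlation_matrix`: `features`, `r` and `p`
#'   (full symmetric matrices, diagonal `NA`), `pairs` (data frame with
#'   one row per unordered pair: `a`, `b`, `r`, `p`, `n`).
#' @export
correlation_matrix <- function(x, features = NULL) {
  X <- if (inherits(x, "sample_table")) x$concentrations else as.matrix(x)
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  m <- ncol(X)
  if (m < 2) stop("need at least 2 features", call. = FALSE)
  nm <- colnames(X)
  R <- P <- matrix(NA_real_, m, m, dimnames = list(nm, nm))
  pairs <- NULL
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      cr <- pearson_cor(X[, i], X[, j])
      R[i, j] <- R[j, i] <- cr$r
      P[i, j] <- P[j, i] <- cr$p
      pairs <- rbind(pairs,
                     data.frame(a = nm[i], b = nm[j], r = cr$r, p = cr$p,
                                n = cr$n, stringsAsFactors = FALSE))
    }
  }
  structure(list(features = nm, r = R, p = P, pairs = pairs),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("Pairwise Pearson correlations (", length(x$features), " features, ",
      nrow(x$pairs), " pairs):\n", sep = "")
  ut <- x$r
  ut[lower.tri(ut, diag = TRUE)] <- NA
  print(round(ut, 4), na.print = "")
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects decomposition: `F = MS_between / MS_within` with
#' `K - 1` and `n - K` degrees of freedom. Used here to test for group
#' differences in age before deciding whether an age-filtered reanalysis is
#' warranted.
#'
#' @param values numeric response, one per subject.
#' @param groups class label per subject (>= 2 groups, each with >= 2
#'   values).
#' @return list of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p`, `ms_between`, `ms_within`.
#' @export
anova_oneway <- function(values, groups) {
  grp <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  if (length(values) != length(grp))
    stop("values and groups lengths differ", call. = FALSE)
  K <- nlevels(grp)
  n <- length(values)
  if (K < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(tabulate(grp) < 2))
    stop("every group needs at least 2 values", call. = FALSE)
  gm <- tapply(values, grp, mean)
  gn <- tabulate(grp)
  grand <- mean(values)
  ssb <- sum(gn * (gm - grand)^2)
  ssw <- sum((values - gm[as.integer(grp)])^2)
  dfb <- K - 1
  dfw <- n - K
  msb <- ssb / dfb
  msw <- ssw / dfw
  f <- msb / msw
  structure(list(F = f, df_between = dfb, df_within = dfw,
                 p = stats::pf(f, dfb, dfw, lower.tail = FALSE),
                 ms_between = msb, ms_within = msw),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Group-wise descriptive summaries
#'
#' Five-number summary (minimum, lower quartile, median, upper quartile,
#' maximum) plus mean and SD for each selected feature within each class --
#' the numbers behind per-group boxplots. Quartiles use linear interpolation
#' (the type-7 convention, R's default).
#'
#' @param x a [sample_table()] or numeric matrix.
#' @param features columns to summarize (default all).
#' @param groups class labels (taken from the table when `x` is one).
#' @return data frame of class `group_summary`: one row per class x
#'   feature with columns `group`, `feature`, `n`, `min`, `q1`, `median`,
#'   `q3`, `max`, `mean`, `sd`.
#' @export
summarize_by_group <- function(x, features = NULL, groups = NULL) {
  if (inherits(x, "sample_table")) {
    groups <- x$group
    X <- x$concentrations
  } else {
    X <- as.matrix(x)
    if (is.null(groups)) stop("groups required for matrix input",
                              call. = FALSE)
  }
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  grp <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  out <- NULL
  for (k in levels(grp)) {
    rows <- grp == k
    for (j in colnames(X)) {
      v <- X[rows, j]
      q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7,
                           names = FALSE)
      out <- rbind(out, data.frame(
        group = k, feature = j, n = length(v),
        min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
        mean = mean(v), sd = stats::sd(v), stringsAsFactors = FALSE))
    }
  }
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Filter a cohort by age within one class
#'
#' Removes subjects of the restricted class(es) whose age falls below a
#' threshold (or whose id is explicitly listed); subjects of other classes
#' are never touched. Used to rerun an analysis after excluding younger
#' members of an over-represented control group.
#'
#' @param tab a [sample_table()] with ages for the affected subjects.
#' @param min_age keep only subjects with `age >= min_age` (within
#'   `classes`). Exactly one of `min_age`/`exclude_ids` must be given.
#' @param exclude_ids explicit subject ids to drop (within `classes`).
#' @param classes class label(s) whose members may be removed; default the
#'   first class in the table's class order.
#' @return a filtered `sample_table`; errors if any class would fall below
#'   2 subjects.
#' @export
age_filter <- function(tab, min_age = NULL, exclude_ids = NULL,
                       classes = levels(tab$group)[1]) {
  validate_sample_table(tab)
  if (is.null(min_age) == is.null(exclude_ids))
    stop("give exactly one of min_age or exclude_ids", call. = FALSE)
  candidate <- tab$group %in% classes
  if (!is.null(min_age)) {
    if (is.null(tab$age))
      stop("table has no age column", call. = FALSE)
    if (anyNA(tab$age[candidate]))
      stop("age missing for a subject in the restricted class",
           call. = FALSE)
    drop <- candidate & tab$age < min_age
  } else {
    drop <- candidate & tab$subject_id %in% exclude_ids
  }
  keep <- !drop
  cnt <- table(tab$group[keep])
  if (any(cnt < 2))
    stop("age filter would leave class '", names(cnt)[cnt < 2][1],
         "' with fewer than 2 subjects", call. = FALSE)
  subset_subjects(tab, keep)
}
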