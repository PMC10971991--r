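#' Fit a multi-class linear discriminant model
#'
#' Gaussian classifier with class-specific mean vectors and a shared
#' (pooled within-class) covariance matrix, the classical setting in which
#' classification by maximum posterior coincides with assignment to the
#' Mahalanobis-nearest class centroid under equal priors.
#'
#' The pooled covariance is \eqn{S = \sum_k (n_k - 1) S_k / (n - K)}. If
#' `S` is numerically singular (as can happen when monomial term columns
#' are nearly collinear at small n), a ridge `eps * tr(S)/p` is added to
#' the diagonal, with `eps` starting at 1e-8 and escalating tenfold up to
#' 1e-2 until the Cholesky factorization succeeds; the ridge actually used
#' is recorded in the model (`ridge_used`, 0 when none was needed).
#'
#' Discriminant axes (LD1, LD2, ...) are the eigenvectors of the
#' within-inverse times between-scatter problem, computed via the
#' symmetric whitened form; there are `min(K - 1, p)` of them, ordered by
#' decreasing between/within eigenvalue, normalized so that each axis has
#' unit pooled within-class variance, with sign fixed so the
#' largest-magnitude loading is positive.
#'
#' Features enter on their raw concentration scale (no standardization):
#' discriminant loadings then apply directly to concentrations and their
#' products, which is how the reported discriminant equations in this
#' field are written.
#'
#' @param x a [sample_table()], or a numeric matrix of feature columns.
#' @param features metabolite names or column indices to use (default all
#'   columns). Ignored when `x` is a plain matrix and `NULL`.
#' @param groups class labels, required when `x` is a matrix; taken from
#'   the table otherwise.
#' @param priors `"proportional"` (class sample shares, the default) or
#'   `"equal"`.
#' @return an object of class `lda_model`: list with `class_names`,
#'   `counts`, `priors`, `priors_mode`, `means` (K x p), `pooled_cov`,
#'   `axes` (p x r loadings), `svd` (between/within eigenvalues),
#'   `ridge_used`, `features`.
#' @examples
#' tab <- generate_cohort(synthetic_config(
#'   n_per_group = c(10, 10), n_metabolites = 3, class_names = c("A", "B"),
#'   markers = list(list(index = 1, shift = c(1, 8))),
#'   noise_sigma = 0.2, seed = 1))
#' fit_lda(tab, features = "M001")
#' @export
fit_lda <- function(x, features = NULL, groups = NULL,
                    priors = c("proportional", "equal")) {
  priors <- match.arg(priors)
  if (inherits(x, "sample_table")) {
    validate_sample_table(x)
    groups <- x$group
    X <- x$concentrations
    if (!is.null(features)) X <- X[, features, drop = FALSE]
  } else {
    X <- as.matrix(x)
    if (is.null(groups)) stop("groups required when x is a matrix",
                              call. = FALSE)
    if (!is.null(features)) X <- X[, features, drop = FALSE]
  }
  if (ncol(X) == 0) stop("features: empty feature set", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  grp <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  core <- lda_core(X, grp, priors)
  axes <- lda_axes(core)
  structure(c(core, axes, list(features = colnames(X))), class = "lda_model")
}

# Means, pooled covariance, Cholesky factor and priors -- the part needed on
# every leave-one-out fold; kept free of the eigen decomposition for speed.
lda_core <- function(X, grp, priors_mode) {
  cls <- levels(grp)
  K <- length(cls)
  n <- nrow(X)
  p <- ncol(X)
  counts <- tabulate(grp, K)
  if (any(counts < 2))
    stop("class '", cls[which(counts < 2)[1]],
         "' has fewer than 2 subjects; cannot estimate covariance",
         call. = FALSE)
  cv <- apply(X, 2, function(col) stats::var(col))
  if (any(cv == 0))
    stop("feature '", colnames(X)[which(cv == 0)[1]],
         "' is constant across all subjects", call. = FALSE)
  gi <- as.integer(grp)
  means <- matrix(0, K, p, dimnames = list(cls, colnames(X)))
  W <- matrix(0, p, p)
  for (k in seq_len(K)) {
    rows <- gi == k
    Xk <- X[rows, , drop = FALSE]
    mk <- colMeans(Xk)
    means[k, ] <- mk
    Xc <- sweep(Xk, 2, mk)
    W <- W + crossprod(Xc)
  }
  S <- W / (n - K)
  dimnames(S) <- list(colnames(X), colnames(X))
  # a Cholesky pivot collapsing relative to the largest marks numerical
  # singularity (chol() itself can succeed on exactly rank-deficient input)
  safe_chol <- function(M) {
    U <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(U)) return(NULL)
    d2 <- diag(U)^2
    if (any(d2 < max(d2) * 1e-12)) return(NULL)
    U
  }
  ridge <- 0
  U <- safe_chol(S)
  if (is.null(U)) {
    scale <- sum(diag(S)) / p
    eps <- 1e-8
    while (is.null(U) && eps <= 1e-2) {
      Sr <- S + diag(eps * scale, p)
      U <- safe_chol(Sr)
      if (!is.null(U)) {
        ridge <- eps * scale
        S <- Sr
      } else eps <- eps * 10
    }
    if (is.null(U))
      stop("pooled covariance singular even after maximal ridge",
           call. = FALSE)
  }
  pri <- if (priors_mode == "equal") rep(1 / K, K) else counts / n
  names(pri) <- cls
  list(class_names = cls, counts = stats::setNames(counts, cls),
       priors = pri, priors_mode = priors_mode, means = means,
       pooled_cov = S, chol = U, ridge_used = ridge)
}

# Discriminant axes from the whitened between-scatter eigenproblem.
lda_axes <- function(core) {
  S <- core$pooled_cov
  p <- ncol(S)
  K <- length(core$class_names)
  r <- min(K - 1, p)
  es <- eigen(S, symmetric = TRUE)
  d <- pmax(es$values, max(es$values) * 1e-14)
  Sinv_half <- es$vectors %*% (t(es$vectors) / sqrt(d))
  mbar <- colSums(core$means * core$counts) / sum(core$counts)
  Mc <- sweep(core$means, 2, mbar)
  B <- crossprod(Mc * core$counts, Mc) / max(K - 1, 1)
  Mw <- Sinv_half %*% B %*% Sinv_half
  ew <- eigen((Mw + t(Mw)) / 2, symmetric = TRUE)
  A <- Sinv_half %*% ew$vectors[, seq_len(r), drop = FALSE]
  for (j in seq_len(r)) {           # sign: largest-magnitude loading positive
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) A[, j] <- -A[, j]
  }
  dimnames(A) <- list(colnames(S), paste0("LD", seq_len(r)))
  list(axes = A, svd = ew$values[seq_len(r)])
}

#' @export
print.lda_model <- function(x, ...) {
  cat("lda_model:", length(x$class_names), "classes,",
      length(x$features), "features,", ncol(x$axes), "discriminant axes\n")
  cat("  priors (", x$priors_mode, "): ",
      paste(sprintf("%s=%.3f", x$class_names, x$priors), collapse = ", "),
      "\n", sep = "")
  if (x$ridge_used > 0)
    cat("  ridge added to pooled covariance:", format(x$ridge_used), "\n")
  invisible(x)
}

# Squared Mahalanobis distances (n x K) of rows of X to each class mean
# under the pooled covariance, via the stored Cholesky factor.
mahal_sq <- function(core, X) {
  K <- length(core$class_names)
  D <- matrix(0, nrow(X), K, dimnames = list(NULL, core$class_names))
  for (k in seq_len(K)) {
    df <- sweep(X, 2, core$means[k, ])
    z <- backsolve(core$chol, t(df), transpose = TRUE)
    D[, k] <- colSums(z^2)
  }
  D
}

# Posterior matrix (n x K) from distances and priors, via log-sum-exp.
posterior_from_dist <- function(core, D) {
  lp <- sweep(-D / 2, 2, log(core$priors), "+")
  m <- apply(lp, 1, max)
  P <- exp(lp - m)
  P / rowSums(P)
}

#' Classify observations with a fitted discriminant model
#'
#' Posterior class probabilities follow Bayes' rule for the shared-covariance
#' Gaussian model: posterior_k is proportional to
#' `prior_k * exp(-d_k^2 / 2)` with `d_k` the Mahalanobis distance to class
#' k's centroid under the pooled covariance. With equal priors the predicted
#' class is the Mahalanobis-nearest centroid. Exact posterior ties are broken
#' in favour of the first class in the model's declared class order.
#'
#' @param model an `lda_model`.
#' @param x numeric vector (one observation) or matrix (one row each) with
#'   `length(model$features)` feature values.
#' @param ids optional subject identifiers for the output.
#' @return a data frame of class `posterior_record`: one row per
#'   observation with `subject_id`, one posterior column per class,
#'   `predicted` and `held_out` (`FALSE` here).
#' @export
classify <- function(model, x, ids = NULL) {
  stopifnot(inherits(model, "lda_model"))
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != length(model$features))
    stop("x has ", ncol(X), " features; model expects ",
         length(model$features), call. = FALSE)
  if (any(!is.finite(X)))
    stop("non-finite feature values cannot be classified", call. = FALSE)
  D <- mahal_sq(model, X)
  P <- posterior_from_dist(model, D)
  pred <- model$class_names[apply(P, 1, which.max)]
  if (is.null(ids)) ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("obs%d", seq_len(nrow(X)))
  out <- data.frame(subject_id = ids, P, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$predicted <- pred
  out$held_out <- FALSE
  class(out) <- c("posterior_record", "data.frame")
  out
}

#' Leave-one-out evaluation of a discriminant model
#'
#' For each subject in turn the model is refit from scratch on the remaining
#' n - 1 subjects and the held-out subject is classified; the aggregated
#' held-out predictions form the classification report. This is the standard
#' guard against overfitting when the same small cohort must both select and
#' assess a panel. The result does not depend on subject order.
#'
#' @param x a [sample_table()] or a numeric feature/term design matrix.
#' @param features columns to use (table input) or `NULL` for all.
#' @param groups class labels (required for matrix input).
#' @param priors `"proportional"` or `"equal"`.
#' @param ids optional subject identifiers (matrix input).
#' @return a list of class `loo_result`: `report` (a
#'   [classification_report()]), `records` (held-out `posterior_record`
#'   rows), `priors_mode`, `ridge_events` (number of folds needing a
#'   ridge), `accuracy`.
#' @export
loo_evaluate <- function(x, features = NULL, groups = NULL,
                         priors = c("proportional", "equal"), ids = NULL) {
  priors <- match.arg(priors)
  if (inherits(x, "sample_table")) {
    validate_sample_table(x)
    groups <- x$group
    ids <- x$subject_id
    X <- x$concentrations
    if (!is.null(features)) X <- X[, features, drop = FALSE]
  } else {
    X <- as.matrix(x)
    if (is.null(groups)) stop("groups required when x is a matrix",
                              call. = FALSE)
    if (!is.null(features)) X <- X[, features, drop = FALSE]
    if (is.null(ids)) ids <- rownames(X)
    if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(X)))
  }
  grp <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  cnt <- tabulate(grp, nlevels(grp))
  if (any(cnt < 3))
    stop("degenerate leave-one-out fold: class '",
         levels(grp)[which(cnt < 3)[1]],
         "' has only ", min(cnt), " subjects, leaving fewer than 2 when one",
         " is held out", call. = FALSE)
  n <- nrow(X)
  K <- nlevels(grp)
  P <- matrix(0, n, K, dimnames = list(NULL, levels(grp)))
  pred <- character(n)
  ridge_events <- 0L
  for (i in seq_len(n)) {
    core <- lda_core(X[-i, , drop = FALSE], grp[-i], priors)
    if (core$ridge_used > 0) ridge_events <- ridge_events + 1L
    D <- mahal_sq(core, X[i, , drop = FALSE])
    P[i, ] <- posterior_from_dist(core, D)
    pred[i] <- core$class_names[which.max(P[i, ])]
  }
  records <- data.frame(subject_id = ids, P, check.names = FALSE,
                        stringsAsFactors = FALSE)
  records$predicted <- pred
  records$held_out <- TRUE
  class(records) <- c("posterior_record", "data.frame")
  report <- classification_report(as.character(grp), pred,
                                  class_order = levels(grp))
  report$priors_mode <- priors
  structure(list(report = report, records = records, priors_mode = priors,
                 ridge_events = ridge_events,
                 accuracy = report$overall_accuracy),
            class = "loo_result")
}

# Fast internal LOO accuracy used by the subset searches: identical folds
# and tie-breaking to loo_evaluate, without building report objects.
loo_accuracy <- function(X, grp, priors_mode) {
  n <- nrow(X)
  hits <- 0L
  for (i in seq_len(n)) {
    core <- lda_core(X[-i, , drop = FALSE], grp[-i], priors_mode)
    D <- mahal_sq(core, X[i, , drop = FALSE])
    P <- posterior_from_dist(core, D)
    if (core$class_names[which.max(P)] == as.character(grp[i]))
      hits <- hits + 1L
  }
  hits / n
}

#' @export
print.loo_result <- function(x, ...) {
  cat("Leave-one-out evaluation (priors:", x$priors_mode, ")\n")
  cat("  accuracy:", sprintf("%.4f", x$accuracy), "\n")
  if (x$ridge_events > 0)
    cat("  folds needing covariance ridge:", x$ridge_events, "\n")
  print(x$report)
  invisible(x)
}

#' Serialize / reload a discriminant model as JSON
#'
#' Stores class names, counts, priors, means, pooled covariance, axes and
#' ridge at full double precision, sufficient to reconstruct the model
#' exactly.
#'
#' @param model an `lda_model`.
#' @param path output (input) file path.
#' @return `write_lda_json`: `path` invisibly. `read_lda_json`: the
#'   reconstructed `lda_model`.
#' @export
write_lda_json <- function(model, path) {
  stopifnot(inherits(model, "lda_model"))
  obj <- list(class_names = model$class_names,
              counts = unname(model$counts),
              priors = unname(model$priors),
              priors_mode = model$priors_mode,
              features = model$features,
              means = model$means,
              pooled_cov = model$pooled_cov,
              axes = model$axes,
              svd = model$svd,
              ridge_used = model$ridge_used)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_lda_json
#' @export
read_lda_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$class_names
  means <- as.matrix(obj$means)
  dimnames(means) <- list(cls, obj$features)
  S <- as.matrix(obj$pooled_cov)
  dimnames(S) <- list(obj$features, obj$features)
  A <- as.matrix(obj$axes)
  dimnames(A) <- list(obj$features, paste0("LD", seq_len(ncol(A))))
  structure(list(class_names = cls,
                 counts = stats::setNames(as.integer(obj$counts), cls),
                 priors = stats::setNames(obj$priors, cls),
                 priors_mode = obj$priors_mode,
                 means = means, pooled_cov = S, chol = chol(S),
                 ridge_used = obj$ridge_used, axes = A, svd = obj$svd,
                 features = obj$features),
            class = "lda_model")
}
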