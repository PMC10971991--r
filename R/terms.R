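#' Monomial term universe over a selected metabolite panel
#'
#' Enumerates every monomial of total degree 1..`max_degree` over the
#' given metabolites: the linear, quadratic and cubic powers plus all
#' double and triple interaction products. For m metabolites and maximum
#' degree d there are `choose(m + d, d) - 1` such terms.
#'
#' Terms are returned in a deterministic canonical order: ascending total
#' degree, then descending lexicographic order of the exponent vector
#' (earlier metabolites more significant), so pure powers of the first
#' metabolite come first within a degree. Labels use the field's notation:
#' `^` for powers and `*` for products, factors in the order the
#' metabolites were supplied (for example `C3^2*Ac-Orn`).
#'
#' @param metabolites character vector of unique metabolite names.
#' @param max_degree maximum total degree, between 1 and 3.
#' @return object of class `term_set`: list with `metabolites`,
#'   `exponents` (terms x metabolites integer matrix, rownames = labels)
#'   and `labels`.
#' @examples
#' expand_terms(c("C3", "Ac-Orn"), max_degree = 2)$labels
#' @export
expand_terms <- function(metabolites, max_degree = 3) {
  metabolites <- as.character(metabolites)
  if (anyDuplicated(metabolites))
    stop("duplicate metabolite name '",
         metabolites[duplicated(metabolites)][1], "'", call. = FALSE)
  if (max_degree < 1 || max_degree > 3)
    stop("max_degree must be 1, 2 or 3", call. = FALSE)
  m <- length(metabolites)
  rows <- list()
  for (deg in seq_len(max_degree))
    rows <- c(rows, compositions_desc(m, deg))
  E <- do.call(rbind, rows)
  colnames(E) <- metabolites
  labels <- apply(E, 1, term_label, metabolites = metabolites)
  rownames(E) <- labels
  structure(list(metabolites = metabolites, exponents = E, labels = labels),
            class = "term_set")
}

# All vectors of m non-negative integers summing to deg, in descending
# lexicographic order (earlier positions more significant).
compositions_desc <- function(m, deg) {
  if (m == 1) return(list(matrix(deg, 1, 1)))
  out <- list()
  for (e1 in deg:0) {
    rest <- compositions_desc(m - 1, deg - e1)
    for (r in rest)
      out[[length(out) + 1L]] <- cbind(e1, r, deparse.level = 0)
  }
  out
}

term_label <- function(e, metabolites) {
  parts <- character(0)
  for (j in seq_along(e)) {
    if (e[j] == 1) parts <- c(parts, metabolites[j])
    else if (e[j] > 1) parts <- c(parts, paste0(metabolites[j], "^", e[j]))
  }
  paste(parts, collapse = "*")
}

#' @export
print.term_set <- function(x, ...) {
  cat("term_set:", length(x$labels), "monomials over",
      length(x$metabolites), "metabolites\n")
  cat("  ", paste(utils::head(x$labels, 12), collapse = ", "),
      if (length(x$labels) > 12) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Evaluate monomial terms on a cohort
#'
#' Builds the term-feature design matrix: one column per monomial, each
#' value the product of the subject's raw concentrations raised to the
#' term's exponents. No centering or standardization is applied, so
#' discriminant loadings on these columns read directly as coefficients on
#' concentration products.
#'
#' @param tab a [sample_table()] (or numeric matrix with named columns).
#' @param terms a `term_set` from [expand_terms()], or a subset of one.
#' @return numeric matrix, rows = subjects, columns = terms (canonical
#'   labels).
#' @export
build_design <- function(tab, terms) {
  stopifnot(inherits(terms, "term_set"))
  X <- if (inherits(tab, "sample_table")) tab$concentrations else
    as.matrix(tab)
  missing <- setdiff(terms$metabolites, colnames(X))
  if (length(missing))
    stop("metabolite '", missing[1], "' not found in table", call. = FALSE)
  Xm <- X[, terms$metabolites, drop = FALSE]
  E <- terms$exponents
  D <- matrix(1, nrow(Xm), nrow(E),
              dimnames = list(rownames(X), rownames(E)))
  for (t in seq_len(nrow(E)))
    for (j in which(E[t, ] > 0))
      D[, t] <- D[, t] * Xm[, j]^E[t, j]
  D
}

#' Subset a term set
#' @param terms a `term_set`.
#' @param i integer index, logical vector or term labels.
#' @return a `term_set` restricted to the selected terms.
#' @export
subset_terms <- function(terms, i) {
  stopifnot(inherits(terms, "term_set"))
  E <- terms$exponents[i, , drop = FALSE]
  structure(list(metabolites = terms$metabolites, exponents = E,
                 labels = rownames(E)),
            class = "term_set")
}

#' Stage 2: best monomial-variable subset per size
#'
#' Applies the same best-subset search semantics as [stage1_search()]
#' (candidate order, tie-breaking, cumulative-best tracking, plateau rule,
#' determinism) to the monomial term columns built from a selected
#' metabolite panel, reporting the smallest variable set attaining the
#' maximum leave-one-out accuracy. This is the stage that can capture
#' class structure visible only in products of concentrations.
#'
#' @param tab a [sample_table()].
#' @param terms a `term_set` (typically [expand_terms()] over the stage-1
#'   winning panel).
#' @param max_vars largest variable-set size to consider.
#' @inheritParams stage1_search
#' @return a `search_result` whose feature names are canonical term
#'   labels.
#' @export
stage2_search <- function(tab, terms, max_vars = 8,
                          strategy = c("forward", "exhaustive", "beam"),
                          budget = 1e5, patience = 2, beam_width = 20,
                          priors = c("proportional", "equal")) {
  strategy <- match.arg(strategy)
  priors <- match.arg(priors)
  if (!length(terms$labels)) stop("terms: empty term set", call. = FALSE)
  if (max_vars > length(terms$labels))
    stop("max_vars exceeds the number of terms", call. = FALSE)
  D <- build_design(tab, terms)
  grp <- if (inherits(tab, "sample_table")) tab$group else
    stop("stage2_search needs a sample_table", call. = FALSE)
  search_subsets(D, grp, max_k = max_vars, strategy = strategy,
                 budget = budget, patience = patience,
                 beam_width = beam_width, priors = priors)
}
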