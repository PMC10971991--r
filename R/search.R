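# Shared best-subset machinery over an arbitrary feature design matrix.
# Used by stage1_search (raw metabolites) and stage2_search (monomial
# terms), so both stages obey identical semantics: deterministic candidate
# order, tie-breaking by (accuracy desc, smaller size, lexicographically
# smallest index set), cumulative-best tracking and plateau early stop.

# All k-subsets of 1..m in lexicographic order, as a list.
lex_subsets <- function(m, k) {
  if (k > m) return(list())
  cmb <- utils::combn(m, k)
  lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
}

search_subsets <- function(X, grp, max_k,
                           strategy = c("forward", "exhaustive", "beam"),
                           budget = 1e5, patience = 2, beam_width = 20,
                           priors = "proportional") {
  strategy <- match.arg(strategy)
  m <- ncol(X)
  if (max_k < 1 || max_k > m)
    stop("max_k must be between 1 and the number of features (", m, ")",
         call. = FALSE)
  nm <- colnames(X)
  evaluations <- 0L
  per_size <- list()
  best_cum_acc <- -Inf
  best_cum_feats <- integer(0)
  best_cum_k <- NA_integer_
  stale <- 0L
  prev_sets <- list(integer(0))   # subsets extended by forward/beam

  for (k in seq_len(max_k)) {
    if (strategy == "exhaustive") {
      planned <- choose(m, k)
      if (evaluations + planned > budget)
        stop("evaluation budget (", format(budget), ") exceeded at size k=",
             k, " (", format(planned), " subsets); use strategy='forward' ",
             "or 'beam', or raise the budget", call. = FALSE)
      cand <- lex_subsets(m, k)
    } else {
      ext <- list()
      for (s in prev_sets)
        for (j in setdiff(seq_len(m), s))
          ext[[length(ext) + 1L]] <- sort(c(s, j))
      key <- vapply(ext, function(s) paste(sprintf("%06d", s),
                                           collapse = ","), character(1))
      ext <- ext[!duplicated(key)]
      key <- key[!duplicated(key)]
      # lexicographic order on index sets keeps tie-breaking deterministic
      cand <- ext[order(key)]
      if (evaluations + length(cand) > budget)
        stop("evaluation budget (", format(budget), ") exceeded at size k=",
             k, "; raise the budget or reduce max_k", call. = FALSE)
    }
    if (!length(cand)) break
    acc <- vapply(cand, function(s)
      loo_accuracy(X[, s, drop = FALSE], grp, priors), numeric(1))
    evaluations <- evaluations + length(cand)
    best_i <- which.max(acc)        # first max = lexicographically smallest
    per_size[[k]] <- list(k = k, features = cand[[best_i]],
                          feature_names = nm[cand[[best_i]]],
                          accuracy = acc[best_i],
                          n_evaluated = length(cand))
    if (acc[best_i] > best_cum_acc) {
      best_cum_acc <- acc[best_i]
      best_cum_feats <- cand[[best_i]]
      best_cum_k <- k
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    per_size[[k]]$cumulative_best <- best_cum_acc
    if (strategy %in% c("forward", "beam")) {
      keep <- if (strategy == "forward") 1L else min(beam_width, length(cand))
      prev_sets <- cand[order(-acc)[seq_len(keep)]]
    }
    if (stale >= patience) break
  }

  report <- loo_evaluate(X[, best_cum_feats, drop = FALSE], groups = grp,
                         priors = priors)
  structure(list(per_size = per_size,
                 selected_size = best_cum_k,
                 selected_features = best_cum_feats,
                 selected_names = nm[best_cum_feats],
                 selected_report = report$report,
                 selected_accuracy = best_cum_acc,
                 strategy = strategy, evaluations = evaluations,
                 priors_mode = priors),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("Best-subset search (", x$strategy, "): ", x$evaluations,
      " leave-one-out evaluations\n", sep = "")
  for (s in x$per_size)
    cat(sprintf("  k=%d  acc=%.4f  cum=%.4f  {%s}\n", s$k, s$accuracy,
                s$cumulative_best, paste(s$feature_names, collapse = ", ")))
  cat(sprintf("selected: k=%d {%s}, accuracy %.4f\n", x$selected_size,
              paste(x$selected_names, collapse = ", "),
              x$selected_accuracy))
  invisible(x)
}

#' Stage 1: best metabolite subset per panel size
#'
#' For each panel size k = 1..`max_k`, finds the metabolite subset with
#' the highest leave-one-out classification accuracy, tracks the cumulative
#' best over sizes, and stops early once `patience` consecutive sizes bring
#' no improvement (the accuracy plateau). The selected panel is the
#' smallest size whose cumulative best accuracy equals the overall maximum.
#'
#' Strategies: `"exhaustive"` enumerates all `choose(M, k)` subsets in
#' lexicographic order (refusing to start a size that would exceed
#' `budget` evaluations); `"forward"` (default) grows the best subset of
#' the previous size by one feature at a time; `"beam"` extends the
#' `beam_width` best subsets of the previous size. All strategies are
#' deterministic; accuracy ties go to the lexicographically smallest index
#' set.
#'
#' @param tab a [sample_table()].
#' @param max_k largest panel size to consider.
#' @param strategy `"forward"`, `"exhaustive"` or `"beam"`.
#' @param budget maximum number of leave-one-out evaluations.
#' @param patience consecutive sizes without cumulative improvement before
#'   stopping (default 2).
#' @param beam_width beam strategy width (default 20).
#' @param priors `"proportional"` or `"equal"`.
#' @return object of class `search_result`: `per_size` (best subset and
#'   accuracy per size), `selected_size`, `selected_names`,
#'   `selected_report`, `evaluations`, `strategy`.
#' @export
stage1_search <- function(tab, max_k = 8,
                          strategy = c("forward", "exhaustive", "beam"),
                          budget = 1e5, patience = 2, beam_width = 20,
                          priors = c("proportional", "equal")) {
  validate_sample_table(tab)
  strategy <- match.arg(strategy)
  priors <- match.arg(priors)
  search_subsets(tab$concentrations, tab$group, max_k = max_k,
                 strategy = strategy, budget = budget, patience = patience,
                 beam_width = beam_width, priors = priors)
}

#' Rank every metabolite by single-feature discriminative power
#'
#' Runs a one-feature leave-one-out discriminant evaluation for each
#' metabolite and orders the results by accuracy (descending), breaking
#' ties by metabolite name (ascending), so the ranking is deterministic
#' even with duplicated columns.
#'
#' @param tab a [sample_table()].
#' @param priors `"proportional"` or `"equal"`.
#' @return object of class `feature_ranking`: data frame `ranking`
#'   (metabolite, accuracy) in rank order, plus `reports`, a named list of
#'   the per-metabolite [classification_report()]s.
#' @export
single_feature_ranking <- function(tab,
                                   priors = c("proportional", "equal")) {
  validate_sample_table(tab)
  priors <- match.arg(priors)
  nm <- metabolite_names(tab)
  res <- lapply(nm, function(j)
    loo_evaluate(tab, features = j, priors = priors))
  acc <- vapply(res, function(r) r$accuracy, numeric(1))
  ord <- order(-acc, nm)
  ranking <- data.frame(metabolite = nm[ord], accuracy = acc[ord],
                        stringsAsFactors = FALSE)
  structure(list(ranking = ranking,
                 reports = stats::setNames(lapply(res[ord],
                                                  function(r) r$report),
                                           nm[ord])),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat("Single-metabolite leave-one-out ranking (top 10):\n")
  print(utils::head(x$ranking, 10), row.names = FALSE)
  invisible(x)
}

#' Write a search trace as TSV
#'
#' One row per panel size: size, best subset, accuracy, cumulative best
#' accuracy and number of evaluations -- the data behind an
#' accuracy-versus-panel-size curve.
#'
#' @param result a `search_result`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_search_trace <- function(result, path) {
  stopifnot(inherits(result, "search_result"))
  df <- do.call(rbind, lapply(result$per_size, function(s)
    data.frame(k = s$k,
               subset = paste(s$feature_names, collapse = "+"),
               accuracy = num12(s$accuracy),
               cumulative_best = num12(s$cumulative_best),
               n_evaluated = s$n_evaluated, stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Serialize a double at 12 significant digits (stable text output).
num12 <- function(x) signif(x, 12)
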