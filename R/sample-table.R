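#' Cohort concentration table
#'
#' A `sample_table` bundles a subjects-by-metabolites concentration matrix
#' (micromolar units) with a class label per subject and, optionally, an age
#' covariate. It is the common input of every analysis stage: discriminant
#' fitting, leave-one-out evaluation, subset search, term expansion and the
#' descriptive summaries.
#'
#' @param concentrations numeric matrix, rows = subjects, columns =
#'   metabolites, non-negative, no missing values. Column names are the
#'   metabolite names; they must be unique.
#' @param group class label per subject (character or factor). The level
#'   order of the resulting factor fixes the class order used everywhere
#'   downstream (tie-breaking, report layout).
#' @param subject_id unique subject identifiers; defaults to `S001`, ...
#' @param age optional non-negative age in years, one value per subject.
#' @param class_order optional explicit class order; defaults to order of
#'   first appearance in `group`.
#'
#' @return an object of class `sample_table`: a list with elements
#'   `subject_id`, `group` (factor), `concentrations` (named matrix) and
#'   `age` (numeric or `NULL`).
#' @export
sample_table <- function(concentrations, group, subject_id = NULL,
                         age = NULL, class_order = NULL) {
  concentrations <- as.matrix(concentrations)
  storage.mode(concentrations) <- "double"
  n <- nrow(concentrations)
  if (is.null(subject_id)) {
    subject_id <- sprintf("S%03d", seq_len(n))
  }
  subject_id <- as.character(subject_id)
  if (is.null(class_order)) {
    class_order <- if (is.factor(group)) levels(group) else unique(as.character(group))
  }
  group <- factor(as.character(group), levels = class_order)
  if (is.null(colnames(concentrations))) {
    colnames(concentrations) <- sprintf("M%03d", seq_len(ncol(concentrations)))
  }
  rownames(concentrations) <- subject_id
  tab <- structure(
    list(subject_id = subject_id, group = group,
         concentrations = concentrations,
         age = if (is.null(age)) NULL else as.numeric(age)),
    class = "sample_table")
  validate_sample_table(tab)
  tab
}

#' Validate a sample table
#'
#' Checks the structural invariants every downstream stage relies on:
#' matching row counts, unique subject ids and metabolite names, at least two
#' subjects in every class present, finite non-negative concentrations.
#'
#' @param tab a `sample_table`.
#' @return `tab`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_sample_table <- function(tab) {
  stopifnot(inherits(tab, "sample_table"))
  n <- nrow(tab$concentrations)
  if (length(tab$subject_id) != n)
    stop("subject_id: length ", length(tab$subject_id),
         " does not match ", n, " concentration rows", call. = FALSE)
  if (anyDuplicated(tab$subject_id))
    stop("subject_id: duplicated id '",
         tab$subject_id[duplicated(tab$subject_id)][1], "'", call. = FALSE)
  if (length(tab$group) != n)
    stop("group: length does not match subject count", call. = FALSE)
  if (anyNA(tab$group))
    stop("group: missing or out-of-order class label", call. = FALSE)
  cnt <- table(droplevels(tab$group))
  if (any(cnt < 2))
    stop("group: class '", names(cnt)[cnt < 2][1],
         "' has fewer than 2 subjects", call. = FALSE)
  if (anyDuplicated(colnames(tab$concentrations)))
    stop("metabolite_names: duplicated name '",
         colnames(tab$concentrations)[duplicated(colnames(tab$concentrations))][1],
         "'", call. = FALSE)
  if (anyNA(tab$concentrations) || any(!is.finite(tab$concentrations)))
    stop("concentrations: missing or non-finite values present", call. = FALSE)
  if (any(tab$concentrations < 0))
    stop("concentrations: negative values present", call. = FALSE)
  if (!is.null(tab$age)) {
    if (length(tab$age) != n)
      stop("age: length does not match subject count", call. = FALSE)
    if (any(!is.na(tab$age) & tab$age < 0))
      stop("age: negative values present", call. = FALSE)
  }
  invisible(tab)
}

#' @export
print.sample_table <- function(x, ...) {
  cnt <- table(x$group)
  cat("sample_table:", nrow(x$concentrations), "subjects x",
      ncol(x$concentrations), "metabolites\n")
  cat("  classes:", paste(sprintf("%s (%d)", names(cnt), cnt), collapse = ", "),
      "\n")
  if (!is.null(x$age))
    cat("  age: present (mean ", round(mean(x$age), 1), ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.sample_table <- function(x, ...) {
  df <- data.frame(subject_id = x$subject_id,
                   group = as.character(x$group),
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(x$age)) df$age <- x$age
  cbind(df, as.data.frame(x$concentrations, check.names = FALSE))
}

#' Number of subjects / metabolites
#' @param tab a `sample_table`.
#' @return integer count.
#' @export
n_subjects <- function(tab) nrow(tab$concentrations)

#' @rdname n_subjects
#' @export
n_metabolites <- function(tab) ncol(tab$concentrations)

#' Metabolite names of a table
#' @param tab a `sample_table`.
#' @return character vector of column names.
#' @export
metabolite_names <- function(tab) colnames(tab$concentrations)

#' Subset a sample table by subjects
#'
#' @param tab a `sample_table`.
#' @param i logical or integer subject index.
#' @return a `sample_table` restricted to the selected subjects. Class order
#'   is preserved even for classes that lose all members (validation will
#'   then fail, as downstream stages need two subjects per class).
#' @export
subset_subjects <- function(tab, i) {
  out <- structure(
    list(subject_id = tab$subject_id[i],
         group = tab$group[i],
         concentrations = tab$concentrations[i, , drop = FALSE],
         age = if (is.null(tab$age)) NULL else tab$age[i]),
    class = "sample_table")
  validate_sample_table(out)
  out
}

#' Write a cohort table to CSV
#'
#' Wide RFC-4180 CSV: `subject_id`, `group`, optional `age`, then one column
#' per metabolite. Floats are written at full precision so that
#' write-then-load round-trips exactly.
#'
#' @param tab a `sample_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(tab, path) {
  validate_sample_table(tab)
  df <- as.data.frame(tab)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Load a cohort table from CSV
#'
#' Reads a wide concentration CSV (one header row; one row per subject) into
#' a validated [sample_table()]. Column roles are configurable so that files
#' from different sources can be mapped without editing them. Missing or
#' below-detection cells are handled by an explicit policy:
#'
#' * `"impute-half-min"` (default): an empty/NA cell is replaced by half the
#'   smallest positive value observed in that metabolite's column. Metabolite
#'   columns missing in more than `max_missing_frac` of subjects are dropped
#'   entirely (with a message).
#' * `"error"`: any missing cell is a load error.
#'
#' @param path CSV file path.
#' @param id_col,group_col,age_col names of the subject-id, class-label and
#'   (optional) age columns. `age_col = NA` suppresses age detection.
#' @param missing_policy `"impute-half-min"` or `"error"`.
#' @param max_missing_frac drop metabolites missing in more than this
#'   fraction of subjects (only under `"impute-half-min"`).
#' @param class_order optional explicit class order.
#' @return a validated `sample_table`.
#' @export
load_table <- function(path, id_col = "subject_id", group_col = "group",
                       age_col = "age",
                       missing_policy = c("impute-half-min", "error"),
                       max_missing_frac = 0.2, class_order = NULL) {
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!group_col %in% names(df))
    stop("missing group column '", group_col, "' in ", path, call. = FALSE)
  if (!id_col %in% names(df)) {
    ids <- sprintf("S%03d", seq_len(nrow(df)))
  } else {
    ids <- as.character(df[[id_col]])
    if (anyDuplicated(ids))
      stop("duplicate subject id '", ids[duplicated(ids)][1],
           "' (row ", which(duplicated(ids))[1], ")", call. = FALSE)
  }
  age <- NULL
  if (!is.na(age_col) && age_col %in% names(df)) age <- as.numeric(df[[age_col]])
  meta_cols <- setdiff(names(df), c(id_col, group_col, age_col))
  conc <- matrix(NA_real_, nrow(df), length(meta_cols),
                 dimnames = list(ids, meta_cols))
  for (j in seq_along(meta_cols)) {
    v <- df[[meta_cols[j]]]
    if (is.character(v)) v[v %in% c("", "NA", "<LOD", "< LOD")] <- NA
    v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(df[[meta_cols[j]]]) & df[[meta_cols[j]]] != "" &
                   is.na(v) & !(as.character(df[[meta_cols[j]]]) %in%
                                  c("NA", "<LOD", "< LOD")))
    if (length(bad))
      stop("non-numeric value in column '", meta_cols[j], "', row ", bad[1],
           call. = FALSE)
    conc[, j] <- v
  }
  if (anyNA(conc)) {
    if (missing_policy == "error") {
      idx <- which(is.na(conc), arr.ind = TRUE)[1, ]
      stop("missing value at row ", idx[1], ", column '",
           colnames(conc)[idx[2]], "'", call. = FALSE)
    }
    frac <- colMeans(is.na(conc))
    drop <- frac > max_missing_frac
    if (any(drop)) {
      message("dropping ", sum(drop), " metabolite(s) missing in >",
              round(100 * max_missing_frac), "% of subjects: ",
              paste(colnames(conc)[drop], collapse = ", "))
      conc <- conc[, !drop, drop = FALSE]
    }
    for (j in seq_len(ncol(conc))) {
      na <- is.na(conc[, j])
      if (any(na)) {
        pos <- conc[!na, j]
        pos <- pos[pos > 0]
        if (!length(pos))
          stop("cannot impute column '", colnames(conc)[j],
               "': no positive values observed", call. = FALSE)
        conc[na, j] <- min(pos) / 2
      }
    }
  }
  sample_table(conc, df[[group_col]], subject_id = ids, age = age,
               class_order = class_order)
}
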