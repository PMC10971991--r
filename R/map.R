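#' Project observations onto the first two discriminant axes
#'
#' Coordinates are inner products of the raw feature vectors with the LD1
#' and LD2 axis loadings. The axes are scaled to unit pooled within-class
#' variance, so Euclidean geometry in the LD plane is the Mahalanobis
#' geometry of the original feature space restricted to the discriminant
#' subspace. For a 3-class model the two axes carry all discriminative
#' information (number of axes = number of classes minus 1).
#'
#' @param model an `lda_model` with at least 2 axes.
#' @param x a [sample_table()], design matrix or feature matrix with the
#'   model's features as columns (or exactly the model's feature count).
#' @return numeric matrix with columns `LD1`, `LD2`, one row per subject.
#' @export
project_lda <- function(model, x) {
  stopifnot(inherits(model, "lda_model"))
  if (ncol(model$axes) < 2)
    stop("model has ", ncol(model$axes), " discriminant axis; a 2-D map ",
         "needs at least 2 (use the 1-D projection for 2-class models)",
         call. = FALSE)
  X <- if (inherits(x, "sample_table")) x$concentrations else as.matrix(x)
  if (!is.null(colnames(X)) && all(model$features %in% colnames(X)))
    X <- X[, model$features, drop = FALSE]
  if (ncol(X) != length(model$features))
    stop("x has ", ncol(X), " features; model expects ",
         length(model$features), call. = FALSE)
  X %*% model$axes[, 1:2, drop = FALSE]
}

#' Decision-region map in the discriminant plane
#'
#' Classifies the centre of every cell of a rectangular LD1/LD2 grid,
#' producing the "cake-slice" decision regions of the discriminant model.
#' Each cell is assigned to the class whose centroid is nearest in the
#' Mahalanobis metric of the LD plane (which is Euclidean there, by the
#' axis normalization) under equal priors, or to the maximum-posterior
#' class under proportional priors. With the default equal-priors rule the
#' regions are convex and their boundaries are perpendicular bisectors of
#' centroid pairs.
#'
#' @param model an `lda_model` with >= 2 axes.
#' @param x optional data ([sample_table()] or matrix) used to set default
#'   bounds and to report subject coordinates.
#' @param bounds optional `list(LD1 = c(min, max), LD2 = c(min, max))`;
#'   default: range of the projected data expanded by 10% per side.
#' @param resolution grid cells per axis (default 400, minimum 2).
#' @param priors `"equal"` (geometric nearest-centroid, default) or
#'   `"proportional"`.
#' @return object of class `map_result`: `grid` (resolution x resolution
#'   integer matrix of class indices, rows = LD1 cells, columns = LD2
#'   cells), `class_names`, `bounds`, `resolution`, `ld1`, `ld2` (cell
#'   centres), `centroids` (class centroids in the LD plane), and --
#'   when `x` is given -- `coordinates` and `groups`.
#' @export
region_grid <- function(model, x = NULL, bounds = NULL, resolution = 400,
                        priors = c("equal", "proportional")) {
  stopifnot(inherits(model, "lda_model"))
  priors <- match.arg(priors)
  if (ncol(model$axes) < 2)
    stop("model has fewer than 2 discriminant axes", call. = FALSE)
  if (resolution < 2) stop("resolution must be >= 2", call. = FALSE)
  coords <- NULL
  groups <- NULL
  if (!is.null(x)) {
    coords <- project_lda(model, x)
    if (inherits(x, "sample_table")) groups <- x$group
  }
  cent <- model$means %*% model$axes[, 1:2, drop = FALSE]
  if (is.null(bounds)) {
    ref <- if (is.null(coords)) cent else rbind(coords, cent)
    pad <- function(r) r + c(-1, 1) * 0.1 * diff(r)
    bounds <- list(LD1 = pad(range(ref[, 1])), LD2 = pad(range(ref[, 2])))
  }
  if (diff(bounds$LD1) <= 0 || diff(bounds$LD2) <= 0 ||
      any(!is.finite(unlist(bounds))))
    stop("degenerate bounds", call. = FALSE)
  mid <- function(r) {
    edges <- seq(r[1], r[2], length.out = resolution + 1)
    (edges[-1] + edges[-length(edges)]) / 2
  }
  ld1 <- mid(bounds$LD1)
  ld2 <- mid(bounds$LD2)
  pts <- cbind(rep(ld1, times = resolution),
               rep(ld2, each = resolution))
  lab <- classify_ld(model, pts, priors)
  grid <- matrix(lab, resolution, resolution)   # [LD1 cell, LD2 cell]
  structure(list(grid = grid, class_names = model$class_names,
                 bounds = bounds, resolution = resolution,
                 ld1 = ld1, ld2 = ld2, centroids = cent,
                 coordinates = coords, groups = groups,
                 priors_mode = priors),
            class = "map_result")
}

# Class index of points in the LD plane: squared Euclidean distance to the
# projected centroids (Mahalanobis in the original space, by the axis
# scaling), plus the log-prior term under proportional priors.
classify_ld <- function(model, pts, priors_mode) {
  cent <- model$means %*% model$axes[, 1:2, drop = FALSE]
  K <- nrow(cent)
  D <- matrix(0, nrow(pts), K)
  for (k in seq_len(K))
    D[, k] <- (pts[, 1] - cent[k, 1])^2 + (pts[, 2] - cent[k, 2])^2
  score <- -D / 2
  if (priors_mode == "proportional")
    score <- sweep(score, 2, log(model$priors), "+")
  apply(score, 1, which.max)
}

#' @export
print.map_result <- function(x, ...) {
  cat("Discriminant-region map:", x$resolution, "x", x$resolution,
      "grid, priors:", x$priors_mode, "\n")
  shares <- tabulate(x$grid, length(x$class_names)) / length(x$grid)
  cat("  region area shares:",
      paste(sprintf("%s=%.3f", x$class_names, shares), collapse = ", "),
      "\n")
  invisible(x)
}

#' Export a discriminant map as TSV files
#'
#' Writes subject coordinates (`<stem>_coordinates.tsv`), class centroids
#' (`<stem>_centroids.tsv`) and the region grid as a compact matrix with a
#' class-index legend in its header comment (`<stem>_grid.tsv`).
#'
#' @param map a `map_result`.
#' @param stem output path stem.
#' @return character vector of the files written, invisibly.
#' @export
write_map <- function(map, stem) {
  stopifnot(inherits(map, "map_result"))
  files <- character(0)
  if (!is.null(map$coordinates)) {
    f <- paste0(stem, "_coordinates.tsv")
    df <- data.frame(subject_id = rownames(map$coordinates),
                     LD1 = num12(map$coordinates[, 1]),
                     LD2 = num12(map$coordinates[, 2]))
    if (!is.null(map$groups)) df$group <- as.character(map$groups)
    utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  f <- paste0(stem, "_centroids.tsv")
  utils::write.table(
    data.frame(class = rownames(map$centroids),
               LD1 = num12(map$centroids[, 1]),
               LD2 = num12(map$centroids[, 2])),
    f, sep = "\t", row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  f <- paste0(stem, "_grid.tsv")
  con <- file(f, "w")
  writeLines(paste0("# class legend: ",
                    paste(sprintf("%d=%s", seq_along(map$class_names),
                                  map$class_names), collapse = ", ")), con)
  writeLines(paste0("# rows = LD1 cells [", num12(map$bounds$LD1[1]), ", ",
                    num12(map$bounds$LD1[2]), "], columns = LD2 cells [",
                    num12(map$bounds$LD2[1]), ", ", num12(map$bounds$LD2[2]),
                    "]"), con)
  utils::write.table(map$grid, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  close(con)
  invisible(c(files, f))
}
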