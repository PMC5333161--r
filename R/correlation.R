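#' Shared time points of two profiles
#'
#' Metabolite and culture-metric profiles are typically sampled on days
#' 0--5 while gene expression covers days 0--3; cross-kind correlations are
#' computed on the intersection of the two grids, never by interpolation.
#'
#' @param a,b [ts_profile] objects.
#' @return Ascending numeric vector of shared time points (possibly empty).
#' @export
common_grid <- function(a, b) {
  stopifnot(inherits(a, "ts_profile"), inherits(b, "ts_profile"))
  sort(intersect(a$times, b$times))
}

#' Pearson correlation of two vectors
#'
#' The similarity measure used throughout: plain Pearson's r of two
#' equal-length vectors. Returns `NA` when either vector has zero variance
#' (a constant profile carries no directional information).
#'
#' @param x,y Numeric vectors of equal length, at least `min_n` points.
#' @param min_n Minimum admissible length (default 3).
#' @return r in `[-1, 1]`, or `NA`.
#' @export
pearson_r <- function(x, y, min_n = 3L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  if (length(x) < min_n)
    stop(sprintf("need at least %d points for a correlation, got %d",
                 min_n, length(x)), call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  r <- stats::cor(x, y, method = "pearson")
  # guard against floating-point excursions just outside [-1, 1]
  max(-1, min(1, r))
}

#' All-pairs correlation matrix of profile means
#'
#' Builds the labeled matrix of Pearson correlations between the
#' replicate-mean time courses of two entity sets under one condition.
#' Cross-kind pairs are correlated on the intersection of their time grids;
#' pairs whose shared grid is shorter than `min_n` get `NA` with a warning.
#' With `include_culture = TRUE` the culture metrics (cell number,
#' extracellular glucose and lactate) are appended to both axes so their
#' relationships to every metabolite and gene appear in the same matrix.
#'
#' @param d An `omics_dataset`.
#' @param condition Condition label present in `d`.
#' @param rows,cols Entity kinds for the two axes (character vectors drawn
#'   from `metabolite`, `gene`, `culture_metric`).
#' @param include_culture Append culture metrics to both axes.
#' @param min_n Minimum shared-grid length (default 3).
#' @return An object of class `corr_matrix`: a numeric matrix with entity
#'   dimnames and attributes `condition` and `n_obs` (shared-grid length
#'   per pair).
#' @export
correlation_matrix <- function(d, condition, rows = "metabolite",
                               cols = rows, include_culture = FALSE,
                               min_n = 3L) {
  stopifnot(inherits(d, "omics_dataset"))
  if (!condition %in% dataset_conditions(d))
    stop(sprintf("unknown condition '%s'", condition), call. = FALSE)
  row_ids <- dataset_entities(d, kind = rows, condition = condition)
  col_ids <- dataset_entities(d, kind = cols, condition = condition)
  if (include_culture) {
    cm <- dataset_entities(d, kind = "culture_metric", condition = condition)
    row_ids <- c(setdiff(row_ids, cm), cm)
    col_ids <- c(setdiff(col_ids, cm), cm)
  }
  vals <- matrix(NA_real_, length(row_ids), length(col_ids),
                 dimnames = list(row_ids, col_ids))
  nobs <- matrix(0L, length(row_ids), length(col_ids),
                 dimnames = list(row_ids, col_ids))
  means <- lapply(stats::setNames(union(row_ids, col_ids),
                                  union(row_ids, col_ids)),
                  function(id) mean_profile(get_profile(d, id, condition)))
  short <- character()
  for (i in seq_along(row_ids)) for (j in seq_along(col_ids)) {
    a <- means[[row_ids[i]]]; b <- means[[col_ids[j]]]
    grid <- sort(intersect(a$time, b$time))
    nobs[i, j] <- length(grid)
    if (length(grid) < min_n) {
      short <- c(short, sprintf("%s~%s", row_ids[i], col_ids[j]))
      next
    }
    vals[i, j] <- pearson_r(a$mean[match(grid, a$time)],
                            b$mean[match(grid, b$time)], min_n = min_n)
  }
  if (length(short))
    warning(sprintf("%d pair(s) below the minimum shared grid (%d): %s",
                    length(short), min_n,
                    paste(utils::head(short, 5L), collapse = ", ")),
            call. = FALSE)
  structure(vals, condition = condition, n_obs = nobs,
            class = c("corr_matrix", "matrix", "array"))
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("<corr_matrix> %d x %d, condition %s\n", nrow(x), ncol(x),
              attr(x, "condition")))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE], digits = 3)
  invisible(x)
}

#' Write a correlation matrix as CSV with row/column headers
#' @param cm A `corr_matrix` (or plain matrix with dimnames).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(cm, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(entity_id = rownames(cm),
                   format(unclass(cm), digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}
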