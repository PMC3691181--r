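#' Collapse a chromatographic peak table into one composition row
#'
#' Relative abundance of a protein family is the summed peak area of all
#' peaks assigned to that family, as a percentage of the total peak area of
#' the chromatogram. Output sums to exactly 100 before any rounding.
#'
#' @param peaks A data.frame with columns `peak_id`, `family`, `area`
#'   (areas finite and >= 0, total > 0).
#' @return Named numeric vector of percentages, one entry per family, in
#'   first-appearance order.
#' @export
#' @examples
#' pk <- data.frame(peak_id = c("p1", "p2", "p3"),
#'                  family  = c("A", "A", "B"),
#'                  area    = c(2, 1, 1))
#' peaks_to_composition(pk)  # A 75, B 25
peaks_to_composition <- function(peaks) {
  stopifnot(is.data.frame(peaks),
            all(c("peak_id", "family", "area") %in% names(peaks)))
  area <- peaks$area
  if (any(!is.finite(area)) || any(area < 0))
    stop("peak areas must be finite and >= 0", call. = FALSE)
  tot <- sum(area)
  if (tot <= 0) stop("total peak area is zero", call. = FALSE)
  fam <- factor(peaks$family, levels = unique(peaks$family))
  out <- tapply(area, fam, sum) / tot * 100
  c(out)  # drop tapply's array class, keep names
}

#' Validate a taxa x family composition table
#'
#' @param comp Data.frame or matrix of percentages with taxa as row names
#'   and protein families as columns.
#' @param row_sum_tol Allowed deviation of each row sum from 100 (default 2,
#'   accommodating printed rounding). Published tables occasionally exclude
#'   an unassigned fraction; pass a larger value (or `Inf`) for those.
#' @return The table as a numeric matrix.
#' @export
validate_composition <- function(comp, row_sum_tol = 2) {
  m <- as.matrix(comp)
  storage.mode(m) <- "double"
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("composition table needs unique taxon row names", call. = FALSE)
  if (any(!is.finite(m)) || any(m < 0))
    stop("composition entries must be finite and >= 0", call. = FALSE)
  dev <- abs(rowSums(m) - 100)
  if (any(dev > row_sum_tol)) {
    bad <- rownames(m)[dev > row_sum_tol]
    stop("row(s) not summing to 100 within +/-", row_sum_tol, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m
}

#' Filter protein families by mean abundance and prevalence
#'
#' Keeps families whose mean relative abundance across taxa is strictly
#' greater than `min_mean_pct` percent AND which are present (abundance
#' strictly > 0) in at least `min_presence` taxa. Column order is preserved;
#' the filter is idempotent.
#'
#' @param comp Composition table (taxa x families, percentages).
#' @param min_mean_pct Mean-abundance threshold in percent (default 1).
#' @param min_presence Minimum number of taxa with non-zero abundance
#'   (default 6).
#' @param row_sum_tol Passed to [validate_composition()].
#' @return The filtered composition matrix.
#' @export
filter_families <- function(comp, min_mean_pct = 1, min_presence = 6,
                            row_sum_tol = Inf) {
  m <- validate_composition(comp, row_sum_tol = row_sum_tol)
  if (min_presence > nrow(m))
    stop("min_presence (", min_presence, ") exceeds number of taxa (",
         nrow(m), ")", call. = FALSE)
  keep <- colMeans(m) > min_mean_pct & colSums(m > 0) >= min_presence
  m[, keep, drop = FALSE]
}

#' Arcsine-square-root transform of proportions
#'
#' The variance-stabilizing transform \eqn{\theta = \arcsin\sqrt{p}}
#' (radians), applied elementwise. The input scale is declared explicitly
#' via `mode`, never guessed from magnitudes.
#'
#' @param x Numeric vector or matrix: percentages in \[0, 100\]
#'   (`mode = "percent"`) or proportions in \[0, 1\] (`mode = "proportion"`).
#' @param mode `"percent"` or `"proportion"`.
#' @return Transformed values in \[0, pi/2\], same shape and dimnames.
#' @export
#' @examples
#' arcsin_sqrt(c(0, 50, 100), mode = "percent")   # 0, pi/4, pi/2
arcsin_sqrt <- function(x, mode = c("percent", "proportion")) {
  mode <- match.arg(mode)
  p <- if (mode == "percent") x / 100 else x
  bad <- !is.finite(p) | p < 0 | p > 1
  if (any(bad)) {
    where <- if (is.matrix(x)) {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      paste0("row ", rownames(x)[idx[1]] %||% idx[1],
             ", column ", colnames(x)[idx[2]] %||% idx[2])
    } else {
      i <- which(bad)[1]
      paste0("element ", names(x)[i] %||% i)
    }
    stop("value out of range for mode '", mode, "' at ", where, call. = FALSE)
  }
  out <- asin(sqrt(p))
  if (is.matrix(x)) dimnames(out) <- dimnames(x) else names(out) <- names(x)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson correlation with contract checks
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return The sample Pearson correlation coefficient.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance", call. = FALSE)
  stats::cor(x, y)
}

#' Principal components of a trait table
#'
#' Eigen-decomposition of the covariance (default) or correlation matrix of
#' a column-centered taxa x trait table. Besides eigenvalues and scores the
#' result carries \emph{scaled loadings}: eigenvector entry times
#' \eqn{\sqrt{\lambda_j}} divided by the variable's standard deviation,
#' which equals the Pearson correlation between the variable and the
#' component score. Each component is oriented so that its
#' largest-magnitude scaled loading is positive; signs are otherwise
#' arbitrary and comparisons to published loadings should allow a global
#' per-component flip (see [orient_component()]).
#'
#' @param x Numeric matrix or data.frame, taxa in rows, traits in columns
#'   (>= 3 rows, >= 2 columns, all finite).
#' @param matrix `"covariance"` (default) or `"correlation"`.
#' @return Object of class `"trait_pca"`: list with `eigenvalues`,
#'   `variance_fractions`, `scaled_loadings` (traits x components),
#'   `scores` (taxa x components), `matrix`, `center`, `sd`.
#' @export
pca_traits <- function(x, matrix = c("covariance", "correlation")) {
  matrix <- match.arg(matrix)
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("non-finite input", call. = FALSE)
  if (nrow(m) < 3 || ncol(m) < 2)
    stop("need >= 3 taxa and >= 2 traits", call. = FALSE)
  sdv <- apply(m, 2, stats::sd)
  if (matrix == "correlation" && any(sdv == 0))
    stop("constant column not allowed with correlation matrix", call. = FALSE)
  C <- if (matrix == "covariance") stats::cov(m) else stats::cor(m)
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  vec <- e$vectors
  centered <- scale(m, center = TRUE, scale = FALSE)
  scores <- if (matrix == "covariance") centered %*% vec
            else scale(m, center = TRUE, scale = sdv) %*% vec
  denom <- if (matrix == "covariance") sdv else rep(1, ncol(m))
  loadings <- sweep(vec %*% diag(sqrt(lam), length(lam)), 1, denom, "/")
  # orient: largest-|loading| variable positive, per component
  for (j in seq_along(lam)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      vec[, j] <- -vec[, j]
      scores[, j] <- -scores[, j]
    }
  }
  cn <- paste0("PC", seq_along(lam))
  dimnames(loadings) <- list(colnames(m), cn)
  dimnames(scores) <- list(rownames(m), cn)
  structure(list(
    eigenvalues = lam,
    variance_fractions = lam / sum(lam),
    scaled_loadings = loadings,
    eigenvectors = `dimnames<-`(vec, list(colnames(m), cn)),
    scores = scores,
    matrix = matrix,
    center = colMeans(m),
    sd = sdv
  ), class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, digits = 3, ...) {
  cat("Principal components (", x$matrix, " matrix)\n", sep = "")
  cat("Variance fractions:",
      paste(round(x$variance_fractions, digits), collapse = " "), "\n")
  cat("Scaled loadings (variable-component correlations):\n")
  print(round(x$scaled_loadings, digits))
  invisible(x)
}

#' Flip a principal component so a chosen variable loads positively
#'
#' Component signs are arbitrary; published tables fix them by convention.
#' This flips the loading and score signs of component `component` so that
#' the scaled loading of `variable` is positive.
#'
#' @param pca A `"trait_pca"` object.
#' @param component Component index.
#' @param variable Variable (trait) name or index.
#' @return The modified `"trait_pca"` object.
#' @export
orient_component <- function(pca, component, variable) {
  stopifnot(inherits(pca, "trait_pca"))
  if (pca$scaled_loadings[variable, component] < 0) {
    pca$scaled_loadings[, component] <- -pca$scaled_loadings[, component]
    pca$eigenvectors[, component] <- -pca$eigenvectors[, component]
    pca$scores[, component] <- -pca$scores[, component]
  }
  pca
}

#' Read a taxa x trait CSV
#'
#' Expects a `taxon` first column; remaining columns are traits/families.
#'
#' @param path CSV path (UTF-8, period decimal separator).
#' @return Numeric matrix with taxa as row names.
#' @export
read_trait_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (tolower(names(d)[1]) != "taxon")
    stop("first column must be named 'taxon'", call. = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- d[[1]]
  m
}

#' Write a taxa x trait table to CSV
#'
#' @param x Matrix with taxa as row names.
#' @param path Output CSV path.
#' @export
write_trait_csv <- function(x, path) {
  d <- data.frame(taxon = rownames(x), as.data.frame(x, check.names = FALSE),
                  check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
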