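#' Phylogenetic generalized least squares regression
#'
#' Fits \eqn{y = \beta_0 + \beta_1 x + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma^2 V)}, with V the Brownian-motion
#' covariance of the tree (used as-is, i.e. fixed \eqn{\lambda = 1}):
#' \deqn{\hat\beta = (X'V^{-1}X)^{-1} X'V^{-1} y,\qquad
#'       \hat\sigma^2 = (y - X\hat\beta)'V^{-1}(y - X\hat\beta)/(n-2).}
#' Standard errors come from \eqn{\hat\sigma^2 (X'V^{-1}X)^{-1}}; the slope
#' is tested two-sided against Student-t with n - 2 df. With V = I this is
#' exactly ordinary least squares. The slope, t and p are invariant to
#' rescaling all branch lengths (sigma2_hat scales inversely).
#'
#' @param V Phylogenetic covariance matrix or a \code{"phylo"} tree.
#' @param y Response vector (names aligned to V's taxa when present).
#' @param x Predictor vector.
#' @param response_name,predictor_name Labels carried into the result.
#' @return Object of class `"pgls_result"`: list with `slope`, `intercept`,
#'   `se_slope`, `se_intercept`, `t_stat`, `df`, `p_value`, `sigma2_hat`,
#'   `n`, and the two names.
#' @export
pgls_fit <- function(V, y, x, response_name = "y", predictor_name = "x") {
  if (inherits(V, "phylo")) V <- phylo_vcv(V)
  V <- validate_vcv(V)
  n <- nrow(V)
  align <- function(v, what) {
    if (!is.null(names(v)) && !is.null(rownames(V))) {
      um <- c(setdiff(rownames(V), names(v)), setdiff(names(v), rownames(V)))
      if (length(um)) stop("taxa mismatch for ", what, "; unmatched: ",
                           paste(unique(um), collapse = ", "), call. = FALSE)
      v <- v[rownames(V)]
    }
    if (length(v) != n) stop(what, " length != dim(V)", call. = FALSE)
    if (any(!is.finite(v))) stop("non-finite ", what, call. = FALSE)
    as.numeric(v)
  }
  y <- align(y, "response"); x <- align(x, "predictor")
  if (n < 4) stop("need at least 4 taxa for a slope test", call. = FALSE)
  if (stats::sd(x) == 0) stop("predictor is constant (collinear with intercept)",
                              call. = FALSE)
  if (rcond(V) < 1e-12)
    stop("V is singular or ill-conditioned; inspect branch lengths",
         call. = FALSE)
  X <- cbind(intercept = 1, slope = x)
  invV <- chol2inv(chol(V))
  XtVi <- crossprod(X, invV)
  A <- XtVi %*% X
  if (rcond(A) < 1e-12) stop("design is collinear", call. = FALSE)
  Ainv <- solve(A)
  beta <- drop(Ainv %*% (XtVi %*% y))
  r <- y - drop(X %*% beta)
  df <- n - 2L
  sigma2 <- as.numeric(crossprod(r, invV %*% r)) / df
  se <- unname(sqrt(pmax(diag(Ainv) * sigma2, 0)))
  tstat <- beta[["slope"]] / se[2]
  structure(list(
    response_name = response_name, predictor_name = predictor_name,
    slope = beta[["slope"]], intercept = beta[["intercept"]],
    se_slope = se[2], se_intercept = se[1],
    t_stat = tstat, df = df,
    p_value = 2 * stats::pt(-abs(tstat), df),
    sigma2_hat = sigma2, n = n
  ), class = "pgls_result")
}

#' @export
print.pgls_result <- function(x, ...) {
  cat(sprintf(
    "PGLS: %s ~ %s (n = %d)\n  slope = %.4g (se %.4g), t(%d) = %.3f, p = %.4g\n",
    x$response_name, x$predictor_name, x$n, x$slope, x$se_slope, x$df,
    x$t_stat, x$p_value))
  invisible(x)
}

#' PGLS screen of many responses against one predictor
#'
#' Fits [pgls_fit()] for every column of `traits` against the same
#' predictor; failing columns are reported as NA rows without aborting the
#' others.
#'
#' @param V Phylogenetic covariance matrix or a \code{"phylo"} tree.
#' @param traits Numeric matrix, taxa x responses.
#' @param predictor Predictor vector (e.g. a diet PC1 score).
#' @param predictor_name Label for the predictor column of the output.
#' @return Data.frame with one row per response: `trait`, `slope`, `se`,
#'   `t`, `df`, `p_value`, `error`.
#' @export
pgls_screen <- function(V, traits, predictor, predictor_name = "predictor") {
  if (inherits(V, "phylo")) V <- phylo_vcv(V)
  m <- as.matrix(traits)
  res <- lapply(seq_len(ncol(m)), function(j) {
    nm <- colnames(m)[j] %||% paste0("trait", j)
    y <- stats::setNames(m[, j], rownames(m))
    tryCatch({
      f <- pgls_fit(V, y, predictor, response_name = nm,
                    predictor_name = predictor_name)
      data.frame(trait = nm, slope = f$slope, se = f$se_slope, t = f$t_stat,
                 df = f$df, p_value = f$p_value, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(trait = nm, slope = NA_real_, se = NA_real_, t = NA_real_,
                 df = NA_integer_, p_value = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, res)
}

#' Benjamini-Yekutieli adjusted critical p-value
#'
#' FDR control valid under arbitrary dependence among k tests: the critical
#' value is \eqn{\alpha / \sum_{i=1}^{k} 1/i}. Raw p-values at or below
#' this value are declared significant (single-critical-value usage; no
#' per-test adjusted p-values). Strictly decreasing in k; equals alpha at
#' k = 1.
#'
#' @param alpha Family-wise level in (0, 1).
#' @param k Number of tests (>= 1).
#' @return The adjusted critical p-value.
#' @references Benjamini & Yekutieli (2001) Ann. Statist. 29:1165-1188;
#'   Narum (2006) Conserv. Genet. 7:783-787.
#' @export
#' @examples
#' by_critical(0.05, 9)   # 0.01767...
by_critical <- function(alpha, k) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
    stop("k must be a positive integer", call. = FALSE)
  alpha / sum(1 / seq_len(k))
}
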