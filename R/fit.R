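# Gene-wise least-squares fits and contrast propagation.

#' Fit a linear model to every gene
#'
#' Ordinary least squares of each gene's log2 expression profile on the
#' design matrix. Returns, per gene, the coefficient estimates, the unscaled
#' standard deviations (square roots of the diagonal of `(X'X)^-1`), the
#' residual standard deviation `s_g` with its residual degrees of freedom
#' `d_g = n - rank(X)`, and the mean log2 intensity `A`.
#'
#' @param exprs A `mir_exprs` object or genes-by-arrays matrix.
#' @param design Arrays-by-coefficients design matrix (full column rank),
#'   rows aligned with the expression columns.
#' @return An object of class `mir_fit`: list with `coefficients` and
#'   `stdev_unscaled` (genes x coefficients), `sigma`, `df_residual`,
#'   `Amean`, `cov_unscaled` (`(X'X)^-1`), `design` and `genes`.
#' @export
lm_fit <- function(exprs, design) {
  e <- if (inherits(exprs, "mir_exprs")) exprs$exprs else exprs
  check_matrix(e, "exprs")
  design <- as.matrix(design)
  if (nrow(design) != ncol(e))
    stopf("design rows (%d) must match expression columns (%d)",
          nrow(design), ncol(e))
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) stopf("design matrix is rank deficient")
  n <- nrow(design)
  d <- n - qrX$rank
  if (d == 0)
    stopf("no residual degrees of freedom (n = rank(design) = %d)", n)
  fit <- stats::lm.fit(design, t(e))
  B <- t(fit$coefficients)                       # genes x coefficients
  res <- fit$residuals                           # arrays x genes
  sigma <- sqrt(colSums(res^2) / d)
  cov_unscaled <- chol2inv(chol(crossprod(design)))
  dimnames(cov_unscaled) <- list(colnames(design), colnames(design))
  u <- matrix(sqrt(diag(cov_unscaled)), nrow(e), ncol(design), byrow = TRUE,
              dimnames = dimnames(B))
  out <- list(coefficients = B, stdev_unscaled = u,
              sigma = stats::setNames(unname(sigma), rownames(e)),
              df_residual = rep(d, nrow(e)),
              Amean = rowMeans(e),
              cov_unscaled = cov_unscaled,
              design = design,
              genes = rownames(e))
  class(out) <- "mir_fit"
  out
}

#' Re-express a fit in terms of contrasts
#'
#' Transforms coefficient estimates to contrast estimates,
#' `beta_c = C' beta`, propagating the unscaled covariance through
#' `C' (X'X)^-1 C`. Residual variances and degrees of freedom are unchanged.
#'
#' @param fit A `mir_fit` from [lm_fit()].
#' @param contrasts Coefficients-by-contrasts matrix (e.g. from
#'   [make_contrasts()]).
#' @return A `mir_fit` whose columns are the contrasts.
#' @export
contrast_fit <- function(fit, contrasts) {
  if (!inherits(fit, "mir_fit")) stopf("'fit' must come from lm_fit()")
  contrasts <- as.matrix(contrasts)
  if (nrow(contrasts) != ncol(fit$coefficients))
    stopf("contrast rows (%d) must match fit coefficients (%d)",
          nrow(contrasts), ncol(fit$coefficients))
  cov_c <- t(contrasts) %*% fit$cov_unscaled %*% contrasts
  out <- fit
  out$coefficients <- fit$coefficients %*% contrasts
  out$stdev_unscaled <- matrix(sqrt(diag(cov_c)),
                               nrow(fit$coefficients), ncol(contrasts),
                               byrow = TRUE,
                               dimnames = list(rownames(fit$coefficients),
                                               colnames(contrasts)))
  out$cov_unscaled <- cov_c
  out$contrasts <- contrasts
  out
}

#' @export
print.mir_fit <- function(x, ...) {
  cat(sprintf("Gene-wise linear fit (mir_fit): %d genes, %d %s, df = %d\n",
              nrow(x$coefficients), ncol(x$coefficients),
              if (is.null(x$contrasts)) "coefficients" else "contrasts",
              x$df_residual[1]))
  invisible(x)
}
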