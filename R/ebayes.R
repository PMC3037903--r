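# Empirical-Bayes moderation of gene-wise variances and multiple-testing
# adjustment.

#' Inverse of the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by Newton iteration on the
#' monotone decreasing trigamma function, with asymptotic starting values at
#' the extremes.
#'
#' @param y Positive numeric vector.
#' @return Numeric vector `x` with `trigamma(x) = y`.
#' @keywords internal
#' @export
trigamma_inverse <- function(y) {
  out <- y
  big <- y > 1e7        # trigamma(x) ~ 1/x for tiny x
  out[big] <- 1 / sqrt(y[big])
  small <- y < 1e-6     # trigamma(x) ~ 1/x for large x
  out[small] <- 1 / y[small]
  mid <- !big & !small
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (max(-dif / x) < 1e-10) break
    }
    out[mid] <- x
  }
  out
}

#' Empirical-Bayes moderated statistics
#'
#' Shrinks the gene-wise residual variances toward a prior variance estimated
#' across all genes and computes moderated t (and F) statistics. The prior
#' degrees of freedom `d0` and prior variance `s0^2` are estimated by moment
#' matching on `e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)`:
#' `trigamma(d0/2)` equals the excess of the sample variance of `e` over
#' `mean(trigamma(d_g/2))` (solved with [trigamma_inverse()]), and `s0^2`
#' follows from the mean of `e`. If the excess is non-positive, `d0` is
#' infinite and every posterior variance equals `s0^2`. The posterior
#' variance is `s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`; moderated
#' t-statistics are `beta_c / (u_c s~_g)` with `d0 + d_g` degrees of freedom,
#' and a moderated F over all contrasts is computed from the decorrelated
#' t-vector.
#'
#' @param fit A `mir_fit` from [lm_fit()] or [contrast_fit()].
#' @return An object of class `mir_ebayes` extending the fit with
#'   `df_prior`, `s2_prior`, `s2_post`, `t`, `p_value`, `df_total`, `F` and
#'   `F_p`.
#' @export
moderate <- function(fit) {
  if (!inherits(fit, "mir_fit")) stopf("'fit' must come from lm_fit()")
  s2 <- fit$sigma^2
  d <- fit$df_residual
  if (length(s2) < 2) stopf("moderation needs >= 2 genes")
  ok <- d > 0 & is.finite(s2) & s2 > 0
  if (!any(ok)) stopf("all gene variances are zero; nothing to moderate")
  e <- log(s2[ok]) - digamma(d[ok] / 2) + log(d[ok] / 2)
  emean <- mean(e)
  G <- length(e)
  evar <- mean((e - emean)^2) * G / (G - 1) - mean(trigamma(d[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    # no detectable spread beyond chi-square sampling noise: variances are
    # exchangeable and the prior absorbs them completely
    df_prior <- Inf
    s2_prior <- mean(s2[ok])
  }
  s2_post <- if (is.finite(df_prior))
    (df_prior * s2_prior + d * s2) / (df_prior + d)
  else rep(s2_prior, length(s2))
  df_total <- d + df_prior
  tstat <- fit$coefficients / (fit$stdev_unscaled * sqrt(s2_post))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  m <- ncol(fit$coefficients)
  if (m >= 1) {
    R <- stats::cov2cor(fit$cov_unscaled)
    Ri <- chol2inv(chol(R))
    Fstat <- rowSums((tstat %*% Ri) * tstat) / m
    Fp <- stats::pf(Fstat, m, df_total, lower.tail = FALSE)
  } else {
    Fstat <- Fp <- NULL
  }
  out <- fit
  out$df_prior <- df_prior
  out$s2_prior <- s2_prior
  out$s2_post <- s2_post
  out$df_total <- df_total
  out$t <- tstat
  out$p_value <- p
  out$F <- Fstat
  out$F_p <- Fp
  class(out) <- c("mir_ebayes", "mir_fit")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (`min(cummin(p * n / rank))`), delegated to [stats::p.adjust()]. Input is
#' validated to lie in `[0, 1]`.
#'
#' @param pvals Numeric vector of p-values.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals)) stopf("p-values must be numeric")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
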