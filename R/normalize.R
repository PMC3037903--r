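# Between-array normalization and negative-value handling.

#' Correct negative total gene signals
#'
#' The AFE total gene signal is background-subtracted and can be negative for
#' dim microRNAs; it must be made positive before log transformation. Two
#' corrections are offered: `half` (the default) rounds every value below 0.5
#' up to 0.5; `offset` adds `|min(x)| + offset` to the whole matrix.
#'
#' @param x Linear-scale TGS matrix (or vector).
#' @param method `"half"` or `"offset"`.
#' @param offset Nonnegative constant used by the offset method.
#' @return Corrected matrix, strictly positive (for the offset method this
#'   requires `offset > 0` unless the minimum is already positive).
#' @examples
#' correct_negative_tgs(c(-3, 0.2, 7))                      # 0.5 0.5 7
#' correct_negative_tgs(c(-3, 0.2, 7), "offset", offset = 1) # 1 4.2 11
#' @export
correct_negative_tgs <- function(x, method = c("half", "offset"), offset = 0) {
  method <- match.arg(method)
  if (!is.numeric(x)) stopf("'x' must be numeric")
  if (method == "half") {
    x[x < 0.5] <- 0.5
    return(x)
  }
  if (!is.numeric(offset) || length(offset) != 1 || offset < 0)
    stopf("'offset' must be a nonnegative number")
  mn <- min(x)
  if (mn <= 0 && offset <= 0)
    stopf("offset method with offset <= 0 leaves non-positive values")
  x + abs(mn) + offset
}

#' Quantile normalization between arrays
#'
#' Forces every column of the matrix onto a common distribution: the
#' row-wise mean of the per-column sorted values. Ties within a column
#' receive the mean of the target values at the tied ranks. The computation
#' is delegated to [limma::normalizeQuantiles()].
#'
#' @param x Numeric matrix with no missing values (spots or genes by arrays).
#' @return Matrix of the same shape with identical column value distributions.
#' @export
quantile_normalize <- function(x) {
  check_matrix(x)
  if (anyNA(x)) stopf("missing values are not supported")
  if (ncol(x) < 2) return(x)
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Scale normalization between arrays
#'
#' Shifts each column of a log2 matrix so that all column medians equal the
#' mean of the original column medians.
#'
#' @param x Log2-scale numeric matrix.
#' @return Shifted matrix.
#' @export
scale_normalize <- function(x) {
  check_matrix(x)
  meds <- apply(x, 2L, med)
  sweep(x, 2L, meds - mean(meds))
}
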