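# Design and contrast matrices for the gene-wise linear models.

#' Build a design matrix from the target table
#'
#' The first factor is the treatment factor, coded as one indicator column
#' per group (no intercept), so that contrasts are direct differences of
#' group means. Any further factors (e.g. `Subject` in a paired design) are
#' added as centered indicator columns, dropping each factor's first level.
#' The matrix is checked for full column rank.
#'
#' @param targets A `mir_targets` table.
#' @param factors Character vector of target-table column names; the first is
#'   the treatment factor. Default `"Treatment"`.
#' @return Numeric arrays-by-coefficients matrix of class `mir_design_matrix`
#'   with named columns, rows aligned with the target rows.
#' @examples
#' tf <- data.frame(FileName = paste0("a", 1:6, ".txt"),
#'                  Treatment = rep(c("A", "B", "C"), each = 2),
#'                  GErep = rep(1:3, each = 2), Subject = rep(1:2, 3))
#' class(tf) <- c("mir_targets", "data.frame")
#' build_design(tf, c("Treatment", "Subject"))  # 6 x 4, full rank
#' @export
build_design <- function(targets, factors = "Treatment") {
  if (!is.data.frame(targets)) stopf("'targets' must be a target table")
  missing_cols <- setdiff(factors, names(targets))
  if (length(missing_cols) > 0)
    stopf("factor column(s) not in targets: %s",
          paste(missing_cols, collapse = ", "))
  if (length(factors) < 1) stopf("at least one factor is required")
  trt <- factor(targets[[factors[1]]])
  X <- if (nlevels(trt) == 1L)
    matrix(1, nrow(targets), 1, dimnames = list(NULL, levels(trt)))
  else stats::model.matrix(~ 0 + trt)
  colnames(X) <- levels(trt)
  for (f in factors[-1]) {
    fac <- factor(targets[[f]])
    if (nlevels(fac) < 2) next
    B <- stats::model.matrix(~ 0 + fac)[, -1, drop = FALSE]
    B <- scale(B, scale = FALSE)          # centered blocking indicators
    colnames(B) <- paste0(f, levels(fac)[-1])
    X <- cbind(X, B)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    stopf("design matrix is rank deficient; confounded column(s): %s",
          paste(dropped, collapse = ", "))
  }
  rownames(X) <- targets$FileName
  attr(X, "factors") <- factors
  class(X) <- c("mir_design_matrix", class(X))
  X
}

#' Build a contrast matrix from difference expressions
#'
#' Each contrast is a string of the form `"B-A"` naming two coefficients of
#' the design matrix; the resulting column carries +1 for the first and -1
#' for the second. Plain coefficient names are also accepted (a single +1).
#'
#' @param contrasts Character vector, e.g. `c("B-A", "C-A")`.
#' @param design A design matrix from [build_design()] (its column names
#'   define the coefficients).
#' @return Coefficients-by-contrasts numeric matrix with contrast names.
#' @export
make_contrasts <- function(contrasts, design) {
  coefs <- colnames(design)
  C <- matrix(0, length(coefs), length(contrasts),
              dimnames = list(coefs, contrasts))
  for (k in seq_along(contrasts)) {
    parts <- strsplit(gsub(" ", "", contrasts[k]), "-", fixed = TRUE)[[1]]
    if (!all(parts %in% coefs))
      stopf("contrast '%s' references unknown coefficient(s): %s",
            contrasts[k], paste(setdiff(parts, coefs), collapse = ", "))
    if (length(parts) == 1L) {
      C[parts, k] <- 1
    } else if (length(parts) == 2L) {
      C[parts[1], k] <- 1
      C[parts[2], k] <- C[parts[2], k] - 1
    } else stopf("contrast '%s' is not of the form 'X' or 'X-Y'",
                 contrasts[k])
  }
  if (any(colSums(C != 0) == 0)) stopf("all-zero contrast column")
  C
}
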