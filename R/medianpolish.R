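# Median of replicated probes and median-polish summarization (the RMA
# summary step).

#' Collapse replicate spots to probe-level medians
#'
#' Step 4 of the RMA protocol: features sharing a probe sequence are
#' collapsed to their median per array, normally leaving 2, 3 or 4 probe-level
#' measures per microRNA. Even replicate counts use the arithmetic mean of
#' the central pair.
#'
#' @param dataset A `mir_probes` dataset.
#' @param signal Matrix to collapse: a spots-by-arrays matrix, or the name of
#'   a dataset component (default `"mean_signal"`).
#' @param include_controls Keep control probes? Default drops them.
#' @return List with `values` (distinct probes by arrays matrix, probe row
#'   names) and `gene` (named character vector mapping probe to gene).
#' @export
median_replicate_probes <- function(dataset, signal = "mean_signal",
                                    include_controls = FALSE) {
  if (!inherits(dataset, "mir_probes")) stopf("'dataset' must be a mir_probes")
  x <- if (is.matrix(signal)) signal else dataset[[signal]]
  check_matrix(x, "signal")
  keep <- if (include_controls) rep(TRUE, length(dataset$probe_name))
  else dataset$control_type == 0L
  idx <- split(which(keep), dataset$probe_name[keep])
  vals <- t(vapply(idx, function(i)
    apply(x[i, , drop = FALSE], 2L, med), numeric(ncol(x))))
  if (ncol(x) == 1L) vals <- matrix(vals, ncol = 1L,
                                    dimnames = list(names(idx), colnames(x)))
  gene <- vapply(idx, function(i) dataset$gene_name[i[1]], "")
  list(values = vals, gene = gene)
}

#' Tukey median polish of a two-way table
#'
#' Fits the additive model `x[i,j] = overall + probe[i] + array[j] + resid`
#' by alternately sweeping row and column medians (rows first), re-centering
#' the accumulated effects by their medians after each sweep. Iteration stops
#' when the change in the sum of absolute residuals falls below `tol`, or
#' after `max_iter` full sweeps. The decomposition reconstructs the input
#' exactly: `overall + probe[i] + array[j] + residuals[i,j] == x[i,j]`.
#'
#' @param x Numeric matrix (probes by arrays), at least 1 row and column.
#' @param tol Absolute convergence tolerance on the change in sum of
#'   absolute residuals.
#' @param max_iter Maximum number of full row+column sweeps.
#' @return List with `overall` (scalar), `probe` (row effects), `array`
#'   (column effects), `residuals` (matrix) and `iterations`.
#' @export
median_polish <- function(x, tol = 0.01, max_iter = 10L) {
  check_matrix(x)
  if (nrow(x) < 1 || ncol(x) < 1) stopf("empty matrix")
  z <- x
  overall <- 0
  r <- numeric(nrow(x))
  cc <- numeric(ncol(x))
  oldsum <- sum(abs(z))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    rdelta <- apply(z, 1L, med)
    z <- z - rdelta
    r <- r + rdelta
    delta <- med(cc)
    cc <- cc - delta
    overall <- overall + delta
    cdelta <- apply(z, 2L, med)
    z <- sweep(z, 2L, cdelta)
    cc <- cc + cdelta
    delta <- med(r)
    r <- r - delta
    overall <- overall + delta
    newsum <- sum(abs(z))
    if (newsum == 0 || abs(newsum - oldsum) < tol || iter >= max_iter) break
    oldsum <- newsum
  }
  list(overall = overall, probe = stats::setNames(r, rownames(x)),
       array = stats::setNames(cc, colnames(x)),
       residuals = z, iterations = iter)
}

#' Summarize probe-level data into gene signals
#'
#' Step 5 of the RMA protocol: for each microRNA the probes-by-arrays
#' submatrix (log2 scale) is fitted with [median_polish()], and the gene
#' signal on array `j` is `overall + array_effect[j]` — the probe-affinity
#' corrected expression. Single-probe genes pass through unchanged.
#'
#' @param probe_matrix Distinct probes by arrays log2 matrix with probe row
#'   names.
#' @param probe_gene Named character vector mapping every probe (names) to
#'   its gene.
#' @param ... Passed to [median_polish()].
#' @return Genes-by-arrays matrix, genes in first-appearance order.
#' @export
summarize_rma <- function(probe_matrix, probe_gene, ...) {
  check_matrix(probe_matrix, "probe_matrix")
  probes <- rownames(probe_matrix)
  if (is.null(probes)) stopf("probe_matrix must have probe row names")
  unmapped <- setdiff(probes, names(probe_gene))
  if (length(unmapped) > 0)
    stopf("probe(s) not mapped to a gene: %s",
          paste(utils::head(unmapped, 3), collapse = ", "))
  gene <- probe_gene[probes]
  genes <- unique(gene)
  out <- matrix(NA_real_, length(genes), ncol(probe_matrix),
                dimnames = list(genes, colnames(probe_matrix)))
  for (g in genes) {
    sub <- probe_matrix[gene == g, , drop = FALSE]
    if (nrow(sub) == 1L) {
      out[g, ] <- sub[1L, ]
    } else {
      mp <- median_polish(sub, ...)
      out[g, ] <- mp$overall + mp$array
    }
  }
  out
}
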