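# Quality assessment: replicate CV, reference array, MA/RLE values,
# sample clustering, report plots.

#' Per-array reproducibility coefficient of variation
#'
#' Agilent miRNA arrays replicate every probe several times across the array
#' surface. For each array the CV (sd/mean of the replicate raw mean signals)
#' is computed for every non-control probe with at least two replicates, and
#' the median CV over probes is reported as the array's reproducibility.
#' Lower values indicate better within-array reproducibility. Probes whose
#' replicate mean is zero on an array are excluded from that array's median
#' (with a log line).
#'
#' @param dataset A `mir_probes` dataset.
#' @return Named numeric vector, one median CV per array.
#' @export
array_reproducibility_cv <- function(dataset) {
  if (!inherits(dataset, "mir_probes")) stopf("'dataset' must be a mir_probes")
  keep <- dataset$control_type == 0L
  idx <- split(which(keep), dataset$probe_name[keep])
  idx <- idx[lengths(idx) >= 2L]
  if (length(idx) == 0)
    stopf("no non-control probe with >= 2 replicates")
  x <- dataset$mean_signal
  out <- vapply(seq_len(ncol(x)), function(j) {
    m <- vapply(idx, function(i) mean(x[i, j]), 0)
    s <- vapply(idx, function(i) stats::sd(x[i, j]), 0)
    zero <- m == 0
    if (any(zero))
      msg(sprintf("array %s: %d probe(s) with zero mean excluded from CV",
                  colnames(x)[j], sum(zero)))
    med(s[!zero] / m[!zero])
  }, 0)
  names(out) <- colnames(x)
  out
}

#' Median reference array
#'
#' The reference array against which MA and RLE values are computed: each
#' spot is the median of that spot across all arrays.
#'
#' @param matrix A spots-by-arrays numeric matrix.
#' @return Numeric vector of per-spot medians.
#' @export
reference_array <- function(matrix) {
  check_matrix(matrix)
  if (ncol(matrix) < 1 || nrow(matrix) < 1) stopf("empty matrix")
  apply(matrix, 1L, med)
}

#' MA values against the median reference array
#'
#' For a log2 matrix, computes for one array the fold change
#' `M = x_j - reference` and average log expression
#' `A = (x_j + reference)/2`, where the reference is the per-spot median
#' across all arrays ([reference_array()]).
#'
#' @param matrix Log2-scale spots-by-arrays matrix.
#' @param array_index Column index of the array to compare.
#' @return List with numeric vectors `A` and `M`.
#' @export
ma_values <- function(matrix, array_index) {
  check_matrix(matrix)
  if (!is_count(array_index) || array_index < 1 ||
      array_index > ncol(matrix))
    stopf("array_index out of range (1..%d)", ncol(matrix))
  ref <- reference_array(matrix)
  x <- matrix[, array_index]
  list(A = (x + ref) / 2, M = x - ref)
}

#' Relative log expression values
#'
#' RLE of spot `s` on array `j` is `x[s,j] - reference[s]` with the median
#' reference array. Since most genes are expected unchanged, per-array RLE
#' boxplots should center on zero with comparable spread; the per-array
#' median and IQR are returned as attributes.
#'
#' @param matrix Log2-scale spots-by-arrays matrix.
#' @return Matrix of RLE values with attributes `median` and `iqr` (per-array
#'   summaries).
#' @export
rle_values <- function(matrix) {
  check_matrix(matrix)
  if (ncol(matrix) < 1 || nrow(matrix) < 1) stopf("empty matrix")
  ref <- reference_array(matrix)
  out <- matrix - ref
  attr(out, "median") <- apply(out, 2L, med)
  attr(out, "iqr") <- apply(out, 2L, function(v)
    diff(stats::quantile(v, c(0.25, 0.75), names = FALSE)))
  out
}

#' Hierarchical clustering of samples
#'
#' Agglomeratively clusters the arrays (Euclidean distance, complete
#' linkage) on the full gene set or an optional gene subset. Note that the
#' genes separating experimental groups are usually a small fraction of the
#' array, so sample clusters often reflect other structure or noise rather
#' than treatment.
#'
#' @param matrix Genes-by-arrays matrix with gene row names.
#' @param gene_subset Optional character vector of gene names to restrict to.
#' @return An object of class `hclust`.
#' @export
cluster_samples <- function(matrix, gene_subset = NULL) {
  check_matrix(matrix)
  if (ncol(matrix) < 2) stopf("clustering needs at least 2 arrays")
  if (!is.null(gene_subset)) {
    keep <- rownames(matrix) %in% gene_subset
    if (!any(keep)) stopf("gene_subset shares no genes with the matrix")
    matrix <- matrix[keep, , drop = FALSE]
  }
  stats::hclust(stats::dist(t(matrix)), method = "complete")
}

#' Write a quality-assessment report
#'
#' Produces the standard QC graphics for a dataset and its processed
#' expression matrix — boxplot, density plot, MA plots against the median
#' reference array, RLE boxplot, sample dendrogram — plus a tab-delimited
#' summary (`qc_summary.txt`) with the per-array reproducibility CV and RLE
#' median/IQR. MA and RLE panels are skipped (with a log line) when fewer
#' than two arrays are available.
#'
#' @param dataset A `mir_probes` dataset.
#' @param processed A `mir_exprs` expression matrix (see [tgs_pipeline()] or
#'   [rma_pipeline()]).
#' @param out_dir Output directory.
#' @return Invisibly, the character vector of files written.
#' @export
qc_report <- function(dataset, processed, out_dir) {
  if (!inherits(processed, "mir_exprs"))
    stopf("'processed' must be a mir_exprs expression matrix")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  e <- processed$exprs
  n <- ncol(e)
  files <- character(0)
  plot_file <- function(name, fun) {
    p <- file.path(out_dir, name)
    grDevices::png(p, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    fun()
    files[[length(files) + 1]] <<- p
  }
  plot_file("boxplot.png", function()
    graphics::boxplot(e, las = 2, main = "Processed signal (log2)",
                      ylab = "log2 signal"))
  plot_file("density.png", function() {
    dens <- apply(e, 2L, stats::density)
    xl <- range(vapply(dens, function(d) range(d$x), numeric(2)))
    yl <- c(0, max(vapply(dens, function(d) max(d$y), 0)))
    graphics::plot(NA, xlim = xl, ylim = yl, xlab = "log2 signal",
                   ylab = "density", main = "Signal densities")
    for (j in seq_len(n)) graphics::lines(dens[[j]], col = j)
    graphics::legend("topright", legend = colnames(e), col = seq_len(n),
                     lty = 1, cex = 0.7)
  })
  rle_med <- rep(NA_real_, n)
  rle_iqr <- rep(NA_real_, n)
  if (n >= 2) {
    plot_file("ma.png", function() {
      nr <- ceiling(n / 3)
      graphics::par(mfrow = c(nr, min(n, 3)))
      for (j in seq_len(n)) {
        ma <- ma_values(e, j)
        graphics::plot(ma$A, ma$M, pch = 16, cex = 0.3,
                       xlab = "A", ylab = "M", main = colnames(e)[j])
        graphics::abline(h = 0, col = "red")
      }
    })
    r <- rle_values(e)
    rle_med <- attr(r, "median")
    rle_iqr <- attr(r, "iqr")
    plot_file("rle.png", function() {
      graphics::boxplot(r, las = 2, main = "Relative log expression",
                        ylab = "RLE")
      graphics::abline(h = 0, col = "red")
    })
    plot_file("dendrogram.png", function()
      graphics::plot(cluster_samples(e), main = "Sample clustering",
                     xlab = "", sub = ""))
  } else {
    msg("fewer than 2 arrays: MA, RLE and clustering panels skipped")
  }
  cv <- array_reproducibility_cv(dataset)
  summ <- data.frame(Array = colnames(e),
                     ReproducibilityCV = unname(cv[colnames(e)]),
                     RLEMedian = rle_med, RLEIQR = rle_iqr,
                     stringsAsFactors = FALSE)
  spath <- file.path(out_dir, "qc_summary.txt")
  utils::write.table(format(summ, digits = 6), spath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files[[length(files) + 1]] <- spath
  invisible(unlist(files))
}
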