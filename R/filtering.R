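# Probe/gene filtering on control status, detection flags and
# negative-control expression thresholds.

new_filter_report <- function(retained, removed, reasons, params) {
  out <- list(retained = retained, removed = removed,
              reasons = reasons, params = params)
  class(out) <- "mir_filter_report"
  out
}

#' @export
print.mir_filter_report <- function(x, ...) {
  cat("Filter report (mir_filter_report)\n")
  cat(sprintf("  retained %d, removed %d\n", length(x$retained),
              length(x$removed)))
  if (length(x$removed) > 0) {
    tab <- table(x$reasons)
    cat("  reasons:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a filter report as tab-delimited text
#'
#' @param report A `mir_filter_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_filter_report <- function(report, path) {
  tab <- data.frame(Gene = c(report$retained, report$removed),
                    Status = rep(c("retained", "removed"),
                                 c(length(report$retained),
                                   length(report$removed))),
                    Reason = c(rep("", length(report$retained)),
                               report$reasons),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove control features
#'
#' Restricts a probe-level dataset or an annotated matrix to microRNA gene
#' features (`ControlType == 0`), dropping positive and negative controls.
#'
#' @param x A `mir_probes` dataset, or a matrix with as many rows as
#'   `control_type`.
#' @param control_type Required when `x` is a matrix: vector of -1/0/+1
#'   control codes per row.
#' @return The subset object of the same kind, with a `filter_report`
#'   attribute listing removed control genes.
#' @export
remove_controls <- function(x, control_type = NULL) {
  if (inherits(x, "mir_probes")) {
    keep <- x$control_type == 0L
    removed <- unique(x$gene_name[!keep])
    out <- x
    for (f in c("mean_signal", "processed_signal", "total_probe_signal",
                "total_gene_signal", "bg_median", "bg_used"))
      out[[f]] <- out[[f]][keep, , drop = FALSE]
    out$flags <- lapply(out$flags, function(m) m[keep, , drop = FALSE])
    out$probe_name <- out$probe_name[keep]
    out$gene_name <- out$gene_name[keep]
    out$control_type <- out$control_type[keep]
    attr(out, "filter_report") <-
      new_filter_report(unique(out$gene_name), removed,
                        rep("control", length(removed)),
                        list())
    return(out)
  }
  check_matrix(x)
  if (is.null(control_type) || length(control_type) != nrow(x))
    stopf("'control_type' must annotate every row of the matrix")
  keep <- control_type == 0
  out <- x[keep, , drop = FALSE]
  removed <- unique(rownames(x)[!keep])
  attr(out, "filter_report") <-
    new_filter_report(unique(rownames(out)), removed,
                      rep("control", length(removed)), list())
  out
}

#' Gene-level detection flags
#'
#' Collapses spot-level `gIsGeneDetected` flags to the gene level: a gene is
#' detected on an array when any of its spots carries the detection flag
#' (if one probe of the probe set is detected, the gene is considered
#' detected). Control genes are excluded.
#'
#' @param dataset A `mir_probes` dataset.
#' @return Genes-by-arrays 0/1 integer matrix.
#' @export
gene_detection_flags <- function(dataset) {
  if (!inherits(dataset, "mir_probes")) stopf("'dataset' must be a mir_probes")
  keep <- dataset$control_type == 0L
  idx <- split(which(keep), dataset$gene_name[keep])
  f <- dataset$flags$detected
  out <- t(vapply(idx, function(i)
    apply(f[i, , drop = FALSE], 2L, max), integer(ncol(f))))
  if (ncol(f) == 1L)
    out <- matrix(out, ncol = 1L, dimnames = list(names(idx), colnames(f)))
  out
}

.check_groups <- function(groups, n_arrays) {
  if (length(groups) != n_arrays)
    stopf("'groups' must assign every array to a group")
  gs <- split(seq_len(n_arrays), groups)
  if (any(lengths(gs) == 0)) stopf("empty experimental group")
  gs
}

#' Filter genes on detection percentage
#'
#' A gene is retained when, in at least one experimental group, the
#' percentage of arrays on which it is detected is greater than or equal to
#' the limit `L`. For example with 4 replicates per group, requiring
#' detection in at least 3 replicates of some group corresponds to `L = 75`.
#'
#' @param flags Genes-by-arrays 0/1 matrix of detection flags (gene row
#'   names), e.g. from [gene_detection_flags()].
#' @param groups Vector assigning each array (column) to a group.
#' @param L Detection limit as a percentage in `[0, 100]`.
#' @return A `mir_filter_report` with `retained` and `removed` gene names.
#' @export
detection_filter <- function(flags, groups, L) {
  check_matrix(flags, "flags")
  if (!is.numeric(L) || length(L) != 1 || L < 0 || L > 100)
    stopf("L must be a percentage in [0, 100]")
  gs <- .check_groups(groups, ncol(flags))
  pct <- vapply(gs, function(cols)
    100 * rowMeans(flags[, cols, drop = FALSE] != 0), numeric(nrow(flags)))
  if (nrow(flags) == 1L) pct <- matrix(pct, nrow = 1L)
  best <- apply(pct, 1L, max)
  genes <- rownames(flags)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(flags)))
  keep <- best >= L
  new_filter_report(genes[keep], genes[!keep],
                    rep("not_detected", sum(!keep)),
                    list(L_detect = L))
}

#' Negative-control expression threshold
#'
#' Per-array expression threshold below which a signal is considered
#' indistinguishable from the negative controls: the mean of the array's
#' negative-control signals plus 1.5 times their standard deviation
#' (sample sd, n-1 denominator).
#'
#' @param negctrl_values List (one element per array) of numeric
#'   negative-control values, on the same scale as the expression matrix to
#'   be filtered; at least 2 values per array.
#' @return Named numeric vector of per-array thresholds.
#' @examples
#' negative_control_threshold(list(a1 = c(-1, 0, 1)))  # mean 0, sd 1 -> 1.5
#' @export
negative_control_threshold <- function(negctrl_values) {
  if (is.numeric(negctrl_values)) negctrl_values <- list(negctrl_values)
  vapply(negctrl_values, function(v) {
    if (length(v) < 2) stopf("need >= 2 negative-control values per array")
    mean(v) + 1.5 * stats::sd(v)
  }, 0)
}

#' Filter genes on expression above the negative-control threshold
#'
#' A gene is retained when, in at least one experimental group, the
#' percentage of that group's arrays where the gene's value exceeds the
#' array's threshold is greater than or equal to `L`. Thresholds must be on
#' the same (log2, normalized) scale as the expression matrix; a mismatch is
#' not detectable by the function.
#'
#' @param exprs A `mir_exprs` object or a genes-by-arrays matrix.
#' @param thresholds Per-array numeric thresholds (e.g. from
#'   [negative_control_threshold()]).
#' @param groups Vector assigning each array to a group.
#' @param L Percentage limit in `[0, 100]`.
#' @return A `mir_filter_report`.
#' @export
expression_filter <- function(exprs, thresholds, groups, L) {
  e <- if (inherits(exprs, "mir_exprs")) exprs$exprs else exprs
  check_matrix(e, "exprs")
  if (!is.numeric(L) || length(L) != 1 || L < 0 || L > 100)
    stopf("L must be a percentage in [0, 100]")
  if (length(thresholds) != ncol(e))
    stopf("one threshold per array is required")
  gs <- .check_groups(groups, ncol(e))
  above <- sweep(e, 2L, thresholds, `>`)
  pct <- vapply(gs, function(cols)
    100 * rowMeans(above[, cols, drop = FALSE]), numeric(nrow(e)))
  if (nrow(e) == 1L) pct <- matrix(pct, nrow = 1L)
  best <- apply(pct, 1L, max)
  genes <- rownames(e)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(e)))
  keep <- best >= L
  new_filter_report(genes[keep], genes[!keep],
                    rep("below_threshold", sum(!keep)),
                    list(L_expr = L, thresholds = thresholds))
}
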