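# The two pre-processing protocols: AFE total gene signal (TGS) and robust
# multiarray average (RMA).

new_mir_exprs <- function(exprs, targets, method, options, probe, negctrl) {
  out <- list(exprs = exprs, targets = targets,
              groups = stats::setNames(targets$GErep, targets$FileName),
              treatment = stats::setNames(targets$Treatment,
                                          targets$FileName),
              method = method, options = options, probe = probe,
              negctrl = negctrl)
  class(out) <- "mir_exprs"
  out
}

#' @export
print.mir_exprs <- function(x, ...) {
  cat(sprintf("microRNA expression matrix (mir_exprs, %s protocol)\n",
              x$method))
  cat(sprintf("  %d genes x %d arrays (log2 scale)\n", nrow(x$exprs),
              ncol(x$exprs)))
  opts <- paste(names(x$options), unlist(lapply(x$options, format)),
                sep = "=", collapse = ", ")
  cat("  options:", opts, "\n")
  invisible(x)
}

#' @export
dim.mir_exprs <- function(x) dim(x$exprs)

# Map values observed on an array through the monotone transform that
# normalization applied to that array (pre -> post), by interpolating the
# sorted pre/post value pairs. Values outside the observed range are clamped
# to the boundary transform (rule = 2).
.map_normalization <- function(pre, post, values) {
  o <- order(pre)
  stats::approx(pre[o], post[o], xout = values, rule = 2, ties = mean)$y
}

# representative probe per gene: lexicographically smallest probe name
.representative_probes <- function(probe_name, gene_name) {
  idx <- split(probe_name, gene_name)
  vapply(idx, function(p) sort(unique(p))[1], "")
}

#' TGS pre-processing protocol
#'
#' First protocol: uses the total gene signal computed by the AFE image
#' software. Steps: collapse the (spot-constant) TGS to one value per
#' microRNA gene, convert negative values to positive ones with
#' [correct_negative_tgs()], log2 transform, and normalize between arrays by
#' the quantile (default) or scale method. Control genes are excluded;
#' negative-control processed signals are carried through the same
#' correction, log transform and per-array normalization mapping and stored
#' for expression-threshold filtering.
#'
#' @param dataset A `mir_probes` dataset with `total_gene_signal` present.
#' @param normalization `"quantile"` (default), `"scale"` or `"none"`.
#' @param negative_method `"half"` or `"offset"` (see
#'   [correct_negative_tgs()]).
#' @param offset Offset for the offset correction method.
#' @return A `mir_exprs` object: log2 genes-by-arrays matrix `exprs`, the
#'   target table, group codes, per-gene representative probes, and `negctrl`
#'   (per-array list of negative-control values on the final scale).
#' @export
tgs_pipeline <- function(dataset, normalization = c("quantile", "scale",
                                                    "none"),
                         negative_method = c("half", "offset"), offset = 0) {
  if (!inherits(dataset, "mir_probes")) stopf("'dataset' must be a mir_probes")
  normalization <- match.arg(normalization)
  negative_method <- match.arg(negative_method)
  if (anyNA(dataset$total_gene_signal))
    stopf("total_gene_signal is not fully populated")
  gene_rows <- dataset$control_type == 0L
  idx <- split(which(gene_rows), dataset$gene_name[gene_rows])
  tgs <- matrix(NA_real_, length(idx), ncol(dataset$total_gene_signal),
                dimnames = list(names(idx),
                                colnames(dataset$total_gene_signal)))
  for (g in names(idx)) {
    sub <- dataset$total_gene_signal[idx[[g]], , drop = FALSE]
    rng <- apply(sub, 2L, function(v) diff(range(v)))
    if (any(rng > 1e-8 * pmax(1, abs(sub[1, ]))))
      stopf("inconsistent total gene signal within spots of gene %s", g)
    tgs[g, ] <- sub[1L, ]
  }
  corrected <- correct_negative_tgs(tgs, negative_method, offset)
  le <- log2(corrected)

  neg_rows <- dataset$control_type == -1L
  negctrl_raw <- dataset$processed_signal[neg_rows, , drop = FALSE]
  if (negative_method == "half") {
    negc <- correct_negative_tgs(negctrl_raw, "half")
  } else {
    negc <- pmax(negctrl_raw + abs(min(tgs)) + offset, 0.5)
  }
  lnc <- log2(negc)

  norm <- switch(normalization,
                 quantile = quantile_normalize(le),
                 scale = scale_normalize(le),
                 none = le)
  negctrl <- lapply(seq_len(ncol(le)), function(j)
    if (nrow(lnc) > 0) .map_normalization(le[, j], norm[, j], lnc[, j])
    else numeric(0))
  names(negctrl) <- colnames(le)

  new_mir_exprs(norm, dataset$targets, method = "tgs",
                options = list(normalization = normalization,
                               negative_method = negative_method,
                               offset = offset),
                probe = .representative_probes(
                  dataset$probe_name[gene_rows],
                  dataset$gene_name[gene_rows]),
                negctrl = negctrl)
}

#' RMA pre-processing protocol
#'
#' Second protocol: summarizes the raw mean signal with the robust multiarray
#' average. Steps, in order, on non-control spots: 1) optional background
#' correction with the normal + exponential convolution model (fitted per
#' array, [normexp_fit()]/[normexp_adjust()]); 2) quantile normalization
#' between arrays; 3) log2 transformation; 4) median of replicated probes
#' ([median_replicate_probes()]); 5) median-polish summarization into a
#' single gene measure ([summarize_rma()]). Background correction defaults to
#' off, which reduces signal variability at low intensities. Negative-control
#' mean signals are carried through the same per-array background and
#' normalization mappings for threshold filtering.
#'
#' @param dataset A `mir_probes` dataset with `mean_signal` present.
#' @param background `"off"` (default) or `"on"`.
#' @param normalization `"quantile"` (default) or `"none"`.
#' @return A `mir_exprs` object (see [tgs_pipeline()]).
#' @export
rma_pipeline <- function(dataset, background = c("off", "on"),
                         normalization = c("quantile", "none")) {
  if (!inherits(dataset, "mir_probes")) stopf("'dataset' must be a mir_probes")
  background <- match.arg(background)
  normalization <- match.arg(normalization)
  gene_rows <- dataset$control_type == 0L
  neg_rows <- dataset$control_type == -1L
  x <- dataset$mean_signal[gene_rows, , drop = FALSE]
  nc <- dataset$mean_signal[neg_rows, , drop = FALSE]

  # step 1: optional normexp background correction, per array
  if (background == "on") {
    for (j in seq_len(ncol(x))) {
      par <- normexp_fit(x[, j])
      x[, j] <- normexp_adjust(x[, j], par)
      if (nrow(nc) > 0) nc[, j] <- normexp_adjust(nc[, j], par)
    }
  }
  # step 2: quantile normalization on the linear signal
  if (normalization == "quantile") {
    xn <- quantile_normalize(x)
    if (nrow(nc) > 0)
      for (j in seq_len(ncol(x)))
        nc[, j] <- .map_normalization(x[, j], xn[, j], nc[, j])
    x <- xn
  }
  if (any(x <= 0))
    stopf("non-positive signals before log2; use background correction or check input")
  # step 3: log2
  lx <- log2(x)
  lnc <- if (nrow(nc) > 0) log2(pmax(nc, .Machine$double.xmin)) else nc
  # step 4: median over replicate spots per probe
  sub <- list(probe_name = dataset$probe_name[gene_rows],
              gene_name = dataset$gene_name[gene_rows],
              control_type = dataset$control_type[gene_rows])
  class(sub) <- "mir_probes"
  probes <- median_replicate_probes(sub, signal = lx)
  # step 5: median-polish summarization per gene
  exprs <- summarize_rma(probes$values, probes$gene)

  negctrl <- lapply(seq_len(ncol(lx)), function(j)
    if (nrow(nc) > 0) lnc[, j] else numeric(0))
  names(negctrl) <- colnames(dataset$mean_signal)
  new_mir_exprs(exprs, dataset$targets, method = "rma",
                options = list(background = background,
                               normalization = normalization),
                probe = .representative_probes(
                  dataset$probe_name[gene_rows],
                  dataset$gene_name[gene_rows]),
                negctrl = negctrl)
}

#' Write an expression matrix as tab-delimited text
#'
#' Serializes a `mir_exprs` object: first column `Gene`, one column per
#' array. Provenance (protocol and options) is written to a sidecar
#' `<path>.meta` file.
#'
#' @param exprs A `mir_exprs` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(exprs, path) {
  if (!inherits(exprs, "mir_exprs")) stopf("'exprs' must be a mir_exprs")
  tab <- data.frame(Gene = rownames(exprs$exprs), exprs$exprs,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(sprintf("protocol\t%s", exprs$method),
            vapply(names(exprs$options), function(k)
              sprintf("%s\t%s", k, format(exprs$options[[k]])), ""))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}
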