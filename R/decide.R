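# Significance calls, per-contrast result tables and report files.

#' Call significant genes per contrast
#'
#' Two selection strategies are offered. `separated`: each contrast's
#' moderated-t p-values are adjusted independently (`BH` or `none`) and a
#' gene/contrast cell is called significant when the adjusted p-value is
#' below `cutoff`, signed by the contrast estimate. `nestedF`: genes are
#' first screened with the BH-adjusted moderated F-statistic at `cutoff`,
#' then, within screened genes, contrasts are called at unadjusted t
#' p-values below `cutoff` (a simplification of gene-wise closed testing).
#'
#' @param stats A `mir_ebayes` object from [moderate()].
#' @param method `"separated"` or `"nestedF"`.
#' @param adjust `"BH"` or `"none"` (per-contrast adjustment of t p-values in
#'   the separated method; the nestedF screen always uses BH on F).
#' @param cutoff Significance cutoff in `(0, 1]` applied to adjusted
#'   p-values.
#' @return Genes-by-contrasts integer matrix with values -1/0/+1, with
#'   attributes `method`, `adjust`, `cutoff`.
#' @export
decide_tests <- function(stats, method = c("separated", "nestedF"),
                         adjust = c("BH", "none"), cutoff = 0.05) {
  if (!inherits(stats, "mir_ebayes")) stopf("'stats' must come from moderate()")
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1)
    stopf("cutoff must be in (0, 1]")
  p <- stats$p_value
  dec <- matrix(0L, nrow(p), ncol(p), dimnames = dimnames(p))
  if (method == "separated") {
    for (k in seq_len(ncol(p))) {
      padj <- if (adjust == "BH") bh_adjust(p[, k]) else p[, k]
      sig <- padj < cutoff
      dec[sig, k] <- as.integer(sign(stats$coefficients[sig, k]))
    }
  } else {
    keep <- bh_adjust(stats$F_p) < cutoff
    for (k in seq_len(ncol(p))) {
      sig <- keep & p[, k] < cutoff
      dec[sig, k] <- as.integer(sign(stats$coefficients[sig, k]))
    }
  }
  attr(dec, "method") <- method
  attr(dec, "adjust") <- adjust
  attr(dec, "cutoff") <- cutoff
  dec
}

#' Per-contrast result table
#'
#' Lists every analyzed gene with its statistics for one contrast, sorted by
#' p-value. Columns are exactly `Probe` (a representative probe of the gene),
#' `Gene`, `M` (log2 fold change: the contrast estimate), `A` (mean log2
#' intensity), `t` (moderated t), `pval`, `adj.pval` (p-value adjusted by the
#' selected method: identical to `pval` under `"none"` and to `fdr.pval`
#' under `"BH"`), and `fdr.pval` (always the BH-adjusted p-value).
#'
#' @param stats A `mir_ebayes` object.
#' @param decisions Decision matrix from [decide_tests()] (provides the
#'   adjustment method).
#' @param exprs The `mir_exprs` object the fit was computed from (provides
#'   representative probes).
#' @param contrast Contrast name or column index.
#' @return Data frame with the eight columns above, one row per analyzed
#'   gene.
#' @export
significant_table <- function(stats, decisions, exprs, contrast) {
  if (!inherits(stats, "mir_ebayes")) stopf("'stats' must come from moderate()")
  if (is.character(contrast)) {
    if (!contrast %in% colnames(stats$t))
      stopf("unknown contrast '%s'", contrast)
    k <- match(contrast, colnames(stats$t))
  } else k <- contrast
  adjust <- attr(decisions, "adjust")
  if (is.null(adjust)) adjust <- "BH"
  genes <- stats$genes
  probes <- if (inherits(exprs, "mir_exprs")) exprs$probe[genes]
  else stats::setNames(genes, genes)
  pval <- stats$p_value[, k]
  fdr <- bh_adjust(pval)
  tab <- data.frame(Probe = unname(probes), Gene = genes,
                    M = unname(stats$coefficients[, k]),
                    A = unname(stats$Amean),
                    t = unname(stats$t[, k]),
                    pval = unname(pval),
                    adj.pval = unname(if (adjust == "BH") fdr else pval),
                    fdr.pval = unname(fdr),
                    stringsAsFactors = FALSE, check.names = FALSE)
  tab[order(tab$pval), , drop = FALSE]
}

.mirbase_url <- "http://microrna.sanger.ac.uk/"

#' Write per-contrast reports
#'
#' For each contrast writes: the full tab-delimited result table
#' (`<contrast>_all.txt`, every analyzed gene), an HTML file
#' (`<contrast>_significant.html`) listing only the significant genes with
#' hyperlinks to the miRBase registry, and an MA plot
#' (`<contrast>_ma.png`) highlighting the significant genes. The decision
#' matrix is written once as `decisions.txt`.
#'
#' @param tables Named list of result tables from [significant_table()], one
#'   per contrast.
#' @param decisions Decision matrix from [decide_tests()].
#' @param out_dir Output directory.
#' @return Invisibly, the character vector of files written.
#' @export
write_reports <- function(tables, decisions, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (cn in names(tables)) {
    tab <- tables[[cn]]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", cn)
    tpath <- file.path(out_dir, paste0(safe, "_all.txt"))
    utils::write.table(tab, tpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    sig_genes <- rownames(decisions)[decisions[, cn] != 0]
    sig <- tab[tab$Gene %in% sig_genes, , drop = FALSE]
    hpath <- file.path(out_dir, paste0(safe, "_significant.html"))
    items <- if (nrow(sig) > 0)
      sprintf('  <li><a href="%squery.pl?terms=%s">%s</a> (M = %.3f, adj.p = %.3g)</li>',
              .mirbase_url, utils::URLencode(sig$Gene, reserved = TRUE),
              sig$Gene, sig$M, sig$adj.pval)
    else character(0)
    writeLines(c("<html><head><title>Significant microRNAs</title></head>",
                 "<body>",
                 sprintf("<h1>Contrast %s</h1>", cn),
                 sprintf("<p>%d significant microRNA(s)</p>", nrow(sig)),
                 "<ul>", items, "</ul>", "</body></html>"), hpath)
    mpath <- file.path(out_dir, paste0(safe, "_ma.png"))
    grDevices::png(mpath, width = 700, height = 500)
    is_sig <- tab$Gene %in% sig_genes
    graphics::plot(tab$A, tab$M, pch = 16, cex = 0.5,
                   col = ifelse(is_sig, "red", "grey40"),
                   xlab = "A (mean log2 intensity)",
                   ylab = "M (log2 fold change)",
                   main = sprintf("Contrast %s", cn))
    graphics::abline(h = 0, col = "blue")
    grDevices::dev.off()
    files <- c(files, tpath, hpath, mpath)
  }
  dpath <- file.path(out_dir, "decisions.txt")
  utils::write.table(data.frame(Gene = rownames(decisions), decisions,
                                check.names = FALSE),
                     dpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, dpath))
}
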