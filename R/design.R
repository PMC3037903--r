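# Synthetic array design emulating the Agilent Human miRNA Microarray v2.0
# composition.

#' Build a microRNA array design
#'
#' Constructs the probe layout of a single-color Agilent-style microRNA
#' array. Every standard microRNA gene is interrogated by 16 spots, spread
#' over 1-4 distinct probes: 2-probe genes use 8 replicates per probe,
#' 4-probe genes 4 replicates per probe, 3-probe genes the closest-to-even
#' split (6,5,5), and single-probe genes one probe replicated 16 times.
#' Positive controls use 4 probes replicated to 20 spots; negative-control
#' spots are spread evenly over `neg_control_probes` probes sharing one
#' `NegativeControl` gene.
#'
#' The defaults reproduce the Human miRNA Microarray v2.0 composition:
#' 723 human plus 76 viral microRNA genes, partitioned as 362 two-probe,
#' 45 three-probe, 390 four-probe and 2 single-probe genes. Gene names are
#' synthetic (`hsa-miR-sim-*`, `vir-miR-sim-*`).
#'
#' @param n_1probe,n_2probe,n_3probe,n_4probe Number of microRNA genes
#'   interrogated by 1, 2, 3 and 4 distinct probes.
#' @param n_human Number of genes labelled as human; the remainder are
#'   labelled viral. Must not exceed the total gene count.
#' @param n_pos_controls Number of positive-control genes (20 spots each).
#' @param n_neg_spots Total number of negative-control spots.
#' @param neg_control_probes Number of distinct negative-control probes.
#' @return An object of class `mir_design`: a data frame with one row per
#'   gene and columns `gene_name`, `species_class`
#'   (human/viral/pos_control/neg_control), `control_type`, and list columns
#'   `probe_names` and `replicates`.
#' @examples
#' d <- make_array_design()
#' sum(vapply(d$replicates[d$control_type == 0], sum, 1)) # 799 * 16 spots
#' @export
make_array_design <- function(n_1probe = 2, n_2probe = 362, n_3probe = 45,
                              n_4probe = 390, n_human = 723,
                              n_pos_controls = 10, n_neg_spots = 200,
                              neg_control_probes = 4) {
  for (v in c(n_1probe, n_2probe, n_3probe, n_4probe, n_human,
              n_pos_controls, n_neg_spots, neg_control_probes))
    if (!is_count(v)) stopf("design counts must be nonnegative integers")
  n_genes <- n_1probe + n_2probe + n_3probe + n_4probe
  if (n_human > n_genes)
    stopf("n_human (%d) exceeds total gene count (%d)", n_human, n_genes)
  if (n_genes == 0 && n_pos_controls == 0 && n_neg_spots == 0)
    stopf("empty design")
  rep_scheme <- list(`1` = 16L, `2` = c(8L, 8L), `3` = c(6L, 5L, 5L),
                     `4` = c(4L, 4L, 4L, 4L))
  n_probes_per_gene <- rep(c(2L, 3L, 4L, 1L),
                           c(n_2probe, n_3probe, n_4probe, n_1probe))
  species <- rep(c("human", "viral"), c(n_human, n_genes - n_human))
  gene_name <- character(n_genes)
  gene_name[species == "human"] <-
    sprintf("hsa-miR-sim-%04d", seq_len(n_human))
  gene_name[species == "viral"] <-
    sprintf("vir-miR-sim-%03d", seq_len(n_genes - n_human))
  rows <- vector("list", n_genes + n_pos_controls +
                   (if (n_neg_spots > 0) 1L else 0L))
  for (g in seq_len(n_genes)) {
    np <- n_probes_per_gene[g]
    rows[[g]] <- list(gene_name = gene_name[g], species_class = species[g],
                      control_type = 0L,
                      probe_names = sprintf("%s_P%d", gene_name[g],
                                            seq_len(np)),
                      replicates = rep_scheme[[as.character(np)]])
  }
  for (k in seq_len(n_pos_controls)) {
    nm <- sprintf("PosControl-sim-%02d", k)
    rows[[n_genes + k]] <- list(gene_name = nm, species_class = "pos_control",
                                control_type = 1L,
                                probe_names = sprintf("%s_P%d", nm, 1:4),
                                replicates = c(5L, 5L, 5L, 5L))
  }
  if (n_neg_spots > 0) {
    base <- n_neg_spots %/% neg_control_probes
    extra <- n_neg_spots %% neg_control_probes
    reps <- rep(base, neg_control_probes) +
      rep(c(1L, 0L), c(extra, neg_control_probes - extra))
    rows[[length(rows)]] <- list(gene_name = "NegativeControl",
                                 species_class = "neg_control",
                                 control_type = -1L,
                                 probe_names = sprintf("NegControl_P%d",
                                                       seq_len(neg_control_probes)),
                                 replicates = as.integer(reps))
  }
  d <- data.frame(gene_name = vapply(rows, `[[`, "", "gene_name"),
                  species_class = vapply(rows, `[[`, "", "species_class"),
                  control_type = vapply(rows, `[[`, 1L, "control_type"),
                  stringsAsFactors = FALSE)
  d$probe_names <- lapply(rows, `[[`, "probe_names")
  d$replicates <- lapply(rows, `[[`, "replicates")
  probes <- unlist(d$probe_names)
  if (anyDuplicated(probes)) stopf("probe names are not globally unique")
  class(d) <- c("mir_design", "data.frame")
  d
}

#' @export
print.mir_design <- function(x, ...) {
  cat("microRNA array design (mir_design)\n")
  tab <- table(x$species_class)
  cat("  genes by class:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  %d distinct probes, %d spots\n",
              length(unlist(x$probe_names)),
              sum(unlist(x$replicates))))
  invisible(x)
}
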