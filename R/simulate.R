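# Simulation of probe-level AFE datasets with known ground truth.

#' Simulation configuration
#'
#' Collects the parameters governing [simulate_probe_signals()]. The signal
#' model is multiplicative on the raw scale: the mean signal of spot `s`
#' (gene g, probe p) on array `j` is
#' `2^(baseline_g + effect_{g, group(j)} + affinity_p + e_sj)` with
#' `e_sj ~ N(0, noise_sd^2)`. Probe affinities are drawn `N(0, affinity_sd^2)`
#' and centered to sum to zero within each gene, matching the additive
#' probe-effect model that median-polish summarization assumes. Negative
#' controls are drawn on the linear scale from `N(negctrl_mean,
#' negctrl_sd^2)` (floored at `negctrl_floor`), emulating near-background
#' spots. The background used by the image software is emulated as a
#' per-array constant plus a small linear spatial gradient over spot index.
#'
#' @param groups Character vector of treatment labels, one per array, in
#'   array order. The default is the three-treatment, two-subject paired
#'   layout (`A,A,B,B,C,C`).
#' @param subjects Optional covariate (same length as `groups`) recorded as a
#'   `Subject` column of the target table.
#' @param baseline_mean,baseline_sd Mean and sd of per-gene baseline log2
#'   abundances (drawn once per gene).
#' @param affinity_sd Sd of per-probe affinity terms (log2 scale) before
#'   within-gene centering.
#' @param noise_sd Sd of the spot-level log2 measurement noise. Must be
#'   nonnegative; 0 yields deterministic, replicate-identical signals.
#' @param spikes Optional data frame with columns `gene`, `group`, `effect`
#'   giving log2 effects added to the named gene in the named group.
#' @param negctrl_mean,negctrl_sd,negctrl_floor Linear-scale location, spread
#'   and floor of negative-control mean signals.
#' @param pos_baseline Log2 baseline of positive-control genes.
#' @param bg_base,bg_gradient Linear-scale background constant and total
#'   gradient amplitude across the array surface (`gBGUsed`).
#' @param detect_k Detection multiple: a gene is flagged detected on an array
#'   when its maximum probe-level background-subtracted signal exceeds
#'   `detect_k` times the spread of the negative controls on that array.
#' @param saturation_level Linear signal above which a spot is flagged
#'   saturated.
#' @param seed Mandatory integer random seed; identical seeds give
#'   byte-identical datasets.
#' @return A list of class `mir_sim_config`.
#' @export
simulation_config <- function(groups = c("A", "A", "B", "B", "C", "C"),
                              subjects = rep(1:2, length.out = length(groups)),
                              baseline_mean = 8, baseline_sd = 2,
                              affinity_sd = 0.5, noise_sd = 0.2,
                              spikes = NULL,
                              negctrl_mean = 40, negctrl_sd = 8,
                              negctrl_floor = 1,
                              pos_baseline = 12,
                              bg_base = 30, bg_gradient = 5,
                              detect_k = 3, saturation_level = 62000,
                              seed) {
  if (missing(seed) || !is_count(abs(seed))) stopf("a fixed integer seed is mandatory")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stopf("noise_sd must be nonnegative")
  if (length(groups) < 1) stopf("at least one array is required")
  if (!is.null(spikes)) {
    if (!is.data.frame(spikes) ||
        !all(c("gene", "group", "effect") %in% names(spikes)))
      stopf("spikes must be a data frame with columns gene, group, effect")
    if (!all(spikes$group %in% groups))
      stopf("spike groups must be among the array groups")
  }
  cfg <- list(groups = as.character(groups), subjects = subjects,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              affinity_sd = affinity_sd, noise_sd = noise_sd,
              spikes = spikes, negctrl_mean = negctrl_mean,
              negctrl_sd = negctrl_sd, negctrl_floor = negctrl_floor,
              pos_baseline = pos_baseline, bg_base = bg_base,
              bg_gradient = bg_gradient, detect_k = detect_k,
              saturation_level = saturation_level, seed = as.integer(seed))
  class(cfg) <- "mir_sim_config"
  cfg
}

#' Simulate probe-level signals for an array design
#'
#' Draws a complete probe-level dataset (raw mean signals, background,
#' background-subtracted processed signals, quality flags and AFE-style
#' total probe/gene summaries) under the model described in
#' [simulation_config()]. The configured ground-truth effect table is
#' attached as the `truth` component.
#'
#' @param design A `mir_design` from [make_array_design()].
#' @param config A `mir_sim_config` from [simulation_config()].
#' @return A `mir_probes` dataset (see [assemble_dataset()]) with a `truth`
#'   component: list of `baselines` (named per-gene log2 means), `effects`
#'   (gene x group log2 effect matrix) and `affinities` (named per-probe
#'   log2 affinities).
#' @export
simulate_probe_signals <- function(design, config) {
  if (!inherits(design, "mir_design")) stopf("'design' must be a mir_design")
  if (!inherits(config, "mir_sim_config"))
    stopf("'config' must come from simulation_config()")
  set.seed(config$seed)
  n_arrays <- length(config$groups)
  glev <- unique(config$groups)

  # spot layout: genes in design order, probes in order, replicates contiguous
  spot_gene_idx <- rep(seq_len(nrow(design)),
                       vapply(design$replicates, sum, 1L))
  probe_per_gene <- design$probe_names
  spot_probe <- unlist(mapply(function(p, r) rep(p, r), design$probe_names,
                              design$replicates, SIMPLIFY = FALSE),
                       use.names = FALSE)
  n_spots <- length(spot_probe)
  spot_gene <- design$gene_name[spot_gene_idx]
  spot_ct <- design$control_type[spot_gene_idx]

  # per-gene baselines
  is_gene <- design$control_type == 0L
  is_pos <- design$control_type == 1L
  is_neg <- design$control_type == -1L
  baselines <- numeric(nrow(design))
  baselines[is_gene] <- stats::rnorm(sum(is_gene), config$baseline_mean,
                                     config$baseline_sd)
  baselines[is_pos] <- config$pos_baseline +
    stats::rnorm(sum(is_pos), 0, 0.3)
  names(baselines) <- design$gene_name

  # zero-sum probe affinities within each gene
  affinities <- unlist(lapply(seq_len(nrow(design)), function(g) {
    np <- length(design$probe_names[[g]])
    if (design$control_type[g] != 0L || np == 1L) return(rep(0, np))
    a <- stats::rnorm(np, 0, config$affinity_sd)
    a - mean(a)
  }), use.names = FALSE)
  names(affinities) <- unlist(design$probe_names)

  # group effects
  effects <- matrix(0, nrow(design), length(glev),
                    dimnames = list(design$gene_name, glev))
  if (!is.null(config$spikes)) {
    for (i in seq_len(nrow(config$spikes))) {
      g <- config$spikes$gene[i]
      if (!g %in% design$gene_name) stopf("spike gene %s not in design", g)
      effects[g, config$spikes$group[i]] <-
        effects[g, config$spikes$group[i]] + config$spikes$effect[i]
    }
  }

  bg_profile <- if (n_spots > 1)
    config$bg_base + config$bg_gradient * (seq_len(n_spots) - 1) / (n_spots - 1)
  else rep(config$bg_base, n_spots)

  mean_signal <- matrix(NA_real_, n_spots, n_arrays)
  neg_spots <- spot_ct == -1L
  for (j in seq_len(n_arrays)) {
    lg <- baselines[spot_gene_idx] +
      effects[cbind(spot_gene_idx, match(config$groups[j], glev))] +
      affinities[spot_probe] +
      (if (config$noise_sd > 0) stats::rnorm(n_spots, 0, config$noise_sd)
       else 0)
    v <- 2^lg
    if (any(neg_spots))
      v[neg_spots] <- pmax(stats::rnorm(sum(neg_spots), config$negctrl_mean,
                                        config$negctrl_sd),
                           config$negctrl_floor)
    mean_signal[, j] <- v
  }
  file_names <- sprintf("array_%02d.txt", seq_len(n_arrays))
  colnames(mean_signal) <- file_names
  bg_used <- matrix(rep(bg_profile, n_arrays), n_spots, n_arrays,
                    dimnames = list(NULL, file_names))
  processed <- mean_signal - bg_used

  targets <- data.frame(FileName = file_names, Treatment = config$groups,
                        GErep = match(config$groups, glev),
                        stringsAsFactors = FALSE)
  if (!is.null(config$subjects)) targets$Subject <- config$subjects
  class(targets) <- c("mir_targets", "data.frame")

  ds <- list(mean_signal = mean_signal, processed_signal = processed,
             total_probe_signal = matrix(NA_real_, n_spots, n_arrays,
                                         dimnames = list(NULL, file_names)),
             total_gene_signal = matrix(NA_real_, n_spots, n_arrays,
                                        dimnames = list(NULL, file_names)),
             bg_median = bg_used * 0.8,
             bg_used = bg_used,
             flags = list(
               detected = matrix(0L, n_spots, n_arrays,
                                 dimnames = list(NULL, file_names)),
               saturated = matrix(as.integer(mean_signal >
                                               config$saturation_level),
                                  n_spots, n_arrays,
                                  dimnames = list(NULL, file_names)),
               nonunif_outlier = matrix(0L, n_spots, n_arrays,
                                        dimnames = list(NULL, file_names)),
               popn_outlier = matrix(0L, n_spots, n_arrays,
                                     dimnames = list(NULL, file_names))),
             probe_name = spot_probe, gene_name = spot_gene,
             control_type = spot_ct, targets = targets)
  class(ds) <- "mir_probes"
  ds <- compute_afe_summaries(ds)

  # detection flags: gene detected when its brightest probe-level
  # background-subtracted signal exceeds detect_k x negative-control spread
  probe_idx <- split(seq_len(n_spots), spot_probe)
  gene_probe <- split(unlist(design$probe_names),
                      rep(design$gene_name,
                          lengths(design$probe_names)))
  for (j in seq_len(n_arrays)) {
    noise_scale <- if (any(neg_spots)) stats::sd(processed[neg_spots, j]) else 0
    if (!is.finite(noise_scale)) noise_scale <- 0
    probe_level <- vapply(probe_idx, function(i) mean(processed[i, j]), 0)
    gene_max <- vapply(gene_probe, function(p) max(probe_level[p]), 0)
    det_genes <- names(gene_max)[gene_max > config$detect_k * noise_scale]
    ds$flags$detected[spot_gene %in% det_genes, j] <- 1L
  }

  ds$truth <- list(baselines = baselines, effects = effects,
                   affinities = affinities, config = config)
  ds
}

#' Fill AFE total probe/gene summaries
#'
#' Recomputes the two AFE summary columns from the background-subtracted
#' processed signal. The total probe signal (TPS) of a probe on an array is
#' the average of its replicate processed signals multiplied by the number of
#' replicates, written to every replicate spot; the total gene signal (TGS)
#' of a gene is the sum of its distinct probes' TPS values, written to every
#' spot of the gene.
#'
#' @param dataset A `mir_probes` dataset with `processed_signal` present.
#' @return The dataset with `total_probe_signal` and `total_gene_signal`
#'   filled.
#' @examples
#' # a gene with 2 probes x 8 replicates, all processed signals 10:
#' # TPS = 10 * 8 = 80 per probe, TGS = 160
#' @export
compute_afe_summaries <- function(dataset) {
  if (!inherits(dataset, "mir_probes")) stopf("'dataset' must be a mir_probes")
  n_spots <- length(dataset$probe_name)
  if (n_spots == 0) stopf("dataset has no spots")
  x <- dataset$processed_signal
  probe_idx <- split(seq_len(n_spots), dataset$probe_name)
  gene_of_probe <- vapply(probe_idx,
                          function(i) dataset$gene_name[i[1]], "")
  tps_spot <- matrix(NA_real_, n_spots, ncol(x),
                     dimnames = dimnames(x))
  tps_probe <- matrix(NA_real_, length(probe_idx), ncol(x))
  for (j in seq_len(ncol(x))) {
    tpj <- vapply(probe_idx, function(i) mean(x[i, j]) * length(i), 0)
    tps_probe[, j] <- tpj
    for (k in seq_along(probe_idx)) tps_spot[probe_idx[[k]], j] <- tpj[k]
  }
  gene_rows <- split(seq_along(probe_idx), gene_of_probe)
  tgs_spot <- matrix(NA_real_, n_spots, ncol(x), dimnames = dimnames(x))
  for (g in names(gene_rows)) {
    spots_g <- which(dataset$gene_name == g)
    if (length(spots_g) == 0) stopf("gene %s has zero spots", g)
    for (j in seq_len(ncol(x)))
      tgs_spot[spots_g, j] <- sum(tps_probe[gene_rows[[g]], j])
  }
  dataset$total_probe_signal <- tps_spot
  dataset$total_gene_signal <- tgs_spot
  dataset
}

#' Write a dataset as AFE-format files
#'
#' Serializes every array of a probe-level dataset to a tab-delimited AFE
#' feature file readable by [read_afe_features()], plus the matching target
#' file (`targets.txt`). Two dialects can be written: `flat` (one header row)
#' and `blocked` (vendor-style `TYPE`/`FEPARAMS`/`STATS`/`FEATURES` blocks).
#' Numbers are written with 17 significant digits so the round trip is
#' bit-exact.
#'
#' @param dataset A `mir_probes` dataset.
#' @param out_dir Output directory (created if absent).
#' @param dialect `"flat"` or `"blocked"`.
#' @return Invisibly, a list with `files` (per-array paths) and `targets`
#'   (target-file path).
#' @export
write_afe_files <- function(dataset, out_dir, dialect = c("flat", "blocked")) {
  if (!inherits(dataset, "mir_probes")) stopf("'dataset' must be a mir_probes")
  if (length(dataset$probe_name) == 0) stopf("empty dataset")
  dialect <- match.arg(dialect)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory %s", out_dir)
  num <- function(x) sprintf("%.17g", x)
  files <- character(nrow(dataset$targets))
  for (j in seq_len(nrow(dataset$targets))) {
    tab <- data.frame(
      ProbeName = dataset$probe_name,
      GeneName = dataset$gene_name,
      ControlType = as.character(dataset$control_type),
      gMeanSignal = num(dataset$mean_signal[, j]),
      gProcessedSignal = num(dataset$processed_signal[, j]),
      gTotalProbeSignal = num(dataset$total_probe_signal[, j]),
      gTotalGeneSignal = num(dataset$total_gene_signal[, j]),
      gIsGeneDetected = as.character(dataset$flags$detected[, j]),
      gIsSaturated = as.character(dataset$flags$saturated[, j]),
      gIsFeatNonUnifOL = as.character(dataset$flags$nonunif_outlier[, j]),
      gIsFeatPopnOL = as.character(dataset$flags$popn_outlier[, j]),
      gBGMedianSignal = num(dataset$bg_median[, j]),
      gBGUsed = num(dataset$bg_used[, j]),
      stringsAsFactors = FALSE, check.names = FALSE)
    path <- file.path(out_dir, dataset$targets$FileName[j])
    if (dialect == "flat") {
      utils::write.table(tab, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else {
      .write_afe_blocked(tab, path)
    }
    files[j] <- path
  }
  tpath <- file.path(out_dir, "targets.txt")
  utils::write.table(as.data.frame(dataset$targets), tpath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(files = files, targets = tpath))
}

.write_afe_blocked <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste(..., sep = "\t", collapse = "\t"), con)
  # header blocks mimicking the vendor layout; content is nominal
  writeLines(c(paste(c("TYPE", "text", "text"), collapse = "\t"),
               paste(c("FEPARAMS", "Protocol", "Scanner"), collapse = "\t"),
               paste(c("DATA", "miRNA_sim", "simulated"), collapse = "\t"),
               "*",
               paste(c("TYPE", "float"), collapse = "\t"),
               paste(c("STATS", "gDarkOffsetAverage"), collapse = "\t"),
               paste(c("DATA", "0"), collapse = "\t"),
               "*"), con)
  writeLines(paste(c("TYPE", rep("text", ncol(tab))), collapse = "\t"), con)
  writeLines(paste(c("FEATURES", names(tab)), collapse = "\t"), con)
  body <- do.call(paste, c(list("DATA"), tab, list(sep = "\t")))
  writeLines(body, con)
  writeLines("*", con)
}

#' Simulate and write a complete AFE dataset
#'
#' Convenience wrapper: simulates a dataset for a design and configuration,
#' writes the AFE files, the target file and the ground-truth effect table
#' (`truth.txt`, tab-delimited) to `out_dir`.
#'
#' @inheritParams simulate_probe_signals
#' @inheritParams write_afe_files
#' @return Invisibly, a list with `dataset`, `files`, `targets` and `truth`
#'   (path of the truth table).
#' @export
simulate_afe_dataset <- function(design = make_array_design(),
                                 config = simulation_config(seed = 1L),
                                 out_dir, dialect = "flat") {
  ds <- simulate_probe_signals(design, config)
  paths <- write_afe_files(ds, out_dir, dialect = dialect)
  eff <- ds$truth$effects
  truth_tab <- data.frame(gene = rep(rownames(eff), ncol(eff)),
                          group = rep(colnames(eff), each = nrow(eff)),
                          effect = as.vector(eff),
                          stringsAsFactors = FALSE)
  truth_tab <- truth_tab[truth_tab$effect != 0, , drop = FALSE]
  tpath <- file.path(out_dir, "truth.txt")
  utils::write.table(truth_tab, tpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  msg(sprintf("simulated %d arrays x %d spots into %s",
              nrow(ds$targets), length(ds$probe_name), out_dir))
  invisible(list(dataset = ds, files = paths$files, targets = paths$targets,
                 truth = tpath))
}
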