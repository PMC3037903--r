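# Whole-workflow orchestration from a configuration list or YAML file.

#' Build a pipeline configuration
#'
#' Assembles (and validates) the configuration consumed by
#' [run_pipeline()]. Any part can be overridden; defaults give the
#' recommended workflow: RMA without background correction, quantile
#' normalization, detection and expression filters at L = 75, separated
#' BH-adjusted tests at cutoff 0.05.
#'
#' @param targets Path to the target file.
#' @param data_dir Directory holding the AFE feature files named in the
#'   target file.
#' @param out_dir Output directory for all artifacts.
#' @param protocol `"rma"` or `"tgs"`.
#' @param background RMA background correction, `"off"` or `"on"`.
#' @param normalization `"quantile"`, `"scale"` (TGS only) or `"none"`.
#' @param negative_method,offset Negative-TGS handling (TGS protocol).
#' @param filter_detect,filter_expr Enable the detection / expression
#'   filters.
#' @param limit_detect,limit_expr Percentage limits L for the two filters.
#' @param factors Target-table columns entering the design matrix (first =
#'   treatment).
#' @param contrasts Character contrasts such as `"B-A"`; default compares
#'   every non-reference treatment to the first.
#' @param method,adjust,cutoff Significance calling (see [decide_tests()]).
#' @param seed Seed recorded for simulation use.
#' @return A list of class `mir_config`.
#' @export
pipeline_config <- function(targets, data_dir, out_dir,
                            protocol = c("rma", "tgs"),
                            background = c("off", "on"),
                            normalization = "quantile",
                            negative_method = c("half", "offset"),
                            offset = 0,
                            filter_detect = TRUE, filter_expr = TRUE,
                            limit_detect = 75, limit_expr = 75,
                            factors = "Treatment", contrasts = NULL,
                            method = c("separated", "nestedF"),
                            adjust = c("BH", "none"), cutoff = 0.05,
                            seed = 1L) {
  protocol <- match.arg(protocol)
  negative_method <- match.arg(negative_method)
  if (negative_method == "offset" && offset <= 0)
    stopf("negative_method 'offset' requires a positive offset")
  cfg <- list(paths = list(targets = targets, data_dir = data_dir,
                           out_dir = out_dir),
              protocol = protocol,
              preprocess = list(background = match.arg(background),
                                normalization = normalization,
                                negative_method = negative_method,
                                offset = offset),
              filter = list(detect = filter_detect, expr = filter_expr,
                            limit_detect = limit_detect,
                            limit_expr = limit_expr),
              de = list(factors = factors, contrasts = contrasts,
                        method = match.arg(method),
                        adjust = match.arg(adjust), cutoff = cutoff),
              seed = as.integer(seed))
  class(cfg) <- "mir_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the nested sections of [pipeline_config()].
#' @return A `mir_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, c(
    list(targets = y$paths$targets, data_dir = y$paths$data_dir,
         out_dir = y$paths$out_dir),
    y[setdiff(names(y), c("paths"))] [!vapply(y[setdiff(names(y), "paths")],
                                              is.list, TRUE)],
    if (!is.null(y$preprocess)) y$preprocess,
    if (!is.null(y$filter)) y$filter,
    if (!is.null(y$de)) y$de))
}

#' Run the complete workflow
#'
#' Executes read, quality assessment, pre-processing, filtering,
#' differential expression and reporting, writing every artifact under the
#' configured output directory together with a run log, the resolved
#' configuration, and a manifest listing every written file with its MD5
#' checksum. A failure in any stage aborts with the stage name and cause.
#'
#' @param config A `mir_config` from [pipeline_config()] /
#'   [read_pipeline_config()], or the path of a YAML configuration file.
#' @return Invisibly, a list with `status` (0 on success), `manifest` (data
#'   frame of files and checksums), `exprs` (filtered `mir_exprs`) and
#'   `tables` (per-contrast result tables).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "mir_config"))
    stopf("'config' must come from pipeline_config()")
  out_dir <- config$paths$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    msg(...)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  written <- character(0)

  targets <- stage("read", read_targets(config$paths$targets))
  records <- stage("read", {
    r <- lapply(targets$FileName, function(f)
      read_afe_features(file.path(config$paths$data_dir, f)))
    names(r) <- targets$FileName
    r
  })
  dataset <- stage("read", assemble_dataset(targets, records))
  log(sprintf("read %d arrays x %d spots", nrow(targets),
              length(dataset$probe_name)))

  exprs <- stage("preprocess", switch(
    config$protocol,
    rma = rma_pipeline(dataset, background = config$preprocess$background,
                       normalization = if (config$preprocess$normalization ==
                                           "none") "none" else "quantile"),
    tgs = tgs_pipeline(dataset,
                       normalization = config$preprocess$normalization,
                       negative_method = config$preprocess$negative_method,
                       offset = config$preprocess$offset)))
  log(sprintf("pre-processed with %s protocol: %d genes", config$protocol,
              nrow(exprs$exprs)))
  epath <- file.path(out_dir, "expression.txt")
  write_expression(exprs, epath)
  written <- c(written, epath, paste0(epath, ".meta"))

  qc_files <- stage("qc", qc_report(dataset, exprs,
                                    file.path(out_dir, "qc")))
  written <- c(written, qc_files)
  log(sprintf("quality report: %d files", length(qc_files)))

  groups <- exprs$groups
  keep <- rownames(exprs$exprs)
  reports <- list()
  if (isTRUE(config$filter$detect)) {
    flags <- gene_detection_flags(dataset)
    rep_d <- stage("filter", detection_filter(flags, groups,
                                              config$filter$limit_detect))
    keep <- intersect(keep, rep_d$retained)
    reports$detection <- rep_d
    log(sprintf("detection filter (L=%g): %d of %d genes retained",
                config$filter$limit_detect, length(rep_d$retained),
                nrow(flags)))
  }
  if (isTRUE(config$filter$expr)) {
    thr <- stage("filter", negative_control_threshold(exprs$negctrl))
    rep_e <- stage("filter", expression_filter(exprs, thr, groups,
                                               config$filter$limit_expr))
    keep <- intersect(keep, rep_e$retained)
    reports$expression <- rep_e
    log(sprintf("expression filter (L=%g): %d of %d genes retained",
                config$filter$limit_expr, length(rep_e$retained),
                nrow(exprs$exprs)))
  }
  removed <- setdiff(rownames(exprs$exprs), keep)
  reasons <- vapply(removed, function(g) {
    if (!is.null(reports$detection) && g %in% reports$detection$removed)
      "not_detected" else "below_threshold"
  }, "")
  combined <- new_filter_report(keep, removed, unname(reasons),
                                list(L_detect = config$filter$limit_detect,
                                     L_expr = config$filter$limit_expr))
  fpath <- file.path(out_dir, "filter_report.txt")
  write_filter_report(combined, fpath)
  written <- c(written, fpath)
  exprs$exprs <- exprs$exprs[keep, , drop = FALSE]
  log(sprintf("after filtering: %d genes", length(keep)))

  design <- stage("de", build_design(targets, config$de$factors))
  contrasts <- config$de$contrasts
  if (is.null(contrasts)) {
    lev <- unique(targets$Treatment)
    contrasts <- paste0(lev[-1], "-", lev[1])
  }
  C <- stage("de", make_contrasts(contrasts, design))
  fit <- stage("de", lm_fit(exprs, design))
  cfit <- stage("de", contrast_fit(fit, C))
  stats <- stage("de", moderate(cfit))
  decisions <- stage("de", decide_tests(stats, method = config$de$method,
                                        adjust = config$de$adjust,
                                        cutoff = config$de$cutoff))
  tables <- lapply(colnames(C), function(cn)
    significant_table(stats, decisions, exprs, cn))
  names(tables) <- colnames(C)
  de_files <- stage("report", write_reports(tables, decisions,
                                            file.path(out_dir, "de")))
  written <- c(written, de_files)
  for (cn in colnames(C))
    log(sprintf("contrast %s: %d significant genes (%s, %s, cutoff %g)",
                cn, sum(decisions[, cn] != 0), config$de$method,
                config$de$adjust, config$de$cutoff))

  cpath <- file.path(out_dir, "config_resolved.yaml")
  yaml::write_yaml(unclass(config), cpath)
  lpath <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, lpath)
  written <- c(written, cpath, lpath)
  manifest <- data.frame(File = sub(paste0("^", out_dir, "/?"), "",
                                    written),
                         MD5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  mpath <- file.path(out_dir, "manifest.txt")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(status = 0L, manifest = manifest, exprs = exprs,
                 stats = stats, decisions = decisions, tables = tables))
}
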