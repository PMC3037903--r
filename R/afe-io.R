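# Reading target files and AFE feature-extraction exports.

# Column dictionary for AFE feature files. 'required' columns must be present;
# the rest are filled with NA (and logged) when absent.
.afe_numeric_cols <- c("gMeanSignal", "gProcessedSignal", "gTotalProbeSignal",
                       "gTotalGeneSignal", "gBGMedianSignal", "gBGUsed")
.afe_flag_cols <- c("gIsGeneDetected", "gIsSaturated", "gIsFeatNonUnifOL",
                    "gIsFeatPopnOL")
.afe_required_cols <- c("gMeanSignal", "gProcessedSignal", "gTotalGeneSignal",
                        "ProbeName", "GeneName", "ControlType")
.afe_all_cols <- c("ProbeName", "GeneName", "ControlType", .afe_numeric_cols,
                   .afe_flag_cols)

#' Read an experiment target file
#'
#' The target file is a tab-delimited text file describing the experiment
#' layout: one row per array, with a `FileName` column naming the AFE feature
#' file, a `Treatment` column with the experimental group label, and a `GErep`
#' column assigning an integer code to each treatment. Any additional columns
#' (for example `Subject` in a paired design) are preserved as covariates and
#' can later enter the linear model through [build_design()].
#'
#' @param path Path to a tab-delimited target file with a header row.
#' @return A data frame of class `mir_targets` with columns `FileName`
#'   (character), `Treatment` (character), `GErep` (integer) and any extra
#'   covariate columns, rows in file order.
#' @examples
#' tf <- tempfile()
#' writeLines(c("FileName\tTreatment\tGErep\tSubject",
#'              "a1.txt\tA\t1\t1", "a2.txt\tA\t1\t2",
#'              "b1.txt\tB\t2\t1", "b2.txt\tB\t2\t2"), tf)
#' read_targets(tf)
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) stopf("target file not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("FileName", "Treatment", "GErep")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0)
    stopf("target file lacks required column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (nrow(tab) > 0) {
    if (anyDuplicated(tab$FileName))
      stopf("duplicate FileName in target file: %s",
            tab$FileName[duplicated(tab$FileName)][1])
    tab$FileName <- as.character(tab$FileName)
    tab$Treatment <- as.character(tab$Treatment)
    ge <- suppressWarnings(as.integer(tab$GErep))
    if (anyNA(ge) || any(ge < 1))
      stopf("GErep must contain positive integers")
    if (!setequal(unique(ge), seq_len(max(ge))))
      stopf("GErep codes must form a contiguous set 1..G; got {%s}",
            paste(sort(unique(ge)), collapse = ","))
    if (any(tapply(ge, tab$Treatment, function(g) length(unique(g))) != 1L))
      stopf("each Treatment must map to exactly one GErep code")
    tab$GErep <- ge
  }
  class(tab) <- c("mir_targets", "data.frame")
  tab
}

#' Read one AFE feature-extraction file
#'
#' Reads a per-array Agilent Feature Extraction text export into one record
#' per spot. Two dialects are supported and auto-detected: the multi-block
#' vendor layout (`TYPE`/`FEPARAMS`/`STATS`/`FEATURES` blocks, of which only
#' the `FEATURES` rows are read) and a flat tab-delimited table with a single
#' header row. Column matching is by exact AFE header name
#' (`gMeanSignal`, `gProcessedSignal`, `gTotalProbeSignal`,
#' `gTotalGeneSignal`, `ProbeName`, `GeneName`, `ControlType`, the four
#' quality flags, `gBGMedianSignal`, `gBGUsed`); unknown columns are ignored
#' with a log line and missing optional columns are filled with `NA`.
#'
#' @param path Path to an AFE feature file (flat or blocked dialect).
#' @return A data frame with one row per spot and the standard AFE columns.
#'   Flag columns are coerced to 0/1 integers (any nonzero value maps to 1);
#'   `ControlType` is -1, 0 or +1.
#' @export
read_afe_features <- function(path) {
  if (!file.exists(path)) stopf("AFE file not found: %s", path)
  first <- readLines(path, n = 1L)
  blocked <- identical(strsplit(first, "\t", fixed = TRUE)[[1]][1], "TYPE")
  tab <- if (blocked) .read_afe_blocked(path) else
    utils::read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                      stringsAsFactors = FALSE, check.names = FALSE)
  missing_req <- setdiff(.afe_required_cols, names(tab))
  if (length(missing_req) > 0)
    stopf("AFE file %s lacks required column(s): %s", path,
          paste(missing_req, collapse = ", "))
  unknown <- setdiff(names(tab), .afe_all_cols)
  if (length(unknown) > 0)
    msg("ignoring unknown column(s) in ", basename(path), ": ",
        paste(unknown, collapse = ", "))
  out <- data.frame(ProbeName = as.character(tab$ProbeName),
                    GeneName = as.character(tab$GeneName),
                    stringsAsFactors = FALSE)
  out$ControlType <- .parse_numeric(tab$ControlType, "ControlType", path)
  if (!all(out$ControlType %in% c(-1, 0, 1)))
    stopf("ControlType values outside {-1,0,+1} in %s", path)
  for (cn in .afe_numeric_cols) {
    if (cn %in% names(tab)) {
      out[[cn]] <- .parse_numeric(tab[[cn]], cn, path)
    } else {
      msg("optional column ", cn, " absent in ", basename(path),
          "; filled with NA")
      out[[cn]] <- NA_real_
    }
  }
  for (cn in .afe_flag_cols) {
    if (cn %in% names(tab)) {
      v <- .parse_numeric(tab[[cn]], cn, path)
      out[[cn]] <- as.integer(v != 0)
    } else {
      msg("optional column ", cn, " absent in ", basename(path),
          "; filled with NA")
      out[[cn]] <- NA_integer_
    }
  }
  out
}

.parse_numeric <- function(x, col, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & x != "" & toupper(x) != "NA")
  if (length(bad) > 0)
    stopf("non-numeric value '%s' in column %s, row %d of %s",
          x[bad[1]], col, bad[1], path)
  v
}

# Blocked AFE dialect: blocks are (TYPE line, block-name line with column
# names, DATA lines), separated by a lone "*" line. Only FEATURES rows carry
# spot data.
.read_afe_blocked <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  heads <- vapply(fields, function(f) if (length(f)) f[1] else "", "")
  feat <- which(heads == "FEATURES")
  if (length(feat) != 1L)
    stopf("blocked AFE file %s has no single FEATURES block", path)
  cols <- fields[[feat]][-1]
  rows <- list()
  i <- feat + 1L
  while (i <= length(fields) && heads[i] == "DATA") {
    rows[[length(rows) + 1L]] <- fields[[i]][-1]
    i <- i + 1L
  }
  if (length(rows) == 0)
    return(stats::setNames(as.data.frame(matrix(character(0), 0,
                                                length(cols)),
                                         stringsAsFactors = FALSE), cols))
  m <- do.call(rbind, rows)
  if (ncol(m) != length(cols))
    stopf("ragged FEATURES block in %s", path)
  colnames(m) <- cols
  as.data.frame(m, stringsAsFactors = FALSE)
}

#' Assemble a probe-level dataset from per-array feature records
#'
#' Combines the records read from each array's AFE file into a single
#' probe-level dataset whose matrices are spots x arrays, with the column
#' order taken from the target table (not from the order the files were
#' read). Spot annotation (`ProbeName`, `GeneName`, `ControlType`) is taken
#' from the first array; every array must carry an identical probe sequence.
#'
#' @param targets A `mir_targets` table from [read_targets()].
#' @param records A named list of per-array record data frames from
#'   [read_afe_features()], with names equal to the target `FileName` values
#'   (any order).
#' @return An object of class `mir_probes`: a list with signal matrices
#'   `mean_signal`, `processed_signal`, `total_probe_signal`,
#'   `total_gene_signal`, `bg_median`, `bg_used`; a `flags` list of 0/1
#'   matrices (`detected`, `saturated`, `nonunif_outlier`, `popn_outlier`);
#'   spot annotation vectors `probe_name`, `gene_name`, `control_type`; and
#'   the `targets` table.
#' @export
assemble_dataset <- function(targets, records) {
  if (!inherits(targets, "mir_targets")) stopf("'targets' must come from read_targets()")
  if (nrow(targets) == 0) stopf("empty target table")
  missing_files <- setdiff(targets$FileName, names(records))
  if (length(missing_files) > 0)
    stopf("no feature records for file(s): %s",
          paste(missing_files, collapse = ", "))
  records <- records[targets$FileName]
  ref <- records[[1]]
  n_spots <- nrow(ref)
  for (k in seq_along(records)) {
    rk <- records[[k]]
    if (nrow(rk) != n_spots)
      stopf("array %s has %d spots; expected %d", targets$FileName[k],
            nrow(rk), n_spots)
    mism <- which(rk$ProbeName != ref$ProbeName)
    if (length(mism) > 0)
      stopf("array %s: probe mismatch at spot %d ('%s' vs '%s')",
            targets$FileName[k], mism[1], rk$ProbeName[mism[1]],
            ref$ProbeName[mism[1]])
  }
  pull <- function(col) {
    m <- vapply(records, function(r) as.numeric(r[[col]]), numeric(n_spots))
    m <- matrix(m, nrow = n_spots,
                dimnames = list(NULL, targets$FileName))
    m
  }
  flagpull <- function(col) {
    m <- pull(col)
    storage.mode(m) <- "integer"
    m
  }
  ds <- list(
    mean_signal = pull("gMeanSignal"),
    processed_signal = pull("gProcessedSignal"),
    total_probe_signal = pull("gTotalProbeSignal"),
    total_gene_signal = pull("gTotalGeneSignal"),
    bg_median = pull("gBGMedianSignal"),
    bg_used = pull("gBGUsed"),
    flags = list(
      detected = flagpull("gIsGeneDetected"),
      saturated = flagpull("gIsSaturated"),
      nonunif_outlier = flagpull("gIsFeatNonUnifOL"),
      popn_outlier = flagpull("gIsFeatPopnOL")
    ),
    probe_name = ref$ProbeName,
    gene_name = ref$GeneName,
    control_type = as.integer(ref$ControlType),
    targets = targets
  )
  # spots sharing a probe must interrogate one gene
  gpp <- tapply(ds$gene_name, ds$probe_name, function(g) length(unique(g)))
  if (any(gpp != 1L))
    stopf("probe %s maps to multiple gene names", names(gpp)[gpp != 1L][1])
  class(ds) <- "mir_probes"
  ds
}

#' @export
print.mir_probes <- function(x, ...) {
  cat("Probe-level microRNA dataset (mir_probes)\n")
  cat(sprintf("  %d spots x %d arrays; %d distinct probes, %d genes\n",
              length(x$probe_name), ncol(x$mean_signal),
              length(unique(x$probe_name)), length(unique(x$gene_name))))
  ct <- table(factor(x$control_type, levels = c(-1, 0, 1)))
  cat(sprintf("  control spots: %d negative, %d positive; %d gene spots\n",
              ct[["-1"]], ct[["1"]], ct[["0"]]))
  cat("  arrays:", paste(utils::head(colnames(x$mean_signal), 6),
                         collapse = ", "),
      if (ncol(x$mean_signal) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.mir_probes <- function(x) c(length(x$probe_name), ncol(x$mean_signal))
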