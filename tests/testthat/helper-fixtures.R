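# Shared fixture builders. Everything is generated in code; no data files.

options(mirafe.verbose = FALSE)

# A scaled-down array design (same structure as the v2.0 layout) used where
# the full 13k-spot design would be wasteful.
small_design <- function() {
  make_array_design(n_1probe = 1, n_2probe = 10, n_3probe = 4, n_4probe = 10,
                    n_human = 20, n_pos_controls = 2, n_neg_spots = 40)
}

# Build a minimal mir_probes object by hand from a processed-signal matrix
# and spot annotation; other matrices default to copies/zeros.
manual_probes <- function(probe_name, gene_name, control_type, processed,
                          mean_signal = NULL, detected = NULL,
                          treatments = NULL) {
  processed <- as.matrix(processed)
  n <- length(probe_name)
  stopifnot(nrow(processed) == n)
  arrays <- colnames(processed)
  if (is.null(arrays)) {
    arrays <- sprintf("array_%02d.txt", seq_len(ncol(processed)))
    colnames(processed) <- arrays
  }
  if (is.null(mean_signal)) mean_signal <- processed + 30
  dimnames(mean_signal) <- dimnames(processed)
  zero <- matrix(0L, n, ncol(processed), dimnames = dimnames(processed))
  if (is.null(detected)) detected <- zero + 1L
  if (is.null(treatments))
    treatments <- rep(LETTERS[1:2], length.out = ncol(processed))
  targets <- data.frame(FileName = arrays, Treatment = treatments,
                        GErep = match(treatments, unique(treatments)),
                        stringsAsFactors = FALSE)
  class(targets) <- c("mir_targets", "data.frame")
  ds <- list(mean_signal = mean_signal, processed_signal = processed,
             total_probe_signal = zero + NA_real_,
             total_gene_signal = zero + NA_real_,
             bg_median = zero + 0, bg_used = zero + 0,
             flags = list(detected = detected, saturated = zero,
                          nonunif_outlier = zero, popn_outlier = zero),
             probe_name = probe_name, gene_name = gene_name,
             control_type = as.integer(control_type), targets = targets)
  class(ds) <- "mir_probes"
  ds
}

# Write a Table-1-style target file and return its path.
write_targets_file <- function(path = tempfile(fileext = ".txt"),
                               lines = NULL) {
  if (is.null(lines))
    lines <- c("FileName\tTreatment\tGErep\tSubject",
               "mscA1.txt\tA\t1\t1", "mscA2.txt\tA\t1\t2",
               "mscB1.txt\tB\t2\t1", "mscB2.txt\tB\t2\t2",
               "mscC1.txt\tC\t3\t1", "mscC2.txt\tC\t3\t2")
  writeLines(lines, path)
  path
}

# Two-group design/contrast pair used by the DE tests.
two_group_design <- function(n_per_group = 3) {
  X <- cbind(A = rep(c(1, 0), each = n_per_group),
             B = rep(c(0, 1), each = n_per_group))
  C <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "B-A"))
  list(X = X, C = C)
}
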