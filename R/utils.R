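# Internal helpers: logging and small checks.

msg <- function(..., verbose = getOption("mirafe.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[mirafe] ", ...)
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

# Median with the arithmetic-mean convention for even counts (stats::median
# already does this for numeric input); kept as a named wrapper so the
# convention is explicit at call sites.
med <- function(x) stats::median(x)

check_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) stopf("'%s' must be a numeric matrix", what)
  invisible(x)
}
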