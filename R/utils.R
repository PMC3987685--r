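#' @keywords internal
"_PACKAGE"

#' @importFrom stats pf phyper kmeans hclust cutree as.dist cor approx
#'   oneway.test fft rbinom runif rnorm sd quantile chisq.test
#' @importFrom utils combn read.delim write.table head
NULL

# Derive a reproducible per-stage seed from a master seed. Kept below 2^31
# so it is always a valid R integer.
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  as.integer((as.numeric(master) * 7919 + stage * 104729) %% 2147483647)
}

# stop() with a consistent error class so callers can test for invalid input
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("clockmine_invalid_input",
                                             "error", "condition")))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 1))
    stop_invalid(name, " must be numeric in [0, 1]")
  invisible(x)
}

# collapse maximal runs of TRUE into 0-based half-open intervals
runs_to_intervals <- function(flag) {
  if (!any(flag)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep] - 1L, end = ends[keep])
}
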