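# Stage 1: select differentially expressed probesets across time by
# one-way ANOVA with Storey positive-FDR control. Default thresholds are
# the study's: p < 0.001 and q < 0.01.

#' Filter differentially expressed probesets
#'
#' Runs a one-way ANOVA per probeset with sampling occasions as groups
#' (0 h and 24 h are distinct occasions even though they share a clock
#' phase), then converts the p-values to Storey q-values over the whole
#' chip. A probeset passes iff `p < p_thresh` and `q < q_thresh`.
#'
#' @param dataset an `expression_dataset`.
#' @param p_thresh ANOVA p-value threshold (default 0.001).
#' @param q_thresh Storey q-value threshold (default 0.01).
#' @param seed seed for the bootstrap pi0 estimate.
#' @param n_boot bootstrap resamples for pi0.
#' @return data.frame (probeset, p, q, pass) with attributes `thresholds`
#'   and `pi0`. Probesets with missing values are excluded with a warning.
#' @export
filter_differential <- function(dataset, p_thresh = 0.001, q_thresh = 0.01,
                                seed = 1L, n_boot = 100L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  tp <- dataset$samples$timepoint_h
  if (length(unique(tp)) < 2L || min(table(tp)) < 2L)
    stop_invalid("need >= 2 timepoints with >= 2 replicates each")
  vals <- dataset$values
  bad <- rowSums(!is.finite(vals)) > 0
  if (any(bad)) {
    warning(sum(bad), " probeset(s) with missing samples excluded from ",
            "the differential filter")
    vals <- vals[!bad, , drop = FALSE]
  }
  groups_idx <- split(seq_len(ncol(vals)), tp)
  p <- vapply(seq_len(nrow(vals)), function(i) {
    anova_pvalue(lapply(groups_idx, function(j) vals[i, j]))$pvalue
  }, 0)
  q <- storey_qvalues(p, n_boot = n_boot, seed = seed)
  res <- data.frame(probeset = rownames(vals), p = p, q = q$qvalues,
                    pass = p < p_thresh & q$qvalues < q_thresh)
  attr(res, "thresholds") <- c(p_thresh = p_thresh, q_thresh = q_thresh)
  attr(res, "pi0") <- q$pi0
  res
}

#' Write a differential-filter result with its stage summary
#' @param result data.frame from [filter_differential()].
#' @param path TSV output; a `.json` summary is written alongside.
#' @param seed seed recorded in the summary.
#' @export
write_differential_tsv <- function(result, path, seed = NA_integer_) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summ <- list(n_tested = nrow(result), n_pass = sum(result$pass),
               thresholds = as.list(attr(result, "thresholds")),
               pi0 = attr(result, "pi0"), seed = seed)
  jsonlite::write_json(summ, paste0(tools::file_path_sans_ext(path),
                                    ".json"),
                       auto_unbox = TRUE, digits = NA)
}
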