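# Stage 3: test clustered probesets for 24 h periodicity. Replicates at
# each sampling occasion are redistributed over three consecutive cycles
# (t, t + 24, t + 48), giving one extended series per probeset, which is
# then tested with Fisher's exact g-test (even grid) or a least-squares
# periodogram with a permutation null (uneven spacing, the default).

#' Redistribute replicates over consecutive 24 h cycles
#'
#' For each timepoint t with r replicates, a uniformly random permutation
#' assigns exactly one replicate to each of t, t + 24, ..., t + 24(r - 1).
#' The value multiset is preserved exactly.
#'
#' @param profile numeric matrix of timepoints x replicates; rownames are
#'   hours (or pass `times_h`).
#' @param seed integer seed.
#' @param times_h timepoint hours (defaults to numeric rownames).
#' @return object of class `extended_series`: `times_h`, `values` (sorted
#'   by time) and `origin` mapping each observation back to its
#'   (timepoint, replicate).
#' @export
redistribute_replicates <- function(profile, seed = 1L, times_h = NULL) {
  profile <- as.matrix(profile)
  if (is.null(times_h)) times_h <- as.numeric(rownames(profile))
  if (any(is.na(times_h)) || length(times_h) != nrow(profile))
    stop_invalid("timepoint hours must be supplied as rownames or times_h")
  if (any(!is.finite(profile)))
    stop_invalid("missing replicate values")
  r <- ncol(profile)
  if (r < 2L) stop_invalid("need >= 2 replicates per timepoint")
  offsets <- 24 * (seq_len(r) - 1L)
  withr::with_seed(as.integer(seed), {
    rows <- lapply(seq_len(nrow(profile)), function(i) {
      perm <- sample.int(r)
      data.frame(times_h = times_h[i] + offsets,
                 values = profile[i, perm],
                 src_timepoint_h = times_h[i], src_replicate = perm)
    })
    out <- do.call(rbind, rows)
    ord <- order(out$times_h)
    structure(list(times_h = out$times_h[ord], values = out$values[ord],
                   origin = out[ord, c("src_timepoint_h", "src_replicate")]),
              class = "extended_series")
  })
}

#' Test an extended series for periodicity
#'
#' Two methods:
#' \describe{
#'   \item{lomb_perm (default)}{least-squares spectral ordinates at the
#'     harmonic frequencies of the series span (periods from the span down
#'     to `period_h / 4`), g = max ordinate / sum of ordinates, p-value
#'     from [permutation_g_pvalue()]. Safe for unevenly spaced times.}
#'   \item{exact_grid}{the series is averaged onto an even 2 h grid
#'     (missing cells linearly interpolated), the classical periodogram is
#'     computed at the Fourier frequencies, and the p-value comes from the
#'     closed-form [fisher_g_pvalue()].}
#' }
#'
#' @param series an `extended_series`.
#' @param method "lomb_perm" or "exact_grid".
#' @param period_h target period (hours).
#' @param n_perm permutations for the lomb_perm null.
#' @param seed integer seed.
#' @return list of class `periodicity_result` with `g`, `m` (number of
#'   ordinates), `p` and `method`. A constant series gives g = 1/m, p = 1.
#' @export
periodicity_test <- function(series, method = c("lomb_perm", "exact_grid"),
                             period_h = 24, n_perm = 999L, seed = 1L) {
  method <- match.arg(method)
  t_h <- series$times_h
  y <- series$values
  if (length(t_h) != length(y) || length(y) < 8L)
    stop_invalid("series needs aligned times/values with >= 8 observations")
  if (method == "lomb_perm") {
    span <- max(t_h) - min(t_h) + min(diff(sort(unique(t_h))))
    m <- length(default_freqs(span_h = span, min_period_h = period_h / 4))
    if (stats::sd(y) == 0) {
      res <- list(g = 1 / m, m = m, p = 1, method = method)
    } else {
      pg <- permutation_g_pvalue(series, period_h = period_h,
                                 n_perm = n_perm, seed = seed)
      res <- list(g = pg$statistic, m = m, p = pg$pvalue, method = method)
    }
  } else {
    grid <- seq(min(t_h), max(t_h), by = 2)
    means <- tapply(y, factor(t_h, levels = grid), mean)
    yy <- as.numeric(means)
    if (any(is.na(yy))) {
      yy <- stats::approx(grid[!is.na(yy)], yy[!is.na(yy)], xout = grid,
                          rule = 2)$y
    }
    n <- length(yy)
    m <- floor((n - 1) / 2)
    if (stats::sd(yy) == 0) {
      res <- list(g = 1 / m, m = m, p = 1, method = method)
    } else {
      I <- Mod(stats::fft(yy - mean(yy)))^2 / n
      ords <- I[2:(m + 1L)]
      g <- max(ords) / sum(ords)
      res <- list(g = g, m = m, p = fisher_g_pvalue(g, m), method = method)
    }
  }
  structure(res, class = "periodicity_result")
}

#' Apply the periodicity test to every probeset in a cluster set
#'
#' Builds the redistributed extended series per probeset (fresh seed per
#' probeset, derived from `seed`) and tests it.
#'
#' @param dataset an `expression_dataset`.
#' @param ids probesets to test.
#' @param method,period_h,n_perm passed to [periodicity_test()].
#' @param seed master seed.
#' @return data.frame (probeset, g, m, p).
#' @export
periodicity_scan <- function(dataset, ids, method = "lomb_perm",
                             period_h = 24, n_perm = 999L, seed = 1L) {
  tp <- dataset$samples$timepoint_h
  times <- sort(unique(tp))
  rows <- lapply(seq_along(ids), function(i) {
    prof <- t(vapply(times, function(t0) dataset$values[ids[i], tp == t0],
                     numeric(sum(tp == times[1]))))
    rownames(prof) <- times
    es <- redistribute_replicates(prof, seed = derive_seed(seed, i))
    r <- periodicity_test(es, method = method, period_h = period_h,
                          n_perm = n_perm, seed = derive_seed(seed, i) + 1L)
    data.frame(probeset = ids[i], g = r$g, m = r$m, p = r$p)
  })
  do.call(rbind, rows)
}

#' FDR-filter periodicity results
#'
#' @param results data.frame with a `p` column (e.g. from
#'   [periodicity_scan()]).
#' @param q_thresh Storey q-value threshold (default 0.01, the study's
#'   cut).
#' @param seed seed for the bootstrap pi0.
#' @return the input with `q` and `pass` columns appended.
#' @export
filter_periodic <- function(results, q_thresh = 0.01, seed = 1L) {
  if (nrow(results) == 0L) stop_invalid("results must be non-empty")
  q <- storey_qvalues(results$p, seed = seed)
  results$q <- q$qvalues
  results$pass <- results$q < q_thresh
  attr(results, "pi0") <- q$pi0
  results
}
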