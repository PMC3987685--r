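# Statistical kernels shared by all pipeline stages: one-way ANOVA,
# Storey q-values with bootstrap pi0, hypergeometric tail probability,
# Fisher's exact g p-value, and a permutation null for the g statistic on
# unevenly spaced series.

#' One-way fixed-effects ANOVA p-value
#'
#' Tests whether group means differ, treating each sampling occasion (time
#' point) as a separate group. The duplicated clock time in a 0--24 h design
#' (0 h and 24 h are the same zeitgeber phase) is deliberately kept as two
#' groups: they are distinct sampling occasions.
#'
#' @param groups list of two or more numeric vectors, each of length >= 2.
#' @return list with elements `statistic` (the F statistic) and `pvalue`
#'   (upper-tail p). When all values are identical, or when every group has
#'   zero internal variance, the result is the degenerate `F = 0, p = 1`:
#'   such profiles carry no usable evidence of differential expression.
#' @examples
#' anova_pvalue(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' @export
anova_pvalue <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_invalid("groups must be a list of >= 2 numeric vectors")
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stop_invalid("every group must contain >= 2 values")
  vals <- unlist(groups, use.names = FALSE)
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop_invalid("groups must contain finite numeric values")
  within_ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  if (within_ss == 0) {
    # all-identical values, or zero within-group variance everywhere:
    # no error variance to test against
    return(list(statistic = 0, pvalue = 1))
  }
  g <- factor(rep.int(seq_along(groups), sizes))
  fit <- stats::oneway.test(vals ~ g, var.equal = TRUE)
  list(statistic = unname(fit$statistic), pvalue = unname(fit$p.value))
}

#' Storey q-values with bootstrap pi0 estimation
#'
#' Converts p-values to positive-FDR q-values. The null proportion pi0 is
#' estimated as pi0(lambda) = #(p > lambda) / (m (1 - lambda)) on a grid of
#' lambda values; the working lambda is chosen by Storey's bootstrap,
#' minimising the bootstrap mean squared error of pi0(lambda) around the
#' plug-in minimum. q-values are the step-up transform
#' q(p_(i)) = min_{j >= i} pi0 m p_(j) / j.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @param lambda_grid grid of lambda values in (0, 1).
#' @param n_boot number of bootstrap resamples (>= 1).
#' @param seed integer seed; the result is deterministic given the seed.
#' @param pi0 optionally force pi0 instead of estimating it (used when a
#'   known null proportion should be imposed).
#' @return list with `qvalues` (aligned to the input order), `pi0`,
#'   `lambda`, `n_boot` and `lambda_grid`.
#' @export
storey_qvalues <- function(pvalues, lambda_grid = seq(0.05, 0.95, by = 0.05),
                           n_boot = 100L, seed = 1L, pi0 = NULL) {
  if (length(pvalues) == 0L) stop_invalid("pvalues must be non-empty")
  assert_prob(pvalues, "pvalues")
  if (n_boot < 1L) stop_invalid("n_boot must be >= 1")
  if (any(lambda_grid <= 0 | lambda_grid >= 1))
    stop_invalid("lambda_grid values must lie in (0, 1)")
  m <- length(pvalues)
  lambda_used <- NA_real_
  if (is.null(pi0)) {
    pi0_grid <- vapply(lambda_grid,
                       function(l) mean(pvalues > l) / (1 - l), 0)
    min_pi0 <- min(pi0_grid)
    mse <- withr::with_seed(as.integer(seed), {
      boot <- matrix(0, nrow = n_boot, ncol = length(lambda_grid))
      for (b in seq_len(n_boot)) {
        pb <- pvalues[sample.int(m, m, replace = TRUE)]
        boot[b, ] <- vapply(lambda_grid,
                            function(l) mean(pb > l) / (1 - l), 0)
      }
      colMeans((boot - min_pi0)^2)
    })
    lambda_used <- lambda_grid[which.min(mse)]
    pi0 <- pi0_grid[which.min(mse)]
  }
  pi0 <- min(max(pi0, 1 / m), 1)  # clamp to (0, 1]
  ord <- order(pvalues)
  q_ord <- pmin(pi0 * m * pvalues[ord] / seq_len(m), 1)
  q_ord <- rev(cummin(rev(q_ord)))
  q <- numeric(m)
  q[ord] <- q_ord
  list(qvalues = q, pi0 = pi0, lambda = lambda_used,
       n_boot = as.integer(n_boot), lambda_grid = lambda_grid)
}

#' Hypergeometric upper-tail enrichment p-value
#'
#' For a background of `B` genes of which `b` carry a feature, and a
#' foreground sample of `N` genes of which `n` carry it, returns
#' P(X >= n) under sampling without replacement:
#' sum_{k = n}^{min(N, b)} C(b, k) C(B - b, N - k) / C(B, N).
#' The upper tail (not the point mass) is used because the quantity is an
#' over-representation p-value. `n = 0` returns 1.
#'
#' @param counts list or vector with fields `B`, `b`, `N`, `n` satisfying
#'   0 <= b <= B, 0 <= n <= N <= B, n <= b.
#' @return the tail probability, a number in [0, 1].
#' @examples
#' hypergeom_tail(list(B = 10, b = 5, N = 4, n = 4))  # 5/210
#' @export
hypergeom_tail <- function(counts) {
  counts <- as.list(counts)
  B <- counts$B; b <- counts$b; N <- counts$N; n <- counts$n
  ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == round(x)
  if (!ok(B) || !ok(b) || !ok(N) || !ok(n))
    stop_invalid("B, b, N, n must be single integers")
  if (b < 0 || b > B || n < 0 || n > N || N > B || n > b)
    stop_invalid("counts violate 0 <= b <= B, 0 <= n <= N <= B, n <= b")
  if (n == 0) return(1)
  stats::phyper(n - 1, b, B - b, N, lower.tail = FALSE)
}

#' Fisher's exact g-test p-value
#'
#' Exact null distribution of the g statistic (largest periodogram ordinate
#' divided by the sum of all m ordinates) for a Gaussian white-noise series:
#' P(G > g) = sum_{j = 1}^{floor(1/g)} (-1)^(j-1) C(m, j) (1 - j g)^(m-1).
#'
#' @param g observed g statistic, in [1/m, 1].
#' @param m number of periodogram ordinates (>= 2).
#' @return the p-value, clamped to [0, 1]. At the minimum g = 1/m the
#'   p-value is exactly 1.
#' @export
fisher_g_pvalue <- function(g, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 2 || m != round(m))
    stop_invalid("m must be an integer >= 2")
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g))
    stop_invalid("g must be a finite number")
  eps <- 1e-12
  if (g < 1 / m - eps || g > 1 + eps)
    stop_invalid("g must lie in [1/m, 1]")
  if (g <= 1 / m + eps) return(1)  # minimum of the support
  jmax <- floor(1 / g + 1e-9)
  j <- seq_len(jmax)
  terms <- (-1)^(j - 1) * choose(m, j) * pmax(1 - j * g, 0)^(m - 1)
  min(max(sum(terms), 0), 1)
}

# Orthonormal projector bases for the least-squares periodogram: one n x 2
# matrix per frequency, spanning the centred (cos, sin) design at the given
# time stamps. The regression sum of squares of centred y on frequency k is
# then colSums((t(Q_k) %*% yc)^2), which makes permutation nulls cheap.
periodogram_projectors <- function(times_h, freqs) {
  lapply(freqs, function(f) {
    X <- cbind(cos(2 * pi * f * times_h), sin(2 * pi * f * times_h))
    X <- scale(X, center = TRUE, scale = FALSE)
    qr.Q(qr(X))[, seq_len(qr(X)$rank), drop = FALSE]
  })
}

# Least-squares spectral ordinates for (possibly unevenly spaced) series.
# `values` may be a vector or a matrix with one series per column.
lsq_ordinates <- function(times_h, values, freqs, projectors = NULL) {
  if (is.null(projectors)) projectors <- periodogram_projectors(times_h, freqs)
  Y <- as.matrix(values)
  Yc <- sweep(Y, 2L, colMeans(Y))
  out <- vapply(projectors,
                function(Q) colSums((crossprod(Q, Yc))^2),
                numeric(ncol(Y)))
  # one row per series, one column per frequency
  if (ncol(Y) == 1L) as.numeric(out) else matrix(out, nrow = ncol(Y))
}

# Frequencies tested by default: harmonics k / span for periods from the
# full span down to `min_period_h`.
default_freqs <- function(span_h = 72, min_period_h = 6) {
  k <- seq_len(floor(span_h / min_period_h))
  k / span_h
}

#' Permutation p-value for the g statistic on unevenly spaced series
#'
#' Computes the g statistic (max ordinate / sum of ordinates) from a
#' least-squares periodogram at the harmonic frequencies of the series span,
#' then compares it with the distribution of g over random permutations of
#' the values across the fixed time stamps:
#' p = (1 + #(g* >= g_obs)) / (1 + n_perm).
#'
#' @param series an `extended_series` (see [redistribute_replicates()]) or
#'   any list with numeric `times_h` and `values` of equal length.
#' @param period_h target period in hours; only used to pick the frequency
#'   grid span (frequencies run from 1/span down to periods of
#'   `period_h / 4`).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list with `statistic` (observed g) and `pvalue`. A constant
#'   series returns p = 1 by convention.
#' @export
permutation_g_pvalue <- function(series, period_h = 24, n_perm = 999L,
                                 seed = 1L) {
  t_h <- series$times_h
  y <- series$values
  if (length(t_h) != length(y) || length(y) < 8L)
    stop_invalid("series needs aligned times/values with >= 8 observations")
  if (n_perm < 100L) stop_invalid("n_perm must be >= 100")
  span <- max(t_h) - min(t_h) + min(diff(sort(unique(t_h))))
  freqs <- default_freqs(span_h = span, min_period_h = period_h / 4)
  if (stats::sd(y) == 0) {
    return(list(statistic = 1 / length(freqs), pvalue = 1))
  }
  proj <- periodogram_projectors(t_h, freqs)
  ords <- lsq_ordinates(t_h, y, freqs, projectors = proj)
  g_obs <- max(ords) / sum(ords)
  g_null <- withr::with_seed(as.integer(seed), {
    P <- vapply(seq_len(n_perm), function(i) sample(y), numeric(length(y)))
    O <- lsq_ordinates(t_h, P, freqs, projectors = proj)
    apply(O, 1L, function(o) max(o) / sum(o))
  })
  list(statistic = g_obs,
       pvalue = (1 + sum(g_null >= g_obs)) / (1 + n_perm))
}
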