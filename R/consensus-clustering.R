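# Stage 2: group differentially expressed probesets into coherent
# co-expression clusters by consensus over many randomly initialised base
# partitions, then dissolve trivial or non-significant clusters.

#' Replicate-averaged, z-scored expression profiles
#'
#' Averages replicates per timepoint and standardises each probeset's
#' profile (mean 0, sd 1 over the timepoint means). Clustering operates on
#' these vectors; for row-standardised profiles, squared Euclidean distance
#' is proportional to 1 - Pearson correlation, so partitioning them with
#' k-means is correlation-distance clustering.
#'
#' @param dataset an `expression_dataset`.
#' @param ids optional subset of probesets.
#' @return matrix of probesets x timepoints, rows z-scored. Flat profiles
#'   (zero variance) become all-zero rows.
#' @export
mean_profiles <- function(dataset, ids = NULL) {
  vals <- dataset$values
  if (!is.null(ids)) vals <- vals[ids, , drop = FALSE]
  tp <- dataset$samples$timepoint_h
  prof <- vapply(split(seq_along(tp), tp),
                 function(j) rowMeans(vals[, j, drop = FALSE]),
                 numeric(nrow(vals)))
  if (nrow(vals) == 1L) prof <- matrix(prof, nrow = 1L,
                                       dimnames = list(rownames(vals)))
  s <- apply(prof, 1L, stats::sd)
  z <- (prof - rowMeans(prof)) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  colnames(z) <- paste0("t", sort(unique(tp)))
  z
}

# one randomly initialised k-means partition; retries on degenerate starts
base_partition <- function(z, k) {
  for (try in 1:5) {
    centers <- z[sample.int(nrow(z), k), , drop = FALSE]
    if (anyDuplicated(centers)) next
    fit <- tryCatch(stats::kmeans(z, centers = centers, iter.max = 25L),
                    error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) return(fit$cluster)
  }
  stats::kmeans(z, centers = min(k, nrow(unique(z))), iter.max = 25L,
                nstart = 1L)$cluster
}

#' Build a consensus co-clustering matrix
#'
#' Averages pairwise co-membership indicators over `n_runs` base
#' partitions, each a k-means run with `k` drawn uniformly from `k_range`
#' and random initial centroids.
#'
#' @param expr matrix of z-scored profiles (rows = probesets), e.g. from
#'   [mean_profiles()].
#' @param n_runs number of base partitions (>= 10).
#' @param k_range candidate cluster numbers for the base learner.
#' @param seed integer seed.
#' @return object of class `consensus_matrix`: list with `ids`, `M`
#'   (symmetric, unit diagonal, entries in [0, 1]) and `n_runs`.
#' @export
build_consensus_matrix <- function(expr, n_runs = 200L, k_range = 2:8,
                                   seed = 1L) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)))
    rownames(expr) <- sprintf("p%05d", seq_len(nrow(expr)))
  if (nrow(expr) < 2L) stop_invalid("need >= 2 profiles")
  if (n_runs < 10L) stop_invalid("n_runs must be >= 10 for a usable consensus")
  k_range <- k_range[k_range >= 2 & k_range < nrow(expr)]
  if (length(k_range) == 0L) k_range <- 2L
  n <- nrow(expr)
  M <- withr::with_seed(as.integer(seed), {
    acc <- matrix(0, n, n)
    for (r in seq_len(n_runs)) {
      k <- if (length(k_range) == 1L) k_range else sample(k_range, 1L)
      cl <- base_partition(expr, k)
      Z <- outer(cl, cl, "==")
      acc <- acc + Z
    }
    acc / n_runs
  })
  diag(M) <- 1
  dimnames(M) <- list(rownames(expr), rownames(expr))
  structure(list(ids = rownames(expr), M = M, n_runs = as.integer(n_runs)),
            class = "consensus_matrix")
}

#' Cut the consensus matrix into clusters
#'
#' Hierarchical clustering of the dissimilarity 1 - M. With
#' `cut_k = "auto"` the number of clusters maximising the mean silhouette
#' width on 1 - M over `k_range` is chosen. Rows are processed in
#' lexicographic id order so ties in the dendrogram break
#' deterministically.
#'
#' @param cm a `consensus_matrix`.
#' @param linkage_rule hclust agglomeration method (default "average").
#' @param cut_k number of clusters, or "auto".
#' @param k_range candidate k for "auto".
#' @return object of class `cluster_set`: `assignments` (named integer
#'   vector), `tightness` (mean within-cluster consensus per cluster),
#'   `sizes`, and NA p-values (filled by [remove_trivial_clusters()]).
#' @export
extract_clusters <- function(cm, linkage_rule = "average", cut_k = "auto",
                             k_range = 2:8) {
  stopifnot(inherits(cm, "consensus_matrix"))
  ord <- order(cm$ids)
  M <- cm$M[ord, ord]
  n <- nrow(M)
  if (is.numeric(cut_k) && cut_k > n)
    stop_invalid("cut_k exceeds the number of items")
  d <- stats::as.dist(1 - M)
  hc <- stats::hclust(d, method = linkage_rule)
  if (identical(cut_k, "auto")) {
    ks <- k_range[k_range >= 2 & k_range < n]
    if (length(ks) == 0L) ks <- 2L
    sil <- vapply(ks, function(k) {
      cl <- stats::cutree(hc, k = k)
      mean(cluster::silhouette(cl, dmatrix = 1 - M)[, "sil_width"])
    }, 0)
    cut_k <- ks[which.max(sil)]
  }
  cl <- stats::cutree(hc, k = cut_k)
  new_cluster_set(cl, M)
}

new_cluster_set <- function(assignments, M = NULL) {
  labs <- sort(unique(assignments[assignments != 0L]))
  tight <- if (is.null(M)) rep(NA_real_, length(labs)) else
    vapply(labs, function(k) {
      idx <- which(assignments == k)
      if (length(idx) < 2L) return(1)
      mean(M[idx, idx][upper.tri(diag(length(idx)))])
    }, 0)
  structure(list(assignments = assignments,
                 tightness = stats::setNames(tight, labs),
                 sizes = stats::setNames(
                   as.integer(table(factor(assignments[assignments != 0L],
                                           levels = labs))), labs),
                 pvalues = stats::setNames(rep(NA_real_, length(labs)),
                                           labs)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters (sizes %s), %d unassigned\n",
              length(x$sizes), paste(x$sizes, collapse = "/"),
              sum(x$assignments == 0L)))
  invisible(x)
}

# mean pairwise Pearson correlation among member profiles; the cheap
# coherence statistic used for the permutation null
profile_coherence <- function(z) {
  if (nrow(z) < 2L) return(0)
  C <- suppressWarnings(stats::cor(t(z)))
  C[is.na(C)] <- 0
  mean(C[upper.tri(C)])
}

#' Remove trivial and non-significant clusters
#'
#' Each cluster's coherence (mean pairwise correlation of its z-scored
#' profiles) is compared with a permutation null in which every
#' probeset's timepoints are permuted independently. Because the observed
#' clusters were themselves discovered from the data, the null must
#' include the selection step: each null draw re-partitions the permuted
#' profiles into the same number of clusters and records the best
#' (maximum) cluster coherence. A cluster's p-value is the fraction of
#' null maxima at least as large as its observed coherence. Clusters
#' smaller than `min_size` or with p >= `cluster_p_thresh` are dissolved
#' to unassigned (label 0).
#'
#' @param clusters a `cluster_set` from [extract_clusters()].
#' @param expr the z-scored profile matrix the clustering was built from
#'   (all clustered probesets).
#' @param min_size minimum retained cluster size.
#' @param cluster_p_thresh significance threshold (default 0.001, the
#'   study's cut).
#' @param n_null number of null permutations (>= 100).
#' @param seed integer seed.
#' @return the pruned `cluster_set`, with `pvalues` filled in.
#' @export
remove_trivial_clusters <- function(clusters, expr, min_size = 5L,
                                    cluster_p_thresh = 0.001,
                                    n_null = 999L, seed = 1L) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (n_null < 100L) stop_invalid("n_null must be >= 100")
  expr <- as.matrix(expr)
  asg <- clusters$assignments
  labs <- as.integer(names(clusters$sizes))
  keep <- logical(length(labs))
  pvals <- rep(NA_real_, length(labs))
  k_obs <- max(2L, length(labs))
  withr::with_seed(as.integer(seed), {
    null_max <- vapply(seq_len(n_null), function(b) {
      zp <- t(apply(expr, 1L, sample))
      cl <- tryCatch(
        stats::kmeans(zp, centers = min(k_obs, nrow(zp) - 1L),
                      iter.max = 10L, nstart = 1L)$cluster,
        error = function(e) rep(1L, nrow(zp)))
      max(vapply(split(seq_along(cl), cl), function(ii) {
        if (length(ii) < 2L) return(-Inf)
        profile_coherence(zp[ii, , drop = FALSE])
      }, 0))
    }, 0)
    for (i in seq_along(labs)) {
      idx <- which(asg == labs[i])
      if (length(idx) < max(2L, min_size)) next
      obs <- profile_coherence(expr[names(asg)[idx], , drop = FALSE])
      pvals[i] <- mean(null_max >= obs)
      keep[i] <- pvals[i] < cluster_p_thresh
    }
  })
  asg[asg %in% labs[!keep]] <- 0L
  out <- new_cluster_set(asg)
  # keep consensus tightness/pvalues from the original labelling
  kept <- as.character(labs[keep])
  out$tightness <- clusters$tightness[kept]
  out$sizes <- clusters$sizes[kept]
  out$pvalues <- stats::setNames(pvals[keep], kept)
  out
}
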