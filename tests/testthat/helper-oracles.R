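# Independent oracles and small fixture builders shared across test files.

# exhaustive-enumeration oracle for the hypergeometric upper tail: mark
# items 1..b as carriers, enumerate every N-subset of 1..B, and count how
# many contain >= n carriers
hypergeom_enum_oracle <- function(B, b, N, n) {
  if (n == 0) return(1)
  subsets <- utils::combn(B, N)
  hits <- colSums(subsets <= b)
  mean(hits >= n)
}

# brute-force frequent-set miner: enumerate every non-empty family subset
mine_bruteforce <- function(pm, support_thresh) {
  fams <- sort(colnames(pm))
  out <- NULL
  for (k in seq_along(fams)) {
    sets <- utils::combn(fams, k, simplify = FALSE)
    for (s in sets) {
      supp <- mean(rowSums(pm[, s, drop = FALSE]) == k)
      if (supp >= support_thresh)
        out <- rbind(out, data.frame(set = paste(s, collapse = ";"),
                                     size = k, support = supp))
    }
  }
  if (is.null(out)) {
    return(data.frame(set = character(0), size = integer(0),
                      support = numeric(0)))
  }
  out <- out[order(out$size, out$set), ]
  rownames(out) <- NULL
  out
}

# independent one-way ANOVA F for a matrix of datasets (columns = datasets,
# rows = observations with fixed group labels); used as permutation oracle
perm_f_stats <- function(Y, groups) {
  k <- length(unique(groups))
  n <- length(groups)
  G <- stats::model.matrix(~ 0 + factor(groups))
  gs <- crossprod(G, Y)                     # group sums
  gn <- colSums(G)
  gm <- gs / gn
  tot <- colSums(Y)
  ssb <- colSums(gn * (gm - rep(tot / n, each = k))^2)
  sst <- colSums(Y^2) - tot^2 / n
  ssw <- sst - ssb
  (ssb / (k - 1)) / (ssw / (n - k))
}

# minimal site_list construction for unit tests
fake_site_list <- function(families, promoter_id = "p1") {
  n <- length(families)
  structure(data.frame(family = families,
                       matrix_id = paste0("M_", families),
                       start = seq_len(n) * 20L,
                       end = seq_len(n) * 20L + 10L,
                       strand = rep("+", n),
                       core_score = rep(1, n),
                       matrix_score = rep(1, n),
                       in_conserved_region = rep(NA, n)),
            promoter_id = promoter_id, class = c("site_list", "data.frame"))
}

# shared heavy fixture: one faithful-scale simulated study, computed once
# per test session
faithful_cache <- new.env(parent = emptyenv())
faithful_run <- function() {
  if (!is.null(faithful_cache$res)) return(faithful_cache$res)
  cfg <- sim_config(seed = 101L)
  expr <- generate_expression(cfg)
  de <- filter_differential(expr$dataset, seed = 102L)
  ids <- de$probeset[de$pass]
  z <- mean_profiles(expr$dataset, ids)
  cm <- build_consensus_matrix(z, n_runs = 200L, seed = 103L)
  cl <- extract_clusters(cm, cut_k = "auto")
  faithful_cache$res <- list(cfg = cfg, expr = expr, de = de, ids = ids,
                             z = z, cm = cm, clusters = cl)
  faithful_cache$res
}
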