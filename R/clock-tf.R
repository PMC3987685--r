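# Stage 5: identify clock-controlled TFs (differentially expressed TFs
# with an E-box on a promoter), mine frequent clock-TF combinations per
# cluster by level-wise breadth-first search, and score each set by
# hypergeometric enrichment against a GC-matched background with Storey
# bootstrap q-values.

#' Identify clock-controlled transcription factors
#'
#' A gene is a clock-controlled TF (ccTF) candidate iff it is (a)
#' differentially expressed, (b) annotated as a TF, and (c) carries at
#' least one CLOCK:BMAL1 (E-box) hit on any of its promoters.
#'
#' @param de_genes character vector of differentially expressed genes.
#' @param tf_annotation data.frame (gene, family) marking TF genes and
#'   their families.
#' @param site_lists named list: gene -> list of `site_list`s over its
#'   promoters.
#' @param clock_family family name of the core clock matrix.
#' @return data.frame (gene, family) of ccTFs. Candidate TFs without
#'   promoter annotation are skipped with a warning.
#' @export
identify_ccTFs <- function(de_genes, tf_annotation, site_lists,
                           clock_family = "CLOCK:BMAL1") {
  cand <- tf_annotation[tf_annotation$gene %in% de_genes, , drop = FALSE]
  missing <- setdiff(cand$gene, names(site_lists))
  if (length(missing) > 0L)
    warning("no promoter annotation for: ", paste(missing, collapse = ", "))
  cand <- cand[cand$gene %in% names(site_lists), , drop = FALSE]
  has_ebox <- vapply(cand$gene, function(g) {
    sl <- site_lists[[g]]
    if (is.data.frame(sl)) sl <- list(sl)
    any(vapply(sl, function(s) clock_family %in% s$family, TRUE))
  }, TRUE)
  out <- cand[has_ebox, c("gene", "family")]
  rownames(out) <- NULL
  out
}

#' Gene-by-family presence matrix
#'
#' A cell is TRUE iff any promoter of the gene carries at least one hit of
#' the family (physical hits; conservation not required at this stage).
#'
#' @param genes character vector of gene ids (rows).
#' @param families character vector of TF families (columns).
#' @param site_lists named list: gene -> list of `site_list`s.
#' @return logical matrix of class `presence_matrix`.
#' @export
gene_presence_matrix <- function(genes, families, site_lists) {
  if (length(families) == 0L) stop_invalid("families must be non-empty")
  pm <- matrix(FALSE, nrow = length(genes), ncol = length(families),
               dimnames = list(genes, families))
  for (g in genes) {
    sl <- site_lists[[g]]
    if (is.null(sl)) next
    if (is.data.frame(sl)) sl <- list(sl)
    present <- unique(unlist(lapply(sl, function(s) s$family)))
    pm[g, families %in% present] <- TRUE
  }
  structure(pm, class = c("presence_matrix", class(pm)))
}

#' Mine frequent clock-TF sets by level-wise breadth-first search
#'
#' Level 1 keeps single families with support >= `support_thresh`;
#' level-k candidates are unions of frequent (k-1)-sets sharing their
#' first k-2 elements, pruned by the antimonotone property (every
#' (k-1)-subset must be frequent). The support of a set is the fraction
#' of genes carrying every member family.
#'
#' @param pm a `presence_matrix` (genes x families, logical).
#' @param support_thresh minimum support in (0, 1] (default 0.7, the
#'   study's common level).
#' @param max_size largest set size emitted.
#' @return data.frame (set, size, support) with members semicolon-joined
#'   in alphabetical order, sorted by size then lexicographically.
#' @export
mine_frequent_tf_sets <- function(pm, support_thresh = 0.7,
                                  max_size = Inf) {
  if (support_thresh <= 0 || support_thresh > 1)
    stop_invalid("support_thresh must be in (0, 1]")
  empty <- data.frame(set = character(0), size = integer(0),
                      support = numeric(0))
  if (is.null(dim(pm)) || nrow(pm) == 0L || ncol(pm) == 0L) return(empty)
  pm <- pm[, order(colnames(pm)), drop = FALSE]
  n_genes <- nrow(pm)
  support_of <- function(members) {
    sum(rowSums(pm[, members, drop = FALSE]) == length(members)) / n_genes
  }
  singles <- colnames(pm)[colMeans(pm) >= support_thresh]
  if (length(singles) == 0L) return(empty)
  out <- data.frame(set = singles, size = 1L,
                    support = colMeans(pm)[singles])
  frequent <- lapply(singles, identity)
  level <- 1L
  while (length(frequent) > 1L && level < max_size) {
    keys <- vapply(frequent, function(s) paste(s, collapse = ";"), "")
    cand <- list()
    for (i in seq_along(frequent)) {
      for (j in seq_along(frequent)) {
        if (j <= i) next
        a <- frequent[[i]]; b <- frequent[[j]]
        if (level > 1L &&
            !identical(a[seq_len(level - 1L)], b[seq_len(level - 1L)]))
          next
        u <- sort(union(a, b))
        if (length(u) != level + 1L) next
        # antimonotone pruning: every level-subset must be frequent
        subs <- vapply(seq_along(u), function(d)
          paste(u[-d], collapse = ";"), "")
        if (!all(subs %in% keys)) next
        cand[[paste(u, collapse = ";")]] <- u
      }
    }
    if (length(cand) == 0L) break
    supp <- vapply(cand, support_of, 0)
    ok <- supp >= support_thresh
    if (!any(ok)) break
    frequent <- unname(cand[ok])
    out <- rbind(out, data.frame(set = names(cand)[ok],
                                 size = level + 1L,
                                 support = unname(supp[ok])))
    level <- level + 1L
  }
  out <- out[order(out$size, out$set), ]
  rownames(out) <- NULL
  out
}

#' GC fraction of promoter sequences, averaged per gene
#' @param promoters promoter data.frame (gene, sequence).
#' @return named numeric vector, one mean GC per gene.
#' @export
promoter_gc <- function(promoters) {
  gc1 <- vapply(promoters$sequence, function(s) {
    x <- strsplit(toupper(s), "")[[1]]
    mean(x %in% c("G", "C"))
  }, 0, USE.NAMES = FALSE)
  tapply(gc1, promoters$gene, mean)[unique(promoters$gene)]
}

#' Sample a GC-matched background gene set
#'
#' The foreground's per-gene promoter GC histogram (bins of `bin_width`)
#' defines target proportions; pool genes are sampled without replacement
#' per bin to a total of about `size`. Bins with an insufficient pool are
#' topped up proportionally from adjacent bins with a warning.
#'
#' @param foreground_gc named numeric vector of foreground per-gene GC
#'   (e.g. from [promoter_gc()]).
#' @param pool_gc named numeric vector of candidate background genes' GC.
#' @param size requested background size.
#' @param bin_width GC histogram bin width.
#' @param seed integer seed.
#' @return object of class `background_set`: data.frame (gene, gc) with
#'   `bin_edges` attribute.
#' @export
build_gc_matched_background <- function(foreground_gc, pool_gc,
                                        size = 10000L, bin_width = 0.05,
                                        seed = 1L) {
  if (length(pool_gc) < size) {
    warning("pool smaller than requested size; background scaled down to ",
            length(pool_gc))
    size <- length(pool_gc)
  }
  edges <- seq(0, 1, by = bin_width)
  fg_bin <- cut(foreground_gc, edges, include.lowest = TRUE)
  pool_bin <- cut(pool_gc, edges, include.lowest = TRUE)
  target <- round(size * table(fg_bin) / length(foreground_gc))
  withr::with_seed(as.integer(seed), {
    chosen <- character(0)
    deficit <- 0L
    avail <- split(names(pool_gc), pool_bin)
    for (b in names(target)) {
      want <- target[[b]]
      have <- avail[[b]]
      take <- min(want, length(have))
      if (take < want) deficit <- deficit + (want - take)
      if (take > 0L) {
        chosen <- c(chosen, sample(have, take))
        avail[[b]] <- setdiff(have, chosen)
      }
    }
    if (deficit > 0L) {
      warning("insufficient pool in ", deficit,
              " bin slot(s); filled from remaining pool")
      rest <- setdiff(names(pool_gc), chosen)
      chosen <- c(chosen, sample(rest, min(deficit, length(rest))))
    }
    structure(data.frame(gene = chosen, gc = unname(pool_gc[chosen])),
              bin_edges = edges, class = c("background_set", "data.frame"))
  })
}

#' Score TF sets by hypergeometric enrichment with Storey q-values
#'
#' For each set A: n = foreground genes carrying every member of A, N =
#' foreground size, b = carriers in the scoring population, B = population
#' size, p = P(X >= n) hypergeometric, q = Storey bootstrap over all sets
#' tested in the call. The scoring population is the background set
#' united with the foreground so that the count invariants (n <= b,
#' N <= B) always hold. Non-significant records are flagged but still
#' reported.
#'
#' @param sets data.frame from [mine_frequent_tf_sets()] (columns set,
#'   support) or a character vector of semicolon-joined sets.
#' @param foreground_genes character vector of foreground gene ids.
#' @param background a `background_set` (or character vector of gene ids).
#' @param site_lists named list: gene -> list of `site_list`s covering
#'   foreground and background genes.
#' @param p_thresh,q_thresh significance thresholds (defaults 0.05/0.10,
#'   the study's cuts).
#' @param n_boot,seed Storey bootstrap parameters.
#' @return data.frame (set, support, B, b, N, n, p, q, significant).
#'   Sets naming a family absent from all site lists get b = n = 0 and
#'   p = 1, with a warning.
#' @export
score_tf_sets <- function(sets, foreground_genes, background, site_lists,
                          p_thresh = 0.05, q_thresh = 0.10,
                          n_boot = 100L, seed = 1L) {
  if (is.data.frame(sets)) {
    set_str <- sets$set
    support <- if ("support" %in% names(sets)) sets$support else NA_real_
  } else {
    set_str <- sets
    support <- rep(NA_real_, length(sets))
  }
  if (length(set_str) == 0L) {
    return(data.frame(set = character(0), support = numeric(0),
                      B = integer(0), b = integer(0), N = integer(0),
                      n = integer(0), p = numeric(0), q = numeric(0),
                      significant = logical(0)))
  }
  bg_genes <- if (is.data.frame(background)) background$gene else background
  members <- strsplit(set_str, ";", fixed = TRUE)
  fams <- sort(unique(unlist(members)))
  seen <- unique(unlist(lapply(site_lists, function(sl) {
    if (is.data.frame(sl)) sl <- list(sl)
    unlist(lapply(sl, function(s) s$family))
  })))
  absent <- setdiff(fams, seen)
  if (length(absent) > 0L)
    warning("families absent from all site lists: ",
            paste(absent, collapse = ", "))
  pop_genes <- union(bg_genes, foreground_genes)
  pm_pop <- gene_presence_matrix(pop_genes, fams, site_lists)
  pm_fg <- pm_pop[match(foreground_genes, pop_genes), , drop = FALSE]
  B <- length(pop_genes)
  N <- length(foreground_genes)
  counts <- t(vapply(members, function(mm) {
    c(b = sum(rowSums(pm_pop[, mm, drop = FALSE]) == length(mm)),
      n = sum(rowSums(pm_fg[, mm, drop = FALSE]) == length(mm)))
  }, c(b = 0, n = 0)))
  p <- vapply(seq_along(members), function(i) {
    hypergeom_tail(list(B = B, b = counts[i, "b"], N = N,
                        n = counts[i, "n"]))
  }, 0)
  q <- storey_qvalues(p, n_boot = n_boot, seed = seed)$qvalues
  out <- data.frame(set = set_str, support = support, B = B,
                    b = as.integer(counts[, "b"]), N = N,
                    n = as.integer(counts[, "n"]), p = p, q = q,
                    significant = p < p_thresh & q < q_thresh)
  rownames(out) <- NULL
  out
}
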