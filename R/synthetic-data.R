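# Ground-truthed synthetic inputs emulating the study design: a replicated
# six-point circadian expression matrix (zeitgeber times 0, 2, 4, 8, 16,
# 24 h; n = 3) and a promoter/PWM/ortholog/TF-annotation bundle with
# planted regulatory structure.

#' Simulation configuration
#'
#' Defaults mirror the study conditions: six sampling occasions at
#' zeitgeber times 0, 2, 4, 8, 16 and 24 h with three replicates each, four
#' rhythmic clusters of 153/64/52/83 probesets peaking near ZT0/ZT4/ZT8/ZT16
#' (the sizes of the four reported expression patterns) inside a background
#' of non-rhythmic probesets, and promoters of 600 bp (500 bp upstream +
#' 100 bp downstream of the TSS) with six orthologous species.
#'
#' @param n_probesets total probesets on the simulated chip (scaled down
#'   from the 31,099 of the real array so simulation studies run quickly).
#' @param n_rhythmic_per_cluster planted sizes of the four rhythmic
#'   clusters.
#' @param cluster_peak_zt_h peak zeitgeber time (h) of each cluster.
#' @param timepoints_h sampling occasions in hours.
#' @param n_replicates replicates per occasion.
#' @param amplitude cosine amplitude of rhythmic probesets (log-scale
#'   units).
#' @param noise_sd replicate noise standard deviation (log-scale units).
#' @param baseline_mean,baseline_sd distribution of probeset baselines.
#' @param n_genes_promoter foreground genes in the promoter bundle.
#' @param n_background_genes background-pool genes (GC-matching pool).
#' @param n_orthologs orthologous promoters per foreground gene.
#' @param promoter_len promoter length in bp.
#' @param gc_foreground GC fraction of foreground (reference) promoters.
#' @param gc_background_modes modes of the background-pool GC mixture.
#' @param planted_family_presence named vector: fraction of foreground
#'   genes carrying a planted site per TF family. Planting is comonotone
#'   (a single uniform per gene is compared with every rate), so the
#'   planted families form a frequent set with joint support equal to the
#'   smallest rate.
#' @param n_tf_genes number of foreground genes annotated as TFs; each
#'   gets a planted CLOCK:BMAL1 (E-box) site, making them clock-controlled
#'   TF candidates.
#' @param n_conserved_blocks,conserved_block_len conserved blocks planted
#'   per promoter (ortholog substitution rate is reduced inside them).
#' @param divergence_out,divergence_in per-site ortholog substitution
#'   probability outside/inside conserved blocks.
#' @param unmapped_fraction fraction of probesets left without a gene
#'   mapping (the real chip has unmapped probesets).
#' @param seed master seed for all generators.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_probesets = 2000L,
                       n_rhythmic_per_cluster = c(153L, 64L, 52L, 83L),
                       cluster_peak_zt_h = c(0, 4, 8, 16),
                       timepoints_h = c(0, 2, 4, 8, 16, 24),
                       n_replicates = 3L,
                       amplitude = 1.0,
                       noise_sd = 0.25,
                       baseline_mean = 7,
                       baseline_sd = 1,
                       n_genes_promoter = 50L,
                       n_background_genes = 400L,
                       n_orthologs = 6L,
                       promoter_len = 600L,
                       gc_foreground = 0.55,
                       gc_background_modes = c(0.45, 0.6),
                       planted_family_presence = c(CREB = 0.8, EBOX = 0.8,
                                                   RORA = 0.8),
                       n_tf_genes = 10L,
                       n_conserved_blocks = 4L,
                       conserved_block_len = 60L,
                       divergence_out = 0.5,
                       divergence_in = 0.02,
                       unmapped_fraction = 0,
                       seed = 1L) {
  cfg <- list(n_probesets = as.integer(n_probesets),
              n_rhythmic_per_cluster = as.integer(n_rhythmic_per_cluster),
              cluster_peak_zt_h = cluster_peak_zt_h,
              timepoints_h = timepoints_h,
              n_replicates = as.integer(n_replicates),
              amplitude = amplitude, noise_sd = noise_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              n_genes_promoter = as.integer(n_genes_promoter),
              n_background_genes = as.integer(n_background_genes),
              n_orthologs = as.integer(n_orthologs),
              promoter_len = as.integer(promoter_len),
              gc_foreground = gc_foreground,
              gc_background_modes = gc_background_modes,
              planted_family_presence = planted_family_presence,
              n_tf_genes = as.integer(n_tf_genes),
              n_conserved_blocks = as.integer(n_conserved_blocks),
              conserved_block_len = as.integer(conserved_block_len),
              divergence_out = divergence_out,
              divergence_in = divergence_in,
              unmapped_fraction = unmapped_fraction,
              seed = as.integer(seed))
  if (sum(cfg$n_rhythmic_per_cluster) > cfg$n_probesets)
    stop_invalid("sum of cluster sizes exceeds n_probesets")
  if (length(cfg$n_rhythmic_per_cluster) != length(cfg$cluster_peak_zt_h))
    stop_invalid("one peak time needed per cluster")
  if (cfg$noise_sd <= 0) stop_invalid("noise_sd must be > 0")
  assert_prob(cfg$planted_family_presence, "planted_family_presence")
  assert_prob(cfg$gc_foreground, "gc_foreground")
  structure(cfg, class = "sim_config")
}

sample_ids <- function(timepoints_h, n_replicates) {
  data.frame(
    sample = paste0("t", rep(timepoints_h, each = n_replicates),
                    "_r", rep(seq_len(n_replicates), length(timepoints_h))),
    timepoint_h = rep(timepoints_h, each = n_replicates),
    replicate = rep(seq_len(n_replicates), length(timepoints_h)))
}

#' Generate a replicated circadian expression matrix with planted clusters
#'
#' Rhythmic probesets follow
#' `baseline + amplitude * cos(2*pi*(t - peak)/24) + N(0, noise_sd)` per
#' replicate; background probesets are noise around probeset-specific
#' baselines. Values are on a log-like continuous scale.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (an `expression_dataset`: `values` matrix of
#'   probesets x samples plus sample annotation) and `truth` (rhythmic ids
#'   per cluster, peak times, probeset-to-gene map).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  smp <- sample_ids(config$timepoints_h, config$n_replicates)
  n <- config$n_probesets
  ids <- sprintf("ps%05d", seq_len(n))
  n_cl <- length(config$n_rhythmic_per_cluster)
  cluster_of <- rep(c(seq_len(n_cl), 0L),
                    c(config$n_rhythmic_per_cluster,
                      n - sum(config$n_rhythmic_per_cluster)))
  vals <- withr::with_seed(config$seed, {
    base <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
    mu <- matrix(base, nrow = n, ncol = nrow(smp))
    for (k in seq_len(n_cl)) {
      rows <- which(cluster_of == k)
      if (length(rows) == 0L) next
      phase <- cos(2 * pi * (smp$timepoint_h -
                               config$cluster_peak_zt_h[k]) / 24)
      mu[rows, ] <- mu[rows, ] +
        config$amplitude * matrix(phase, nrow = length(rows),
                                  ncol = nrow(smp), byrow = TRUE)
    }
    mu + matrix(stats::rnorm(n * nrow(smp), 0, config$noise_sd), nrow = n)
  })
  dimnames(vals) <- list(ids, smp$sample)
  gene_map <- withr::with_seed(config$seed + 1L, {
    genes <- sprintf("g%05d", seq_len(n))
    if (config$unmapped_fraction > 0) {
      drop <- sample.int(n, round(config$unmapped_fraction * n))
      genes[drop] <- NA_character_
    }
    genes
  })
  dataset <- structure(list(values = vals, probeset_ids = ids,
                            samples = smp,
                            timepoints_h = smp$timepoint_h,
                            replicate_index = smp$replicate),
                       class = "expression_dataset")
  truth <- list(
    rhythmic_ids = split(ids[cluster_of > 0], cluster_of[cluster_of > 0]),
    cluster_of = stats::setNames(cluster_of, ids),
    peak_zt_h = config$cluster_peak_zt_h,
    probeset_gene = stats::setNames(gene_map, ids))
  list(dataset = dataset, truth = truth)
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d probesets x %d samples (%d timepoints x %d replicates)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$timepoint_h)),
              max(x$samples$replicate)))
  invisible(x)
}

#' Write/read an expression matrix as TSV
#'
#' Columns are named `t<hours>_r<replicate>`; the first column holds the
#' probeset id.
#' @param dataset an `expression_dataset`.
#' @param path file path.
#' @export
write_expression_tsv <- function(dataset, path) {
  df <- data.frame(probeset = rownames(dataset$values),
                   dataset$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  m <- regmatches(colnames(vals),
                  regexec("^t([0-9.]+)_r([0-9]+)$", colnames(vals)))
  if (any(lengths(m) != 3L))
    stop_invalid("sample columns must be named t<hours>_r<replicate>")
  smp <- data.frame(sample = colnames(vals),
                    timepoint_h = as.numeric(vapply(m, `[`, "", 2L)),
                    replicate = as.integer(vapply(m, `[`, "", 3L)))
  if (any(vals < 0 | vals > 25, na.rm = TRUE))
    warning("values outside the usual normalised log scale [0, 25]")
  structure(list(values = vals, probeset_ids = rownames(vals),
                 samples = smp, timepoints_h = smp$timepoint_h,
                 replicate_index = smp$replicate),
            class = "expression_dataset")
}

#' Generate a synthetic PWM library
#'
#' Twelve family matrices of length 8--14 with controlled information
#' content: the clock families used throughout (CLOCK:BMAL1 with a
#' palindromic CACGTG E-box core, EBOX, STAT, FKHD, CREB, RXRF, KLFS,
#' AHRR, PARF, RORA) plus two decoys (GATA, SORY). Consensus base weights
#' are drawn per position in [0.85, 0.97] so each matrix is informative
#' but not degenerate.
#'
#' @param config a [sim_config()]; only the seed is used.
#' @return a `pwm_library`.
#' @export
generate_pwm_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  consensi <- c("CLOCK:BMAL1" = "GTCACGTGAC",
                EBOX = "ACCACCTGGT",
                STAT = "TTCCCGGAA",
                FKHD = "ATGTTTACAT",
                CREB = "TGACGTCA",
                RXRF = "AGGTCAAAGGTCA",
                KLFS = "GGGGCGGGG",
                AHRR = "TTGCGTGACA",
                PARF = "TTATGTAA",
                RORA = "AATATAGGTCA",
                GATA = "AGATAAGA",
                SORY = "AACAATGG")
  withr::with_seed(config$seed + 2L, {
    pwms <- lapply(names(consensi), function(fam) {
      cons <- strsplit(consensi[[fam]], "")[[1]]
      L <- length(cons)
      w <- stats::runif(L, 0.85, 0.97)
      mat <- matrix((1 - rep(w, each = 4)) / 3, nrow = 4,
                    dimnames = list(DNA_BASES, NULL))
      mat[cbind(match(cons, DNA_BASES), seq_len(L))] <- w
      build_pwm(paste0("M_", gsub("[^A-Za-z0-9]", "", fam)), fam, mat,
                matrix_threshold = 0.85)
    })
    pwm_library(pwms)
  })
}

random_dna <- function(n, gc) {
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

revcomp_chars <- function(x) rev(chartr("ACGT", "TGCA", x))

mutate_chars <- function(x, rate) {
  hit <- stats::runif(length(x)) < rate
  if (any(hit)) {
    x[hit] <- vapply(x[hit],
                     function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  }
  x
}

#' Generate promoters, orthologs and TF annotation with planted structure
#'
#' For each foreground gene a reference promoter is simulated at the
#' configured GC composition with planted conserved blocks; orthologous
#' promoters for `n_orthologs` species derive from the reference by point
#' substitutions (slower inside conserved blocks). Planted TF-family sites
#' (PWM consensus, random strand) are inserted inside conserved blocks at
#' the configured per-family presence rates; genes annotated as TFs also
#' receive a CLOCK:BMAL1 site, making them clock-controlled TF candidates.
#' Background-pool genes are drawn with GC from the background modes and
#' carry no planted sites.
#'
#' @param config a [sim_config()].
#' @param library a `pwm_library` containing matrices for the planted
#'   families.
#' @param gene_ids optional foreground gene ids (defaults to
#'   `g00001, ...`).
#' @return list with `promoters` (data.frame: gene, species, promoter_id,
#'   strand, tss_offset, sequence), `tf_annotation` (gene, family) and
#'   `truth` (planted sites, conserved blocks, TF genes, planted set).
#' @export
generate_promoters <- function(config, library, gene_ids = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(library, "pwm_library"))
  fams <- pwm_families(library)
  planted <- config$planted_family_presence
  need <- union(names(planted), "CLOCK:BMAL1")
  if (!all(need %in% fams))
    stop_invalid("library lacks matrices for: ",
                 paste(setdiff(need, fams), collapse = ", "))
  fam_cons <- lapply(library, pwm_consensus)
  cons_of_family <- function(fam) {
    m <- which(vapply(library, `[[`, "", "family") == fam)[1]
    fam_cons[[m]]
  }
  if (any(nchar(vapply(need, cons_of_family, ""))
          > config$conserved_block_len))
    stop_invalid("planted site longer than a conserved block")
  if (max(nchar(unlist(fam_cons))) > config$promoter_len)
    stop_invalid("planted site longer than promoter")
  if (is.null(gene_ids))
    gene_ids <- sprintf("g%05d", seq_len(config$n_genes_promoter))
  species <- c("human", "macaque", "chimp", "mouse", "horse",
               "dog", "cow")[seq_len(config$n_orthologs)]
  L <- config$promoter_len
  withr::with_seed(config$seed + 3L, {
    tf_genes <- gene_ids[seq_len(min(config$n_tf_genes, length(gene_ids)))]
    u <- stats::runif(length(gene_ids))  # comonotone planting variable
    prom <- list(); sites <- list(); blocks <- list()
    for (gi in seq_along(gene_ids)) {
      gene <- gene_ids[gi]
      seq_ref <- random_dna(L, config$gc_foreground)
      # conserved blocks: one per equal-width segment, random offset
      seg <- floor(L / config$n_conserved_blocks)
      bstart <- (seq_len(config$n_conserved_blocks) - 1L) * seg +
        sample.int(seg - config$conserved_block_len, config$n_conserved_blocks,
                   replace = TRUE)
      bint <- data.frame(gene = gene, start = bstart - 1L,
                         end = bstart - 1L + config$conserved_block_len)
      blocks[[gi]] <- bint
      # planted families for this gene (comonotone across families)
      gfam <- names(planted)[u[gi] <= planted]
      if (gene %in% tf_genes) gfam <- union(gfam, "CLOCK:BMAL1")
      in_block <- rep(FALSE, L)
      for (b in seq_len(nrow(bint)))
        in_block[(bint$start[b] + 1L):bint$end[b]] <- TRUE
      gsites <- NULL
      if (length(gfam) > 0) {
        slots <- sample(seq_len(config$n_conserved_blocks))
        for (fi in seq_along(gfam)) {
          site <- strsplit(cons_of_family(gfam[fi]), "")[[1]]
          strand <- sample(c("+", "-"), 1L)
          if (strand == "-") site <- revcomp_chars(site)
          blk <- bint[slots[(fi - 1L) %% length(slots) + 1L], ]
          room <- config$conserved_block_len - length(site)
          start0 <- blk$start + sample.int(room + 1L, 1L) - 1L
          seq_ref[(start0 + 1L):(start0 + length(site))] <- site
          gsites <- rbind(gsites, data.frame(
            gene = gene, family = gfam[fi], species = "rat",
            start = start0, end = start0 + length(site), strand = strand))
        }
      }
      rows <- data.frame(gene = gene, species = "rat",
                         promoter_id = paste0(gene, "_p1"), strand = "+",
                         tss_offset = -500L,
                         sequence = paste(seq_ref, collapse = ""))
      for (sp in species) {
        o <- seq_ref
        o[!in_block] <- mutate_chars(o[!in_block], config$divergence_out)
        o[in_block] <- mutate_chars(o[in_block], config$divergence_in)
        rows <- rbind(rows, data.frame(
          gene = gene, species = sp,
          promoter_id = paste0(gene, "_", sp, "_p1"), strand = "+",
          tss_offset = -500L, sequence = paste(o, collapse = "")))
      }
      prom[[gi]] <- rows
      sites[[gi]] <- gsites
    }
    # background pool: one promoter per gene, GC from the mixture modes
    bg <- lapply(seq_len(config$n_background_genes), function(i) {
      gc <- sample(config$gc_background_modes, 1L) + stats::runif(1, -0.02, 0.02)
      gene <- sprintf("bg%05d", i)
      data.frame(gene = gene, species = "rat",
                 promoter_id = paste0(gene, "_p1"), strand = "+",
                 tss_offset = -500L,
                 sequence = paste(random_dna(L, gc), collapse = ""))
    })
    promoters <- do.call(rbind, c(prom, bg))
    rownames(promoters) <- NULL
    cctf_fams <- c("STAT", "FKHD", "CREB", "RXRF", "KLFS", "AHRR", "EBOX")
    tf_annotation <- data.frame(
      gene = tf_genes,
      family = rep_len(cctf_fams, length(tf_genes)))
    truth <- list(planted_sites = do.call(rbind, sites),
                  conserved_blocks = do.call(rbind, blocks),
                  tf_genes = tf_genes,
                  planted_set = sort(names(planted)),
                  planted_family_presence = planted,
                  foreground_genes = gene_ids,
                  background_genes = sprintf("bg%05d",
                                             seq_len(config$n_background_genes)))
    list(promoters = promoters, tf_annotation = tf_annotation, truth = truth)
  })
}

#' Write/read promoters as FASTA
#'
#' Headers follow `gene|species|promoter_id|strand|tss_offset`.
#' @param promoters promoter data.frame as from [generate_promoters()].
#' @param path FASTA file.
#' @export
write_promoters_fasta <- function(promoters, path) {
  ss <- Biostrings::DNAStringSet(promoters$sequence)
  names(ss) <- with(promoters,
                    paste(gene, species, promoter_id, strand, tss_offset,
                          sep = "|"))
  Biostrings::writeXStringSet(ss, path)
}

#' @rdname write_promoters_fasta
#' @export
read_promoters_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(ss), "|", fixed = TRUE)
  if (any(lengths(parts) != 5L))
    stop_invalid("FASTA headers must be gene|species|promoter_id|strand|tss_offset")
  data.frame(gene = vapply(parts, `[`, "", 1L),
             species = vapply(parts, `[`, "", 2L),
             promoter_id = vapply(parts, `[`, "", 3L),
             strand = vapply(parts, `[`, "", 4L),
             tss_offset = as.integer(vapply(parts, `[`, "", 5L)),
             sequence = as.character(ss))
}
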