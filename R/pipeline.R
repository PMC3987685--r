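# End-to-end orchestration: simulate -> filter -> cluster -> periodicity
# -> scan/footprint -> ccTF -> mine/score, with per-stage outputs and a
# reproducible run manifest.

#' Pipeline configuration
#'
#' Bundles every stage threshold (defaults are the study's printed values)
#' and a master seed from which per-stage seeds are derived.
#'
#' @param sim a [sim_config()] used when the pipeline simulates its own
#'   inputs.
#' @param p_thresh,q_thresh differential-filter thresholds (0.001 / 0.01).
#' @param cluster_p trivial-cluster removal threshold (0.001).
#' @param min_cluster_size smallest retained cluster.
#' @param n_consensus_runs,k_range consensus-clustering parameters.
#' @param periodicity_q periodicity q-value threshold (0.01).
#' @param n_perm permutations for the periodicity null.
#' @param core_sim core similarity for PWM scanning (0.75).
#' @param target_fp_rate background hits/kb used to calibrate matrix
#'   thresholds.
#' @param common_thresh common-presence threshold for regulator reports
#'   and set mining (0.7).
#' @param set_p,set_q significance thresholds for clock-TF sets
#'   (0.05 / 0.10).
#' @param background_size GC-matched background size (capped by the
#'   available pool).
#' @param gc_bin_width GC histogram bin width for background matching.
#' @param conservation_window,conservation_identity,min_species
#'   footprinting parameters.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            p_thresh = 0.001, q_thresh = 0.01,
                            cluster_p = 0.001, min_cluster_size = 5L,
                            n_consensus_runs = 200L, k_range = 2:8,
                            periodicity_q = 0.01, n_perm = 499L,
                            core_sim = 0.75, target_fp_rate = 0.3,
                            common_thresh = 0.7,
                            set_p = 0.05, set_q = 0.10,
                            background_size = 10000L,
                            gc_bin_width = 0.05,
                            conservation_window = 20L,
                            conservation_identity = 0.7,
                            min_species = 4L,
                            seed = 1L) {
  for (x in list(p_thresh, q_thresh, cluster_p, periodicity_q, core_sim,
                 common_thresh, set_p, set_q, conservation_identity))
    assert_prob(x, "threshold")
  structure(list(sim = sim, p_thresh = p_thresh, q_thresh = q_thresh,
                 cluster_p = cluster_p,
                 min_cluster_size = as.integer(min_cluster_size),
                 n_consensus_runs = as.integer(n_consensus_runs),
                 k_range = k_range, periodicity_q = periodicity_q,
                 n_perm = as.integer(n_perm), core_sim = core_sim,
                 target_fp_rate = target_fp_rate,
                 common_thresh = common_thresh, set_p = set_p,
                 set_q = set_q,
                 background_size = as.integer(background_size),
                 gc_bin_width = gc_bin_width,
                 conservation_window = as.integer(conservation_window),
                 conservation_identity = conservation_identity,
                 min_species = as.integer(min_species),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# site lists for each gene's promoters, all matrices of a calibrated
# library; batch-scans every promoter per matrix, then splits hits back
# into per-promoter site_list objects (gene -> list of site_list)
site_lists_by_gene <- function(promoters, library, core_sim = 0.75,
                               species = "rat") {
  use <- promoters[promoters$species %in% species, , drop = FALSE]
  hits <- do.call(rbind, lapply(library, function(p) {
    h <- scan_pwm_multi(use$sequence, p, core_thresh = core_sim)
    if (nrow(h) == 0L) return(NULL)
    data.frame(seq_idx = h$seq_idx, family = p$family,
               matrix_id = p$matrix_id, start = h$start,
               end = h$start + ncol(p$mat), strand = h$strand,
               core_score = h$core_score, matrix_score = h$matrix_score)
  }))
  per_seq <- if (is.null(hits)) list() else
    split(hits[, -1], factor(hits$seq_idx, levels = seq_len(nrow(use))))
  empty <- data.frame(family = character(0), matrix_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), core_score = numeric(0),
                      matrix_score = numeric(0))
  lapply(split(seq_len(nrow(use)), use$gene), function(idx) {
    lapply(idx, function(i) {
      h <- if (is.null(hits)) empty else per_seq[[i]]
      if (is.null(h) || nrow(h) == 0L) h <- empty
      h <- h[!duplicated(h[, c("matrix_id", "start", "strand")]), ]
      h <- h[order(h$start, h$family), ]
      rownames(h) <- NULL
      h$in_conserved_region <- rep(NA, nrow(h))
      structure(h, promoter_id = use$promoter_id[i],
                class = c("site_list", "data.frame"))
    })
  })
}

#' Run the full discovery pipeline on simulated inputs
#'
#' Executes: simulate expression + promoter bundle, differential filter,
#' consensus clustering with trivial-cluster removal, periodicity testing,
#' PWM threshold calibration, footprint-based regulator reports per
#' cluster, clock-controlled TF identification, and per-cluster frequent
#' clock-TF set mining scored against a GC-matched background. Per-stage
#' tables, a run manifest and a summary are written under `out_dir` when
#' given.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @return (invisibly when writing) list with every stage result: `truth`,
#'   `differential`, `clusters`, `periodicity`, `regulators` (per
#'   cluster), `cctfs`, `tf_sets` (per cluster, scored), and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  # --- simulate ---------------------------------------------------------
  sim <- config$sim
  expr <- generate_expression(sim)
  lib <- generate_pwm_library(sim)
  # promoters are generated for the genes of the planted rhythmic
  # probesets, so every downstream cluster has promoter annotation
  rhythmic_genes <- unique(stats::na.omit(
    expr$truth$probeset_gene[unlist(expr$truth$rhythmic_ids)]))
  prom <- generate_promoters(sim, lib, gene_ids = rhythmic_genes)
  # --- stage 1: differential filter ------------------------------------
  de <- filter_differential(expr$dataset, p_thresh = config$p_thresh,
                            q_thresh = config$q_thresh,
                            seed = derive_seed(seed, 1L))
  de_ids <- de$probeset[de$pass]
  # --- stage 2: consensus clustering -----------------------------------
  clusters <- NULL; retained <- NULL; z <- NULL
  if (length(de_ids) >= 2L) {
    z <- mean_profiles(expr$dataset, de_ids)
    cm <- build_consensus_matrix(z, n_runs = config$n_consensus_runs,
                                 k_range = config$k_range,
                                 seed = derive_seed(seed, 2L))
    cl0 <- extract_clusters(cm, cut_k = "auto", k_range = config$k_range)
    clusters <- remove_trivial_clusters(cl0, z,
                                        min_size = config$min_cluster_size,
                                        cluster_p_thresh = config$cluster_p,
                                        n_null = 999L,
                                        seed = derive_seed(seed, 3L))
    retained <- clusters$assignments[clusters$assignments != 0L]
  }
  # --- stage 3: periodicity --------------------------------------------
  periodic <- NULL
  if (length(retained) > 0L) {
    per <- periodicity_scan(expr$dataset, names(retained),
                            n_perm = config$n_perm,
                            seed = derive_seed(seed, 4L))
    per$cluster <- retained[per$probeset]
    periodic <- filter_periodic(per, q_thresh = config$periodicity_q,
                                seed = derive_seed(seed, 5L))
  }
  # --- stage 4: scanning, footprinting, regulator reports --------------
  bg_prom <- prom$promoters[grepl("^bg", prom$promoters$gene), ]
  lib_cal <- calibrate_library(lib, bg_prom$sequence,
                               target_rate = config$target_fp_rate,
                               core_thresh = config$core_sim)
  gene_of <- expr$truth$probeset_gene
  slists <- site_lists_by_gene(prom$promoters, lib_cal,
                               core_sim = config$core_sim)
  fg_genes_all <- prom$truth$foreground_genes
  cluster_genes <- list()
  regulators <- list()
  if (length(retained) > 0L) {
    for (k in sort(unique(retained))) {
      ids_k <- names(retained)[retained == k]
      genes_k <- unique(stats::na.omit(gene_of[ids_k]))
      genes_k <- intersect(genes_k, fg_genes_all)
      cluster_genes[[as.character(k)]] <- genes_k
      if (length(genes_k) == 0L) next
      fp <- lapply(genes_k, function(g) {
        oset <- prom$promoters[prom$promoters$gene == g, ]
        if (sum(oset$species != "rat") < 3L) return(NULL)
        cons <- find_conserved_regions(
          oset, window = config$conservation_window,
          identity_thresh = config$conservation_identity,
          min_species = config$min_species)
        lapply(slists[[g]], footprint_filter, conserved = cons)
      })
      names(fp) <- genes_k
      fp <- fp[!vapply(fp, is.null, TRUE)]
      if (length(fp) > 0L)
        regulators[[as.character(k)]] <-
          enriched_regulators(names(fp), fp,
                              common_thresh = config$common_thresh)
    }
  }
  # --- stage 5: ccTFs, mining, enrichment ------------------------------
  de_genes <- unique(stats::na.omit(gene_of[de_ids]))
  cctfs <- identify_ccTFs(de_genes, prom$tf_annotation, slists)
  clock_universe <- union(c("CLOCK:BMAL1", "PARF", "RORA"),
                          unique(cctfs$family))
  bg_gc <- promoter_gc(bg_prom)
  tf_sets <- list()
  for (k in names(cluster_genes)) {
    genes_k <- cluster_genes[[k]]
    if (length(genes_k) < 2L) next
    fg_gc <- promoter_gc(prom$promoters[prom$promoters$gene %in% genes_k &
                                          prom$promoters$species == "rat", ])
    bg <- build_gc_matched_background(fg_gc, bg_gc,
                                      size = min(config$background_size,
                                                 length(bg_gc)),
                                      bin_width = config$gc_bin_width,
                                      seed = derive_seed(seed, 6L))
    pm <- gene_presence_matrix(genes_k, clock_universe, slists)
    mined <- mine_frequent_tf_sets(pm, support_thresh = config$common_thresh)
    if (nrow(mined) == 0L) {
      tf_sets[[k]] <- score_tf_sets(mined, genes_k, bg, slists)
      next
    }
    tf_sets[[k]] <- score_tf_sets(mined, genes_k, bg, slists,
                                  p_thresh = config$set_p,
                                  q_thresh = config$set_q,
                                  seed = derive_seed(seed, 7L))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("clockmine")),
    seed = seed,
    thresholds = config[c("p_thresh", "q_thresh", "cluster_p",
                          "periodicity_q", "core_sim", "common_thresh",
                          "set_p", "set_q", "background_size")],
    sim = unclass(sim)[c("n_probesets", "n_rhythmic_per_cluster",
                         "timepoints_h", "n_replicates", "amplitude",
                         "noise_sd", "seed")],
    counts = list(n_differential = length(de_ids),
                  cluster_sizes = if (!is.null(clusters))
                    as.list(clusters$sizes) else list(),
                  n_periodic_pass = if (!is.null(periodic))
                    sum(periodic$pass) else 0L,
                  n_cctfs = nrow(cctfs)))
  result <- list(truth = list(expression = expr$truth,
                              promoters = prom$truth),
                 dataset = expr$dataset,
                 library = lib_cal,
                 differential = de, clusters = clusters,
                 periodicity = periodic, regulators = regulators,
                 cctfs = cctfs, tf_sets = tf_sets,
                 cluster_genes = cluster_genes, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pipeline_outputs(result, out_dir)
    return(invisible(result))
  }
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  w <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  w(result$differential, "differential.tsv")
  if (!is.null(result$clusters)) {
    asg <- result$clusters$assignments
    w(data.frame(probeset = names(asg), cluster = unname(asg)),
      "clusters.tsv")
  }
  if (!is.null(result$periodicity)) w(result$periodicity, "periodicity.tsv")
  if (length(result$regulators) > 0L) {
    reg <- do.call(rbind, lapply(names(result$regulators), function(k) {
      r <- result$regulators[[k]]
      if (nrow(r) == 0L) return(NULL)
      cbind(cluster = k, r)
    }))
    if (!is.null(reg)) w(reg, "regulators.tsv")
  }
  w(result$cctfs, "cctfs.tsv")
  if (length(result$tf_sets) > 0L) {
    ts <- do.call(rbind, lapply(names(result$tf_sets), function(k) {
      r <- result$tf_sets[[k]]
      if (nrow(r) == 0L) return(NULL)
      cbind(cluster = k, r)
    }))
    if (!is.null(ts)) w(ts, "tf_sets.tsv")
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
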