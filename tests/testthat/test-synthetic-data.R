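# The synthetic-data generators: expression matrix, PWM library,
# promoter/ortholog bundle.

test_that("generate_expression honours shape, truth and determinism", {
  cfg <- sim_config(n_probesets = 500L,
                    n_rhythmic_per_cluster = c(40L, 30L, 30L, 40L),
                    noise_sd = 0.2, seed = 3L)
  ge <- generate_expression(cfg)
  expect_equal(dim(ge$dataset$values), c(500L, 18L))
  expect_equal(length(unlist(ge$truth$rhythmic_ids)), 140L)
  expect_equal(length(ge$truth$rhythmic_ids), 4L)
  ge2 <- generate_expression(cfg)
  expect_identical(ge$dataset$values, ge2$dataset$values)
  expect_error(sim_config(n_probesets = 10, n_rhythmic_per_cluster =
                            c(10, 10, 10, 10)),
               class = "clockmine_invalid_input")
})

test_that("amplitude zero makes rhythmic and background indistinguishable", {
  cfg <- sim_config(n_probesets = 400L,
                    n_rhythmic_per_cluster = c(50L, 50L, 50L, 50L),
                    amplitude = 0, seed = 9L)
  ge <- generate_expression(cfg)
  de <- filter_differential(ge$dataset, p_thresh = 0.05, q_thresh = 1,
                            seed = 2L)
  rate <- mean(de$p < 0.05)
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(rate - 0.05), 3 * se + 0.01)
})

test_that("PWM library is well-formed, E-box bearing and reproducible", {
  cfg <- sim_config(seed = 5L)
  lib <- generate_pwm_library(cfg)
  expect_gte(length(lib), 10L)
  cons <- vapply(lib, pwm_consensus, "")
  expect_true(any(grepl("CACGTG", cons[vapply(lib, `[[`, "", "family") ==
                                         "CLOCK:BMAL1"])))
  for (p in lib) {
    expect_true(all(abs(colSums(p$mat) - 1) < 1e-9))
    expect_true(ncol(p$mat) >= 8 && ncol(p$mat) <= 14)
    expect_true(all(p$info >= 0 & p$info <= 2))
    expect_length(p$core, 4L)
  }
  expect_true(all(c("STAT", "FKHD", "CREB", "RXRF", "KLFS", "AHRR",
                    "EBOX", "PARF", "RORA") %in% pwm_families(lib)))
  lib2 <- generate_pwm_library(cfg)
  expect_identical(lapply(lib, `[[`, "mat"), lapply(lib2, `[[`, "mat"))
})

test_that("promoter bundle: planted sites, GC composition, determinism", {
  cfg <- sim_config(n_genes_promoter = 40L, n_background_genes = 20L,
                    gc_foreground = 0.6,
                    planted_family_presence = c(CREB = 1.0), seed = 13L)
  lib <- generate_pwm_library(cfg)
  pr <- generate_promoters(cfg, lib)
  refs <- pr$promoters[pr$promoters$species == "rat" &
                         pr$promoters$gene %in% pr$truth$foreground_genes, ]
  # presence 1.0: every reference promoter carries the planted site, and
  # the recorded coordinates match the sequence
  st <- pr$truth$planted_sites
  expect_true(all(pr$truth$foreground_genes %in%
                    st$gene[st$family == "CREB"]))
  cons <- pwm_consensus(lib[[which(vapply(lib, `[[`, "", "family") ==
                                     "CREB")[1]]])
  for (i in seq_len(nrow(st))) {
    if (st$family[i] != "CREB") next
    s <- refs$sequence[refs$gene == st$gene[i]]
    frag <- substr(s, st$start[i] + 1, st$end[i])
    if (st$strand[i] == "-")
      frag <- paste(rev(strsplit(chartr("ACGT", "TGCA", frag), "")[[1]]),
                    collapse = "")
    expect_equal(frag, cons)
  }
  gc <- promoter_gc(refs)
  expect_lt(abs(mean(gc) - 0.6), 0.02)
  pr2 <- generate_promoters(cfg, lib)
  expect_identical(pr$promoters, pr2$promoters)
  # planted coordinates lie inside conserved blocks
  bl <- pr$truth$conserved_blocks
  for (i in seq_len(nrow(st))) {
    b <- bl[bl$gene == st$gene[i], ]
    expect_true(any(st$start[i] >= b$start & st$end[i] <= b$end))
  }
})

test_that("presence rate zero leaves only background-level hits", {
  cfg <- sim_config(n_genes_promoter = 30L, n_background_genes = 30L,
                    planted_family_presence = c(CREB = 0), seed = 17L)
  lib <- generate_pwm_library(cfg)
  pr <- generate_promoters(cfg, lib)
  creb <- lib[[which(vapply(lib, `[[`, "", "family") == "CREB")[1]]]
  hit_rate <- function(genes) {
    mean(vapply(genes, function(g) {
      s <- pr$promoters$sequence[pr$promoters$gene == g &
                                   pr$promoters$species == "rat"]
      nrow(scan_pwm(s, creb)) > 0
    }, TRUE))
  }
  fg <- hit_rate(pr$truth$foreground_genes)
  bg <- hit_rate(pr$truth$background_genes)
  se <- sqrt(max(bg * (1 - bg), 0.01) / 30)
  expect_lte(fg, bg + 3 * se + 0.05)
})

test_that("expression TSV and promoter FASTA round-trip without loss", {
  cfg <- sim_config(n_probesets = 60L,
                    n_rhythmic_per_cluster = c(5L, 5L, 5L, 5L),
                    n_genes_promoter = 4L, n_background_genes = 3L,
                    seed = 23L)
  ge <- generate_expression(cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(ge$dataset, f)
  back <- read_expression_tsv(f)
  expect_equal(back$values, ge$dataset$values)
  expect_equal(back$samples$timepoint_h, ge$dataset$samples$timepoint_h)
  lib <- generate_pwm_library(cfg)
  pr <- generate_promoters(cfg, lib)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_promoters_fasta(pr$promoters, fa)
  back2 <- read_promoters_fasta(fa)
  expect_equal(back2$sequence, pr$promoters$sequence)
  expect_equal(back2$gene, pr$promoters$gene)
  expect_equal(back2$tss_offset, pr$promoters$tss_offset)
  pj <- withr::local_tempfile(fileext = ".txt")
  write_pwm_jaspar(lib, pj)
  lib2 <- read_pwm_jaspar(pj)
  expect_equal(length(lib2), length(lib))
  expect_equal(vapply(lib2, pwm_consensus, ""),
               vapply(lib, pwm_consensus, ""))
  expect_equal(vapply(lib2, `[[`, 0, "matrix_threshold"),
               vapply(lib, `[[`, 0, "matrix_threshold"),
               tolerance = 1e-5)
})
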