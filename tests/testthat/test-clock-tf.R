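# Stage 5: ccTF identification, presence matrix, frequent-set mining,
# GC-matched background, enrichment scoring.

test_that("identify_ccTFs requires DE + TF annotation + an E-box hit", {
  ann <- data.frame(gene = c("tf1", "tf2", "g3"),
                    family = c("STAT", "FKHD", "none"))
  sl <- list(
    tf1 = list(fake_site_list(c("CLOCK:BMAL1", "CREB"))),
    tf2 = list(fake_site_list("CREB")),
    g3 = list(fake_site_list("CLOCK:BMAL1")))
  # DE + TF + E-box -> emitted; DE + TF without E-box -> not;
  # DE non-TF with E-box (g3 not in the annotation) -> not
  out <- identify_ccTFs(c("tf1", "tf2", "g3"), ann[1:2, ], sl)
  expect_equal(out$gene, "tf1")
  expect_equal(out$family, "STAT")
  # non-DE TF with E-box -> not emitted
  out1b <- identify_ccTFs("tf2", ann[1:2, ], sl)
  expect_equal(nrow(out1b), 0L)
  # TF without promoter annotation: warning, skipped
  ann3 <- data.frame(gene = "tf9", family = "STAT")
  expect_warning(out3 <- identify_ccTFs("tf9", ann3, sl), "tf9")
  expect_equal(nrow(out3), 0L)
})

test_that("presence matrix follows the any-promoter rule", {
  sl <- list(
    gA = list(fake_site_list("GATA"), fake_site_list("CREB")),
    gB = list(fake_site_list("GATA")),
    gC = list())
  pm <- gene_presence_matrix(c("gA", "gB", "gC"), c("CREB", "GATA"), sl)
  expect_true(pm["gA", "CREB"])   # hit only on the second promoter
  expect_true(pm["gB", "GATA"])
  expect_false(pm["gB", "CREB"])
  expect_false(any(pm["gC", ]))
  expect_error(gene_presence_matrix("gA", character(0), sl),
               class = "clockmine_invalid_input")
})

test_that("planted presence rate is reflected in the scanned matrix", {
  cfg <- sim_config(n_genes_promoter = 100L, n_background_genes = 10L,
                    planted_family_presence = c(CREB = 0.8), seed = 47L)
  lib <- generate_pwm_library(cfg)
  pr <- generate_promoters(cfg, lib)
  creb_lib <- pwm_library(lib[vapply(lib, `[[`, "", "family") == "CREB"])
  refs <- pr$promoters[pr$promoters$species == "rat" &
                         pr$promoters$gene %in% pr$truth$foreground_genes, ]
  sl <- lapply(seq_len(nrow(refs)), function(i) {
    list(build_site_list(refs$sequence[i], creb_lib,
                         promoter_id = refs$promoter_id[i]))
  })
  names(sl) <- refs$gene
  pm <- gene_presence_matrix(refs$gene, "CREB", sl)
  expect_lt(abs(mean(pm[, "CREB"]) - 0.8), 0.1)
})

test_that("mining: closed-form cases and support on conjunctions", {
  pm <- matrix(TRUE, 5, 3, dimnames = list(paste0("g", 1:5),
                                           c("A", "B", "C")))
  out <- mine_frequent_tf_sets(pm, support_thresh = 0.7)
  expect_equal(nrow(out), 7L)          # all non-empty subsets
  expect_true(all(out$support == 1))
  pm2 <- matrix(FALSE, 10, 2, dimnames = list(paste0("g", 1:10),
                                              c("A", "B")))
  pm2[1:7, "A"] <- TRUE
  pm2[4:10, "B"] <- TRUE               # A on 7, B on 7, A&B on 4
  out2 <- mine_frequent_tf_sets(pm2, support_thresh = 0.7)
  expect_setequal(out2$set, c("A", "B"))
  expect_error(mine_frequent_tf_sets(pm, support_thresh = 0),
               class = "clockmine_invalid_input")
  expect_equal(nrow(mine_frequent_tf_sets(pm[0, , drop = FALSE])), 0L)
})

test_that("mining equals brute-force enumeration on random matrices", {
  set.seed(51)
  for (i in 1:20) {
    pm <- matrix(runif(20 * 8) < 0.6, 20, 8,
                 dimnames = list(paste0("g", 1:20), LETTERS[1:8]))
    thr <- sample(c(0.25, 0.4, 0.6), 1)
    mined <- mine_frequent_tf_sets(pm, support_thresh = thr)
    brute <- mine_bruteforce(pm, thr)
    expect_equal(mined, brute)
  }
})

test_that("mined supports are antimonotone over subset pairs", {
  set.seed(52)
  pm <- matrix(runif(30 * 6) < 0.7, 30, 6,
               dimnames = list(paste0("g", 1:30), LETTERS[1:6]))
  mined <- mine_frequent_tf_sets(pm, support_thresh = 0.3)
  mem <- strsplit(mined$set, ";")
  for (i in seq_along(mem)) for (j in seq_along(mem)) {
    if (i == j || !all(mem[[i]] %in% mem[[j]])) next
    expect_gte(mined$support[i], mined$support[j])
  }
})

test_that("GC-matched background reproduces the foreground histogram", {
  set.seed(53)
  fg <- stats::setNames(runif(100, 0.55, 0.6), paste0("f", 1:100))
  pool_uni <- stats::setNames(runif(500, 0.55, 0.6), paste0("b", 1:500))
  bg <- build_gc_matched_background(fg, pool_uni, size = 200, seed = 2)
  expect_true(all(bg$gc >= 0.55 & bg$gc <= 0.6))
  # bimodal pool, unimodal foreground: selection matches the foreground
  pool_bi <- stats::setNames(c(runif(600, 0.35, 0.45),
                               runif(600, 0.55, 0.65)),
                             paste0("c", 1:1200))
  fg_uni <- stats::setNames(runif(150, 0.55, 0.65), paste0("f", 1:150))
  bg2 <- build_gc_matched_background(fg_uni, pool_bi, size = 300, seed = 3)
  edges <- seq(0, 1, 0.05)
  ofg <- table(cut(fg_uni, edges))
  obg <- table(cut(bg2$gc, edges))
  use <- ofg + obg > 0
  chi <- suppressWarnings(
    stats::chisq.test(rbind(as.vector(ofg[use]), as.vector(obg[use]))))
  expect_gt(chi$p.value, 0.05)
  bg3 <- build_gc_matched_background(fg_uni, pool_bi, size = 300, seed = 3)
  expect_identical(bg2, bg3)
  w <- capture_warnings(
    small <- build_gc_matched_background(fg_uni, pool_bi[1:50], size = 300,
                                         seed = 1))
  expect_true(any(grepl("scaled down", w)))
  expect_lte(nrow(small), 50L)
})

test_that("score_tf_sets: counts, degenerate enrichment, absent families", {
  # population engineered so B=10, b=5, N=4, n=4
  genes <- paste0("g", 1:10)
  sl <- lapply(seq_along(genes), function(i) {
    list(fake_site_list(if (i <= 5) c("CREB", "GATA") else "GATA"))
  })
  names(sl) <- genes
  out <- score_tf_sets(data.frame(set = "CREB", support = 1),
                       foreground_genes = genes[1:4],
                       background = genes, site_lists = sl, seed = 1)
  expect_equal(out$B, 10L); expect_equal(out$b, 5L)
  expect_equal(out$N, 4L); expect_equal(out$n, 4L)
  expect_equal(out$p, 5 / 210, tolerance = 1e-12)
  # present everywhere: no enrichment
  out2 <- score_tf_sets(data.frame(set = "GATA", support = 1),
                        foreground_genes = genes[1:4],
                        background = genes, site_lists = sl, seed = 1)
  expect_equal(out2$p, 1)
  expect_warning(
    out3 <- score_tf_sets(data.frame(set = "ZZZ", support = 1),
                          foreground_genes = genes[1:4],
                          background = genes, site_lists = sl, seed = 1),
    "absent")
  expect_equal(out3$n, 0L)
  expect_equal(out3$p, 1)
})

test_that("enrichment p-values are calibrated under a random foreground", {
  set.seed(57)
  genes <- paste0("g", 1:200)
  pres <- runif(200) < 0.3
  sl <- lapply(seq_along(genes), function(j) {
    list(fake_site_list(if (pres[j]) "CREB" else "GATA"))
  })
  names(sl) <- genes
  reject <- vapply(1:400, function(i) {
    fg <- sample(genes, 20)
    out <- score_tf_sets(data.frame(set = "CREB", support = NA),
                         foreground_genes = fg, background = genes,
                         site_lists = sl, seed = 1)
    out$p < 0.05
  }, TRUE)
  rate <- mean(reject)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})
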