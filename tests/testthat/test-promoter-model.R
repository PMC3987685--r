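# Stage 4: promoter windows, PWM scanning, threshold calibration,
# conservation, footprinting, regulator reports.

toy_pwm <- function(weights = c(0.7, 1, 1, 1), bases = c("A", "G", "C", "T"),
                    threshold = 0.5) {
  mat <- matrix((1 - rep(weights, each = 4)) / 3, nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  mat[cbind(match(bases, rownames(mat)), seq_along(bases))] <- weights
  build_pwm("TOY", "TOY", mat, matrix_threshold = threshold)
}

test_that("promoter windows follow strand conventions and truncate", {
  w <- extract_promoter_window(1000, "+")
  expect_equal(c(w$start, w$end), c(500, 1100))
  expect_false(w$revcomp)
  w2 <- extract_promoter_window(1000, "-")
  expect_equal(c(w2$start, w2$end), c(900, 1500))
  expect_true(w2$revcomp)
  expect_warning(w3 <- extract_promoter_window(200, "+",
                                               chrom_length = 1e6),
                 "truncated")
  expect_equal(c(w3$start, w3$end), c(0, 300))
  expect_error(extract_promoter_window(100, "+", upstream = 0,
                                       downstream = 0),
               class = "clockmine_invalid_input")
})

test_that("consensus scores 1.0 on both strands; scores match the formula", {
  p <- toy_pwm()
  cons <- pwm_consensus(p)
  pad <- paste0("TTTT", cons, "TTTT")
  hits <- scan_pwm(pad, p)
  expect_true(any(hits$matrix_score == 1 & hits$strand == "+"))
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", pad), "")[[1]]),
              collapse = "")
  hits_rc <- scan_pwm(rc, p)
  expect_equal(sort(hits_rc$matrix_score), sort(hits$matrix_score))
  expect_true(any(hits_rc$matrix_score == 1 & hits_rc$strand == "-"))
  # direct formula oracle: score of "CGCT" against the toy matrix
  # (consensus AGCT): position 1 carries the mismatch
  I <- p$info
  f <- p$mat
  expected <- (I[1] * f["C", 1] + I[2] * f["G", 2] + I[3] * f["C", 3] +
                 I[4] * f["T", 4]) /
    sum(I * apply(f, 2, max))
  got <- scan_pwm(paste0("CGCT"), toy_pwm(threshold = 0),
                  core_thresh = 0)
  expect_equal(got$matrix_score[got$strand == "+"], unname(expected))
})

test_that("N positions contribute nothing and all-N promoters scan empty", {
  p <- toy_pwm(threshold = 0)
  full <- scan_pwm("AGCT", p, core_thresh = 0)
  withN <- scan_pwm("NGCT", p, core_thresh = 0)
  I <- p$info; f <- p$mat
  drop1 <- I[1] * f["A", 1] / sum(I * apply(f, 2, max))
  plus <- function(h) h$matrix_score[h$strand == "+"]
  expect_equal(plus(withN), plus(full) - unname(drop1))
  lib <- pwm_library(list(toy_pwm()))
  expect_equal(nrow(build_site_list(strrep("N", 50), lib)), 0L)
})

test_that("threshold calibration bounds the background hit rate", {
  cfg <- sim_config(seed = 19L)
  lib <- generate_pwm_library(cfg)
  pwm <- lib[[which(vapply(lib, `[[`, "", "family") == "FKHD")[1]]]
  set.seed(20)
  mk_bg <- function(n_kb) {
    vapply(seq_len(n_kb), function(i) {
      paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
            collapse = "")
    }, "")
  }
  train <- mk_bg(150)
  heldout <- mk_bg(100)
  cal <- calibrate_matrix_threshold(pwm, train, target_rate = 0.3)
  hits <- clockmine:::scan_pwm_multi(heldout, cal)
  rate <- nrow(hits) / 100
  expect_lte(rate, 0.3 + 3 * sqrt(0.3 / 100))
  # infinite target rate: threshold drops to the floor (all gated windows)
  cal_inf <- suppressWarnings(
    calibrate_matrix_threshold(pwm, train[1:2], target_rate = Inf))
  gated <- clockmine:::scan_pwm_multi(train[1:2], cal_inf,
                                      apply_matrix_threshold = FALSE)
  expect_lte(cal_inf$matrix_threshold, min(gated$matrix_score))
  # determinism
  cal2 <- calibrate_matrix_threshold(pwm, train, target_rate = 0.3)
  expect_identical(cal$matrix_threshold, cal2$matrix_threshold)
})

test_that("site lists are sorted, deduplicated and recover planted sites", {
  cfg <- sim_config(n_genes_promoter = 8L, n_background_genes = 4L,
                    planted_family_presence = c(CREB = 1.0), seed = 29L)
  lib <- generate_pwm_library(cfg)
  pr <- generate_promoters(cfg, lib)
  st <- pr$truth$planted_sites
  g <- pr$truth$foreground_genes[1]
  s <- pr$promoters$sequence[pr$promoters$gene == g &
                               pr$promoters$species == "rat"]
  sl <- build_site_list(s, lib, promoter_id = "ref")
  expect_true(all(diff(sl$start) >= 0))
  expect_false(any(duplicated(sl[, c("matrix_id", "start", "strand")])))
  planted <- st[st$gene == g & st$family == "CREB", ]
  expect_true(any(sl$family == "CREB" & sl$start == planted$start))
})

test_that("conservation: identical orthologs, random orthologs, planted blocks", {
  set.seed(33)
  ref <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
  oset <- list(reference = ref, orthologs = rep(ref, 3))
  cons <- find_conserved_regions(oset)
  expect_equal(nrow(cons), 1L)
  expect_equal(c(cons$start, cons$end), c(0L, 400L))
  rand <- vapply(1:3, function(i) {
    paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  }, "")
  cons_r <- find_conserved_regions(list(reference = ref, orthologs = rand))
  cov <- if (nrow(cons_r) == 0) 0 else sum(cons_r$end - cons_r$start) / 400
  expect_lt(cov, 0.05)
  expect_error(find_conserved_regions(list(reference = ref,
                                           orthologs = rand[1:2])),
               class = "clockmine_invalid_input")
  # planted conserved blocks are recovered nearly in full
  cfg <- sim_config(n_genes_promoter = 6L, n_background_genes = 3L,
                    seed = 35L)
  lib <- generate_pwm_library(cfg)
  pr <- generate_promoters(cfg, lib)
  recovered <- total <- 0
  for (g in pr$truth$foreground_genes) {
    cr <- find_conserved_regions(pr$promoters[pr$promoters$gene == g, ])
    mask <- rep(FALSE, cfg$promoter_len)
    for (i in seq_len(nrow(cr))) mask[(cr$start[i] + 1):cr$end[i]] <- TRUE
    bl <- pr$truth$conserved_blocks[pr$truth$conserved_blocks$gene == g, ]
    for (i in seq_len(nrow(bl))) {
      idx <- (bl$start[i] + 1):bl$end[i]
      recovered <- recovered + sum(mask[idx])
      total <- total + length(idx)
    }
  }
  expect_gte(recovered / total, 0.9)
})

test_that("footprint filter: identity, annihilator, 50% boundary", {
  sl <- fake_site_list(c("CREB", "EBOX", "RORA"))
  whole <- data.frame(start = 0L, end = 1000L)
  expect_equal(nrow(footprint_filter(sl, whole)), nrow(sl))
  expect_true(all(footprint_filter(sl, whole)$in_conserved_region))
  none <- data.frame(start = integer(0), end = integer(0))
  expect_equal(nrow(footprint_filter(sl, none)), 0L)
  # hit [20, 30): exactly half inside [25, 100) is retained,
  # less than half inside [26, 100) is dropped
  one <- fake_site_list("CREB")
  expect_equal(nrow(footprint_filter(one, data.frame(start = 25L,
                                                     end = 100L))), 1L)
  expect_equal(nrow(footprint_filter(one, data.frame(start = 26L,
                                                     end = 100L))), 0L)
})

test_that("enriched_regulators applies the inclusive 70% common threshold", {
  lists <- c(
    lapply(1:7, function(i) fake_site_list(c("CREB", "GATA"))),
    lapply(8:10, function(i) fake_site_list("GATA")))
  names(lists) <- paste0("g", 1:10)
  lists <- lapply(lists, list)
  out <- enriched_regulators(paste0("g", 1:10), lists)
  expect_true("CREB" %in% out$family)
  expect_equal(out$support[out$family == "CREB"], 0.7)
  # on 6 of 10 genes only: below threshold
  lists2 <- c(
    lapply(1:6, function(i) list(fake_site_list("CREB"))),
    lapply(7:10, function(i) list(fake_site_list("GATA"))))
  names(lists2) <- paste0("g", 1:10)
  out2 <- enriched_regulators(paste0("g", 1:10), lists2)
  expect_false("CREB" %in% out2$family)
  expect_error(enriched_regulators(character(0), lists),
               class = "clockmine_invalid_input")
})

test_that("scanning the reverse complement preserves the score multiset", {
  cfg <- sim_config(seed = 39L)
  lib <- generate_pwm_library(cfg)
  set.seed(40)
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
             collapse = "")
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
              collapse = "")
  for (p in lib[1:4]) {
    h1 <- scan_pwm(s, p, core_thresh = 0.6)
    h2 <- scan_pwm(rc, p, core_thresh = 0.6)
    expect_equal(sort(h1$matrix_score), sort(h2$matrix_score))
    expect_equal(sort(h1$start), sort(nchar(s) - h2$end))
  }
})
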