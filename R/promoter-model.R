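# Stage 4: remodel promoters into ordered binding-site lists by
# information-weighted PWM scanning, find conserved regions across
# orthologous promoters by seed-and-extend ungapped alignment, and report
# footprint-supported TF families common to a gene set.

#' Promoter window around a transcription start site
#'
#' Plus strand: [tss - upstream, tss + downstream); minus strand:
#' [tss - downstream, tss + upstream), to be reverse-complemented after
#' extraction. Coordinates are 0-based half-open and truncated at the
#' chromosome edges with a warning.
#'
#' @param tss 0-based TSS coordinate.
#' @param strand "+" or "-".
#' @param upstream,downstream window extents in bp (defaults 500/100, the
#'   TFBS-dense proximal promoter).
#' @param chrom_length chromosome length for truncation.
#' @return list with `start`, `end`, `strand` and `revcomp` (whether the
#'   extracted sequence must be reverse-complemented).
#' @export
extract_promoter_window <- function(tss, strand, upstream = 500L,
                                    downstream = 100L,
                                    chrom_length = Inf) {
  if (upstream + downstream <= 0) stop_invalid("non-positive window")
  if (tss < 0 || tss > chrom_length) stop_invalid("tss outside chromosome")
  if (!strand %in% c("+", "-")) stop_invalid("strand must be + or -")
  if (strand == "+") {
    start <- tss - upstream; end <- tss + downstream
  } else {
    start <- tss - downstream; end <- tss + upstream
  }
  if (start < 0 || end > chrom_length) {
    warning("promoter window truncated at chromosome edge")
    start <- max(start, 0)
    end <- min(end, chrom_length)
  }
  list(start = start, end = end, strand = strand,
       revcomp = strand == "-")
}

encode_dna <- function(sequence) {
  x <- match(strsplit(toupper(sequence), "")[[1]], DNA_BASES)
  x[is.na(x)] <- 0L  # N and other ambiguity codes
  x
}

# Batched scan of many sequences with one PWM: the encoded sequences are
# concatenated and scored in single vector passes; windows straddling
# sequence boundaries are discarded by index arithmetic. Returns a
# data.frame (seq_idx, start, strand, core_score, matrix_score) of gated
# hits. Equivalent to scan_pwm per sequence (property-tested).
scan_pwm_multi <- function(seqs, pwm, core_thresh = 0.75,
                           apply_matrix_threshold = TRUE) {
  L <- ncol(pwm$mat)
  lens <- nchar(seqs)
  usable <- lens >= L
  empty <- data.frame(seq_idx = integer(0), start = integer(0),
                      strand = character(0), core_score = numeric(0),
                      matrix_score = numeric(0))
  if (!any(usable)) return(empty)
  offs <- cumsum(c(0L, lens))[seq_along(seqs)]
  # valid window start positions (1-based, concatenated coordinates)
  valid <- unlist(lapply(which(usable), function(i) {
    offs[i] + seq_len(lens[i] - L + 1L)
  }))
  seq_of <- rep.int(which(usable), lens[usable] - L + 1L)
  res <- list()
  for (str in c("+", "-")) {
    enc <- if (str == "+") {
      unlist(lapply(seqs, encode_dna))
    } else {
      unlist(lapply(seqs, function(s) {
        encode_dna(paste(revcomp_chars(strsplit(toupper(s), "")[[1]]),
                         collapse = ""))
      }))
    }
    core <- pwm_window_scores(enc, pwm, pwm$core)[valid]
    gate <- which(core >= core_thresh)
    if (length(gate) == 0L) next
    full <- pwm_scores_at(enc, pwm, valid[gate])
    keep <- if (apply_matrix_threshold) {
      which(full >= pwm$matrix_threshold)
    } else seq_along(gate)
    if (length(keep) == 0L) next
    g <- gate[keep]
    local0 <- valid[g] - offs[seq_of[g]] - 1L  # 0-based within sequence
    start0 <- if (str == "+") local0 else lens[seq_of[g]] - local0 - L
    res[[str]] <- data.frame(seq_idx = seq_of[g], start = start0,
                             strand = str, core_score = core[g],
                             matrix_score = full[keep])
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# full matrix similarity at selected window positions only
pwm_scores_at <- function(enc, pwm, at) {
  L <- ncol(pwm$mat)
  w <- pwm$mat * rep(pwm$info, each = 4L)
  denom <- sum(pwm$info * apply(pwm$mat, 2L, max))
  num <- numeric(length(at))
  for (j in seq_len(L)) {
    b <- enc[at + j - 1L]
    ok <- b > 0L
    num[ok] <- num[ok] + w[cbind(b[ok], j)]
  }
  num / denom
}

# information-weighted similarity of every window of an encoded sequence
# against a PWM, restricted to positions `which_pos`; N positions (code 0)
# contribute zero to the numerator
pwm_window_scores <- function(enc, pwm, which_pos) {
  L <- ncol(pwm$mat)
  n_win <- length(enc) - L + 1L
  if (n_win < 1L) return(numeric(0))
  w <- pwm$mat * rep(pwm$info, each = 4L)          # I(j) * f(b, j)
  wmax <- pwm$info * apply(pwm$mat, 2L, max)       # I(j) * max_b f(b, j)
  denom <- sum(wmax[which_pos])
  num <- numeric(n_win)
  for (j in which_pos) {
    b <- enc[j:(j + n_win - 1L)]
    contrib <- numeric(n_win)
    ok <- b > 0L
    contrib[ok] <- w[cbind(b[ok], j)]
    num <- num + contrib
  }
  num / denom
}

#' Scan a sequence with one PWM (MatInspector-style)
#'
#' Both strands are scanned. At each offset the core similarity is the
#' information-weighted match over the PWM's core positions and the matrix
#' similarity the same quantity over all positions (1.0 for the
#' consensus). A hit requires core similarity >= `core_thresh` and matrix
#' similarity >= the PWM's `matrix_threshold`.
#'
#' @param sequence promoter sequence (character, A/C/G/T/N).
#' @param pwm a `pwm`.
#' @param core_thresh core similarity threshold (default 0.75).
#' @return data.frame of hits: family, matrix_id, start, end (0-based
#'   half-open), strand, core_score, matrix_score.
#' @export
scan_pwm <- function(sequence, pwm, core_thresh = 0.75) {
  empty <- data.frame(family = character(0), matrix_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), core_score = numeric(0),
                      matrix_score = numeric(0))
  if (nchar(sequence) < ncol(pwm$mat)) return(empty)
  L <- ncol(pwm$mat)
  n <- nchar(sequence)
  hits <- list()
  for (str in c("+", "-")) {
    enc <- if (str == "+") encode_dna(sequence) else
      encode_dna(paste(revcomp_chars(strsplit(toupper(sequence), "")[[1]]),
                       collapse = ""))
    core <- pwm_window_scores(enc, pwm, pwm$core)
    pass_core <- which(core >= core_thresh)
    if (length(pass_core) == 0L) next
    mat_score <- rep(NA_real_, length(core))
    # matrix similarity only where the core passes (the scan's gate)
    full <- pwm_window_scores(enc, pwm, seq_len(L))
    mat_score[pass_core] <- full[pass_core]
    sel <- pass_core[full[pass_core] >= pwm$matrix_threshold]
    if (length(sel) == 0L) next
    start0 <- if (str == "+") sel - 1L else n - (sel - 1L) - L
    hits[[str]] <- data.frame(family = pwm$family,
                              matrix_id = pwm$matrix_id,
                              start = start0, end = start0 + L,
                              strand = str,
                              core_score = core[sel],
                              matrix_score = full[sel])
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Calibrate a PWM's matrix-similarity threshold on background sequence
#'
#' Chooses the smallest threshold giving at most `target_rate` hits per kb
#' (both strands, core similarity gate applied) on the supplied background
#' sequences; this mimics per-matrix "optimised" thresholds that minimise
#' false-positive matches in non-regulatory sequence.
#'
#' @param pwm a `pwm`.
#' @param background_sequences character vector of background sequences
#'   (>= 100 kb total recommended).
#' @param target_rate maximum background hits per kb (default 0.3).
#' @param core_thresh core similarity gate.
#' @return the `pwm` with `matrix_threshold` replaced by the calibrated
#'   value (1.0 with a warning if the rate is unattainable).
#' @export
calibrate_matrix_threshold <- function(pwm, background_sequences,
                                       target_rate = 0.3,
                                       core_thresh = 0.75) {
  total_kb <- sum(nchar(background_sequences)) / 1000
  if (total_kb < 100)
    warning("background shorter than 100 kb; calibration may be unstable")
  scores <- scan_pwm_multi(background_sequences, pwm,
                           core_thresh = core_thresh,
                           apply_matrix_threshold = FALSE)$matrix_score
  allowed <- floor(target_rate * total_kb)
  thr <- if (length(scores) <= allowed) {
    if (length(scores) == 0L) 0 else min(scores)
  } else {
    cand <- sort(unique(scores))
    ok <- cand[vapply(cand, function(s) sum(scores >= s) <= allowed, TRUE)]
    if (length(ok) == 0L || min(ok) > 1) {
      warning("target background rate unattainable; threshold set to 1.0")
      1.0
    } else min(ok)
  }
  pwm$matrix_threshold <- min(thr, 1.0)
  pwm
}

#' Calibrate every matrix of a library
#' @param library a `pwm_library`.
#' @inheritParams calibrate_matrix_threshold
#' @return the calibrated `pwm_library`.
#' @export
calibrate_library <- function(library, background_sequences,
                              target_rate = 0.3, core_thresh = 0.75) {
  pwm_library(lapply(library, calibrate_matrix_threshold,
                     background_sequences = background_sequences,
                     target_rate = target_rate, core_thresh = core_thresh))
}

#' Remodel a promoter into an ordered binding-site list
#'
#' Scans the promoter with every matrix of the library and returns the
#' union of hits sorted by start position (ties broken by family name),
#' deduplicated on (matrix_id, start, strand).
#'
#' @param promoter either a sequence string or a one-row promoter record
#'   (data.frame with `sequence` and `promoter_id`).
#' @param library a calibrated `pwm_library`.
#' @param core_thresh core similarity gate.
#' @param promoter_id id attached to the result.
#' @return object of class `site_list`: the hit data.frame with attribute
#'   `promoter_id`.
#' @export
build_site_list <- function(promoter, library, core_thresh = 0.75,
                            promoter_id = NULL) {
  if (is.data.frame(promoter)) {
    promoter_id <- promoter$promoter_id[1]
    sequence <- promoter$sequence[1]
  } else sequence <- promoter
  hits <- do.call(rbind, lapply(library, scan_pwm, sequence = sequence,
                                core_thresh = core_thresh))
  if (is.null(hits) || nrow(hits) == 0L) {
    hits <- data.frame(family = character(0), matrix_id = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), core_score = numeric(0),
                       matrix_score = numeric(0))
  } else {
    hits <- hits[!duplicated(hits[, c("matrix_id", "start", "strand")]), ]
    hits <- hits[order(hits$start, hits$family), ]
    rownames(hits) <- NULL
  }
  hits$in_conserved_region <- rep(NA, nrow(hits))
  structure(hits, promoter_id = promoter_id, class = c("site_list",
                                                       "data.frame"))
}

# per-ortholog conserved-position mask on the reference, by seed-and-extend
# on exact 8-mers: every shared 8-mer defines a diagonal; along each
# candidate diagonal, reference positions covered by a `window`-long
# ungapped stretch with identity >= identity_thresh are marked conserved
conserved_mask_one <- function(ref, orth, window = 20L,
                               identity_thresh = 0.7, k = 8L) {
  nr <- length(ref); no <- length(orth)
  mask <- rep(FALSE, nr)
  if (nr < k || no < k) return(mask)
  kmer <- function(x) {
    s <- paste(x, collapse = "")
    n <- length(x) - k + 1L
    substring(s, seq_len(n), seq_len(n) + k - 1L)
  }
  kr <- kmer(ref); ko <- kmer(orth)
  pos_o <- split(seq_along(ko), ko)
  idx <- which(kr %in% names(pos_o))
  if (length(idx) == 0L) return(mask)
  diags <- unique(unlist(lapply(idx, function(i) pos_o[[kr[i]]] - i)))
  need <- ceiling(identity_thresh * window)
  for (d in diags) {
    i0 <- max(1L, 1L - d); i1 <- min(nr, no - d)
    if (i1 - i0 + 1L < window) next
    seg <- i0:i1
    m <- ref[seg] == orth[seg + d]
    cs <- c(0L, cumsum(m))
    nw <- length(seg) - window + 1L
    wsum <- cs[(window + 1L):(window + nw)] - cs[1:nw]
    good <- which(wsum >= need)
    if (length(good) == 0L) next
    cov <- rep(FALSE, length(seg))
    for (gset in split(good, cumsum(c(1L, diff(good) > window)))) {
      a <- min(gset); b <- max(gset) + window - 1L
      cov[a:b] <- TRUE
    }
    mask[seg[cov]] <- TRUE
  }
  mask
}

#' Find conserved regions on a reference promoter
#'
#' A reference position is conserved if, in at least `min_species`
#' orthologous promoters, an ungapped local alignment of length `window`
#' covering it (found by seed-and-extend on exact 8-mers) has identity
#' >= `identity_thresh`. Maximal runs of conserved positions are returned
#' as intervals.
#'
#' @param oset list with `reference` (sequence string) and `orthologs`
#'   (character vector of >= 3 ortholog sequences), or an ortholog-set
#'   data.frame from [generate_promoters()] output for one gene (the `rat`
#'   row is the reference).
#' @param window alignment window length (bp).
#' @param identity_thresh minimum identity within the window.
#' @param min_species minimum number of orthologs supporting a position.
#' @return data.frame of 0-based half-open intervals (start, end) on the
#'   reference.
#' @export
find_conserved_regions <- function(oset, window = 20L,
                                   identity_thresh = 0.7,
                                   min_species = 2L) {
  if (is.data.frame(oset)) {
    ref <- oset$sequence[oset$species == "rat"][1]
    orths <- oset$sequence[oset$species != "rat"]
    oset <- list(reference = ref, orthologs = orths)
  }
  if (length(oset$orthologs) < 3L)
    stop_invalid("footprinting requires >= 3 orthologous promoters")
  ref <- strsplit(toupper(oset$reference), "")[[1]]
  support <- rep(0L, length(ref))
  for (o in oset$orthologs) {
    m <- conserved_mask_one(ref, strsplit(toupper(o), "")[[1]],
                            window = window,
                            identity_thresh = identity_thresh)
    support <- support + m
  }
  runs_to_intervals(support >= min_species)
}

#' Restrict a site list to conserved regions (phylogenetic footprinting)
#'
#' Retains hits whose interval overlaps a conserved interval by at least
#' half of the hit length (a hit exactly half inside is retained), and
#' sets `in_conserved_region`.
#'
#' @param slist a `site_list`.
#' @param conserved interval data.frame (start, end; 0-based half-open),
#'   e.g. from [find_conserved_regions()].
#' @return the filtered `site_list`.
#' @export
footprint_filter <- function(slist, conserved) {
  if (nrow(slist) == 0L || nrow(conserved) == 0L) {
    out <- slist[integer(0), ]
    return(structure(out, promoter_id = attr(slist, "promoter_id"),
                     class = class(slist)))
  }
  keep <- vapply(seq_len(nrow(slist)), function(i) {
    ov <- pmin(slist$end[i], conserved$end) -
      pmax(slist$start[i], conserved$start)
    len <- slist$end[i] - slist$start[i]
    max(ov, 0) * 2 >= len
  }, TRUE)
  out <- slist[keep, ]
  out$in_conserved_region <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  structure(out, promoter_id = attr(slist, "promoter_id"),
            class = class(slist))
}

#' TF families common to a gene set after footprinting
#'
#' A family is reported iff it has at least one conserved hit on at least
#' one promoter of at least `common_thresh` of the genes (inclusive at the
#' threshold). This is the footprint-based regulator report for a
#' co-expression cluster.
#'
#' @param gene_set character vector of gene ids.
#' @param footprint_lists named list: gene -> list of footprint-filtered
#'   `site_list`s over its promoters.
#' @param common_thresh common-presence threshold (default 0.7).
#' @return data.frame (family, support) sorted by support descending then
#'   family ascending.
#' @export
enriched_regulators <- function(gene_set, footprint_lists,
                                common_thresh = 0.7) {
  if (length(gene_set) == 0L) stop_invalid("gene_set must be non-empty")
  fams_per_gene <- lapply(gene_set, function(g) {
    sl <- footprint_lists[[g]]
    if (is.null(sl)) return(character(0))
    if (is.data.frame(sl)) sl <- list(sl)
    unique(unlist(lapply(sl, function(s) s$family)))
  })
  fams <- sort(unique(unlist(fams_per_gene)))
  if (length(fams) == 0L)
    return(data.frame(family = character(0), support = numeric(0)))
  supp <- vapply(fams, function(f) {
    mean(vapply(fams_per_gene, function(x) f %in% x, TRUE))
  }, 0)
  out <- data.frame(family = fams, support = supp)
  out <- out[supp >= common_thresh, ]
  out <- out[order(-out$support, out$family), ]
  rownames(out) <- NULL
  out
}

#' Write binding-site hits as BED
#'
#' chrom = promoter id, score = 1000 x matrix similarity.
#' @param slist a `site_list`.
#' @param path BED output file.
#' @export
write_sites_bed <- function(slist, path) {
  if (nrow(slist) == 0L) {
    writeLines(character(0), path)
    return(invisible(NULL))
  }
  bed <- data.frame(chrom = attr(slist, "promoter_id"),
                    start = slist$start, end = slist$end,
                    name = paste0(slist$family, "/", slist$matrix_id),
                    score = round(1000 * slist$matrix_score),
                    strand = slist$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
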