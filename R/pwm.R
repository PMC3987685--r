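# Position weight matrices: construction, information content, core
# positions, and plain-text I/O (JASPAR 4-row and TRANSFAC-style).

DNA_BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix object
#'
#' @param matrix_id unique matrix identifier.
#' @param family TF family name the matrix belongs to (e.g. "CREB",
#'   "EBOX", "CLOCK:BMAL1").
#' @param mat 4 x L numeric matrix of base frequencies or counts, rows
#'   named A, C, G, T. A pseudocount is added and columns renormalised to
#'   sum to 1.
#' @param matrix_threshold minimum matrix similarity for a hit, in (0, 1].
#'   Usually set later by [calibrate_matrix_threshold()].
#' @param core_len number of consecutive positions forming the core (the
#'   window maximising summed information content).
#' @param pseudocount added to every cell before renormalisation.
#' @return object of class `pwm` with fields `matrix_id`, `family`, `mat`,
#'   `info` (per-position information content in bits), `core` (core
#'   position indices) and `matrix_threshold`.
#' @export
build_pwm <- function(matrix_id, family, mat, matrix_threshold = 0.8,
                      core_len = 4L, pseudocount = 0.01) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop_invalid("mat must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 4L) stop_invalid("PWM length must be >= 4")
  if (any(mat < 0)) stop_invalid("mat must be non-negative")
  rownames(mat) <- DNA_BASES
  mat <- sweep(mat + pseudocount, 2L, colSums(mat + pseudocount), "/")
  info <- pmin(pmax(2 + colSums(mat * log2(mat)), 0), 2)
  core_len <- min(core_len, ncol(mat))
  win <- vapply(seq_len(ncol(mat) - core_len + 1L),
                function(i) sum(info[i:(i + core_len - 1L)]), 0)
  core <- which.max(win) + seq_len(core_len) - 1L
  structure(list(matrix_id = matrix_id, family = family, mat = mat,
                 info = info, core = core,
                 matrix_threshold = matrix_threshold),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (family %s): length %d, threshold %.3f, consensus %s\n",
              x$matrix_id, x$family, ncol(x$mat), x$matrix_threshold,
              pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (most frequent base per column)
#' @param pwm a `pwm` object.
#' @return character string of length L.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$mat, 2L, which.max)], collapse = "")
}

#' Bundle PWMs into a library
#' @param pwms list of `pwm` objects.
#' @return object of class `pwm_library`, a named list keyed by matrix id.
#' @export
pwm_library <- function(pwms) {
  stopifnot(all(vapply(pwms, inherits, TRUE, "pwm")))
  names(pwms) <- vapply(pwms, `[[`, "", "matrix_id")
  if (anyDuplicated(names(pwms))) stop_invalid("duplicate matrix ids")
  structure(pwms, class = "pwm_library")
}

#' @export
print.pwm_library <- function(x, ...) {
  cat(sprintf("pwm_library of %d matrices: %s\n", length(x),
              paste(vapply(x, `[[`, "", "family"), collapse = ", ")))
  invisible(x)
}

#' Families represented in a PWM library
#' @param library a `pwm_library`.
#' @return character vector of unique family names.
#' @export
pwm_families <- function(library) {
  unique(vapply(library, `[[`, "", "family"))
}

#' Write a PWM library as JASPAR-style text
#'
#' One record per matrix: a header line `>matrix_id family threshold`
#' followed by four rows `A [ f f ... ]` etc.
#'
#' @param library a `pwm_library`.
#' @param path output file.
#' @export
write_pwm_jaspar <- function(library, path) {
  lines <- unlist(lapply(library, function(p) {
    c(sprintf(">%s %s %.6f", p$matrix_id, p$family, p$matrix_threshold),
      vapply(DNA_BASES, function(b) {
        sprintf("%s [ %s ]", b,
                paste(formatC(p$mat[b, ], format = "f", digits = 6),
                      collapse = " "))
      }, ""))
  }))
  writeLines(lines, path)
}

#' Read a PWM library from JASPAR-style text
#' @param path file written by [write_pwm_jaspar()] or standard JASPAR
#'   4-row text (counts or frequencies; header `>id name [threshold]`).
#' @return a `pwm_library`.
#' @export
read_pwm_jaspar <- function(path) {
  lines <- readLines(path)
  starts <- grep("^>", lines)
  pwms <- lapply(starts, function(i) {
    hdr <- strsplit(sub("^>", "", lines[i]), "\\s+")[[1]]
    thr <- if (length(hdr) >= 3) as.numeric(hdr[3]) else 0.8
    rows <- lapply(lines[i + 1:4], function(l) {
      x <- strsplit(gsub("[][]", " ", sub("^\\s*[ACGTacgt]", "", l)),
                    "\\s+")[[1]]
      as.numeric(x[nzchar(x)])
    })
    build_pwm(hdr[1], if (length(hdr) >= 2) hdr[2] else hdr[1],
              do.call(rbind, rows), matrix_threshold = thr)
  })
  pwm_library(pwms)
}
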