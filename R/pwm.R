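DNA_BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from aligned sites
#'
#' Column probabilities are `(count + pseudocount) / (n + 4 * pseudocount)`.
#' Information content per position is `2 + sum(p * log2(p))` bits, so a
#' uniform column carries 0 bits and a fixed base close to 2.
#'
#' @param sites Character vector of equal-length A/C/G/T sequences (>= 2).
#' @param pseudocount Count added to every cell (default 0.25 per base).
#' @param background Named base frequencies (default uniform).
#' @return An object of class `itr_pwm`: list with `width`, `counts`
#'   (4 x width), `probs`, `ic`, `nsites`, `pseudocount`, `background`.
#' @export
#' @examples
#' pwm <- build_pwm(c("ACGT", "AGGT"), pseudocount = 1)
#' pwm$probs[, 2]
build_pwm <- function(sites, pseudocount = 0.25,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  sites <- toupper(sites)
  if (length(sites) < 2) stop("need at least 2 sites")
  w <- unique(nchar(sites))
  if (length(w) != 1) stop("sites must all have the same length")
  if (w < 4) stop("PWM width must be >= 4")
  if (any(!grepl("^[ACGT]+$", sites))) stop("sites must contain only A/C/G/T")
  stopifnot(setequal(names(background), DNA_BASES), all(background > 0))
  background <- background[DNA_BASES] / sum(background)
  mat <- do.call(rbind, strsplit(sites, ""))
  counts <- vapply(seq_len(w), function(j)
    vapply(DNA_BASES, function(b) sum(mat[, j] == b), 1L), integer(4))
  rownames(counts) <- DNA_BASES
  n <- length(sites)
  probs <- (counts + pseudocount) / (n + 4 * pseudocount)
  ic <- 2 + colSums(probs * log2(probs))
  structure(list(width = w, counts = counts, probs = probs, ic = ic,
                 nsites = n, pseudocount = pseudocount,
                 background = background),
            class = "itr_pwm")
}

#' @export
print.itr_pwm <- function(x, ...) {
  cat(sprintf("<itr_pwm> width %d, %d sites, total IC %.2f bits\n",
              x$width, x$nsites, sum(x$ic)))
  invisible(x)
}

#' @describeIn build_pwm Tidy a PWM into a long tibble
#'   (`position, base, prob, ic`).
#' @param x An `itr_pwm`.
#' @param ... Unused.
#' @export
tidy.itr_pwm <- function(x, ...) {
  tibble::tibble(
    position = rep(seq_len(x$width), each = 4L),
    base = rep(DNA_BASES, x$width),
    prob = as.vector(x$probs),
    ic = rep(x$ic, each = 4L)
  )
}

pwm_revcomp <- function(pwm) {
  p <- pwm
  p$probs <- p$probs[rev(DNA_BASES), rev(seq_len(p$width))]
  rownames(p$probs) <- DNA_BASES
  p$counts <- p$counts[rev(DNA_BASES), rev(seq_len(p$width))]
  rownames(p$counts) <- DNA_BASES
  p$ic <- rev(p$ic)
  p
}

score_offsets <- function(seqchr, probs, background) {
  w <- ncol(probs)
  L <- nchar(seqchr)
  if (L < w) return(numeric(0))
  lo <- log2(probs / background)   # 4 x w log-odds
  codes <- match(strsplit(toupper(seqchr), "")[[1]], DNA_BASES)
  n_off <- L - w + 1L
  sc <- numeric(n_off)
  for (j in seq_len(w)) {
    b <- codes[j:(j + n_off - 1L)]
    col <- lo[, j]
    contrib <- unname(col[b])
    contrib[is.na(contrib)] <- -Inf  # N or other: never matches
    sc <- sc + contrib
  }
  sc
}

#' Scan a sequence with a PWM
#'
#' Log-odds score `sum(log2(p(b,i) / bg(b)))` at every offset on both
#' strands; positions containing non-ACGT bases score `-Inf`. Offsets are
#' 0-based starts of the match window on the forward sequence.
#'
#' @param seq A single sequence (character or `DNAString`).
#' @param pwm An `itr_pwm` from [build_pwm()].
#' @param threshold Minimum log-odds score to report; `-Inf` reports every
#'   offset, `Inf` none.
#' @return Tibble `offset, strand, score` sorted by offset.
#' @export
pwm_scan <- function(seq, pwm, threshold) {
  stopifnot(inherits(pwm, "itr_pwm"), is.numeric(threshold),
            length(threshold) == 1, !is.na(threshold))
  seqchr <- toupper(as.character(seq))
  fwd <- score_offsets(seqchr, pwm$probs, pwm$background)
  rev_ <- score_offsets(seqchr, pwm_revcomp(pwm)$probs, pwm$background)
  out <- dplyr::bind_rows(
    tibble::tibble(offset = seq_along(fwd) - 1L, strand = "+", score = fwd),
    tibble::tibble(offset = seq_along(rev_) - 1L, strand = "-", score = rev_)
  )
  out |>
    dplyr::filter(.data$score >= threshold) |>
    dplyr::arrange(.data$offset, .data$strand)
}

#' Write a PWM in MEME minimal motif format
#' @param pwm An `itr_pwm`.
#' @param path Output path.
#' @param name Motif name.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwm, path, name = "motif_1") {
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(sprintf("%s %.6f", DNA_BASES, pwm$background), collapse = " "), "",
    sprintf("MOTIF %s", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            pwm$width, pwm$nsites),
    vapply(seq_len(pwm$width), function(j)
      paste(sprintf("%.6f", pwm$probs[, j]), collapse = "  "), "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a PWM from MEME minimal motif format
#' @param path MEME-format file (first motif is read).
#' @return An `itr_pwm` (counts reconstructed from nsites and probabilities).
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  bg_i <- grep("^Background letter frequencies", lines)
  background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  if (length(bg_i)) {
    f <- strsplit(trimws(lines[bg_i[1] + 1L]), "\\s+")[[1]]
    background <- stats::setNames(as.numeric(f[c(2, 4, 6, 8)]), f[c(1, 3, 5, 7)])
    background <- background[DNA_BASES]
  }
  hdr_i <- grep("^letter-probability matrix:", lines)
  if (!length(hdr_i)) stop("no letter-probability matrix in ", path)
  hdr <- lines[hdr_i[1]]
  w <- as.integer(sub(".*w= *(\\d+).*", "\\1", hdr))
  nsites <- as.integer(sub(".*nsites= *(\\d+).*", "\\1", hdr))
  if (is.na(nsites)) nsites <- 20L
  rows <- lines[(hdr_i[1] + 1L):(hdr_i[1] + w)]
  probs <- vapply(rows, function(r)
    as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4),
    USE.NAMES = FALSE)
  dimnames(probs) <- list(DNA_BASES, NULL)
  ic <- 2 + colSums(probs * log2(probs))
  counts <- round(probs * nsites)
  structure(list(width = w, counts = counts, probs = probs, ic = ic,
                 nsites = nsites, pseudocount = 0,
                 background = background),
            class = "itr_pwm")
}

#' Build a PWM from ChIP peak sequences anchored on consensus hits
#'
#' For each peak, the best-scoring consensus hit window inside the peak
#' (via [scan_consensus()]) is extracted and the aligned windows feed
#' [build_pwm()] — a verifiable stand-in for de novo motif discovery,
#' which is out of scope.
#'
#' @param peaks Peak interval tibble.
#' @param genome Named character vector or `DNAStringSet`.
#' @param consensus Consensus sequence used to anchor the windows.
#' @param config A [pipeline_config()].
#' @param pseudocount,background Passed to [build_pwm()].
#' @return An `itr_pwm`, or `NULL` if fewer than 2 peaks contain a full
#'   anchor window.
#' @export
peak_pwm <- function(peaks, genome, consensus, config = pipeline_config(),
                     pseudocount = 0.25,
                     background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (methods::is(genome, "DNAStringSet")) {
    nm <- names(genome); genome <- as.character(genome); names(genome) <- nm
  }
  consensus <- toupper(as.character(consensus))
  w <- nchar(consensus)
  sites <- character(0)
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    seqchr <- genome[[p$chrom]]
    if (is.null(seqchr)) next
    sub <- substr(seqchr, p$start + 1L, p$end)
    hits <- scan_consensus(stats::setNames(sub, "peak"), consensus, config)
    if (nrow(hits) == 0) next
    best <- hits[which.max(hits$score), ]
    # anchor a fixed-width window at the hit start so all sites align
    if (best$start + w > nchar(sub)) next
    win <- substr(sub, best$start + 1L, best$start + w)
    if (best$strand == "-") win <- revcomp_chr(win)
    if (grepl("^[ACGT]+$", win)) sites <- c(sites, win)
  }
  if (length(sites) < 2) return(NULL)
  build_pwm(sites, pseudocount = pseudocount, background = background)
}
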