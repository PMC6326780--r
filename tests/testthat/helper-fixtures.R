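# Shared fixtures and independent oracles. Everything here is generated in
# code; no stored data files.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# substitute deterministically at given 1-based positions (first listed
# alternative base), keeping substitutions interior so a local aligner
# cannot trim them off the ends
substitute_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- setdiff(BASES, ch[p])[1]
  paste(ch, collapse = "")
}

# ---- brute-force nearest-feature oracle (all pairs) -----------------------
oracle_nearest <- function(queries, targets) {
  res <- lapply(seq_len(nrow(queries)), function(i) {
    q <- queries[i, ]
    t <- targets[targets$chrom == q$chrom, ]
    if (nrow(t) == 0)
      return(list(distance = NA_integer_, target_name = NA_character_))
    gaps <- pmax(0L, pmax(q$start, t$start) - pmin(q$end, t$end))
    best <- which(gaps == min(gaps))
    best <- best[order(t$start[best], t$name[best])][1]
    list(distance = min(gaps), target_name = t$name[best])
  })
  tibble::tibble(distance = vapply(res, `[[`, 1L, "distance"),
                 target_name = vapply(res, `[[`, "", "target_name"))
}

# ---- exhaustive per-window local-alignment scanner oracle -----------------
# Independent route: Biostrings pairwiseAlignment (Smith-Waterman) on every
# window of width 2 * consensus length, with the same scoring scheme
# (match +1, mismatch -1, first gap base -2, extension -1), then the same
# two retention filters and best-per-overlap-cluster reduction.
oracle_scan <- function(seqchr, cons, cfg = pipeline_config(),
                        apply_filters = TRUE, min_keep = 0) {
  clen <- nchar(cons)
  L <- nchar(seqchr)
  w <- 2L * clen
  starts <- seq_len(max(1L, L - w + 1L))
  windows <- Biostrings::DNAStringSet(
    substring(seqchr, starts, pmin(starts + w - 1L, L)))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  collect <- function(pat, strand) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = windows, subject = Biostrings::DNAString(pat),
      type = "local", substitutionMatrix = mat,
      gapOpening = 1, gapExtension = 1)
    cols <- Biostrings::nchar(aln)           # alignment columns incl. gaps
    matches <- Biostrings::nmatch(aln)
    prow <- BiocGenerics::width(Biostrings::subject(aln))  # consensus positions
    s0 <- starts - 1L + BiocGenerics::start(Biostrings::pattern(aln)) - 1L
    e0 <- starts - 1L + BiocGenerics::end(Biostrings::pattern(aln))
    keep <- Biostrings::score(aln) > 0
    tibble::tibble(start = s0[keep], end = e0[keep], strand = strand,
                   score = Biostrings::score(aln)[keep],
                   identity = (matches / cols)[keep],
                   frac = (prow / clen)[keep])
  }
  hits <- rbind(collect(cons, "+"), collect(revcomp(cons), "-"))
  hits <- unique(hits)
  if (nrow(hits) == 0) return(hits)
  # HSP semantics: greedy non-redundant selection best-score-first (ties:
  # leftmost, then '+'), then the two retention filters on each survivor
  hits <- hits[order(-hits$score, hits$start, hits$strand != "+",
                     hits$end), ]
  ks <- integer(0); ke <- integer(0)
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!any(hits$start[i] < ke & hits$end[i] > ks)) {
      keep[i] <- TRUE
      ks <- c(ks, hits$start[i]); ke <- c(ke, hits$end[i])
    }
  }
  sel <- if (apply_filters) {
    keep & hits$identity >= cfg$min_identity &
      hits$frac >= cfg$min_length_frac
  } else {
    keep & hits$score >= min_keep
  }
  out <- hits[sel, ]
  out[order(out$start), c("start", "end", "strand", "score")]
}

# ---- exhaustive hypergeometric tail oracle --------------------------------
# direct enumeration over the support using exact binomial coefficients
oracle_hyper_tail <- function(N, K, n, k, direction) {
  xs <- max(0, n + K - N):min(n, K)
  probs <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  if (direction == "over") sum(probs[xs >= k]) else sum(probs[xs <= k])
}

# a cohort of genes/peaks/ITRs laid out in disjoint 20 kb slots matching
# the published per-class gene counts (97+61 bound, 35+10 distal, 172
# peak-only over 374 peak-bearing genes)
printed_count_cohort <- function() {
  spec <- rbind(
    data.frame(class = "bound", biotype = "protein_coding", n = 97),
    data.frame(class = "bound", biotype = "non_coding", n = 61),
    data.frame(class = "distal", biotype = "protein_coding", n = 35),
    data.frame(class = "distal", biotype = "non_coding", n = 10),
    data.frame(class = "none", biotype = "protein_coding", n = 172))
  rows <- spec[rep(seq_len(nrow(spec)), spec$n), ]
  slot <- 20000L
  genes <- itrs <- peaks <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    base <- (i - 1L) * slot
    gs <- base + 1000L; ge <- base + 15000L
    genes[[i]] <- tibble::tibble(chrom = "chrA", start = gs, end = ge,
                                 strand = "+",
                                 gene_id = sprintf("g%03d", i),
                                 biotype = rows$biotype[i])
    if (rows$class[i] %in% c("bound", "distal")) {
      itrs[[i]] <- tibble::tibble(chrom = "chrA", start = gs + 5000L,
                                  end = gs + 5028L, strand = "+",
                                  name = sprintf("itr%03d", i))
    }
    peak_off <- switch(rows$class[i],
                       bound = 5128L,    # 100 bp gap to the ITR
                       distal = 6500L,   # 1472 bp gap: > 500
                       none = 2000L)
    peaks[[i]] <- tibble::tibble(chrom = "chrA", start = gs + peak_off,
                                 end = gs + peak_off + 200L, strand = ".",
                                 name = sprintf("p%03d", i))
  }
  list(genes = gene_models(dplyr::bind_rows(genes)),
       itrs = dplyr::bind_rows(itrs),
       peaks = dplyr::bind_rows(peaks),
       truth = rows)
}
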