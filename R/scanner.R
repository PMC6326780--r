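revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# Provable lower bound on the raw alignment score of any hit passing both
# retention filters: a passing alignment has >= min_cols columns, at least
# ceil(min_identity * c) of them matches, and every non-match column costs
# at most gap_open. Used to prune DP candidates without ever losing a
# passing hit.
candidate_min_score <- function(consensus_len, config) {
  min_rows <- ceiling(config$min_length_frac * consensus_len)
  cols <- seq(min_rows, 2L * consensus_len)
  lo <- min(ceiling(config$min_identity * cols) * config$match -
              (cols - ceiling(config$min_identity * cols)) * config$gap_open)
  max(4L, as.integer(floor(lo)))
}

#' Scan a genome for decayed copies of a consensus ITR
#'
#' Local (Smith-Waterman, affine-gap) alignment of the consensus against
#' both strands of every sequence. A hit is retained when it covers at
#' least `min_length_frac` of the consensus length **and** at least
#' `min_identity` of its aligned columns match — two separate filters, the
#' strictest faithful reading of the classical "80% of the length and
#' identity" retention rule. Overlapping alignments are first merged
#' keeping the highest score (ties: leftmost, then `+` strand), then the
#' filters are applied to each locus's best alignment — the behaviour of
#' an HSP-reporting aligner, so a locus whose best alignment fails the
#' filters is rejected even if a weaker overlapping sub-alignment would
#' pass. `N` bases never match. IUPAC ambiguity codes in the consensus
#' match any listed base.
#'
#' Among equal-score tracebacks the diagonal (aligned-column) state is
#' preferred, making reported identity deterministic; note that identity at
#' a locus whose optimal score is achieved by several distinct paths is a
#' convention, unlike the locus, strand and score, which are
#' path-independent.
#'
#' @param genome Named character vector, single string, or
#'   [Biostrings::DNAStringSet].
#' @param consensus Consensus ITR sequence (character or `DNAString`),
#'   typically 28 bp for Hsmar1.
#' @param config A [pipeline_config()].
#' @param apply_filters Apply the two retention filters (default). With
#'   `FALSE`, all greedy-selected best local alignments scoring at or
#'   above the candidate bound are returned — the unfiltered alignment
#'   landscape, useful for diagnostics and cross-validation.
#' @return Interval tibble of hits: `chrom, start, end, strand, name,
#'   score, identity, aligned_consensus_frac`, sorted by position. Names
#'   encode the rank (`itr_00001`, ...).
#' @export
#' @examples
#' cons <- strrep("ACGT", 7)
#' g <- paste0(strrep("A", 50), cons, strrep("T", 50))
#' scan_consensus(c(chr1 = g), cons)
scan_consensus <- function(genome, consensus, config = pipeline_config(),
                           apply_filters = TRUE) {
  if (methods::is(genome, "DNAStringSet")) {
    nm <- names(genome)
    genome <- as.character(genome)
    names(genome) <- nm
  }
  consensus <- toupper(as.character(consensus))
  if (length(consensus) != 1 || !nzchar(consensus) ||
      length(genome) == 0 || any(!nzchar(genome)))
    stop("empty consensus or genome")
  if (is.null(names(genome)))
    names(genome) <- paste0("seq", seq_along(genome))
  clen <- nchar(consensus)
  if (all(nchar(genome) < clen)) {
    warning("consensus longer than every genome sequence; no hits possible")
    return(empty_hits())
  }
  min_score <- candidate_min_score(clen, config)
  rc <- revcomp_chr(consensus)

  hits <- purrr::imap_dfr(genome, function(seqchr, chrom) {
    if (nchar(seqchr) < clen) return(NULL)
    one <- function(pat, strand) {
      d <- sw_scan_cpp(seqchr, pat, config$match, config$mismatch,
                       config$gap_open, config$gap_ext, min_score)
      d <- tibble::as_tibble(d)
      d$strand <- strand
      d
    }
    dplyr::bind_rows(one(consensus, "+"), one(rc, "-")) |>
      dplyr::mutate(chrom = chrom)
  })
  if (nrow(hits) == 0) return(empty_hits())

  hits <- hits |>
    dplyr::mutate(
      identity = .data$matches / .data$columns,
      aligned_consensus_frac = .data$pattern_positions / clen
    ) |>
    dplyr::distinct(.data$chrom, .data$start, .data$end, .data$strand,
                    .keep_all = TRUE)
  merged <- merge_overlapping_hits(hits)
  if (apply_filters) {
    merged <- dplyr::filter(
      merged,
      .data$identity >= config$min_identity,
      .data$aligned_consensus_frac >= config$min_length_frac)
  }
  if (nrow(merged) == 0) return(empty_hits())
  merged |>
    dplyr::arrange(.data$chrom, .data$start, .data$end) |>
    dplyr::mutate(name = sprintf("itr_%05d", dplyr::row_number())) |>
    dplyr::select("chrom", "start", "end", "strand", "name", "score",
                  "identity", "aligned_consensus_frac")
}

empty_hits <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 strand = character(), name = character(), score = integer(),
                 identity = double(), aligned_consensus_frac = double())
}

# Greedy non-redundant selection of overlapping alignments, best score
# first (ties: leftmost, then '+' strand) -- the way an HSP-reporting
# aligner resolves overlapping local alignments. A weaker alignment
# overlapping a kept one is discarded; non-overlapping alignments are
# kept independently, so e.g. the two ITRs of a Made1 element survive a
# low-scoring alignment bridging them.
merge_overlapping_hits <- function(hits) {
  hits <- dplyr::arrange(hits, .data$chrom, dplyr::desc(.data$score),
                         .data$start, dplyr::desc(.data$strand == "+"),
                         .data$end)
  keep <- logical(nrow(hits))
  for (chrom in unique(hits$chrom)) {
    idx <- which(hits$chrom == chrom)
    ks <- integer(0); ke <- integer(0)
    for (i in idx) {
      if (!any(hits$start[i] < ke & hits$end[i] > ks)) {
        keep[i] <- TRUE
        ks <- c(ks, hits$start[i]); ke <- c(ke, hits$end[i])
      }
    }
  }
  hits[keep, ]
}

#' Classify ITR hits into remnant annotations
#'
#' Greedy left-to-right pairing of sorted hits: two adjacent hits on the
#' same chromosome in inverted orientation (opposite strands) separated by
#' a gap within `made1_spacer +/- spacer_tol` become one Made1 annotation;
#' inverted pairs with larger gaps up to `pair_span` become a paired
#' remnant; everything else is a solo ITR. Each hit belongs to exactly one
#' annotation.
#'
#' @param hits Hit tibble from [scan_consensus()] (sorted).
#' @param config A [pipeline_config()].
#' @return Tibble with `remnant_id, remnant_class, chrom, start, end,
#'   n_itrs, spacer_length, itr_names` (comma-joined member hit names).
#' @export
classify_remnants <- function(hits, config = pipeline_config()) {
  out <- list()
  if (nrow(hits) > 0) {
    hits <- dplyr::arrange(hits, .data$chrom, .data$start, .data$end)
    i <- 1L
    while (i <= nrow(hits)) {
      a <- hits[i, ]
      paired <- FALSE
      if (i < nrow(hits)) {
        b <- hits[i + 1L, ]
        if (b$chrom == a$chrom && b$strand != a$strand &&
            a$strand %in% c("+", "-") && b$strand %in% c("+", "-")) {
          gap <- max(0L, b$start - a$end)
          if (abs(gap - config$made1_spacer) <= config$spacer_tol) {
            out[[length(out) + 1L]] <- tibble::tibble(
              remnant_class = "made1", chrom = a$chrom,
              start = a$start, end = max(a$end, b$end), n_itrs = 2L,
              spacer_length = as.integer(gap),
              itr_names = paste(a$name, b$name, sep = ","))
            paired <- TRUE
          } else if (gap <= config$pair_span &&
                     gap > config$made1_spacer + config$spacer_tol) {
            out[[length(out) + 1L]] <- tibble::tibble(
              remnant_class = "paired_itr_remnant", chrom = a$chrom,
              start = a$start, end = max(a$end, b$end), n_itrs = 2L,
              spacer_length = NA_integer_,
              itr_names = paste(a$name, b$name, sep = ","))
            paired <- TRUE
          }
        }
      }
      if (paired) {
        i <- i + 2L
      } else {
        out[[length(out) + 1L]] <- tibble::tibble(
          remnant_class = "solo_itr", chrom = a$chrom, start = a$start,
          end = a$end, n_itrs = 1L, spacer_length = NA_integer_,
          itr_names = a$name)
        i <- i + 1L
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(remnant_class = character(), chrom = character(),
                          start = integer(), end = integer(),
                          n_itrs = integer(), spacer_length = integer(),
                          itr_names = character())
  }
  res |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(remnant_id = sprintf("remnant_%05d", dplyr::row_number())) |>
    dplyr::select("remnant_id", dplyr::everything())
}

remnant_classes <- c("solo_itr", "made1", "paired_itr_remnant")
genomic_contexts <- c("intragenic_exon", "intragenic_intron", "intergenic")

#' Census of remnants by class and genomic context
#'
#' Context is assigned against gene spans (gap 0 intersection), then exon
#' unions: a remnant overlapping an exon of an overlapping gene is
#' `intragenic_exon`, one inside a gene span but off-exon is
#' `intragenic_intron`, anything else `intergenic`.
#'
#' @param annotations Remnant tibble from [classify_remnants()].
#' @param genes Gene-model tibble.
#' @return Count tibble `remnant_class, context, chrom, n`, completed with
#'   zero rows over all class-context combinations; counts sum to the
#'   number of annotations.
#' @export
census_report <- function(annotations, genes) {
  grid <- tidyr::expand_grid(remnant_class = remnant_classes,
                             context = genomic_contexts)
  if (nrow(annotations) == 0) {
    return(dplyr::mutate(grid, chrom = NA_character_, n = 0L))
  }
  ann <- dplyr::mutate(annotations,
                       name = as.character(dplyr::row_number()))
  gene_iv <- if (nrow(genes)) {
    tibble::tibble(chrom = genes$chrom, start = genes$start,
                   end = genes$end, name = genes$gene_id)
  } else tibble::tibble(chrom = character(), start = integer(),
                        end = integer(), name = character())
  exon_iv <- if (nrow(genes)) {
    purrr::map2_dfr(genes$gene_id, genes$exons, function(g, ex)
      tibble::tibble(chrom = NA_character_, start = ex$start, end = ex$end,
                     name = g)) |>
      dplyr::mutate(chrom = rep(genes$chrom,
                                vapply(genes$exons, nrow, 1L)))
  } else gene_iv
  in_gene <- intersect_features(ann, gene_iv, max_gap = 0L)
  # gap 0 includes abutting intervals; require a true overlap
  genuinely_in <- in_gene$within_max_gap & !is.na(in_gene$target_start) &
    ann$start < in_gene$target_end & ann$end > in_gene$target_start
  in_exon <- intersect_features(ann, exon_iv, max_gap = 0L)
  on_exon <- in_exon$within_max_gap & !is.na(in_exon$target_start) &
    ann$start < in_exon$target_end & ann$end > in_exon$target_start
  ann$context <- dplyr::case_when(
    genuinely_in & on_exon ~ "intragenic_exon",
    genuinely_in ~ "intragenic_intron",
    TRUE ~ "intergenic"
  )
  counts <- ann |>
    dplyr::count(.data$remnant_class, .data$context, .data$chrom,
                 name = "n")
  grid |>
    dplyr::left_join(counts, by = c("remnant_class", "context")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}
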