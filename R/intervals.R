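#' Build and validate a genomic-interval tibble
#'
#' Intervals are 0-based half-open (BED-native) throughout the package:
#' `start` is the first base, `end` one past the last, so
#' `length = end - start`. Strand is carried but ignored by all distance
#' and intersection operations.
#'
#' @param chrom Character vector of sequence names.
#' @param start,end Integer-ish vectors, 0-based half-open.
#' @param strand One of `"+"`, `"-"`, `"."` (recycled).
#' @param name Optional feature names (recycled; default `"."`).
#' @param ... Further columns carried along.
#' @return A tibble with columns `chrom, start, end, strand, name, ...`,
#'   sorted by `(chrom, start, end, name)`.
#' @export
#' @examples
#' gintervals("chr1", c(100, 500), c(200, 528), name = c("a", "b"))
gintervals <- function(chrom, start, end, strand = ".", name = ".", ...) {
  x <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), length(chrom)),
    name = rep_len(as.character(name), length(chrom)),
    ...
  )
  validate_intervals(x)
  dplyr::arrange(x, .data$chrom, .data$start, .data$end, .data$name)
}

validate_intervals <- function(x, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (any(is.na(x$chrom) | !nzchar(x$chrom)))
    stop(what, ": chrom must be non-empty")
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    stop(what, ": need 0 <= start < end; violated at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(x)
}

#' @keywords internal
interval_width <- function(x) x$end - x$start

# GRanges from a 0-based half-open tibble; strand dropped on purpose
# (ITRs are inverted repeats, both orientations are equivalent for
# distance work).
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = "*"
  )
}

#' Edge-to-edge gap between two interval sets
#'
#' Vectorised over rows. The gap is 0 when the intervals overlap or abut,
#' otherwise the number of bases strictly between them. Both inputs must be
#' on the same chromosome row-wise.
#'
#' @param a,b Interval tibbles (recycled to a common length).
#' @return Integer vector of gaps in bp.
#' @export
#' @examples
#' a <- gintervals("chr1", 100, 200)
#' b <- gintervals("chr1", 500, 528)
#' gap_distance(a, b)  # 300
gap_distance <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  if (any(a$chrom[ai] != b$chrom[bi]))
    stop("gap_distance: intervals on different chromosomes")
  pmax(0L, pmax(a$start[ai], b$start[bi]) - pmin(a$end[ai], b$end[bi]))
}

#' Pair each query interval with its nearest target
#'
#' Nearest is by edge-to-edge gap (overlap = 0); ties are broken by the
#' leftmost target start, then target name. Strand is ignored. Queries on
#' chromosomes with no target get `NA` distance and are never flagged.
#'
#' @param queries,targets Interval tibbles.
#' @param max_gap Flagging distance in bp; `within_max_gap` is `gap <= max_gap`.
#' @return The `queries` tibble plus `target_name`, `target_start`,
#'   `target_end`, `distance`, `within_max_gap`.
#' @export
intersect_features <- function(queries, targets, max_gap = 0L) {
  validate_intervals(queries, "queries")
  empty_cols <- function(q) {
    dplyr::mutate(q,
      target_name = NA_character_, target_start = NA_integer_,
      target_end = NA_integer_, distance = NA_integer_,
      within_max_gap = FALSE)
  }
  if (nrow(targets) == 0) return(empty_cols(queries))
  validate_intervals(targets, "targets")
  qg <- as_granges0(queries)
  tg <- as_granges0(targets)
  # queries on chromosomes without targets are a defined case (NA
  # distance), not a user error worth a seqlevel warning
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(qg, tg, select = "all",
                                     ignore.strand = TRUE))
  h <- tibble::tibble(
    qidx = S4Vectors::queryHits(hits),
    tidx = S4Vectors::subjectHits(hits),
    distance = as.integer(S4Vectors::mcols(hits)$distance)
  )
  tname <- if ("name" %in% names(targets)) targets$name else
    as.character(seq_len(nrow(targets)))
  h <- h |>
    dplyr::mutate(
      target_start = targets$start[.data$tidx],
      target_end = targets$end[.data$tidx],
      target_name = tname[.data$tidx]
    ) |>
    dplyr::arrange(.data$qidx, .data$target_start, .data$target_name) |>
    dplyr::distinct(.data$qidx, .keep_all = TRUE)
  out <- queries
  out$target_name <- NA_character_
  out$target_start <- NA_integer_
  out$target_end <- NA_integer_
  out$distance <- NA_integer_
  out$target_name[h$qidx] <- h$target_name
  out$target_start[h$qidx] <- h$target_start
  out$target_end[h$qidx] <- h$target_end
  out$distance[h$qidx] <- h$distance
  out$within_max_gap <- !is.na(out$distance) & out$distance <= max_gap
  out
}

#' Assemble gene models from gene and exon tables
#'
#' A gene model is the TSS-to-poly(A) span plus its exon structure. Exons
#' must lie within the gene span and on the same chromosome and strand;
#' overlapping recorded exons are legal (the union is taken where lengths
#' matter).
#'
#' @param genes Tibble with `chrom, start, end, strand, gene_id` and
#'   optionally `biotype` (`protein_coding` or `non_coding`).
#' @param exons Tibble with `gene_id, start, end`. If `NULL`, each gene is
#'   single-exon over its full span.
#' @return A tibble of gene models sorted by `(chrom, start, gene_id)` with
#'   a list-column `exons` of per-gene exon tibbles.
#' @export
gene_models <- function(genes, exons = NULL) {
  stopifnot(all(c("chrom", "start", "end", "strand", "gene_id") %in% names(genes)))
  genes <- tibble::as_tibble(genes)
  if (!"biotype" %in% names(genes)) genes$biotype <- "protein_coding"
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  validate_intervals(genes, "gene")
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (is.null(exons)) {
    exons <- tibble::tibble(gene_id = genes$gene_id,
                            start = genes$start, end = genes$end)
  }
  exons <- tibble::as_tibble(exons)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  ex_by_gene <- split(exons[c("start", "end")], exons$gene_id)
  genes$exons <- purrr::map(genes$gene_id, function(g) {
    ex <- ex_by_gene[[g]]
    if (is.null(ex) || nrow(ex) == 0)
      stop("gene without exons: ", g)
    gi <- which(genes$gene_id == g)
    if (any(ex$start < genes$start[gi]) || any(ex$end > genes$end[gi]))
      stop("exon outside gene span for gene_id ", g)
    dplyr::arrange(tibble::as_tibble(ex), .data$start)
  })
  dplyr::arrange(genes, .data$chrom, .data$start, .data$gene_id)
}

#' Union-exon length per gene
#'
#' Overlapping exons are merged before summing, so a gene recorded with
#' exons `[100,250)` and `[200,300)` has union length 200.
#'
#' @param genes A gene-model tibble from [gene_models()] or [read_annotation()].
#' @return Tibble `gene_id, exon_length`.
#' @export
exon_union_length <- function(genes) {
  tibble::tibble(
    gene_id = genes$gene_id,
    exon_length = purrr::map_int(genes$exons, function(ex) {
      ir <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
      as.integer(sum(IRanges::width(ir)))
    })
  )
}

#' Transcription start sites of gene models
#'
#' TSS is `start` for `+` genes and `end - 1` for `-` genes, returned as a
#' 1 bp interval tibble.
#'
#' @param genes A gene-model tibble.
#' @return Interval tibble of 1 bp TSS positions (one per gene).
#' @export
tss_intervals <- function(genes) {
  pos <- ifelse(genes$strand == "-", genes$end - 1L, genes$start)
  tibble::tibble(chrom = genes$chrom, start = as.integer(pos),
                 end = as.integer(pos + 1L), strand = genes$strand,
                 name = genes$gene_id)
}
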