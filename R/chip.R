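peak_tiers <- c("overlap", "lt150", "le500", "gt500", "no_itr_on_chrom")
gene_chip_classes <- c("bound_itr", "distal_peak_with_itr", "peak_no_itr",
                       "no_peak")

#' Assign ChIP peaks to their nearest ITR and a distance tier
#'
#' Distance is the edge-to-edge gap (overlap = 0). Tiers: `overlap`
#' (gap 0), `lt150` (0 < gap < `near_dist`), `le500` (`near_dist` <= gap <=
#' `bound_dist`), `gt500` (gap > `bound_dist`), `no_itr_on_chrom`. The
#' classic summary "peaks within 500 bp of an ITR" is the union of the
#' first three tiers.
#'
#' @param peaks Peak interval tibble.
#' @param itrs ITR hit tibble (from [scan_consensus()] or a BED file).
#' @param config A [pipeline_config()].
#' @return `peaks` plus `itr_name, distance, tier`.
#' @export
assign_peaks <- function(peaks, itrs, config = pipeline_config()) {
  if (!"name" %in% names(peaks))
    peaks$name <- sprintf("peak_%05d", seq_len(nrow(peaks)))
  near <- intersect_features(peaks, itrs, max_gap = config$bound_dist)
  near |>
    dplyr::mutate(
      itr_name = .data$target_name,
      tier = dplyr::case_when(
        is.na(.data$distance) ~ "no_itr_on_chrom",
        .data$distance == 0L ~ "overlap",
        .data$distance < config$near_dist ~ "lt150",
        .data$distance <= config$bound_dist ~ "le500",
        TRUE ~ "gt500"
      )
    ) |>
    dplyr::select(-"target_name", -"target_start", -"target_end",
                  -"within_max_gap")
}

#' Summarise peak distance tiers
#' @param assignments Output of [assign_peaks()].
#' @return Tibble `tier, n, fraction` completed over all tiers; fractions
#'   sum to 1.
#' @export
peak_tier_summary <- function(assignments) {
  tibble::tibble(tier = peak_tiers) |>
    dplyr::left_join(dplyr::count(assignments, .data$tier), by = "tier") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  fraction = if (sum(.data$n) > 0) .data$n / sum(.data$n) else 0)
}

#' Distinct ITRs bound by at least one peak
#'
#' The bound set contains every ITR with at least one peak within
#' `bound_dist` (edge-to-edge gap), not only nearest pairings — two ITRs
#' of one Made1 element straddled by a single peak are both bound.
#'
#' @param peaks Peak interval tibble.
#' @param itrs ITR hit tibble.
#' @param config A [pipeline_config()].
#' @return Character vector of bound ITR names.
#' @export
bound_itr_set <- function(peaks, itrs, config = pipeline_config()) {
  if (nrow(peaks) == 0 || nrow(itrs) == 0) return(character(0))
  ov <- GenomicRanges::findOverlaps(as_granges0(itrs), as_granges0(peaks),
                                    maxgap = config$bound_dist,
                                    ignore.strand = TRUE)
  sort(unique(itrs$name[S4Vectors::queryHits(ov)]))
}

# peaks overlapping each gene span; overlapping genes each receive the peak
peaks_in_genes <- function(peaks, genes) {
  if (nrow(peaks) == 0 || nrow(genes) == 0)
    return(tibble::tibble(gene_id = character(), peak_name = character(),
                          peak_start = integer(), peak_end = integer(),
                          chrom = character()))
  pg <- as_granges0(peaks)
  gg <- as_granges0(genes)
  ov <- GenomicRanges::findOverlaps(pg, gg, ignore.strand = TRUE)
  tibble::tibble(
    gene_id = genes$gene_id[S4Vectors::subjectHits(ov)],
    peak_name = peaks$name[S4Vectors::queryHits(ov)],
    peak_start = peaks$start[S4Vectors::queryHits(ov)],
    peak_end = peaks$end[S4Vectors::queryHits(ov)],
    chrom = peaks$chrom[S4Vectors::queryHits(ov)]
  )
}

# ITRs intragenic to each gene. mode "span": overlapping the TSS-to-poly(A)
# span; mode "intron": inside the span but not touching the exon union.
intragenic_itrs <- function(itrs, genes, mode = c("span", "intron")) {
  mode <- match.arg(mode)
  if (nrow(itrs) == 0 || nrow(genes) == 0)
    return(tibble::tibble(gene_id = character(), itr_name = character(),
                          itr_start = integer(), itr_end = integer(),
                          chrom = character()))
  ig <- as_granges0(itrs)
  gg <- as_granges0(genes)
  ov <- GenomicRanges::findOverlaps(ig, gg, ignore.strand = TRUE)
  out <- tibble::tibble(
    gene_id = genes$gene_id[S4Vectors::subjectHits(ov)],
    itr_name = itrs$name[S4Vectors::queryHits(ov)],
    itr_start = itrs$start[S4Vectors::queryHits(ov)],
    itr_end = itrs$end[S4Vectors::queryHits(ov)],
    chrom = itrs$chrom[S4Vectors::queryHits(ov)]
  )
  if (mode == "intron") {
    gidx <- match(out$gene_id, genes$gene_id)
    on_exon <- purrr::map_lgl(seq_len(nrow(out)), function(i) {
      ex <- genes$exons[[gidx[i]]]
      any(out$itr_start[i] < ex$end & out$itr_end[i] > ex$start)
    })
    out <- out[!on_exon, ]
  }
  out
}

#' Classify genes by ChIP binding and ITR content
#'
#' A gene is peak-bearing when at least one peak overlaps its span
#' (overlapping genes each receive the peak). Peak-bearing genes are
#' classified, in priority order, as `bound_itr` (some peak within
#' `bound_dist` of an intragenic ITR of the gene), `distal_peak_with_itr`
#' (intragenic ITR present, no peak that close), or `peak_no_itr`; all
#' remaining genes are `no_peak`.
#'
#' @param peaks Peak interval tibble.
#' @param genes Gene-model tibble.
#' @param itrs ITR hit tibble.
#' @param config A [pipeline_config()].
#' @param intragenic `"span"` counts ITRs anywhere between TSS and poly(A)
#'   site (the default reading); `"intron"` restricts to off-exon copies.
#' @return Tibble `gene_id, biotype, class, n_peaks, n_intragenic_itrs`.
#' @export
classify_genes <- function(peaks, genes, itrs, config = pipeline_config(),
                           intragenic = c("span", "intron")) {
  intragenic <- match.arg(intragenic)
  if (!"name" %in% names(peaks) || anyNA(peaks$name))
    peaks$name <- sprintf("peak_%05d", seq_len(nrow(peaks)))
  pk <- peaks_in_genes(peaks, genes)
  it <- intragenic_itrs(itrs, genes, mode = intragenic)
  # min gap between each gene's peaks and its intragenic ITRs
  joined <- dplyr::inner_join(pk, it, by = c("gene_id", "chrom"),
                              relationship = "many-to-many")
  min_gap <- if (nrow(joined)) {
    joined |>
      dplyr::mutate(gap = pmax(0L, pmax(.data$peak_start, .data$itr_start) -
                                 pmin(.data$peak_end, .data$itr_end))) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(min_gap = min(.data$gap), .groups = "drop")
  } else tibble::tibble(gene_id = character(), min_gap = integer())
  genes |>
    dplyr::select("gene_id", "biotype") |>
    dplyr::left_join(dplyr::count(pk, .data$gene_id, name = "n_peaks"),
                     by = "gene_id") |>
    dplyr::left_join(dplyr::count(it, .data$gene_id,
                                  name = "n_intragenic_itrs"),
                     by = "gene_id") |>
    dplyr::left_join(min_gap, by = "gene_id") |>
    dplyr::mutate(
      n_peaks = dplyr::coalesce(.data$n_peaks, 0L),
      n_intragenic_itrs = dplyr::coalesce(.data$n_intragenic_itrs, 0L),
      class = dplyr::case_when(
        n_peaks == 0L ~ "no_peak",
        !is.na(min_gap) & min_gap <= config$bound_dist ~ "bound_itr",
        n_intragenic_itrs > 0L ~ "distal_peak_with_itr",
        TRUE ~ "peak_no_itr"
      )
    ) |>
    dplyr::select("gene_id", "biotype", "class", "n_peaks",
                  "n_intragenic_itrs")
}

#' Summarise gene ChIP classes over peak-bearing genes
#'
#' @param gene_classes Output of [classify_genes()] (or any tibble with a
#'   `class` column using the same labels).
#' @return Tibble `class, n, pct` over the three peak-bearing classes;
#'   `pct` is rounded to the nearest integer percentage of peak-bearing
#'   genes.
#' @export
gene_class_summary <- function(gene_classes) {
  bearing <- dplyr::filter(gene_classes, .data$class != "no_peak")
  total <- nrow(bearing)
  tibble::tibble(class = setdiff(gene_chip_classes, "no_peak")) |>
    dplyr::left_join(dplyr::count(bearing, .data$class), by = "class") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  pct = if (total > 0) round(100 * .data$n / total) else 0)
}

#' Peak distribution with respect to genes
#'
#' Exclusive contexts in priority order: `intragenic` (peak overlaps a gene
#' span), `within_flank` (gap to the nearest gene <= `flank`), else
#' `intergenic`.
#'
#' @param peaks Peak interval tibble.
#' @param genes Gene-model tibble.
#' @param flank Flank distance in bp (>= 0).
#' @return Tibble `context, n, fraction`; counts sum to the peak total.
#' @export
peak_gene_distribution <- function(peaks, genes, flank = 3000L) {
  stopifnot(flank >= 0)
  if (!"name" %in% names(peaks))
    peaks$name <- sprintf("peak_%05d", seq_len(nrow(peaks)))
  gene_iv <- tibble::tibble(chrom = genes$chrom, start = genes$start,
                            end = genes$end, name = genes$gene_id)
  near <- intersect_features(peaks, gene_iv, max_gap = flank)
  truly_in <- !is.na(near$distance) & near$distance == 0L &
    peaks$start < near$target_end & peaks$end > near$target_start
  ctx <- dplyr::case_when(
    truly_in ~ "intragenic",
    !is.na(near$distance) & near$distance <= flank ~ "within_flank",
    TRUE ~ "intergenic"
  )
  tibble::tibble(context = c("intragenic", "within_flank", "intergenic")) |>
    dplyr::left_join(dplyr::count(tibble::tibble(context = ctx),
                                  .data$context), by = "context") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  fraction = if (nrow(peaks) > 0) .data$n / nrow(peaks) else 0)
}
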