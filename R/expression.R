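#' Call differential expression from a DE table
#'
#' A gene is `up` when `log2fc > log2(fc_threshold)` **and**
#' `padj <= padj_threshold`; `down` symmetrically with `<`; otherwise
#' `ns`. Fold-change is strict (a fold-change of exactly 2 is not called);
#' the adjusted-P cutoff is inclusive. Missing `padj` (filtered genes)
#' means `ns`.
#'
#' @param de Tibble with `gene_id, log2fc, padj` (e.g. [read_de_table()]),
#'   or a path to such a TSV.
#' @param config A [pipeline_config()].
#' @return The input tibble plus a `call` column in `{up, down, ns}`.
#' @export
#' @examples
#' de <- tibble::tibble(gene_id = c("a", "b"), mean_expr = 1,
#'                      log2fc = c(1.0, 1.5), padj = c(0.01, 0.01))
#' apply_de_thresholds(de)$call  # "ns" "up": FC = 2 exactly is not called
apply_de_thresholds <- function(de, config = pipeline_config()) {
  if (is.character(de)) de <- read_de_table(de)
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(de)))
  if (anyDuplicated(de$gene_id))
    stop("duplicate gene_id in DE table: ",
         paste(unique(de$gene_id[duplicated(de$gene_id)]), collapse = ", "))
  lfc_cut <- log2(config$fc_threshold)
  dplyr::mutate(de, call = dplyr::case_when(
    !is.na(.data$padj) & .data$padj <= config$padj_threshold &
      .data$log2fc > lfc_cut ~ "up",
    !is.na(.data$padj) & .data$padj <= config$padj_threshold &
      .data$log2fc < -lfc_cut ~ "down",
    TRUE ~ "ns"
  ))
}

#' Count DE calls
#' @param de Output of [apply_de_thresholds()].
#' @return Tibble `call, n` completed over `{up, down, ns}`.
#' @export
de_call_counts <- function(de) {
  tibble::tibble(call = c("up", "down", "ns")) |>
    dplyr::left_join(dplyr::count(de, .data$call), by = "call") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Compute FPKM from gene-level fragment counts
#'
#' `FPKM = fragments * 1e9 / (total_fragments * union_exon_length)`, with
#' the union-exon length from the gene models. Doubling every count leaves
#' FPKM unchanged.
#'
#' @param counts Tibble `gene_id, fragments` or a TSV path.
#' @param genes Gene-model tibble.
#' @return Tibble `gene_id, fpkm` for genes present in `counts`.
#' @export
compute_fpkm <- function(counts, genes) {
  if (is.character(counts)) counts <- read_counts(counts)
  total <- sum(counts$fragments)
  if (!isTRUE(total > 0)) stop("total fragments must be > 0")
  lens <- exon_union_length(genes)
  x <- dplyr::inner_join(counts, lens, by = "gene_id")
  missing <- setdiff(counts$gene_id, lens$gene_id)
  if (length(missing))
    stop("counts for genes without models: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (any(x$exon_length <= 0))
    stop("gene with zero exon length: ",
         paste(x$gene_id[x$exon_length <= 0], collapse = ", "))
  tibble::tibble(gene_id = x$gene_id,
                 fpkm = x$fragments * 1e9 / (total * x$exon_length))
}

#' Fraction of genes per expression bin for named gene sets
#'
#' Bins are half-open `[e_i, e_{i+1})`, the first being `[0, e_1)` and the
#' last `[e_k, Inf)`, so an FPKM exactly at an edge falls in the upper bin.
#' Fractions within each set sum to 1; an empty set yields no rows rather
#' than an error.
#'
#' @param fpkm Tibble `gene_id, fpkm`.
#' @param edges Ascending positive bin edges (e.g. `c(1, 10, 100)`).
#' @param sets Tibble `gene_id, set` mapping genes to named sets; `NULL`
#'   puts every gene in set `"all"`.
#' @return Tibble `set, bin, n, fraction`.
#' @export
expression_bins <- function(fpkm, edges, sets = NULL) {
  stopifnot(length(edges) >= 1, !is.unsorted(edges, strictly = TRUE),
            all(edges > 0))
  if (any(fpkm$fpkm < 0)) stop("negative FPKM")
  if (is.null(sets)) sets <- tibble::tibble(gene_id = fpkm$gene_id, set = "all")
  brk <- c(0, edges, Inf)
  labs <- paste0("[", format(brk[-length(brk)], trim = TRUE, digits = 6), ",",
                 format(brk[-1], trim = TRUE, digits = 6), ")")
  x <- dplyr::inner_join(sets, fpkm, by = "gene_id") |>
    dplyr::mutate(bin = cut(.data$fpkm, breaks = brk, labels = labs,
                            right = FALSE, include.lowest = FALSE))
  if (nrow(x) == 0) {
    return(tibble::tibble(set = character(), bin = character(),
                          n = integer(), fraction = double()))
  }
  x |>
    dplyr::count(.data$set, .data$bin, .drop = FALSE) |>
    dplyr::group_by(.data$set) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(bin = as.character(.data$bin))
}

#' Cross-condition direction concordance of DE calls
#'
#' Compares called genes (up or down) between two conditions: how many are
#' called in both, how many of those flipped direction, and — per
#' direction in A — how many respond in the same direction in B.
#'
#' @param de_a,de_b DE tibbles with `gene_id` and `call` columns (from
#'   [apply_de_thresholds()]).
#' @return A list of class `concordance`: `n_both`, `n_opposite`,
#'   `n_same`, `venn` (tibble of A-only / B-only / shared counts) and
#'   `per_direction` (for each direction in A, genes shared with B and how
#'   many kept or flipped direction).
#' @export
#' @examples
#' a <- tibble::tibble(gene_id = c("g1", "g2"), call = c("up", "down"))
#' b <- tibble::tibble(gene_id = c("g1", "g2"), call = c("down", "down"))
#' glance(direction_concordance(a, b))
direction_concordance <- function(de_a, de_b) {
  for (nm in c("a", "b")) {
    d <- if (nm == "a") de_a else de_b
    if (anyDuplicated(d$gene_id))
      stop("duplicate gene_id in table ", nm, ": ",
           paste(unique(d$gene_id[duplicated(d$gene_id)]), collapse = ", "))
  }
  a <- dplyr::filter(de_a, .data$call %in% c("up", "down"))
  b <- dplyr::filter(de_b, .data$call %in% c("up", "down"))
  shared <- dplyr::inner_join(
    dplyr::select(a, "gene_id", call_a = "call"),
    dplyr::select(b, "gene_id", call_b = "call"), by = "gene_id")
  n_both <- nrow(shared)
  n_same <- sum(shared$call_a == shared$call_b)
  n_opposite <- n_both - n_same
  per_direction <- shared |>
    dplyr::group_by(direction_a = .data$call_a) |>
    dplyr::summarise(
      n_shared = dplyr::n(),
      n_same_in_b = sum(.data$call_b == .data$direction_a[1]),
      n_opposite_in_b = sum(.data$call_b != .data$direction_a[1]),
      .groups = "drop") |>
    dplyr::right_join(tibble::tibble(direction_a = c("up", "down")),
                      by = "direction_a") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                ~ dplyr::coalesce(.x, 0L)))
  # totals called per direction in A (shared or not), for "only 7"-style stats
  a_dir <- dplyr::count(a, .data$call)
  per_direction$n_called_a <- a_dir$n[match(per_direction$direction_a,
                                            a_dir$call)]
  per_direction$n_called_a[is.na(per_direction$n_called_a)] <- 0L
  structure(list(
    n_both = n_both, n_opposite = n_opposite, n_same = n_same,
    venn = tibble::tibble(
      region = c("a_only", "shared", "b_only"),
      n = c(nrow(a) - n_both, n_both, nrow(b) - n_both)),
    per_direction = per_direction
  ), class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("<concordance> %d genes DE in both; %d opposite, %d same\n",
              x$n_both, x$n_opposite, x$n_same))
  print(x$per_direction)
  invisible(x)
}

#' @describeIn direction_concordance One-row summary tibble.
#' @param x A `concordance` object.
#' @param ... Unused.
#' @export
glance.concordance <- function(x, ...) {
  tibble::tibble(n_both = x$n_both, n_opposite = x$n_opposite,
                 n_same = x$n_same,
                 n_a_only = x$venn$n[x$venn$region == "a_only"],
                 n_b_only = x$venn$n[x$venn$region == "b_only"])
}

#' Join ITR, binding and expression status per gene
#'
#' Builds one record per gene: whether it carries an intragenic ITR,
#' whether an ITR-less gene lies within `itr_neighborhood` of an ITR
#' (mutually exclusive with `has_itr`), its ChIP class, its DE calls in
#' the two conditions and its FPKM.
#'
#' @param genes Gene-model tibble.
#' @param itrs ITR hit tibble.
#' @param gene_classes Output of [classify_genes()] (or `NULL`).
#' @param de_a,de_b DE tibbles with calls (or `NULL`); genes absent from a
#'   table are `ns`.
#' @param fpkm Tibble `gene_id, fpkm` (or `NULL`).
#' @param config A [pipeline_config()].
#' @param intragenic Passed to the intragenic-ITR definition (see
#'   [classify_genes()]).
#' @return Tibble `gene_id, biotype, has_itr, near_itr_10kb, chip_class,
#'   call_a, call_b, fpkm`.
#' @export
gene_integration <- function(genes, itrs, gene_classes = NULL,
                             de_a = NULL, de_b = NULL, fpkm = NULL,
                             config = pipeline_config(),
                             intragenic = c("span", "intron")) {
  intragenic <- match.arg(intragenic)
  it <- intragenic_itrs(itrs, genes, mode = intragenic)
  rec <- genes |>
    dplyr::select("gene_id", "biotype") |>
    dplyr::mutate(has_itr = .data$gene_id %in% it$gene_id)
  gene_iv <- tibble::tibble(chrom = genes$chrom, start = genes$start,
                            end = genes$end, name = genes$gene_id)
  near <- intersect_features(gene_iv, itrs,
                             max_gap = config$itr_neighborhood)
  rec$near_itr_10kb <- !rec$has_itr & near$within_max_gap[
    match(rec$gene_id, near$name)]
  rec$chip_class <- if (!is.null(gene_classes))
    gene_classes$class[match(rec$gene_id, gene_classes$gene_id)]
  else NA_character_
  call_of <- function(de) {
    if (is.null(de)) return(rep("ns", nrow(rec)))
    cl <- de$call[match(rec$gene_id, de$gene_id)]
    ifelse(is.na(cl), "ns", cl)
  }
  rec$call_a <- call_of(de_a)
  rec$call_b <- call_of(de_b)
  rec$fpkm <- if (!is.null(fpkm)) fpkm$fpkm[match(rec$gene_id, fpkm$gene_id)]
  else NA_real_
  rec
}

#' Summarise DE status by ChIP class
#'
#' For each ChIP class, the number of genes, the number differentially
#' expressed in condition A (`call_a` of `up` or `down`) and the rounded
#' percentage — the "52% of bound genes are differentially expressed"
#' style of summary.
#'
#' @param records Output of [gene_integration()].
#' @param biotype Optional biotype restriction (e.g. `"protein_coding"`).
#' @return Tibble `chip_class, n_genes, n_de, pct_de`.
#' @export
integration_summary <- function(records, biotype = NULL) {
  if (!is.null(biotype))
    records <- dplyr::filter(records, .data$biotype %in% !!biotype)
  records |>
    dplyr::filter(!is.na(.data$chip_class)) |>
    dplyr::group_by(chip_class = .data$chip_class) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_de = sum(.data$call_a %in% c("up", "down")),
      .groups = "drop") |>
    dplyr::mutate(pct_de = round(100 * .data$n_de / .data$n_genes))
}
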