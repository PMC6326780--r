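#' Pipeline configuration
#'
#' Bundles every numeric threshold used across the pipeline. Defaults follow
#' the Hsmar1/SETMAR analysis conventions: a 28 bp consensus ITR, retention
#' filters of 80% of consensus length and 80% identity, a 500 bp "bound"
#' distance and 150 bp "near" distance for ChIP peaks, a 3 kb gene flank,
#' a 10 kb ITR neighborhood for ITR-less genes, a 2-fold / adjusted-P 0.05
#' differential-expression cutoff, 10 bp profile bins and the 6 bp Made1
#' spacer.
#'
#' @param consensus_length Length of the consensus ITR in bp.
#' @param min_length_frac Minimum fraction of the consensus length a retained
#'   hit must cover (aligned consensus positions / consensus length).
#' @param min_identity Minimum fraction of matching aligned columns.
#' @param bound_dist Maximum peak-to-ITR gap (bp) for a "bound" ITR;
#'   "within X bp" is inclusive (gap <= X).
#' @param near_dist Strict "near" distance in bp ("< 150 bp" is strict).
#' @param gene_flank Flank in bp for peak-near-gene classification.
#' @param itr_neighborhood Distance in bp within which an ITR-less gene
#'   counts as near an ITR.
#' @param fc_threshold Fold-change cutoff (strict: |FC| must exceed it).
#' @param padj_threshold Adjusted-P cutoff (inclusive).
#' @param bin_size Metaprofile bin size in bp.
#' @param made1_spacer Expected Made1 internal spacer in bp.
#' @param spacer_tol Tolerance (bp) around `made1_spacer` when pairing
#'   inverted ITR hits into Made1 annotations.
#' @param pair_span Maximum gap (bp) between inverted ITR hits still treated
#'   as one paired remnant (full-length Hsmar1 is ~1.3 kb).
#' @param profile_halfwidth Metaprofile half-width in bp.
#' @param match,mismatch,gap_open,gap_ext Alignment scores for the scanner
#'   (positive costs for gaps; the first gapped base costs `gap_open`, each
#'   further base `gap_ext`).
#'
#' @return A list of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$bound_dist
pipeline_config <- function(consensus_length = 28L,
                            min_length_frac = 0.80,
                            min_identity = 0.80,
                            bound_dist = 500L,
                            near_dist = 150L,
                            gene_flank = 3000L,
                            itr_neighborhood = 10000L,
                            fc_threshold = 2,
                            padj_threshold = 0.05,
                            bin_size = 10L,
                            made1_spacer = 6L,
                            spacer_tol = 2L,
                            pair_span = 1500L,
                            profile_halfwidth = 2000L,
                            match = 1L, mismatch = -1L,
                            gap_open = 2L, gap_ext = 1L) {
  cfg <- list(
    consensus_length = as.integer(consensus_length),
    min_length_frac = min_length_frac,
    min_identity = min_identity,
    bound_dist = as.integer(bound_dist),
    near_dist = as.integer(near_dist),
    gene_flank = as.integer(gene_flank),
    itr_neighborhood = as.integer(itr_neighborhood),
    fc_threshold = fc_threshold,
    padj_threshold = padj_threshold,
    bin_size = as.integer(bin_size),
    made1_spacer = as.integer(made1_spacer),
    spacer_tol = as.integer(spacer_tol),
    pair_span = as.integer(pair_span),
    profile_halfwidth = as.integer(profile_halfwidth),
    match = as.integer(match), mismatch = as.integer(mismatch),
    gap_open = as.integer(gap_open), gap_ext = as.integer(gap_ext)
  )
  stopifnot(
    cfg$consensus_length > 0,
    cfg$min_length_frac > 0, cfg$min_length_frac <= 1,
    cfg$min_identity > 0, cfg$min_identity <= 1,
    cfg$bound_dist > 0, cfg$near_dist > 0, cfg$gene_flank > 0,
    cfg$itr_neighborhood > 0, cfg$fc_threshold > 1,
    cfg$padj_threshold > 0, cfg$padj_threshold <= 1,
    cfg$bin_size > 0, cfg$made1_spacer > 0, cfg$spacer_tol >= 0,
    cfg$pair_span > 0, cfg$profile_halfwidth > 0
  )
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
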