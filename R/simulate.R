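random_bases <- function(n)
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# Decay a sequence with per-site substitution probability d and indel
# probability d/10 (indel lengths geometric with mean 1). Keeps most decay
# substitutional, the regime the scanner's identity filter addresses.
decay_seq <- function(seq, d) {
  if (d <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  sub <- stats::runif(n) < d
  for (i in which(sub)) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1)
  ind <- stats::runif(n) < d / 10
  if (!any(ind)) return(paste(ch, collapse = ""))
  out <- character(0)
  i <- 1L
  while (i <= n) {
    if (ind[i]) {
      len <- stats::rgeom(1, 0.5) + 1L
      if (stats::runif(1) < 0.5) {    # deletion
        i <- i + len
        next
      } else {                        # insertion before this base
        out <- c(out, sample(DNA_BASES, len, replace = TRUE))
      }
    }
    out <- c(out, ch[i])
    i <- i + 1L
  }
  paste(out, collapse = "")
}

#' Simulate a genome with planted decayed ITR remnants and gene models
#'
#' Plants solo ITRs, Made1-like elements (two inverted decayed ITR copies
#' around a 6 bp spacer) and longer paired remnants into an i.i.d. random
#' background, decays each ITR copy by per-site substitutions (probability
#' `divergence`) and rarer indels (`divergence / 10`, geometric lengths of
#' mean 1), and builds gene models so that a chosen fraction of elements
#' is intronic. Elements are placed in disjoint slots with generous
#' margins, so planted features never overlap and every intragenic
#' element's gene fits inside its slot. Fully deterministic per seed.
#'
#' @param seed Integer seed.
#' @param config A [pipeline_config()].
#' @param genome_length Genome length in bp.
#' @param n_solo,n_made1,n_paired Element counts per remnant class.
#' @param frac_intragenic Fraction of elements placed inside a gene intron.
#' @param n_extra_genes Additional ITR-less genes.
#' @param divergence Per-site substitution probability of planted copies.
#' @param consensus Consensus ITR (28 bp Hsmar1-like random sequence when
#'   `NULL`).
#' @param sequence Materialise the genome sequence? Coordinate-only
#'   layouts (`FALSE`) support peak and expression simulation at large
#'   genome sizes without the memory cost of the sequence itself.
#' @param chrom Chromosome name.
#' @return An object of class `itr_simulation`: list with `genome`
#'   (`DNAStringSet` or `NULL`), `consensus`, `itrs` (planted ITR interval
#'   tibble), `elements` (per-element truth), `genes` (gene models) and
#'   `manifest` (everything needed to recompute expected stage outputs).
#' @export
simulate_genome <- function(seed, config = pipeline_config(),
                            genome_length = 200000L,
                            n_solo = 12L, n_made1 = 10L, n_paired = 3L,
                            frac_intragenic = 2 / 3, n_extra_genes = 8L,
                            divergence = 0.08, consensus = NULL,
                            sequence = TRUE, chrom = "chrS") {
  genome_length <- as.integer(genome_length)
  withr::with_seed(seed, {
    if (is.null(consensus)) consensus <- random_bases(config$consensus_length)
    consensus <- toupper(as.character(consensus))
    clen <- nchar(consensus)
    rc <- revcomp_chr(consensus)

    n_elem <- n_solo + n_made1 + n_paired
    classes <- sample(c(rep("solo_itr", n_solo), rep("made1", n_made1),
                        rep("paired_itr_remnant", n_paired)))
    # build element sequences and within-element ITR offsets
    elems <- purrr::map(classes, function(cl) {
      if (cl == "solo_itr") {
        strand <- sample(c("+", "-"), 1)
        s <- decay_seq(if (strand == "+") consensus else rc, divergence)
        list(class = cl, seq = s, len = nchar(s),
             itr = tibble::tibble(off = 0L, len = nchar(s), strand = strand))
      } else {
        gap <- if (cl == "made1") config$made1_spacer
               else sample(100:600, 1)
        left <- decay_seq(consensus, divergence)
        right <- decay_seq(rc, divergence)
        spacer <- random_bases(gap)
        s <- paste0(left, spacer, right)
        list(class = cl, seq = s, len = nchar(s),
             itr = tibble::tibble(
               off = c(0L, nchar(left) + gap),
               len = c(nchar(left), nchar(right)),
               strand = c("+", "-")))
      }
    })
    if (!sequence) {
      # coordinate-only layout: undecayed geometry
      elems <- purrr::map(classes, function(cl) {
        if (cl == "solo_itr") {
          list(class = cl, seq = NULL, len = clen,
               itr = tibble::tibble(off = 0L, len = clen,
                                    strand = sample(c("+", "-"), 1)))
        } else {
          gap <- if (cl == "made1") config$made1_spacer else sample(100:600, 1)
          list(class = cl, seq = NULL, len = 2L * clen + gap,
               itr = tibble::tibble(off = c(0L, clen + gap),
                                    len = c(clen, clen),
                                    strand = c("+", "-")))
        }
      })
    }

    edge <- 5000L
    margin <- 2100L   # covers the widest gene flank plus exon placement
    n_slots <- n_elem + n_extra_genes
    slot_len <- (genome_length - 2L * edge) %/% n_slots
    max_len <- max(vapply(elems, function(e) e$len, 1L))
    if (slot_len - 2L * margin - max_len < 1L)
      stop("infeasible packing: genome too short for requested elements")
    slot_kind <- sample(c(rep("element", n_elem), rep("gene", n_extra_genes)))
    elem_slots <- which(slot_kind == "element")

    elements <- tibble::tibble(
      element_id = sprintf("elem_%04d", seq_len(n_elem)),
      class = classes,
      start = NA_integer_, end = NA_integer_,
      intragenic = FALSE, gene_id = NA_character_
    )
    for (i in seq_len(n_elem)) {
      slot0 <- edge + (elem_slots[i] - 1L) * slot_len
      off <- sample(margin:(slot_len - margin - elems[[i]]$len), 1)
      elements$start[i] <- slot0 + off
      elements$end[i] <- elements$start[i] + elems[[i]]$len
    }

    # intragenic assignment and gene construction
    n_intra <- round(frac_intragenic * n_elem)
    intra_idx <- sample(n_elem, n_intra)
    elements$intragenic[intra_idx] <- TRUE
    gene_rows <- list(); exon_rows <- list()
    for (i in intra_idx) {
      gid <- sprintf("gene_elem_%04d", i)
      gs <- elements$start[i] - sample(1200:2000, 1)
      ge <- elements$end[i] + sample(1200:2000, 1)
      e1l <- sample(200:400, 1); e2l <- sample(200:400, 1)
      gene_rows[[length(gene_rows) + 1L]] <- tibble::tibble(
        chrom = chrom, start = gs, end = ge,
        strand = sample(c("+", "-"), 1), gene_id = gid,
        biotype = sample(c("protein_coding", "non_coding"), 1,
                         prob = c(0.6, 0.4)))
      exon_rows[[length(exon_rows) + 1L]] <- tibble::tibble(
        gene_id = gid,
        start = c(gs, elements$end[i] + sample(100:300, 1)),
        end = NA_integer_)
      er <- exon_rows[[length(exon_rows)]]
      er$end <- c(er$start[1] + e1l, pmin(er$start[2] + e2l, ge))
      exon_rows[[length(exon_rows)]] <- er
      elements$gene_id[i] <- gid
    }
    gene_slots <- which(slot_kind == "gene")
    for (j in seq_along(gene_slots)) {
      gid <- sprintf("gene_free_%04d", j)
      slot0 <- edge + (gene_slots[j] - 1L) * slot_len
      gs <- slot0 + sample(200:1000, 1)
      glen <- sample(2000:min(5000, slot_len - 1500), 1)
      ge <- gs + glen
      gene_rows[[length(gene_rows) + 1L]] <- tibble::tibble(
        chrom = chrom, start = gs, end = ge,
        strand = sample(c("+", "-"), 1), gene_id = gid,
        biotype = sample(c("protein_coding", "non_coding"), 1,
                         prob = c(0.8, 0.2)))
      exon_rows[[length(exon_rows) + 1L]] <- tibble::tibble(
        gene_id = gid,
        start = c(gs, ge - sample(200:400, 1)),
        end = c(gs + sample(200:400, 1), ge))
    }
    genes <- if (length(gene_rows))
      gene_models(dplyr::bind_rows(gene_rows), dplyr::bind_rows(exon_rows))
    else gene_models(tibble::tibble(chrom = character(), start = integer(),
                                    end = integer(), strand = character(),
                                    gene_id = character()))

    # planted ITR records
    itrs <- purrr::map2_dfr(seq_len(n_elem), elems, function(i, e) {
      tibble::tibble(
        chrom = chrom,
        start = elements$start[i] + e$itr$off,
        end = elements$start[i] + e$itr$off + e$itr$len,
        strand = e$itr$strand,
        element_id = elements$element_id[i],
        element_class = e$class,
        divergence = divergence,
        intragenic = elements$intragenic[i],
        gene_id = elements$gene_id[i])
    }) |>
      dplyr::arrange(.data$chrom, .data$start) |>
      dplyr::mutate(name = sprintf("planted_%05d", dplyr::row_number())) |>
      dplyr::relocate("name", .after = "strand")

    genome <- NULL
    if (sequence) {
      ord <- order(elements$start)
      segs <- character(0)
      cursor <- 0L
      for (i in ord) {
        segs <- c(segs, random_bases(elements$start[i] - cursor),
                  elems[[i]]$seq)
        cursor <- elements$end[i]
      }
      segs <- c(segs, random_bases(genome_length - cursor))
      genome <- Biostrings::DNAStringSet(
        stats::setNames(paste(segs, collapse = ""), chrom))
    }

    manifest <- list(
      seed = seed, genome_length = genome_length, chrom = chrom,
      consensus = consensus, divergence = divergence,
      planted_itrs = itrs, elements = elements, genes = genes,
      config = config
    )
    structure(list(genome = genome, consensus = consensus, itrs = itrs,
                   elements = elements, genes = genes, manifest = manifest),
              class = "itr_simulation")
  })
}

#' @export
print.itr_simulation <- function(x, ...) {
  cat(sprintf(
    "<itr_simulation> %s (%d bp%s): %d planted ITRs in %d elements, %d genes\n",
    x$manifest$chrom, x$manifest$genome_length,
    if (is.null(x$genome)) ", layout only" else "",
    nrow(x$itrs), nrow(x$elements), nrow(x$genes)))
  invisible(x)
}

#' Simulate ChIP peaks and coverage tracks over a planted-ITR genome
#'
#' `round(frac_at_itr * n_peaks)` peaks are centred within `+/- near_dist`
#' of randomly chosen planted ITRs (so each sits well inside the classic
#' 500 bp "bound" distance); the remainder are uniform over the genome.
#' Optional tracks: IP = Poisson background plus a triangular kernel at
#' every peak centre; input = Poisson background alone. The returned truth
#' records which peaks were planted at which ITR and the ground-truth
#' bound-ITR set.
#'
#' @param sim An `itr_simulation` (or its manifest).
#' @param n_peaks Total number of peaks.
#' @param frac_at_itr Fraction of peaks planted at ITRs, in `[0, 1]`.
#' @param seed Integer seed.
#' @param peak_width Peak width in bp.
#' @param tracks Also generate IP/input bedGraph tibbles? (Meant for
#'   small genomes.)
#' @param config A [pipeline_config()].
#' @return List with `peaks` (interval tibble), `truth` (tibble
#'   `peak_name, at_itr`), `bound_itrs` (character), and when
#'   `tracks = TRUE` also `ip_track` and `input_track`.
#' @export
simulate_chip <- function(sim, n_peaks = 875L, frac_at_itr = 0.34, seed = 1L,
                          peak_width = 200L, tracks = FALSE,
                          config = pipeline_config()) {
  manifest <- if (inherits(sim, "itr_simulation")) sim$manifest else sim
  stopifnot(frac_at_itr >= 0, frac_at_itr <= 1)
  itrs <- manifest$planted_itrs
  G <- manifest$genome_length
  chrom <- manifest$chrom
  withr::with_seed(seed, {
    n_at <- round(frac_at_itr * n_peaks)
    n_bg <- n_peaks - n_at
    target <- if (n_at > 0) sample(nrow(itrs), n_at, replace = TRUE)
              else integer(0)
    at_center <- (itrs$start[target] + itrs$end[target]) %/% 2L +
      sample(seq(-config$near_dist, config$near_dist), n_at, replace = TRUE)
    bg_center <- if (n_bg > 0)
      sample(seq(peak_width %/% 2L, G - peak_width %/% 2L), n_bg)
    else integer(0)
    centers <- c(at_center, bg_center)
    peaks <- tibble::tibble(
      chrom = chrom,
      start = pmax(0L, as.integer(centers - peak_width %/% 2L)),
      end = pmin(G, as.integer(centers + peak_width %/% 2L)),
      strand = ".",
      name = sprintf("peak_%05d", seq_len(n_peaks)),
      at_itr = c(itrs$name[target], rep(NA_character_, n_bg))
    ) |> dplyr::arrange(.data$start)
    truth <- tibble::tibble(peak_name = peaks$name, at_itr = peaks$at_itr)
    out <- list(
      peaks = dplyr::select(peaks, -"at_itr"),
      truth = truth,
      bound_itrs = sort(unique(stats::na.omit(truth$at_itr)))
    )
    if (tracks) {
      bin <- config$bin_size
      n_bins <- G %/% bin
      bg1 <- stats::rpois(n_bins, 5)
      bg2 <- stats::rpois(n_bins, 5)
      ip <- as.numeric(bg1)
      half_k <- 300L %/% bin
      kern <- 30 * (1 - abs(seq(-half_k, half_k)) / (half_k + 1))
      for (cc in centers) {
        cb <- cc %/% bin + 1L
        idx <- (cb - half_k):(cb + half_k)
        ok <- idx >= 1L & idx <= n_bins
        ip[idx[ok]] <- ip[idx[ok]] + kern[ok]
      }
      mk <- function(v) tibble::tibble(
        chrom = chrom, start = (seq_len(n_bins) - 1L) * bin,
        end = seq_len(n_bins) * bin, value = v)
      out$ip_track <- mk(ip)
      out$input_track <- mk(as.numeric(bg2))
    }
    out
  })
}

#' Simulate paired differential-expression tables with planted structure
#'
#' Condition A plants `round(frac_de * n_genes)` DE genes (`up_frac`
#' up-regulated), with ITR-carrying genes' odds of entering the up set
#' multiplied by `itr_odds_ratio`. Condition B shares `shared_de` of A's
#' DE genes, flipping each one's direction with probability
#' `opposite_frac`, and adds its own DE genes up to `n_de_b` with up
#' fraction `up_frac_b`. Called genes receive `|log2FC|` of `1 +`
#' lognormal (strictly above the 2-fold threshold) and `padj <= 0.05`;
#' non-called genes stay below both thresholds.
#'
#' @param n_genes Population size (ignored when `gene_ids` given).
#' @param n_itr_genes Number of ITR-carrying genes (ignored when
#'   `itr_gene_ids` given).
#' @param gene_ids Optional explicit gene universe (e.g. from a simulated
#'   genome's gene models).
#' @param itr_gene_ids Optional explicit ITR-carrier set.
#' @param frac_de Fraction of genes DE in condition A.
#' @param up_frac Fraction of A's DE genes that are up-regulated.
#' @param itr_odds_ratio Odds multiplier for ITR genes entering the up set.
#' @param shared_de Number of A's DE genes also DE in condition B.
#' @param opposite_frac Probability a shared DE gene flips direction in B.
#' @param n_de_b Total DE genes in condition B (>= `shared_de`).
#' @param up_frac_b Up fraction among B's non-shared DE genes.
#' @param seed Integer seed.
#' @param config A [pipeline_config()].
#' @return List `de_a`, `de_b` (tibbles `gene_id, mean_expr, log2fc,
#'   padj`) and `truth` (ITR carriers, per-condition planted calls,
#'   shared/flipped gene sets, and `enrichment_truth` counts `N, K, n, k`
#'   for the up-set test).
#' @export
simulate_de <- function(n_genes = 16776L, n_itr_genes = 1342L,
                        gene_ids = NULL, itr_gene_ids = NULL,
                        frac_de = 0.088, up_frac = 0.65,
                        itr_odds_ratio = 1.6,
                        shared_de = 103L, opposite_frac = 0.74,
                        n_de_b = 480L, up_frac_b = 0.25,
                        seed = 1L, config = pipeline_config()) {
  withr::with_seed(seed, {
    if (is.null(gene_ids))
      gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
    n <- length(gene_ids)
    if (is.null(itr_gene_ids))
      itr_gene_ids <- sample(gene_ids, min(n_itr_genes, n))
    has_itr <- gene_ids %in% itr_gene_ids
    n_de <- round(frac_de * n)
    n_up <- round(up_frac * n_de)
    n_down <- n_de - n_up
    w <- ifelse(has_itr, itr_odds_ratio, 1)
    up_a <- if (n_up > 0) sample(gene_ids, n_up, prob = w) else character(0)
    rest <- setdiff(gene_ids, up_a)
    down_a <- if (n_down > 0) sample(rest, n_down) else character(0)

    fill_table <- function(up, down) {
      call <- rep("ns", n)
      call[gene_ids %in% up] <- "up"
      call[gene_ids %in% down] <- "down"
      lfc <- stats::runif(n, -0.99, 0.99)
      mag <- 1 + stats::rlnorm(n, meanlog = -0.7, sdlog = 0.8)
      lfc[call == "up"] <- mag[call == "up"]
      lfc[call == "down"] <- -mag[call == "down"]
      padj <- stats::runif(n)
      padj[call != "ns"] <- stats::runif(sum(call != "ns"),
                                         0, config$padj_threshold)
      list(tbl = tibble::tibble(
        gene_id = gene_ids,
        mean_expr = stats::rlnorm(n, meanlog = 4, sdlog = 1.5),
        log2fc = lfc, padj = padj), call = call)
    }
    a <- fill_table(up_a, down_a)

    de_a_genes <- c(up_a, down_a)
    shared_de <- min(shared_de, length(de_a_genes))
    shared <- if (shared_de > 0) sample(de_a_genes, shared_de) else character(0)
    flip <- stats::runif(length(shared)) < opposite_frac
    dir_a <- ifelse(shared %in% up_a, "up", "down")
    dir_b <- ifelse(flip, ifelse(dir_a == "up", "down", "up"), dir_a)
    n_extra <- max(0L, n_de_b - shared_de)
    pool_b <- setdiff(gene_ids, c(de_a_genes, shared))
    extra <- if (n_extra > 0) sample(pool_b, min(n_extra, length(pool_b)))
             else character(0)
    extra_up <- stats::runif(length(extra)) < up_frac_b
    up_b <- c(shared[dir_b == "up"], extra[extra_up])
    down_b <- c(shared[dir_b == "down"], extra[!extra_up])
    b <- fill_table(up_b, down_b)

    k_up <- sum(up_a %in% itr_gene_ids)
    list(
      de_a = a$tbl, de_b = b$tbl,
      truth = list(
        itr_gene_ids = sort(itr_gene_ids),
        call_a = stats::setNames(a$call, gene_ids),
        call_b = stats::setNames(b$call, gene_ids),
        shared = sort(shared),
        n_flipped = sum(flip),
        enrichment_truth = c(N = n, K = sum(has_itr), n = length(up_a),
                             k = k_up)
      )
    )
  })
}

#' Simulate gene-level fragment counts
#'
#' Poisson counts with lognormal per-gene rates proportional to union-exon
#' length, for exercising FPKM computation end-to-end.
#'
#' @param genes Gene-model tibble.
#' @param mean_depth Mean fragments per kb of exon.
#' @param seed Integer seed.
#' @return Tibble `gene_id, fragments`.
#' @export
simulate_counts <- function(genes, mean_depth = 50, seed = 1L) {
  withr::with_seed(seed, {
    lens <- exon_union_length(genes)
    rate <- stats::rlnorm(nrow(lens), 0, 1) * mean_depth * lens$exon_length / 1000
    tibble::tibble(gene_id = lens$gene_id,
                   fragments = stats::rpois(nrow(lens), rate))
  })
}

#' Simulation presets
#'
#' `small`: a 200 kb genome with 25 elements (12 solo, 10 Made1, 3
#' paired), 8% divergence, two-thirds intragenic, 60 peaks (half at ITRs),
#' IP/input tracks, and DE tables over the simulated genes — the desk
#' scale at which every stage runs in seconds. `paper_scale`: a 2e8 bp
#' coordinate-only layout holding 410 ITRs (the human-genome ITR density),
#' 875 peaks of which 34% are planted at ITRs, and 16,776-gene DE tables
#' sharing 103 DE genes between conditions with 74% direction reversal —
#' the published study's headline geometry.
#'
#' @param preset `"small"` or `"paper_scale"`.
#' @param seed Integer seed.
#' @param tracks Generate coverage tracks (small preset only).
#' @param config A [pipeline_config()].
#' @return List `sim`, `chip`, `de` (and the preset name).
#' @export
simulate_preset <- function(preset = c("small", "paper_scale"), seed = 1L,
                            tracks = TRUE, config = pipeline_config()) {
  preset <- match.arg(preset)
  if (preset == "small") {
    sim <- simulate_genome(seed, config)
    chip <- simulate_chip(sim, n_peaks = 60L, frac_at_itr = 0.5,
                          seed = seed + 1L, tracks = tracks, config = config)
    itr_gene_ids <- unique(stats::na.omit(sim$elements$gene_id))
    de <- simulate_de(gene_ids = sim$genes$gene_id,
                      itr_gene_ids = itr_gene_ids,
                      frac_de = 0.3, up_frac = 0.65, itr_odds_ratio = 3,
                      shared_de = 5L, n_de_b = 8L,
                      seed = seed + 2L, config = config)
  } else {
    sim <- simulate_genome(seed, config, genome_length = 2e8,
                           n_solo = 150L, n_made1 = 115L, n_paired = 15L,
                           n_extra_genes = 0L, sequence = FALSE)
    chip <- simulate_chip(sim, n_peaks = 875L, frac_at_itr = 0.34,
                          seed = seed + 1L, tracks = FALSE, config = config)
    de <- simulate_de(seed = seed + 2L, config = config)
  }
  list(preset = preset, sim = sim, chip = chip, de = de)
}
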