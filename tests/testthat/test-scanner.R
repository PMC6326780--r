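test_that("planted exact copies are found on either strand with identity 1", {
  withr::with_seed(31, {
    cons <- rand_seq(28)
    g_fwd <- paste0(rand_seq(1000), cons, rand_seq(1000))
    g_rev <- paste0(rand_seq(1000), revcomp(cons), rand_seq(1000))
  })
  h1 <- scan_consensus(c(chr1 = g_fwd), cons)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$start, 1000L)
  expect_equal(h1$end, 1028L)
  expect_equal(h1$strand, "+")
  expect_equal(h1$identity, 1)
  expect_equal(h1$aligned_consensus_frac, 1)
  h2 <- scan_consensus(c(chr1 = g_rev), cons)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$strand, "-")
  expect_equal(h2$identity, 1)
})

test_that("the 80% identity filter separates 5 from 6 substitutions in 28 bp", {
  withr::with_seed(32, {
    cons <- rand_seq(28)
    copy5 <- substitute_at(cons, c(4, 8, 12, 16, 20))
    copy6 <- substitute_at(cons, c(4, 8, 12, 16, 20, 24))
    g5 <- paste0(rand_seq(600), copy5, rand_seq(600))
    g6 <- paste0(rand_seq(600), copy6, rand_seq(600))
  })
  h5 <- scan_consensus(c(c5 = g5), cons)
  expect_equal(nrow(h5), 1)
  expect_equal(h5$identity, 23 / 28, tolerance = 1e-12)  # 0.821 >= 0.80
  expect_equal(nrow(scan_consensus(c(c6 = g6), cons)), 0)  # 22/28 < 0.80
  # independent DP oracle agrees on the planted windows
  o5 <- oracle_scan(g5, cons)
  expect_equal(nrow(o5), 1)
  expect_equal(o5$start, h5$start)
  expect_equal(o5$score, as.numeric(h5$score))
  expect_equal(nrow(oracle_scan(g6, cons)), 0)
})

test_that("retained loci equal the exhaustive per-window DP oracle on random genomes", {
  withr::with_seed(33, {
    cons <- rand_seq(28)
    for (rep in 1:5) {
      plants <- list(
        list(seq = cons, strand = "+"),
        list(seq = substitute_at(revcomp(cons), c(5, 9, 14, 19)), strand = "-"),
        list(seq = substitute_at(cons, c(4, 8, 12, 16, 20, 24)), strand = "+"))
      g <- paste0(rand_seq(400), plants[[1]]$seq, rand_seq(400),
                  plants[[2]]$seq, rand_seq(400), plants[[3]]$seq,
                  rand_seq(400))
      cfg <- pipeline_config()
      got <- scan_consensus(c(chr = g), cons, cfg, apply_filters = FALSE)
      want <- oracle_scan(g, cons, cfg, apply_filters = FALSE,
                          min_keep = itrtools:::candidate_min_score(28, cfg))
      # 1:1 by overlap (equal-score paths may wobble a boundary base)
      expect_equal(nrow(got), nrow(want))
      expect_true(all(got$start < want$end & got$end > want$start))
      expect_equal(got$strand, want$strand)
      expect_equal(as.numeric(got$score), want$score)
      # filtered output is a subset of the same landscape
      kept <- scan_consensus(c(chr = g), cons, cfg)
      expect_true(all(kept$start %in% got$start))
    }
  })
})

test_that("scanning the reverse-complemented genome mirrors the hit set", {
  withr::with_seed(34, {
    cons <- rand_seq(28)
    g <- paste0(rand_seq(700), cons, rand_seq(500),
                substitute_at(revcomp(cons), c(6, 11, 17)), rand_seq(700))
  })
  fwd <- scan_consensus(c(chr = g), cons)
  rev_ <- scan_consensus(c(chr = revcomp(g)), cons)
  L <- nchar(g)
  expect_equal(nrow(fwd), nrow(rev_))
  mirrored <- tibble::tibble(start = L - rev(rev_$end),
                             end = L - rev(rev_$start),
                             strand = rev(ifelse(rev_$strand == "+", "-", "+")))
  expect_equal(fwd$start, mirrored$start)
  expect_equal(fwd$end, mirrored$end)
  expect_equal(fwd$strand, mirrored$strand)
})

test_that("raising min_identity never increases the retained-hit count", {
  withr::with_seed(35, {
    cons <- rand_seq(28)
    segs <- c(rand_seq(500))
    for (nsub in c(0, 2, 4, 5, 6, 8))
      segs <- c(segs, substitute_at(cons, utils::head(c(4, 8, 12, 16, 20, 25,
                                                        10, 14), nsub)),
                rand_seq(500))
    g <- paste(segs, collapse = "")
  })
  counts <- vapply(c(0.6, 0.7, 0.8, 0.9, 1.0), function(id) {
    nrow(scan_consensus(c(chr = g), cons,
                        pipeline_config(min_identity = id)))
  }, 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("degenerate scanner inputs behave as documented", {
  expect_error(scan_consensus(c(chr = "ACGT"), ""), "empty consensus or genome")
  expect_error(scan_consensus(character(0), "ACGTACGT"),
               "empty consensus or genome")
  expect_warning(h <- scan_consensus(c(chr = "ACGT"), strrep("ACGT", 3)),
                 "longer than every genome sequence")
  expect_equal(nrow(h), 0)
  # N in the genome never matches: an ITR copy overwritten with N is lost
  withr::with_seed(36, cons <- rand_seq(28))
  g_n <- paste0(strrep("N", 100), cons, strrep("N", 100))
  expect_equal(scan_consensus(c(chr = g_n), cons)$start, 100L)
  g_masked <- paste0(strrep("N", 228))
  expect_equal(nrow(scan_consensus(c(chr = g_masked), cons)), 0)
})

test_that("classify_remnants pairs inverted hits into Made1 and paired remnants", {
  cfg <- pipeline_config()
  hits <- tibble::tibble(
    chrom = "chr1",
    start = c(100L, 134L, 1000L, 5000L, 5328L),
    end = c(128L, 162L, 1028L, 5028L, 5356L),
    strand = c("+", "-", "+", "+", "-"),
    name = sprintf("h%d", 1:5))
  ann <- classify_remnants(hits, cfg)
  made1 <- ann[ann$remnant_class == "made1", ]
  expect_equal(nrow(made1), 1)
  expect_equal(made1$spacer_length, 6L)        # ITRs at [100,128) and [134,162)
  expect_equal(made1$itr_names, "h1,h2")
  expect_equal(ann$remnant_class[ann$itr_names == "h3"], "solo_itr")
  paired <- ann[ann$remnant_class == "paired_itr_remnant", ]
  expect_equal(nrow(paired), 1)                # gap 300 <= pair_span
  expect_equal(paired$itr_names, "h4,h5")
  # every hit belongs to exactly one annotation
  members <- unlist(strsplit(ann$itr_names, ","))
  expect_setequal(members, hits$name)
  expect_equal(anyDuplicated(members), 0L)
})

test_that("ambiguous middles pair greedily left-to-right", {
  cfg <- pipeline_config()
  # middle hit could pair left (gap 6) or right (gap 6); greedy takes left
  hits <- tibble::tibble(
    chrom = "chr1", start = c(100L, 134L, 168L),
    end = c(128L, 162L, 196L), strand = c("+", "-", "+"),
    name = c("a", "b", "c"))
  ann <- classify_remnants(hits, cfg)
  expect_equal(ann$remnant_class, c("made1", "solo_itr"))
  expect_equal(ann$itr_names, c("a,b", "c"))
  # single hit is solo
  solo <- classify_remnants(hits[1, ], cfg)
  expect_equal(solo$remnant_class, "solo_itr")
  # same-strand neighbours never pair
  same <- classify_remnants(
    tibble::tibble(chrom = "c", start = c(0L, 34L), end = c(28L, 62L),
                   strand = "+", name = c("x", "y")), cfg)
  expect_equal(same$remnant_class, c("solo_itr", "solo_itr"))
})

test_that("census_report assigns contexts from generator ground truth", {
  sim <- simulate_genome(99, genome_length = 300000L, n_solo = 10L,
                         n_made1 = 5L, n_paired = 0L,
                         frac_intragenic = 10 / 15, divergence = 0)
  ann <- classify_remnants(sim$itrs, pipeline_config())
  census <- census_report(ann, sim$genes)
  expect_equal(sum(census$n), nrow(ann))
  intra <- sum(census$n[census$context != "intergenic"])
  inter <- sum(census$n[census$context == "intergenic"])
  # generator planted 10 intragenic (intronic) and 5 intergenic elements
  expect_equal(intra, 10L)
  expect_equal(inter, 5L)
  expect_equal(sum(census$n[census$context == "intragenic_intron"]), 10L)
  # empty input: an all-zero completed table
  zero <- census_report(ann[0, ], sim$genes)
  expect_equal(sum(zero$n), 0L)
  expect_equal(nrow(zero), 9L)
})
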