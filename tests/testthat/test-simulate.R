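cfg <- pipeline_config()

test_that("simulation is byte-identical per seed across all generators", {
  s1 <- simulate_genome(123)
  s2 <- simulate_genome(123)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$itrs, s2$itrs)
  expect_identical(s1$genes, s2$genes)
  c1 <- simulate_chip(s1, n_peaks = 40L, frac_at_itr = 0.4, seed = 9,
                      tracks = TRUE)
  c2 <- simulate_chip(s2, n_peaks = 40L, frac_at_itr = 0.4, seed = 9,
                      tracks = TRUE)
  expect_identical(c1$peaks, c2$peaks)
  expect_identical(c1$ip_track, c2$ip_track)
  d1 <- simulate_de(n_genes = 300L, n_itr_genes = 30L, seed = 4)
  d2 <- simulate_de(n_genes = 300L, n_itr_genes = 30L, seed = 4)
  expect_identical(d1$de_a, d2$de_a)
  expect_identical(d1$de_b, d2$de_b)
  # different seed, different genome
  expect_false(identical(as.character(simulate_genome(124)$genome),
                         as.character(s1$genome)))
})

test_that("zero-divergence plants are recovered perfectly; heavy decay is rejected", {
  for (seed in c(3, 17)) {
    sim0 <- simulate_genome(seed, divergence = 0, n_solo = 10L,
                            n_made1 = 5L, n_paired = 2L)
    hits <- scan_consensus(sim0$genome, sim0$consensus, cfg)
    # recall 1.0: every planted locus recovered exactly, at identity 1
    recovered <- dplyr::inner_join(
      sim0$itrs[, c("start", "end")],
      hits[, c("start", "end", "identity")], by = c("start", "end"))
    expect_equal(nrow(recovered), nrow(sim0$itrs))
    expect_true(all(recovered$identity == 1))
    # chance background hits are rare in 200 kb
    expect_lte(nrow(hits) - nrow(recovered), 3L)
  }
  # far beyond the 80% filter: recall 0 at the planted loci (chance
  # background hits elsewhere in 120 kb of random sequence are expected
  # and are not recalls)
  for (seed in 1:20) {
    simx <- simulate_genome(seed, divergence = 0.45, n_solo = 4L,
                            n_made1 = 0L, n_paired = 0L,
                            genome_length = 120000L, n_extra_genes = 2L)
    hits <- scan_consensus(simx$genome, simx$consensus, cfg)
    at_plant <- vapply(seq_len(nrow(simx$itrs)), function(i)
      any(hits$start < simx$itrs$end[i] & hits$end > simx$itrs$start[i]),
      TRUE)
    expect_equal(sum(at_plant), 0L)
  }
})

test_that("mean recovered identity tracks the planted divergence", {
  ids <- c()
  seed <- 0
  while (length(ids) < 50) {
    seed <- seed + 1
    sim <- simulate_genome(seed, divergence = 0.10, n_solo = 10L,
                           n_made1 = 0L, n_paired = 0L,
                           genome_length = 150000L, n_extra_genes = 2L)
    hits <- scan_consensus(sim$genome, sim$consensus, cfg)
    ids <- c(ids, hits$identity)
  }
  expect_equal(mean(ids[1:50]), 0.90, tolerance = 0.03 / 0.90)
})

test_that("made1 geometry carries the 6 bp spacer into classification", {
  sim <- simulate_genome(55, divergence = 0, n_solo = 0L, n_made1 = 8L,
                         n_paired = 0L)
  ann <- classify_remnants(sim$itrs, cfg)
  expect_equal(sort(unique(ann$remnant_class)), "made1")
  expect_equal(nrow(ann), 8L)
  expect_true(all(ann$spacer_length == 6L))
})

test_that("chip planting honours frac_at_itr at both extremes", {
  sim <- simulate_genome(66, divergence = 0)
  all_at <- simulate_chip(sim, n_peaks = 50L, frac_at_itr = 1, seed = 1)
  a <- assign_peaks(all_at$peaks, sim$itrs, cfg)
  expect_true(all(a$distance <= cfg$bound_dist))
  s <- peak_tier_summary(a)
  expect_equal(sum(s$fraction[s$tier %in% c("overlap", "lt150", "le500")]), 1)
  none_at <- simulate_chip(sim, n_peaks = 50L, frac_at_itr = 0, seed = 2)
  expect_true(all(is.na(none_at$truth$at_itr)))
  expect_equal(length(none_at$bound_itrs), 0L)
})

test_that("an input track subtracted from itself gives a zero profile", {
  sim <- simulate_genome(77, divergence = 0)
  chip <- simulate_chip(sim, n_peaks = 20L, frac_at_itr = 0.5, seed = 3,
                        tracks = TRUE)
  pm <- suppressMessages(
    profile_matrix(chip$input_track, sim$itrs, halfwidth = 1000,
                   bin_size = 10))
  expect_true(all(subtract_input(pm, pm)$matrix == 0))
})

test_that("simulate_de plants calls, thresholds and shared-direction structure", {
  de <- simulate_de(n_genes = 1000L, n_itr_genes = 100L, frac_de = 0.2,
                    up_frac = 0.6, shared_de = 40L, opposite_frac = 0.7,
                    n_de_b = 60L, seed = 12)
  called_a <- apply_de_thresholds(de$de_a, cfg)
  expect_equal(unname(called_a$call), unname(de$truth$call_a))
  counts <- de_call_counts(called_a)
  expect_equal(counts$n[counts$call == "up"], round(0.6 * 200))
  expect_equal(sum(counts$n[counts$call != "ns"]), 200L)
  called_b <- apply_de_thresholds(de$de_b, cfg)
  conc <- direction_concordance(called_a, called_b)
  expect_equal(conc$n_both, 40L)
  expect_equal(conc$n_opposite, de$truth$n_flipped)
  # enrichment truth matches a recount from the tables
  k <- sum(called_a$call == "up" &
             called_a$gene_id %in% de$truth$itr_gene_ids)
  expect_equal(unname(de$truth$enrichment_truth["k"]), k)
  # no DE at all
  zero <- simulate_de(n_genes = 100L, n_itr_genes = 10L, frac_de = 0,
                      shared_de = 0L, n_de_b = 0L, seed = 5)
  expect_true(all(apply_de_thresholds(zero$de_a, cfg)$call == "ns"))
})

test_that("null odds ratio gives uniform enrichment p-values over seeds", {
  ps <- vapply(1:60, function(seed) {
    de <- simulate_de(n_genes = 600L, n_itr_genes = 60L, frac_de = 0.2,
                      itr_odds_ratio = 1, shared_de = 0L, n_de_b = 0L,
                      seed = seed)
    rec <- tibble::tibble(
      gene_id = de$de_a$gene_id,
      has_itr = de$de_a$gene_id %in% de$truth$itr_gene_ids,
      call_a = unname(de$truth$call_a), call_b = "ns")
    itr_gene_enrichment(rec, "call_a", "up", "over")$p
  }, 1)
  # p-values are discrete, so ties are expected; the KS statistic is
  # still the right sanity check at this resolution
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(ps), 0.3)
})

test_that("infeasible packing is refused", {
  expect_error(simulate_genome(1, genome_length = 20000L, n_solo = 30L,
                               n_made1 = 10L, n_paired = 5L),
               "infeasible packing")
})
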