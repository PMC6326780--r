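cfg <- pipeline_config()

test_that("assign_peaks tiers follow gap distance and config thresholds", {
  itrs <- tibble::tibble(chrom = "chr1", start = 1500L, end = 1528L,
                         strand = "+", name = "itr1")
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(1490L, 1600L, 1000L, 3000L),
    end = c(1540L, 1700L, 1200L, 3200L),
    strand = ".",
    name = c("overlapping", "near", "mid", "far"))
  a <- assign_peaks(peaks, itrs, cfg)
  a <- a[match(peaks$name, a$name), ]
  expect_equal(a$distance, c(0L, 72L, 300L, 1472L))
  expect_equal(a$tier, c("overlap", "lt150", "le500", "gt500"))
  # peak on an ITR-less chromosome
  lonely <- assign_peaks(tibble::tibble(chrom = "chrZ", start = 0L,
                                        end = 100L, strand = ".",
                                        name = "z"), itrs, cfg)
  expect_equal(lonely$tier, "no_itr_on_chrom")
  expect_true(is.na(lonely$distance))
  s <- peak_tier_summary(a)
  expect_equal(sum(s$fraction), 1)
  expect_equal(sum(s$n), nrow(a))
  expect_equal(bound_itr_set(peaks, itrs, cfg), "itr1")
})

test_that("boundary peaks at exactly bound_dist are within 500 and 501 is not", {
  itrs <- tibble::tibble(chrom = "c", start = 10000L, end = 10028L,
                         strand = "+", name = "i")
  mk <- function(gap) tibble::tibble(chrom = "c", start = 10028L + gap,
                                     end = 10228L + gap, strand = ".",
                                     name = "p")
  expect_equal(assign_peaks(mk(500L), itrs, cfg)$tier, "le500")
  expect_equal(assign_peaks(mk(501L), itrs, cfg)$tier, "gt500")
  expect_equal(assign_peaks(mk(149L), itrs, cfg)$tier, "lt150")
  expect_equal(assign_peaks(mk(150L), itrs, cfg)$tier, "le500")
})

test_that("classify_genes applies the bound > distal > no-ITR priority", {
  genes <- gene_models(tibble::tibble(
    chrom = "chr1", start = c(0L, 20000L, 40000L, 60000L),
    end = c(10000L, 30000L, 50000L, 70000L), strand = "+",
    gene_id = c("bound", "distal", "noitr", "nopeak")))
  itrs <- tibble::tibble(chrom = "chr1",
                         start = c(2000L, 22000L), end = c(2028L, 22028L),
                         strand = "+", name = c("iA", "iB"))
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(2100L, 25000L, 42000L),
    end = c(2300L, 25200L, 42200L), strand = ".",
    name = c("p1", "p2", "p3"))
  gc <- classify_genes(peaks, genes, itrs, cfg)
  expect_equal(gc$class[gc$gene_id == "bound"], "bound_itr")    # gap 72
  expect_equal(gc$class[gc$gene_id == "distal"], "distal_peak_with_itr")
  expect_equal(gc$class[gc$gene_id == "noitr"], "peak_no_itr")
  expect_equal(gc$class[gc$gene_id == "nopeak"], "no_peak")
  expect_equal(gc$n_intragenic_itrs[gc$gene_id == "bound"], 1L)
})

test_that("classify_genes is stable under permutation of peak order", {
  sim <- simulate_genome(71, divergence = 0)
  chip <- simulate_chip(sim, n_peaks = 40L, frac_at_itr = 0.6, seed = 72,
                        config = cfg)
  base <- classify_genes(chip$peaks, sim$genes, sim$itrs, cfg)
  withr::with_seed(73, perm <- sample(nrow(chip$peaks)))
  shuffled <- classify_genes(chip$peaks[perm, ], sim$genes, sim$itrs, cfg)
  expect_equal(base, shuffled)
})

test_that("overlapping genes each receive a shared peak", {
  genes <- gene_models(tibble::tibble(
    chrom = "chr1", start = c(0L, 5000L), end = c(10000L, 15000L),
    strand = "+", gene_id = c("gA", "gB")))
  peaks <- tibble::tibble(chrom = "chr1", start = 6000L, end = 6200L,
                          strand = ".", name = "shared")
  gc <- classify_genes(peaks, genes, tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), name = character()), cfg)
  expect_equal(sum(gc$n_peaks), 2L)    # 1 peak, 2 peak-bearing genes
  expect_equal(gc$class, c("peak_no_itr", "peak_no_itr"))
})

test_that("intron-only mode excludes exonic ITRs from the intragenic set", {
  genes <- gene_models(
    tibble::tibble(chrom = "c", start = 0L, end = 10000L, strand = "+",
                   gene_id = "g"),
    tibble::tibble(gene_id = "g", start = c(0L, 9000L),
                   end = c(3000L, 10000L)))
  itr_exonic <- tibble::tibble(chrom = "c", start = 1000L, end = 1028L,
                               strand = "+", name = "exonic")
  itr_intronic <- tibble::tibble(chrom = "c", start = 5000L, end = 5028L,
                                 strand = "+", name = "intronic")
  peaks <- tibble::tibble(chrom = "c", start = c(1100L, 5100L),
                          end = c(1300L, 5300L), strand = ".",
                          name = c("pe", "pi"))
  both <- rbind(itr_exonic, itr_intronic)
  span <- classify_genes(peaks, genes, both, cfg, intragenic = "span")
  expect_equal(span$n_intragenic_itrs, 2L)
  intron <- classify_genes(peaks, genes, both, cfg, intragenic = "intron")
  expect_equal(intron$n_intragenic_itrs, 1L)
  expect_equal(intron$class, "bound_itr")
})

test_that("peak_gene_distribution uses exclusive contexts with priority", {
  genes <- gene_models(tibble::tibble(
    chrom = "chr1", start = 10000L, end = 20000L, strand = "+",
    gene_id = "g1"))
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(12000L, 8000L, 1000L),
    end = c(12200L, 8200L, 1200L), strand = ".",
    name = c("inside", "upstream2k", "far"))
  d <- peak_gene_distribution(peaks, genes, flank = 3000L)
  expect_equal(d$n[d$context == "intragenic"], 1L)
  expect_equal(d$n[d$context == "within_flank"], 1L)  # gap 1800 <= 3000
  expect_equal(d$n[d$context == "intergenic"], 1L)
  expect_equal(sum(d$n), nrow(peaks))
  # all peaks inside genes
  all_in <- peak_gene_distribution(peaks[1, ], genes, 3000L)
  expect_equal(all_in$fraction[all_in$context == "intragenic"], 1)
  # empty gene list: everything intergenic
  none <- peak_gene_distribution(peaks, genes[0, ], 3000L)
  expect_equal(none$n[none$context == "intergenic"], 3L)
})

test_that("planted bound-ITR genes are recovered exactly when peaks are unambiguous", {
  # solo ITRs only, zero divergence: every peak sits near exactly one ITR
  sim <- simulate_genome(81, divergence = 0, n_solo = 20L, n_made1 = 0L,
                         n_paired = 0L)
  chip <- simulate_chip(sim, n_peaks = 30L, frac_at_itr = 1, seed = 82,
                        config = cfg)
  hits <- scan_consensus(sim$genome, sim$consensus, cfg)
  # with zero divergence, scanning recovers every planted locus
  expect_equal(hits$start, sim$itrs$start)
  expect_equal(hits$end, sim$itrs$end)
  a <- assign_peaks(chip$peaks, sim$itrs, cfg)
  expect_true(all(a$distance <= cfg$bound_dist))
  expect_setequal(bound_itr_set(chip$peaks, sim$itrs, cfg),
                  chip$bound_itrs)
})
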