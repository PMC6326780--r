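uniform_track <- function(value = 1, len = 20000L)
  tibble::tibble(chrom = "c", start = 0L, end = len, value = value)

test_that("normalize_track scales by the documented factors and is linear", {
  tr <- uniform_track(0.5, 1000L)
  # 10 reads of 50 bp on a 1 kb genome: scale 1000/500 = 2
  out <- normalize_track(tr, "rpgc_1x", genome_size = 1000,
                         read_length = 50, total_reads = 10)
  expect_equal(out$value, 1)
  # exact 1x depth is a fixed point
  fix <- normalize_track(uniform_track(1, 1000L), "rpgc_1x",
                         genome_size = 1000, read_length = 100,
                         total_reads = 10)
  expect_equal(fix$value, 1)
  # linearity
  a <- normalize_track(uniform_track(3), "rpkm", total_reads = 500,
                       bin_size = 10)
  b <- normalize_track(uniform_track(6), "rpkm", total_reads = 500,
                       bin_size = 10)
  expect_equal(2 * a$value, b$value)
  expect_equal(a$value, 3 * 1e9 / (500 * 10))
  expect_error(normalize_track(tr, "rpgc_1x", genome_size = 1000,
                               read_length = 50, total_reads = 0),
               "positive count")
  expect_equal(normalize_track(tr, "none"), tr)
})

test_that("profile_matrix reproduces uniform and delta tracks analytically", {
  # plus-strand points: the bin labelled 0 is [midpoint, midpoint + bin);
  # minus-strand reversal maps it to [-bin, 0) and is tested separately
  points <- gintervals("c", c(5000L, 9000L, 13000L),
                       c(5028L, 9028L, 13028L),
                       strand = "+",
                       name = c("p1", "p2", "p3"))
  pm_u <- profile_matrix(uniform_track(2.5), points, halfwidth = 500,
                         bin_size = 10)
  expect_equal(dim(pm_u$matrix), c(3L, 100L))
  expect_true(all(pm_u$matrix == 2.5))
  # delta of value v at each midpoint only: central bin v / bin_size
  mids <- (points$start + points$end) %/% 2L
  delta <- tibble::tibble(chrom = "c", start = mids, end = mids + 1L,
                          value = 7)
  pm_d <- profile_matrix(delta, points, halfwidth = 500, bin_size = 10,
                         chrom_sizes = c(c = 20000L))
  central <- which(colnames(pm_d$matrix) == "0")
  expect_true(all(pm_d$matrix[, central] == 7 / 10))
  expect_equal(sum(pm_d$matrix), 3 * 7 / 10)
  s <- profile_summary(pm_d)
  expect_equal(s$coverage[s$offset == 0], 7 / 10)
})

test_that("minus-strand points read 5prime to 3prime and profiles respect strand flips", {
  # asymmetric track: a step left of the single point midpoint
  track <- tibble::tibble(chrom = "c", start = c(0L, 4000L),
                          end = c(4000L, 20000L), value = c(5, 1))
  pt_plus <- gintervals("c", 3990L, 4010L, strand = "+", name = "x")
  pt_minus <- gintervals("c", 3990L, 4010L, strand = "-", name = "x")
  pm_p <- profile_matrix(track, pt_plus, halfwidth = 1000, bin_size = 10)
  pm_m <- profile_matrix(track, pt_minus, halfwidth = 1000, bin_size = 10)
  expect_equal(pm_m$matrix[1, ], rev(pm_p$matrix[1, ]),
               ignore_attr = TRUE)
  # mean profile invariant under permutation of the points
  pts <- gintervals("c", c(5000L, 9000L, 15000L), c(5028L, 9028L, 15028L),
                    strand = "+", name = c("a", "b", "d"))
  pm1 <- profile_matrix(track, pts, halfwidth = 500, bin_size = 10)
  pm2 <- profile_matrix(track, pts[c(3, 1, 2), ], halfwidth = 500,
                        bin_size = 10)
  expect_equal(profile_summary(pm1), profile_summary(pm2))
})

test_that("edge points are dropped with a message and geometry is validated", {
  track <- uniform_track(1, 10000L)
  pts <- gintervals("c", c(100L, 5000L), c(128L, 5028L), name = c("e", "m"))
  expect_message(pm <- profile_matrix(track, pts, halfwidth = 1000,
                                      bin_size = 10),
                 "too close to a sequence edge")
  expect_equal(pm$n_dropped, 1L)
  expect_equal(nrow(pm$matrix), 1L)
  expect_error(profile_matrix(track, pts, halfwidth = 1003, bin_size = 10),
               "divide")
  expect_error(suppressMessages(
    profile_matrix(track, pts[1, ], halfwidth = 4000, bin_size = 10)),
    "no usable reference points")
})

test_that("subtract_input is exact and enforces identical geometry", {
  track <- uniform_track(4)
  pts <- gintervals("c", 10000L, 10028L, name = "p")
  ip <- profile_matrix(track, pts, halfwidth = 500, bin_size = 10)
  input <- profile_matrix(uniform_track(1.5), pts, halfwidth = 500,
                          bin_size = 10)
  diff <- subtract_input(ip, input)
  expect_true(all(diff$matrix == 2.5))
  # ip == input: all-zero profile
  self <- subtract_input(ip, ip)
  expect_true(all(self$matrix == 0))
  # zero input: identity
  zero <- input
  zero$matrix[] <- 0
  expect_equal(subtract_input(ip, zero)$matrix, ip$matrix)
  other <- profile_matrix(track, pts, halfwidth = 250, bin_size = 10)
  expect_error(subtract_input(ip, other), "geometry")
  # three-bin toy with hand-checked differences
  t3a <- profile_matrix(tibble::tibble(chrom = "c", start = c(0L, 100L, 200L),
                                       end = c(100L, 200L, 20000L),
                                       value = c(3, 1, 2)),
                        gintervals("c", 10000L, 10030L, name = "q"),
                        halfwidth = 15, bin_size = 10)
  t3b <- profile_matrix(uniform_track(0.5),
                        gintervals("c", 10000L, 10030L, name = "q"),
                        halfwidth = 15, bin_size = 10)
  expect_equal(as.numeric(subtract_input(t3a, t3b)$matrix),
               c(1.5, 1.5, 1.5))
})

test_that("nucleosome-style synthetic tracks recover trough and phase", {
  # depletion trough at the ITR centre flanked by a phased cosine
  withr::with_seed(71, {
    centers <- seq(20000L, 180000L, by = 20000L)
    period <- 200
    pos <- seq(0L, 199990L, by = 10L)
    val <- rep(10, length(pos))
    for (cc in centers) {
      d <- pos + 5 - cc
      inwin <- abs(d) <= 1000
      val[inwin] <- val[inwin] +
        ifelse(abs(d[inwin]) < 80, -8,
               4 * cos(2 * pi * d[inwin] / period)) +
        stats::rnorm(sum(inwin), 0, 0.3)
    }
    track <- tibble::tibble(chrom = "c", start = pos, end = pos + 10L,
                            value = val)
  })
  pts <- gintervals("c", centers - 14L, centers + 14L,
                    name = sprintf("itr%d", seq_along(centers)))
  pm <- profile_matrix(track, pts, halfwidth = 1000, bin_size = 10,
                       chrom_sizes = c(c = 200000L))
  s <- profile_summary(pm)
  # trough at the centre (the planted depletion spans +/- 80 bp)
  expect_lte(abs(s$offset[which.min(s$coverage)]), 80L)
  # oscillation period recovered from the flank peaks
  flank <- s[s$offset > 100 & s$offset <= 900, ]
  peaks <- flank$offset[which(diff(sign(diff(flank$coverage))) == -2) + 1]
  expect_equal(mean(diff(peaks)), period, tolerance = 0.15)
})
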