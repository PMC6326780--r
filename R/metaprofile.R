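#' Normalize a coverage track
#'
#' `rpgc_1x` rescales so the genome-wide mean depth is 1x: every value is
#' multiplied by `genome_size / (total_reads * read_length)`. `rpkm`
#' multiplies per-bin values by `1e9 / (total_reads * bin_size)`. `none`
#' returns the track unchanged. Both modes are linear in the input track.
#'
#' @param track bedGraph tibble `chrom, start, end, value`.
#' @param mode `"rpgc_1x"`, `"rpkm"` or `"none"`.
#' @param genome_size Genome size in bp (rpgc_1x).
#' @param read_length Read length in bp (rpgc_1x).
#' @param total_reads Total mapped reads (rpgc_1x, rpkm).
#' @param bin_size Bin size in bp (rpkm).
#' @return The track tibble with rescaled `value`.
#' @export
#' @examples
#' tr <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L, value = 0.5)
#' normalize_track(tr, "rpgc_1x", genome_size = 1000,
#'                 read_length = 50, total_reads = 10)$value  # 2x scale
normalize_track <- function(track, mode = c("rpgc_1x", "rpkm", "none"),
                            genome_size = NULL, read_length = NULL,
                            total_reads = NULL, bin_size = 10L) {
  mode <- match.arg(mode)
  if (mode == "none") return(track)
  if (is.null(total_reads) || total_reads <= 0)
    stop("total_reads must be a positive count")
  scale <- if (mode == "rpgc_1x") {
    if (is.null(genome_size) || is.null(read_length))
      stop("rpgc_1x needs genome_size and read_length")
    genome_size / (total_reads * read_length)
  } else {
    1e9 / (total_reads * bin_size)
  }
  dplyr::mutate(track, value = .data$value * scale)
}

#' Binned coverage matrix around reference points
#'
#' Each row is one reference point; each column the mean per-base coverage
#' in a `bin_size` bin of the `[midpoint - halfwidth, midpoint + halfwidth)`
#' window, with the midpoint defined as `floor((start + end) / 2)`. Rows of
#' minus-strand points are reversed so all bins read 5'->3'. Points whose
#' window extends past a sequence edge are dropped with a message; column
#' names give the bin start offset relative to the midpoint.
#'
#' @param track bedGraph tibble `chrom, start, end, value`.
#' @param points Interval tibble of reference points (strand honoured).
#' @param halfwidth Window half-width in bp; `bin_size` must divide
#'   `2 * halfwidth`.
#' @param bin_size Bin width in bp.
#' @param chrom_sizes Optional named vector of sequence lengths; defaults
#'   to the track extent per chromosome.
#' @param normalization Label recorded on the result (`"none"` unless the
#'   track was passed through [normalize_track()]).
#' @return An object of class `itr_profile`: list with `matrix` (points x
#'   bins), `points`, `halfwidth`, `bin_size`, `normalization`,
#'   `n_dropped`.
#' @export
profile_matrix <- function(track, points, halfwidth = 2000L, bin_size = 10L,
                           chrom_sizes = NULL, normalization = "none") {
  halfwidth <- as.integer(halfwidth); bin_size <- as.integer(bin_size)
  stopifnot(halfwidth > 0, bin_size > 0)
  if ((2L * halfwidth) %% bin_size != 0L)
    stop("bin_size must divide 2 * halfwidth")
  validate_intervals(points, "points")
  if (is.null(chrom_sizes)) {
    chrom_sizes <- track |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(len = max(.data$end), .groups = "drop")
    chrom_sizes <- stats::setNames(chrom_sizes$len, chrom_sizes$chrom)
  }
  mid <- (points$start + points$end) %/% 2L
  len <- chrom_sizes[points$chrom]
  keep <- !is.na(len) & (mid - halfwidth >= 0L) & (mid + halfwidth <= len)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " reference point(s) too close to a sequence edge; dropped")
  points <- points[keep, ]
  mid <- mid[keep]
  if (nrow(points) == 0) stop("no usable reference points")

  # per-chromosome coverage as Rle, then per-point window extraction
  n_bins <- (2L * halfwidth) %/% bin_size
  covs <- lapply(split(track, track$chrom), function(tr) {
    IRanges::coverage(IRanges::IRanges(tr$start + 1L, tr$end),
                      weight = tr$value,
                      width = max(chrom_sizes[tr$chrom[1]], max(tr$end),
                                  na.rm = TRUE))
  })
  mat <- matrix(0, nrow = nrow(points), ncol = n_bins)
  bin_idx <- rep(seq_len(n_bins), each = bin_size)
  for (i in seq_len(nrow(points))) {
    rle <- covs[[points$chrom[i]]]
    win <- as.numeric(S4Vectors::window(rle, start = mid[i] - halfwidth + 1L,
                                        end = mid[i] + halfwidth))
    v <- as.numeric(rowsum(win, bin_idx)) / bin_size
    if (identical(points$strand[i], "-")) v <- rev(v)
    mat[i, ] <- v
  }
  colnames(mat) <- seq(-halfwidth, halfwidth - bin_size, by = bin_size)
  rownames(mat) <- if ("name" %in% names(points)) points$name else NULL
  structure(list(matrix = mat, points = points, halfwidth = halfwidth,
                 bin_size = bin_size, normalization = normalization,
                 n_dropped = n_dropped),
            class = "itr_profile")
}

#' @export
print.itr_profile <- function(x, ...) {
  cat(sprintf("<itr_profile> %d points x %d bins (halfwidth %d bp, bin %d bp, %s)\n",
              nrow(x$matrix), ncol(x$matrix), x$halfwidth, x$bin_size,
              x$normalization))
  invisible(x)
}

#' Subtract an input profile from an IP profile
#'
#' Cell-wise difference of two profile matrices with identical geometry
#' and normalization; results may be negative.
#'
#' @param ip,input `itr_profile` objects.
#' @return An `itr_profile` of differences.
#' @export
subtract_input <- function(ip, input) {
  stopifnot(inherits(ip, "itr_profile"), inherits(input, "itr_profile"))
  if (!identical(dim(ip$matrix), dim(input$matrix)) ||
      ip$halfwidth != input$halfwidth || ip$bin_size != input$bin_size ||
      !identical(ip$normalization, input$normalization))
    stop("profile geometry or normalization mismatch")
  out <- ip
  out$matrix <- ip$matrix - input$matrix
  out
}

#' Mean (or median) metaprofile across reference points
#' @param x An `itr_profile`.
#' @param fun `"mean"` (default, matching the conventional tooling) or
#'   `"median"`.
#' @return Tibble `offset, coverage` with one row per bin.
#' @export
profile_summary <- function(x, fun = c("mean", "median")) {
  fun <- match.arg(fun)
  f <- if (fun == "mean") colMeans else function(m) apply(m, 2, stats::median)
  tibble::tibble(offset = as.integer(colnames(x$matrix)),
                 coverage = as.numeric(f(x$matrix)))
}

#' @describeIn profile_matrix Tidy a profile into a long tibble
#'   (`point, offset, coverage`).
#' @param x An `itr_profile`.
#' @param ... Unused.
#' @export
tidy.itr_profile <- function(x, ...) {
  nm <- rownames(x$matrix)
  if (is.null(nm)) nm <- as.character(seq_len(nrow(x$matrix)))
  tibble::tibble(
    point = rep(nm, times = ncol(x$matrix)),
    offset = rep(as.integer(colnames(x$matrix)), each = nrow(x$matrix)),
    coverage = as.vector(x$matrix)
  )
}

#' @describeIn profile_matrix One-row profile summary.
#' @export
glance.itr_profile <- function(x, ...) {
  s <- profile_summary(x)
  tibble::tibble(n_points = nrow(x$matrix), n_bins = ncol(x$matrix),
                 halfwidth = x$halfwidth, bin_size = x$bin_size,
                 normalization = x$normalization,
                 n_dropped = x$n_dropped,
                 center_coverage = s$coverage[which.min(abs(s$offset))],
                 mean_coverage = mean(s$coverage))
}

#' @describeIn profile_matrix Plot the mean metaprofile.
#' @param object An `itr_profile`.
#' @export
autoplot.itr_profile <- function(object, ...) {
  s <- profile_summary(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$offset, y = .data$coverage)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "distance from reference point (bp)",
                  y = paste0("coverage (", object$normalization, ")")) +
    ggplot2::theme_minimal()
}
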