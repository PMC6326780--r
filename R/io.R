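#' Read a FASTA file
#' @param path Path to a (possibly wrapped, multi-record) FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write sequences to FASTA
#' @param x Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a BED file into an interval tibble
#'
#' BED3-BED6 supported; coordinates kept 0-based half-open. Extra key=value
#' tags encoded in the name field (e.g. `solo_itr|id=0.82`) are preserved
#' verbatim.
#'
#' @param path BED file path.
#' @return Interval tibble with `chrom, start, end, strand, name, score`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED file ", path, ": ",
                                          conditionMessage(e)))
  granges_to_tibble(gr)
}

granges_to_tibble <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = {
      s <- as.character(GenomicRanges::strand(gr))
      ifelse(s == "*", ".", s)
    },
    name = if ("name" %in% names(mc) && !all(is.na(mc$name)))
      as.character(mc$name) else ".",
    score = if ("score" %in% names(mc)) as.numeric(mc$score) else 0
  ) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end, .data$name)
}

#' Write an interval tibble to BED6
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  out <- tibble::tibble(
    chrom = x$chrom, start = x$start, end = x$end,
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0,
    strand = if ("strand" %in% names(x)) ifelse(x$strand == ".", ".", x$strand) else "."
  ) |> dplyr::arrange(.data$chrom, .data$start, .data$end, .data$name)
  readr::write_tsv(out, path, col_names = FALSE, escape = "none")
  invisible(path)
}

#' Read a bedGraph coverage track
#' @param path bedGraph file path.
#' @return Tibble `chrom, start, end, value` (0-based half-open).
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) stop("malformed bedGraph file ", path,
                                          ": ", conditionMessage(e)))
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = as.numeric(S4Vectors::mcols(gr)$score)
  ) |> dplyr::arrange(.data$chrom, .data$start)
}

#' Write a bedGraph coverage track
#' @param x Tibble `chrom, start, end, value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(x)))
  out <- dplyr::arrange(x[c("chrom", "start", "end", "value")],
                        .data$chrom, .data$start)
  readr::write_tsv(out, path, col_names = FALSE, escape = "none")
  invisible(path)
}

check_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 1L)
  bad <- body[nf != 9L]
  if (length(bad))
    stop("malformed GFF3 line ", bad[1], " in ", path,
         " (expected 9 tab-separated fields, got ", nf[which(body == bad[1])], ")")
  invisible(TRUE)
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 1-based closed coordinates are converted to the package's 0-based
#' half-open convention at the boundary. Gene features must carry a
#' `gene_id` (or `ID`) attribute and exons a `gene_id` (or `Parent`)
#' pointing at their gene. For BED12, blocks become exons.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED12 (`.bed`) file.
#' @param biotype_filter Optional biotype to keep (e.g. `"protein_coding"`).
#' @return Gene-model tibble (see [gene_models()]).
#' @export
read_annotation <- function(path, biotype_filter = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  out <- if (ext %in% c("gff", "gff3", "gtf")) {
    check_gff3_lines(path)
    read_gff3_genes(path)
  } else if (ext == "bed") {
    read_bed12_genes(path)
  } else stop("unsupported annotation format: .", ext)
  if (!is.null(biotype_filter))
    out <- dplyr::filter(out, .data$biotype %in% biotype_filter)
  out
}

read_gff3_genes <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3 file ", path, ": ",
                                          conditionMessage(e)))
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  gid <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id)
         else rep(NA_character_, length(gr))
  id <- if ("ID" %in% names(mc)) as.character(mc$ID) else gid
  parent <- if ("Parent" %in% names(mc))
    vapply(mc$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_, "")
  else rep(NA_character_, length(gr))
  is_gene <- type == "gene"
  gene_ids <- ifelse(is.na(gid[is_gene]), id[is_gene], gid[is_gene])
  genes <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene] - 1L,
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    gene_id = gene_ids,
    biotype = if ("biotype" %in% names(mc))
      as.character(mc$biotype)[is_gene] else "protein_coding"
  )
  genes$biotype[is.na(genes$biotype)] <- "protein_coding"
  is_exon <- type == "exon"
  ex_gene <- ifelse(is.na(gid[is_exon]), parent[is_exon], gid[is_exon])
  exons <- tibble::tibble(
    gene_id = ex_gene,
    start = GenomicRanges::start(gr)[is_exon] - 1L,
    end = GenomicRanges::end(gr)[is_exon]
  )
  if (nrow(exons) == 0) exons <- NULL
  gene_models(genes, exons)
}

read_bed12_genes <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED file ", path, ": ",
                                          conditionMessage(e)))
  mc <- S4Vectors::mcols(gr)
  if (!"blocks" %in% names(mc))
    stop("BED12 with block structure required for gene models: ", path)
  genes <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = {
      s <- as.character(GenomicRanges::strand(gr))
      ifelse(s == "*", "+", s)
    },
    gene_id = as.character(mc$name),
    biotype = "protein_coding"
  )
  blocks <- mc$blocks  # IRangesList, block coords relative to gene start (1-based)
  exons <- purrr::map2_dfr(seq_along(gr), genes$gene_id, function(i, g) {
    b <- blocks[[i]]
    tibble::tibble(
      gene_id = g,
      start = genes$start[i] + IRanges::start(b) - 1L,
      end = genes$start[i] + IRanges::end(b)
    )
  })
  gene_models(genes, exons)
}

#' Write gene models as GFF3
#' @param genes Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  esc <- function(x) gsub("[;=\t]", "_", x)
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, sprintf(
      "%s\titrtools\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s;biotype=%s",
      g$chrom, g$start + 1L, g$end, g$strand,
      esc(g$gene_id), esc(g$gene_id), g$biotype))
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, sprintf(
        "%s\titrtools\texon\t%d\t%d\t.\t%s\t.\tParent=%s;gene_id=%s",
        g$chrom, ex$start[j] + 1L, ex$end[j], g$strand,
        esc(g$gene_id), esc(g$gene_id)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Expects tab-separated columns `gene_id, baseMean, log2FoldChange, padj`
#' (the layout emitted by standard DE callers). Non-numeric values in
#' numeric columns raise an error naming the offending row.
#'
#' @param path TSV path.
#' @return Tibble `gene_id, mean_expr, log2fc, padj`.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  need <- c("gene_id", "baseMean", "log2FoldChange", "padj")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("DE table ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  num <- function(col) {
    v <- x[[col]]
    v[v %in% c("NA", "")] <- NA
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v))
    if (length(bad))
      stop("non-numeric value in column ", col, " at data row ", bad[1],
           " of ", path)
    out
  }
  tibble::tibble(gene_id = x$gene_id, mean_expr = num("baseMean"),
                 log2fc = num("log2FoldChange"), padj = num("padj"))
}

#' Write a differential-expression table
#' @param de Tibble with `gene_id, mean_expr, log2fc, padj`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  out <- tibble::tibble(gene_id = de$gene_id, baseMean = de$mean_expr,
                        log2FoldChange = de$log2fc, padj = de$padj)
  readr::write_tsv(out, path, escape = "none")
  invisible(path)
}

#' Read gene-level fragment counts
#' @param path TSV with columns `gene_id, fragments`.
#' @return Tibble `gene_id, fragments`.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_id", "fragments") %in% names(x)))
    stop("counts table ", path, " needs columns gene_id, fragments")
  tibble::tibble(gene_id = as.character(x$gene_id),
                 fragments = as.numeric(x$fragments))
}
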