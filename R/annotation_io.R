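# Gene-annotation input: GTF -> gene models with union exon structure.
#
# A "gene model" collapses all transcripts of a gene into one record carrying
# the gene span, its biotype, and the union of all exon intervals. Exon count
# is the number of union intervals (transcript-independent), and genomic
# length is the gene-feature span end - start + 1; their quotient is the
# length/exon ratio index used by the enrichment test.

GTF_COLS <- c("seqname", "source", "feature", "start", "end",
              "score", "strand", "frame", "attribute")

gtf_attr <- function(attr, key) {
  has <- grepl(paste0(key, '\\s+"'), attr)
  out <- rep(NA_character_, length(attr))
  out[has] <- sub(paste0('^.*', key, '\\s+"([^"]*)".*$'), "\\1", attr[has])
  out
}

new_gene_models <- function(df) {
  stopifnot(is.data.frame(df))
  class(df) <- c("gene_models", "data.frame")
  validate_gene_models(df)
  df
}

validate_gene_models <- function(genes) {
  if (nrow(genes) == 0L) return(invisible(genes))
  assert_that(!anyDuplicated(genes$gene_id), "duplicate gene_id in gene models")
  assert_that(all(genes$start <= genes$end), "gene with start > end")
  assert_that(all(genes$exon_count >= 1L), "gene with exon_count < 1")
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    assert_that(nrow(ex) == genes$exon_count[i], "exon_count out of sync")
    assert_that(all(ex[, 1] >= genes$start[i]) && all(ex[, 2] <= genes$end[i]),
                "exon outside gene span for ", genes$gene_id[i])
    if (nrow(ex) > 1L) {
      assert_that(all(ex[-1, 1] > ex[-nrow(ex), 2] + 1L),
                  "exons not disjoint/non-adjacent for ", genes$gene_id[i])
    }
  }
  assert_that(all(genes$genomic_length ==
                    genes$end - genes$start + 1L), "genomic_length out of sync")
  invisible(genes)
}

#' Parse a GTF file into gene models
#'
#' Reads a 9-column GTF (1-based inclusive coordinates, Ensembl-style
#' attributes; gzip-transparent). One model is produced per distinct
#' `gene_id`: exons of all transcripts are merged into union intervals;
#' a gene with no exon features gets a single exon spanning the gene.
#' Records on unplaced contigs are retained with their literal chromosome
#' string. `gene_biotype` (or `gene_type`) defaults to `"unknown"` when
#' absent; `gene_name` defaults to the `gene_id`.
#'
#' @param path path to a GTF file (optionally gzipped)
#' @return a `gene_models` data frame with columns `gene_id`, `gene_name`,
#'   `chrom`, `strand`, `start`, `end`, `biotype`, `exon_count`,
#'   `genomic_length`, `ratio` and a list column `exons` of two-column
#'   integer matrices (union exon intervals)
#' @export
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste(c("chr1", "src", "gene", "100", "300", ".", "+", ".",
#'   'gene_id "g1"; gene_biotype "protein_coding";'), collapse = "\t"), gtf)
#' parse_gtf(gtf)
parse_gtf <- function(path) {
  assert_that(file.exists(path), "GTF file not found: ", path)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_gene_models())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- lineno[which(nf != 9L)[1]]
    stop_ck("malformed GTF line ", bad, ": expected 9 tab-separated columns",
            class = "circkit_parse_error")
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE,
              dimnames = list(NULL, GTF_COLS))
  feature <- m[, "feature"]
  use <- feature %in% c("gene", "exon", "transcript")
  if (!any(use)) return(empty_gene_models())
  m <- m[use, , drop = FALSE]
  lineno <- lineno[use]

  attr_str <- m[, "attribute"]
  gene_id <- sub('^.*gene_id\\s+"([^"]*)".*$', "\\1", attr_str)
  no_gid <- !grepl('gene_id\\s+"', attr_str)
  if (any(no_gid)) {
    stop_ck("GTF line ", lineno[which(no_gid)[1]], ": missing gene_id attribute",
            class = "circkit_parse_error")
  }
  start <- suppressWarnings(as.integer(m[, "start"]))
  end <- suppressWarnings(as.integer(m[, "end"]))
  if (anyNA(start) || anyNA(end)) {
    bad <- lineno[which(is.na(start) | is.na(end))[1]]
    stop_ck("malformed GTF line ", bad, ": non-integer coordinates",
            class = "circkit_parse_error")
  }

  dt <- data.table::data.table(
    gene_id = gene_id, feature = m[, "feature"], chrom = m[, "seqname"],
    start = start, end = end, strand = m[, "strand"], attr = attr_str)

  ids <- unique(dt$gene_id)
  row_groups <- split(seq_len(nrow(dt)), factor(dt$gene_id, levels = ids))
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    g <- dt[row_groups[[i]], ]
    grow <- g[g$feature == "gene", ]
    base <- if (nrow(grow) > 0L) grow[1, ] else g[1, ]
    ex_rows <- g[g$feature == "exon", ]
    exons <- if (nrow(ex_rows) > 0L) {
      merge_intervals(cbind(ex_rows$start, ex_rows$end))
    } else NULL
    gstart <- if (nrow(grow) > 0L) grow$start[1] else min(g$start)
    gend <- if (nrow(grow) > 0L) grow$end[1] else max(g$end)
    if (!is.null(exons) && nrow(exons) > 0L) {
      gstart <- min(gstart, exons[1, 1])
      gend <- max(gend, exons[nrow(exons), 2])
    } else {
      exons <- cbind(start = gstart, end = gend)
    }
    biotype <- gtf_attr(base$attr, "gene_biotype")
    if (is.na(biotype)) biotype <- gtf_attr(base$attr, "gene_type")
    gname <- gtf_attr(base$attr, "gene_name")
    out[[i]] <- list(gene_id = ids[i],
                     gene_name = if (is.na(gname)) ids[i] else gname,
                     chrom = base$chrom, strand = base$strand,
                     start = gstart, end = gend,
                     biotype = if (is.na(biotype)) "unknown" else biotype,
                     exons = exons)
  }
  df <- data.frame(
    gene_id = vapply(out, `[[`, "", "gene_id"),
    gene_name = vapply(out, `[[`, "", "gene_name"),
    chrom = vapply(out, `[[`, "", "chrom"),
    strand = vapply(out, `[[`, "", "strand"),
    start = vapply(out, `[[`, 1L, "start"),
    end = vapply(out, `[[`, 1L, "end"),
    biotype = vapply(out, `[[`, "", "biotype"),
    stringsAsFactors = FALSE)
  df$exons <- lapply(out, `[[`, "exons")
  df$exon_count <- vapply(df$exons, nrow, 1L)
  df$genomic_length <- df$end - df$start + 1L
  df$ratio <- df$genomic_length / df$exon_count
  new_gene_models(df)
}

empty_gene_models <- function() {
  df <- data.frame(gene_id = character(0), gene_name = character(0),
                   chrom = character(0), strand = character(0),
                   start = integer(0), end = integer(0),
                   biotype = character(0), stringsAsFactors = FALSE)
  df$exons <- list()
  df$exon_count <- integer(0)
  df$genomic_length <- integer(0)
  df$ratio <- numeric(0)
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Genomic-length to exon-count ratio of host genes
#'
#' The ratio index: gene-feature genomic length (end - start + 1) divided by
#' the number of union exon intervals, in nucleotides per exon. A low ratio
#' (below the genome-wide average) marks genes proposed to have the greatest
#' potential for circRNA overexpression.
#'
#' @param genes a `gene_models` data frame (any number of rows)
#' @return numeric vector of ratios, one per gene
#' @export
length_exon_ratio <- function(genes) {
  assert_that(all(genes$exon_count >= 1L), "exon_count must be >= 1")
  genes$genomic_length / genes$exon_count
}

#' Write gene models back to GTF
#'
#' Emits one `gene` feature and, under a single synthetic transcript
#' (`<gene_id>.t1`), one `exon` feature per union exon interval. Re-parsing
#' the output reproduces the models exactly (round-trip property).
#'
#' @param genes a `gene_models` data frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gtf <- function(genes, path) {
  lines <- character(0)
  fmt <- function(chrom, feat, s, e, strand, attrs) {
    paste(chrom, "circkit", feat, s, e, ".", strand, ".", attrs, sep = "\t")
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                     g$gene_id, g$gene_name, g$biotype)
    lines <- c(lines, fmt(g$chrom, "gene", g$start, g$end, g$strand, attrs))
    ex <- genes$exons[[i]]
    tattrs <- sprintf('%s transcript_id "%s.t1";', attrs, g$gene_id)
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, fmt(g$chrom, "exon", ex[j, 1], ex[j, 2], g$strand, tattrs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export a per-gene inspection table
#'
#' @param genes a `gene_models` data frame
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
export_gene_table <- function(genes, path) {
  tab <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = genes$start, end = genes$end,
                    strand = genes$strand, biotype = genes$biotype,
                    genomic_length = genes$genomic_length,
                    exon_count = genes$exon_count,
                    ratio = genes$ratio)
  write_tsv(tab, path)
}
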