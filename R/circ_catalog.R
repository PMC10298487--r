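# Back-splice-junction catalog: loading, host-gene assignment, spliced
# length, known/novel classification, and Table-1-style summaries.

new_circ_catalog <- function(df) {
  assert_that(all(df$start <= df$end), "junction with start > end",
              class = "circkit_validation_error")
  assert_that(all(df$read_count >= 0), "negative read count",
              class = "circkit_validation_error")
  class(df) <- c("circ_catalog", "data.frame")
  df
}

empty_circ_catalog <- function() {
  new_circ_catalog(data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), read_count = integer(0), circ_id = character(0),
    stringsAsFactors = FALSE))
}

#' Load back-splice-junction calls into a circRNA catalog
#'
#' Supported dialects:
#' \describe{
#'   \item{`tsv`}{header `chrom`, `start`, `end`, `strand`, `count`
#'     (or `read_count`); coordinates already 1-based inclusive.}
#'   \item{`bed`}{headerless BED6; 0-based half-open coordinates are converted
#'     to 1-based inclusive; the score column (5) carries the read count.}
#'   \item{`dcc`}{a DCC `CircCoordinates` file plus a `CircRNACount` file
#'     (`counts_path`); rows are matched on chromosome/start/end and the read
#'     count is summed over the sample columns. Starts are taken as 0-based
#'     and converted on load.}
#' }
#' Duplicate junctions (same chromosome, start, end, strand) are collapsed by
#' summing read counts; the catalog is sorted by (chrom, start, end).
#'
#' @param path input file path
#' @param dialect one of `"tsv"`, `"bed"`, `"dcc"`
#' @param counts_path DCC `CircRNACount` path (required for `dialect = "dcc"`)
#' @return a `circ_catalog` data frame with columns `chrom`, `start`, `end`,
#'   `strand`, `read_count`, `circ_id`
#' @export
load_circ_calls <- function(path, dialect = c("tsv", "bed", "dcc"),
                            counts_path = NULL) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), "circRNA call file not found: ", path)
  if (file.size(path) == 0L) return(empty_circ_catalog())

  if (dialect == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = 1))
    if (nrow(dt) == 0L) return(empty_circ_catalog())
    if (!"count" %in% names(dt) && "read_count" %in% names(dt)) {
      data.table::setnames(dt, "read_count", "count")
    }
    need <- c("chrom", "start", "end", "strand", "count")
    assert_that(all(need %in% names(dt)),
                "tsv dialect requires columns: ", paste(need, collapse = ", "),
                class = "circkit_parse_error")
    raw <- data.frame(chrom = as.character(dt$chrom),
                      start = as.integer(dt$start), end = as.integer(dt$end),
                      strand = as.character(dt$strand),
                      read_count = as.numeric(dt$count),
                      stringsAsFactors = FALSE)
  } else if (dialect == "bed") {
    dt <- data.table::fread(path, sep = "\t", header = FALSE)
    if (nrow(dt) == 0L) return(empty_circ_catalog())
    assert_that(ncol(dt) >= 6L, "BED dialect requires at least 6 columns",
                class = "circkit_parse_error")
    raw <- data.frame(chrom = as.character(dt[[1]]),
                      start = as.integer(dt[[2]]) + 1L,
                      end = as.integer(dt[[3]]),
                      strand = as.character(dt[[6]]),
                      read_count = as.numeric(dt[[5]]),
                      stringsAsFactors = FALSE)
  } else {
    assert_that(!is.null(counts_path),
                "dcc dialect requires counts_path (CircRNACount file)")
    coords <- data.table::fread(path, sep = "\t", header = TRUE)
    counts <- data.table::fread(counts_path, sep = "\t", header = TRUE)
    if (nrow(coords) == 0L) return(empty_circ_catalog())
    key_co <- paste(coords[[1]], coords[[2]], coords[[3]])
    key_ct <- paste(counts[[1]], counts[[2]], counts[[3]])
    sample_cols <- setdiff(seq_len(ncol(counts)), 1:3)
    total <- if (length(sample_cols) > 0) {
      rowSums(as.data.frame(counts)[, sample_cols, drop = FALSE])
    } else rep(0, nrow(counts))
    idx <- match(key_co, key_ct)
    assert_that(!anyNA(idx), "CircCoordinates row without CircRNACount match",
                class = "circkit_parse_error")
    strand_col <- if ("Strand" %in% names(coords)) coords$Strand else
      rep(".", nrow(coords))
    raw <- data.frame(chrom = as.character(coords[[1]]),
                      start = as.integer(coords[[2]]) + 1L,
                      end = as.integer(coords[[3]]),
                      strand = as.character(strand_col),
                      read_count = total[idx],
                      stringsAsFactors = FALSE)
  }

  assert_that(all(raw$read_count >= 0), "negative read count in ", path,
              class = "circkit_validation_error")
  assert_that(all(raw$start <= raw$end),
              "junction with start > end after coordinate conversion in ", path,
              class = "circkit_validation_error")
  dt <- data.table::as.data.table(raw)
  collapsed <- dt[, list(read_count = sum(read_count)),
                  by = c("chrom", "start", "end", "strand")]
  data.table::setorderv(collapsed, c("chrom", "start", "end"))
  df <- as.data.frame(collapsed)
  df$circ_id <- make_circ_id(df$chrom, df$start, df$end)
  new_circ_catalog(df)
}

#' Load a known-circRNA database from BED
#'
#' BED 0-based half-open coordinates are converted to 1-based inclusive. The
#' name column carries the database identifier (e.g. `hsa_circ_0000284`).
#'
#' @param path BED file path
#' @return data frame with columns `chrom`, `start`, `end`, `strand`, `db_id`
#' @export
load_known_db <- function(path) {
  assert_that(file.exists(path), "known-circRNA BED not found: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      db_id = character(0), stringsAsFactors = FALSE))
  }
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  assert_that(ncol(dt) >= 4L, "known-circRNA BED needs at least 4 columns",
              class = "circkit_parse_error")
  data.frame(chrom = as.character(dt[[1]]),
             start = as.integer(dt[[2]]) + 1L,
             end = as.integer(dt[[3]]),
             strand = if (ncol(dt) >= 6L) as.character(dt[[6]]) else ".",
             db_id = as.character(dt[[4]]),
             stringsAsFactors = FALSE)
}

strand_compatible <- function(a, b) {
  a %in% c(".", "*") | b %in% c(".", "*") | a == b
}

#' Assign each junction to a host gene
#'
#' A gene hosts a junction when its span fully contains the junction interval
#' on the same chromosome, with matching strand when the record strand is `+`
#' or `-` (a `.` record strand matches either). Ties between candidate genes
#' are broken by (1) larger reciprocal overlap of the gene's union exons with
#' the junction interval, (2) smaller genomic length, (3) lexicographically
#' smaller gene id, making the assignment deterministic. Junctions contained
#' in no gene remain intergenic (`NA` host).
#'
#' @param catalog a `circ_catalog`
#' @param genes a `gene_models` data frame
#' @return the catalog with columns `host_gene_id` and `host_biotype` added
#' @export
assign_host_genes <- function(catalog, genes) {
  catalog$host_gene_id <- rep(NA_character_, nrow(catalog))
  catalog$host_biotype <- rep(NA_character_, nrow(catalog))
  if (nrow(catalog) == 0L || nrow(genes) == 0L) return(new_circ_catalog(catalog))

  levs <- union(unique(catalog$chrom), unique(genes$chrom))
  qry <- GenomicRanges::GRanges(
    seqnames = factor(catalog$chrom, levels = levs),
    ranges = IRanges::IRanges(catalog$start, catalog$end),
    strand = ifelse(catalog$strand == ".", "*", catalog$strand))
  sbj <- GenomicRanges::GRanges(
    seqnames = factor(genes$chrom, levels = levs),
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = ifelse(genes$strand %in% c("+", "-"), genes$strand, "*"))
  fo <- GenomicRanges::findOverlaps(qry, sbj, type = "within")
  if (length(fo) == 0L) return(new_circ_catalog(catalog))

  q <- S4Vectors::queryHits(fo)
  s <- S4Vectors::subjectHits(fo)
  for (qi in unique(q)) {
    cand <- s[q == qi]
    if (length(cand) > 1L) {
      circ_len <- catalog$end[qi] - catalog$start[qi] + 1L
      recip <- vapply(cand, function(gi) {
        ex <- genes$exons[[gi]]
        ov <- interval_intersection_length(ex, catalog$start[qi], catalog$end[qi])
        ex_total <- sum(ex[, 2] - ex[, 1] + 1L)
        min(ov / circ_len, ov / ex_total)
      }, numeric(1))
      ord <- order(-recip, genes$genomic_length[cand], genes$gene_id[cand])
      cand <- cand[ord]
    }
    catalog$host_gene_id[qi] <- genes$gene_id[cand[1]]
    catalog$host_biotype[qi] <- genes$biotype[cand[1]]
  }
  new_circ_catalog(catalog)
}

#' Spliced length of each catalog record
#'
#' For a hosted junction, the spliced length is the summed intersection of the
#' host gene's union exon intervals with the junction interval (1-based
#' inclusive). A fully intronic junction (zero exon overlap) and an intergenic
#' junction fall back to the genomic span `end - start + 1`.
#'
#' @param catalog a `circ_catalog` with host assignment done
#' @param genes the `gene_models` used for assignment
#' @return the catalog with a `spliced_length` column added
#' @export
compute_spliced_lengths <- function(catalog, genes) {
  span <- catalog$end - catalog$start + 1L
  sl <- span
  if (nrow(catalog) > 0L) {
    gi <- match(catalog$host_gene_id, genes$gene_id)
    for (i in which(!is.na(gi))) {
      ov <- interval_intersection_length(genes$exons[[gi[i]]],
                                         catalog$start[i], catalog$end[i])
      if (ov > 0L) sl[i] <- ov
    }
  }
  catalog$spliced_length <- as.integer(sl)
  new_circ_catalog(catalog)
}

#' Match catalog records against a known-circRNA database
#'
#' A database entry matches a record when it lies on the same chromosome, both
#' coordinates agree within `tolerance` nucleotides, and the strands are
#' compatible (`.`/`*` match anything). Records with no match are novel.
#'
#' @param catalog a `circ_catalog`
#' @param db database as returned by [load_known_db()]
#' @param tolerance maximum coordinate slack, in nucleotides (default 0)
#' @return the catalog with list column `known_ids` and logical `novel` added
#' @export
match_known <- function(catalog, db, tolerance = 0L) {
  assert_that(tolerance >= 0L, "tolerance must be >= 0")
  ids <- vector("list", nrow(catalog))
  db_by_chrom <- split(seq_len(nrow(db)), db$chrom)
  for (i in seq_len(nrow(catalog))) {
    cand <- db_by_chrom[[catalog$chrom[i]]]
    if (is.null(cand)) { ids[[i]] <- character(0); next }
    hit <- cand[abs(db$start[cand] - catalog$start[i]) <= tolerance &
                  abs(db$end[cand] - catalog$end[i]) <= tolerance &
                  strand_compatible(catalog$strand[i], db$strand[cand])]
    ids[[i]] <- db$db_id[hit]
  }
  catalog$known_ids <- ids
  catalog$novel <- lengths(ids) == 0L
  new_circ_catalog(catalog)
}

#' Run the full catalog annotation (host, spliced length, known/novel)
#'
#' @param catalog a `circ_catalog` from [load_circ_calls()]
#' @param genes a `gene_models` data frame
#' @param db optional known-circRNA database from [load_known_db()]
#' @param tolerance coordinate tolerance for database matching
#' @return the annotated catalog
#' @export
annotate_catalog <- function(catalog, genes, db = NULL, tolerance = 0L) {
  catalog <- assign_host_genes(catalog, genes)
  catalog <- compute_spliced_lengths(catalog, genes)
  if (!is.null(db)) catalog <- match_known(catalog, db, tolerance)
  catalog
}

#' Summarize a catalog (baseline characteristics)
#'
#' Computes the baseline-characteristics counts: total records, previously
#' annotated records, records hosted by protein-coding genes, records above a
#' read threshold (strict `>`), and records more abundant than the linear
#' transcript of the same host gene (classified by
#' [classify_circ_vs_linear()] with the given fold window).
#'
#' @param catalog an annotated `circ_catalog`
#' @param linear named numeric vector of per-gene linear abundance, or `NULL`
#'   to skip the circular-versus-linear count
#' @param read_threshold read-count threshold (default 50)
#' @param fold_window fold window passed to the classifier (default 2)
#' @return a `catalog_summary` list
#' @export
summarize_catalog <- function(catalog, linear = NULL, read_threshold = 50L,
                              fold_window = 2) {
  n_total <- nrow(catalog)
  n_known <- if ("known_ids" %in% names(catalog)) {
    sum(lengths(catalog$known_ids) > 0L)
  } else 0L
  n_pc <- if ("host_biotype" %in% names(catalog)) {
    sum(!is.na(catalog$host_biotype) & catalog$host_biotype == "protein_coding")
  } else 0L
  n_thr <- sum(catalog$read_count > read_threshold)
  n_higher <- 0L
  if (!is.null(linear) && n_total > 0L) {
    has <- !is.na(catalog$host_gene_id) & catalog$host_gene_id %in% names(linear)
    if (any(has)) {
      cls <- classify_circ_vs_linear(catalog$read_count[has],
                                     linear[catalog$host_gene_id[has]],
                                     fold_window)
      n_higher <- sum(cls == "higher")
    }
  }
  structure(list(n_total = n_total, n_known = n_known,
                 n_in_protein_coding = n_pc,
                 n_over_read_threshold = n_thr,
                 read_threshold = as.integer(read_threshold),
                 n_more_abundant_than_linear = n_higher),
            class = "catalog_summary")
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("circRNA catalog summary\n")
  cat("  total unique circRNAs:            ", x$n_total, "\n")
  cat("  previously annotated:             ", x$n_known, "\n")
  cat("  within protein-coding genes:      ", x$n_in_protein_coding, "\n")
  cat(sprintf("  with more than %d reads:           %d\n",
              x$read_threshold, x$n_over_read_threshold))
  cat("  more abundant than linear mRNA:   ", x$n_more_abundant_than_linear, "\n")
  invisible(x)
}

#' Write an annotated catalog to TSV
#'
#' `known_ids` are semicolon-joined; the `novel` flag is emitted as
#' TRUE/FALSE.
#'
#' @param catalog an annotated `circ_catalog`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_catalog <- function(catalog, path) {
  out <- data.frame(
    circ_id = catalog$circ_id, chrom = catalog$chrom,
    start = catalog$start, end = catalog$end, strand = catalog$strand,
    read_count = catalog$read_count,
    host_gene_id = catalog$host_gene_id %||% NA_character_,
    host_biotype = catalog$host_biotype %||% NA_character_,
    spliced_length = catalog$spliced_length %||% NA_integer_,
    known_ids = if ("known_ids" %in% names(catalog)) {
      vapply(catalog$known_ids, paste, "", collapse = ";")
    } else "",
    novel = catalog$novel %||% NA,
    stringsAsFactors = FALSE)
  write_tsv(out, path)
}
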