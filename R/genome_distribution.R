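# Genome-distribution views of a catalog: per-chromosome gene/circRNA counts,
# per-gene multiplicity, and host-structure versus abundance correlations.

#' Per-chromosome gene and circRNA counts
#'
#' Counts genes passing the biotype filter (default protein-coding, matching
#' the usual framing of genome-distribution figures) and all catalog records
#' per chromosome. Chromosomes with zero in both columns are omitted.
#'
#' @param genes a `gene_models` data frame
#' @param catalog a `circ_catalog`
#' @param biotype_filter gene biotype to count, or `NULL` for all genes
#' @return a `chrom_table` data frame with columns `chromosome`, `n_genes`,
#'   `n_circ`
#' @export
per_chromosome_counts <- function(genes, catalog,
                                  biotype_filter = "protein_coding") {
  g <- genes
  if (!is.null(biotype_filter)) g <- g[g$biotype %in% biotype_filter, ]
  gene_tab <- table(g$chrom)
  circ_tab <- table(catalog$chrom)
  chroms <- sort(union(names(gene_tab)[gene_tab > 0],
                       names(circ_tab)[circ_tab > 0]))
  out <- data.frame(
    chromosome = chroms,
    n_genes = as.integer(ifelse(chroms %in% names(gene_tab),
                                gene_tab[chroms], 0L)),
    n_circ = as.integer(ifelse(chroms %in% names(circ_tab),
                               circ_tab[chroms], 0L)),
    stringsAsFactors = FALSE)
  class(out) <- c("chrom_table", "data.frame")
  out
}

#' Correlation between gene and circRNA counts across chromosomes
#'
#' Spearman correlation between `n_genes` and `n_circ` over the rows of a
#' [per_chromosome_counts()] table.
#'
#' @param table a `chrom_table`
#' @return list with `n`, `rho`, `p_value`, `method`
#' @export
chromosome_correlation <- function(table) {
  assert_that(nrow(table) >= 4L,
              "need at least 4 chromosomes for a correlation",
              class = "circkit_insufficient_data")
  spearman_test(table$n_genes, table$n_circ)
}

#' Per-gene circRNA multiplicity table
#'
#' Groups hosted records by host gene and tabulates how many genes produce
#' exactly k distinct circRNAs, together with the genes at the maximum k.
#'
#' @param catalog an annotated `circ_catalog`
#' @return list with `table` (data frame of `k`, `n_genes`), `max_k`, and
#'   `max_k_genes`
#' @export
multiplicity_table <- function(catalog) {
  hosted <- catalog[!is.na(catalog$host_gene_id), , drop = FALSE]
  if (nrow(hosted) == 0L) {
    return(list(table = data.frame(k = integer(0), n_genes = integer(0)),
                max_k = NA_integer_, max_k_genes = character(0)))
  }
  per_gene <- table(hosted$host_gene_id)
  dist <- table(as.integer(per_gene))
  tab <- data.frame(k = as.integer(names(dist)), n_genes = as.integer(dist))
  tab <- tab[order(tab$k), , drop = FALSE]
  rownames(tab) <- NULL
  max_k <- max(tab$k)
  list(table = tab, max_k = max_k,
       max_k_genes = sort(names(per_gene)[as.integer(per_gene) == max_k]))
}

#' Host-gene structure versus circRNA abundance
#'
#' Spearman correlations, over hosted records, of the host gene's union exon
#' count and genomic length against the circRNA read count. A null result
#' (small |rho|, large p) indicates abundance is not driven by host-gene
#' structure.
#'
#' @param catalog an annotated `circ_catalog`
#' @param genes the `gene_models` used for assignment
#' @return list with elements `exon_count` and `genomic_length`, each a
#'   [spearman_test()] result
#' @export
structure_abundance_correlation <- function(catalog, genes) {
  hosted <- catalog[!is.na(catalog$host_gene_id), , drop = FALSE]
  assert_that(nrow(hosted) >= 4L,
              "need at least 4 hosted records",
              class = "circkit_insufficient_data")
  gi <- match(hosted$host_gene_id, genes$gene_id)
  assert_that(!anyNA(gi), "hosted record with unknown gene id")
  list(exon_count = spearman_test(genes$exon_count[gi], hosted$read_count),
       genomic_length = spearman_test(genes$genomic_length[gi],
                                      hosted$read_count))
}

#' Spliced-length histogram of a catalog
#'
#' @param catalog a `circ_catalog` with `spliced_length` computed
#' @param binwidth histogram bin width in nucleotides
#' @return data frame with `bin_start`, `bin_end`, `n`
#' @export
spliced_length_histogram <- function(catalog, binwidth = 500L) {
  if (nrow(catalog) == 0L) {
    return(data.frame(bin_start = integer(0), bin_end = integer(0),
                      n = integer(0)))
  }
  bin <- (catalog$spliced_length - 1L) %/% binwidth
  tab <- table(bin)
  data.frame(bin_start = as.integer(names(tab)) * binwidth + 1L,
             bin_end = (as.integer(names(tab)) + 1L) * binwidth,
             n = as.integer(tab))
}
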