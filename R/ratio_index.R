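# The length/exon ratio index: classify host genes by genomic-length to
# exon-count ratio relative to the genome-wide average, and test whether
# upregulated circRNAs are overrepresented among low-ratio hosts with a
# 2x2 chi-squared test. Also: microRNA target-site overlap counts and
# recurrent responders across stimulation conditions.

#' Load a differential-expression result table for one condition
#'
#' Accepts deseq2-results-compatible headers: `circ_id` (or a first id
#' column), `log2FoldChange` (or `log2fc`), `pvalue`, `padj`.
#'
#' @param path TSV path
#' @param condition condition label (e.g. `"miR-191"`); defaults to the file
#'   name
#' @return a `de_table` data frame with columns `circ_id`, `log2fc`,
#'   `pvalue`, `padj` and attribute `condition`
#' @export
load_de_table <- function(path, condition = NULL) {
  assert_that(file.exists(path), "DE table not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  nm <- names(dt)
  if (!"circ_id" %in% nm) data.table::setnames(dt, nm[1], "circ_id")
  if ("log2FoldChange" %in% names(dt)) {
    data.table::setnames(dt, "log2FoldChange", "log2fc")
  }
  assert_that(all(c("circ_id", "log2fc", "pvalue", "padj") %in% names(dt)),
              "DE table needs columns circ_id, log2FoldChange, pvalue, padj",
              class = "circkit_parse_error")
  assert_that(!anyDuplicated(dt$circ_id), "duplicate circ_id in DE table",
              class = "circkit_validation_error")
  df <- as.data.frame(dt)[, c("circ_id", "log2fc", "pvalue", "padj")]
  attr(df, "condition") <- condition %||% sub("\\.[^.]*$", "", basename(path))
  class(df) <- c("de_table", "data.frame")
  df
}

#' Upregulated circRNAs of a DE table
#'
#' `padj < alpha` and `log2fc > lfc_min`; missing (NA/NaN) `padj` is treated
#' as non-significant.
#'
#' @param de a `de_table`
#' @param alpha adjusted-p significance level (default 0.05)
#' @param lfc_min minimum log2 fold change, exclusive (default 0)
#' @return character vector of circ ids
#' @export
flag_upregulated <- function(de, alpha = 0.05, lfc_min = 0) {
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  ok <- !is.na(de$padj) & de$padj < alpha & de$log2fc > lfc_min
  de$circ_id[ok]
}

#' Genome-wide average length/exon ratio
#'
#' Arithmetic mean of [length_exon_ratio()] over the scoped genes: either the
#' host genes of the catalog (default; each distinct host gene counted once)
#' or all annotated genes.
#'
#' @param genes a `gene_models` data frame
#' @param scope `"host_genes"` or `"all_genes"`
#' @param catalog required for `scope = "host_genes"`
#' @return the mean ratio, nucleotides per exon
#' @export
genomewide_average_ratio <- function(genes, scope = c("host_genes", "all_genes"),
                                     catalog = NULL) {
  scope <- match.arg(scope)
  if (scope == "host_genes") {
    assert_that(!is.null(catalog), "scope = 'host_genes' requires a catalog")
    ids <- unique(catalog$host_gene_id)
    ids <- ids[!is.na(ids)]
    g <- genes[genes$gene_id %in% ids, , drop = FALSE]
  } else {
    g <- genes
  }
  assert_that(nrow(g) > 0L, "no genes in scope for the average ratio",
              class = "circkit_insufficient_data")
  mean(length_exon_ratio(g))
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' Statistic `sum((O - E)^2 / E)` with expected counts from the margins;
#' 1 degree of freedom. With `continuity = TRUE` the Yates correction is
#' applied (`|O - E|` reduced by 0.5, floored at 0). Without continuity the
#' statistic equals the closed form
#' `(ad - bc)^2 * N / (r1 * r2 * c1 * c2)`.
#'
#' @param table 2x2 numeric matrix of non-negative counts with positive
#'   margins
#' @param continuity apply the Yates continuity correction (default `FALSE`)
#' @return list with `stat`, `p_value`, `df = 1`
#' @export
chi_squared_2x2 <- function(table, continuity = FALSE) {
  m <- as.matrix(table)
  assert_that(all(dim(m) == c(2L, 2L)), "table must be 2x2")
  assert_that(all(m >= 0), "negative cell count",
              class = "circkit_validation_error")
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0) || any(cs == 0)) {
    which_r <- which(rs == 0); which_c <- which(cs == 0)
    margin <- c(if (length(which_r)) paste0("row ", which_r),
                if (length(which_c)) paste0("column ", which_c))
    stop_ck("degenerate 2x2 table: empty margin (", paste(margin, collapse = ", "),
            ")", class = "circkit_degenerate_table")
  }
  e <- outer(rs, cs) / n
  dev <- abs(m - e)
  if (continuity) dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / e)
  list(stat = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Ratio-index enrichment test for one stimulation condition
#'
#' Cross-classifies each assessable circRNA (hosted, and present in the DE
#' table) by whether its host gene's length/exon ratio is below the
#' genome-wide average and whether the circRNA is upregulated
#' ([flag_upregulated()]), then tests the association with
#' [chi_squared_2x2()]. Also reports the mean host ratio of the upregulated
#' ("overexpressed") and non-upregulated ("stable") records. An optional
#' label-permutation p-value for the association is available for unbalanced
#' group sizes.
#'
#' @param catalog an annotated `circ_catalog`
#' @param genes the `gene_models` used for assignment
#' @param de a `de_table`
#' @param alpha,lfc_min passed to [flag_upregulated()]
#' @param continuity passed to [chi_squared_2x2()]
#' @param scope average-ratio scope, see [genomewide_average_ratio()]
#' @param n_perm number of label permutations for the optional permutation
#'   p-value (0 disables; uses the current RNG state)
#' @return an `enrichment_result` list: `condition`,
#'   `avg_ratio_overexpressed`, `avg_ratio_stable`, `contingency`
#'   (2x2 matrix, rows low/high ratio, columns upregulated/stable),
#'   `chi2_stat`, `p_value`, `genomewide_avg`, `n_assessable`, and
#'   `perm_p_value` when requested
#' @export
ratio_enrichment <- function(catalog, genes, de, alpha = 0.05, lfc_min = 0,
                             continuity = FALSE,
                             scope = c("host_genes", "all_genes"),
                             n_perm = 0L) {
  scope <- match.arg(scope)
  hosted <- !is.na(catalog$host_gene_id)
  assess <- hosted & catalog$circ_id %in% de$circ_id
  assert_that(any(assess), "no assessable circRNAs (hosted and present in DE)",
              class = "circkit_insufficient_data")
  sub <- catalog[assess, , drop = FALSE]
  gi <- match(sub$host_gene_id, genes$gene_id)
  ratio <- genes$ratio[gi]
  avg <- genomewide_average_ratio(genes, scope, catalog)
  low <- ratio < avg
  up <- sub$circ_id %in% flag_upregulated(de, alpha, lfc_min)

  cont <- matrix(c(sum(low & up), sum(low & !up),
                   sum(!low & up), sum(!low & !up)),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(ratio = c("low_ratio", "high_ratio"),
                                 status = c("upregulated", "stable")))
  chi <- chi_squared_2x2(cont, continuity = continuity)

  res <- list(
    condition = attr(de, "condition") %||% NA_character_,
    avg_ratio_overexpressed = if (any(up)) mean(ratio[up]) else NA_real_,
    avg_ratio_stable = if (any(!up)) mean(ratio[!up]) else NA_real_,
    contingency = cont,
    chi2_stat = chi$stat,
    p_value = chi$p_value,
    df = chi$df,
    genomewide_avg = avg,
    n_assessable = nrow(sub))
  if (n_perm > 0L) {
    obs <- chi$stat
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      up_b <- sample(up)
      cont_b <- matrix(c(sum(low & up_b), sum(low & !up_b),
                         sum(!low & up_b), sum(!low & !up_b)), 2, byrow = TRUE)
      stat_b <- tryCatch(chi_squared_2x2(cont_b, continuity)$stat,
                         circkit_degenerate_table = function(e) NA_real_)
      if (!is.na(stat_b) && stat_b >= obs - 1e-12) exceed <- exceed + 1L
    }
    res$perm_p_value <- (exceed + 1) / (n_perm + 1)
    res$n_perm <- as.integer(n_perm)
  }
  structure(res, class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("ratio-index enrichment (", x$condition, ")\n", sep = "")
  cat(sprintf("  genome-wide average ratio: %.2f nt/exon over %s\n",
              x$genomewide_avg, "host genes"))
  cat(sprintf("  mean ratio, overexpressed: %.2f; stable: %.2f\n",
              x$avg_ratio_overexpressed, x$avg_ratio_stable))
  print(x$contingency)
  cat(sprintf("  chi-squared = %.4f (df = 1), p = %.4g\n", x$chi2_stat, x$p_value))
  if (!is.null(x$perm_p_value)) {
    cat(sprintf("  permutation p = %.4g (%d permutations)\n",
                x$perm_p_value, x$n_perm))
  }
  invisible(x)
}

#' Overlap between a DE gene set and a microRNA target list
#'
#' @param de_gene_set character vector of differentially expressed genes
#'   (circRNA host genes or linear genes)
#' @param mir_targets character vector of microRNA target genes (same id
#'   namespace)
#' @return list with `n_de` and `n_with_site`
#' @export
target_site_overlap <- function(de_gene_set, mir_targets) {
  de_gene_set <- unique(de_gene_set)
  list(n_de = length(de_gene_set),
       n_with_site = length(intersect(de_gene_set, unique(mir_targets))))
}

#' Read a plain-text gene list (one id per line)
#'
#' @param path file path
#' @return character vector
#' @export
load_gene_list <- function(path) {
  assert_that(file.exists(path), "gene list not found: ", path)
  x <- readLines(path, warn = FALSE)
  x[nzchar(trimws(x))]
}

#' Host genes responding in every stimulation condition
#'
#' The intersection, over conditions, of the host genes of circRNAs with
#' `padj < alpha` in either direction.
#'
#' @param de_tables named list of `de_table` objects (at least 2 conditions)
#' @param catalog an annotated `circ_catalog` providing the circ-to-host map
#' @param alpha adjusted-p significance level
#' @return sorted character vector of host gene ids
#' @export
recurrent_responders <- function(de_tables, catalog, alpha = 0.05) {
  assert_that(length(de_tables) >= 2L, "need at least 2 conditions",
              class = "circkit_validation_error")
  host_of <- stats::setNames(catalog$host_gene_id, catalog$circ_id)
  sets <- lapply(de_tables, function(de) {
    sig <- de$circ_id[!is.na(de$padj) & de$padj < alpha]
    unique(host_of[sig[sig %in% names(host_of)]])
  })
  out <- Reduce(intersect, sets)
  sort(out[!is.na(out)])
}
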