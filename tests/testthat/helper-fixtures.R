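# Shared fixtures, built in code at test time.

gtf_line <- function(chrom, feature, start, end, strand, attrs) {
  paste(chrom, "test", feature, start, end, ".", strand, ".", attrs,
        sep = "\t")
}

gene_attrs <- function(id, name = id, biotype = "protein_coding",
                       transcript = NULL) {
  a <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
               id, name, biotype)
  if (!is.null(transcript)) a <- sprintf('%s transcript_id "%s";', a, transcript)
  a
}

write_gtf_text <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

# A two-gene annotation: CALM1-like gene on chr14 (+) containing the region
# 90404455-90404514, and a nested pair on chr2 for tie-break tests.
fixture_genes <- function() {
  parse_gtf(write_gtf_text(c(
    gtf_line("chr14", "gene", 90396502, 90408268, "+",
             gene_attrs("CALM1")),
    gtf_line("chr14", "exon", 90396502, 90396700, "+",
             gene_attrs("CALM1", transcript = "CALM1.t1")),
    gtf_line("chr14", "exon", 90404400, 90404600, "+",
             gene_attrs("CALM1", transcript = "CALM1.t1")),
    gtf_line("chr14", "exon", 90408000, 90408268, "+",
             gene_attrs("CALM1", transcript = "CALM1.t1")),
    gtf_line("chr2", "gene", 1000, 50000, "+", gene_attrs("OUTER")),
    gtf_line("chr2", "exon", 1000, 1200, "+",
             gene_attrs("OUTER", transcript = "OUTER.t1")),
    gtf_line("chr2", "exon", 49800, 50000, "+",
             gene_attrs("OUTER", transcript = "OUTER.t1")),
    gtf_line("chr2", "gene", 9000, 16000, "+",
             gene_attrs("INNER", biotype = "lncRNA")),
    gtf_line("chr2", "exon", 9000, 9400, "+",
             gene_attrs("INNER", transcript = "INNER.t1")),
    gtf_line("chr2", "exon", 15600, 16000, "+",
             gene_attrs("INNER", transcript = "INNER.t1")))))
}

# A catalog from explicit 1-based rows.
fixture_catalog <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tstrand\tcount",
               vapply(rows, function(r) paste(r, collapse = "\t"), "")),
             path)
  load_circ_calls(path, dialect = "tsv")
}

# Bundle cache: default-config bundles are reused across tests within a run.
.bundle_cache <- new.env(parent = emptyenv())

cached_bundle <- function(seed, ...) {
  key <- paste0("s", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.bundle_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("bundle_", key))
    .bundle_cache[[key]] <- generate_bundle(synth_config(seed = seed, ...), dir)
  }
  .bundle_cache[[key]]
}

# Characterized view of a bundle (parse + load + annotate), cached.
cached_pipeline <- function(seed, ...) {
  key <- paste0("p", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.bundle_cache[[key]])) {
    truth <- cached_bundle(seed, ...)
    genes <- parse_gtf(truth$paths$annotation)
    catalog <- load_circ_calls(truth$paths$circ_calls, "tsv")
    db <- load_known_db(truth$paths$known_db)
    catalog <- annotate_catalog(catalog, genes, db)
    linear <- load_linear_quant(truth$paths$linear_quant)
    .bundle_cache[[key]] <- list(truth = truth, genes = genes,
                                 catalog = catalog, linear = linear)
  }
  .bundle_cache[[key]]
}

# Independent permutation generator for oracle tests (distinct from the
# package's internal perm_matrix): Heap's algorithm, iterative.
oracle_permutations <- function(n) {
  out <- matrix(0L, factorial(n), n)
  a <- seq_len(n)
  c_ <- integer(n)
  out[1, ] <- a
  row <- 1L
  i <- 1L
  while (i <= n) {
    if (c_[i] < i - 1L) {
      if (i %% 2L == 1L) {
        tmp <- a[1L]; a[1L] <- a[i]; a[i] <- tmp
      } else {
        tmp <- a[c_[i] + 1L]; a[c_[i] + 1L] <- a[i]; a[i] <- tmp
      }
      row <- row + 1L
      out[row, ] <- a
      c_[i] <- c_[i] + 1L
      i <- 1L
    } else {
      c_[i] <- 0L
      i <- i + 1L
    }
  }
  out
}
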