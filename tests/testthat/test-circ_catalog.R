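test_that("load_circ_calls converts BED coordinates and reads TSV", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tc1\t7\t+", bed)
  cat_bed <- load_circ_calls(bed, dialect = "bed")
  expect_equal(cat_bed$start, 1000L)
  expect_equal(cat_bed$end, 2000L)
  expect_equal(cat_bed$read_count, 7)
  expect_equal(cat_bed$circ_id, "1:1000-2000")

  empty <- tempfile(); file.create(empty)
  expect_equal(nrow(load_circ_calls(empty, dialect = "tsv")), 0L)
})

test_that("duplicate junctions collapse by summing read counts", {
  cat1 <- fixture_catalog(list(
    c("chr14", 90404455, 90404514, "+", 3),
    c("chr14", 90404455, 90404514, "+", 4),
    c("chr1", 100, 200, "-", 5)))
  expect_equal(nrow(cat1), 2L)
  rec <- cat1[cat1$circ_id == "14:90404455-90404514", ]
  expect_equal(rec$read_count, 7)
  expect_equal(sum(cat1$read_count), 12)  # conservation under collapsing
})

test_that("load_circ_calls validates counts and coordinates", {
  expect_error(fixture_catalog(list(c("chr1", 100, 200, "+", -1))),
               class = "circkit_validation_error")
  expect_error(fixture_catalog(list(c("chr1", 300, 200, "+", 1))),
               class = "circkit_validation_error")
})

test_that("dcc dialect pairs coordinates with summed sample counts", {
  coords <- tempfile(); counts <- tempfile()
  writeLines(c("Chr\tStart\tEnd\tGene\tJunctionType\tStrand",
               "chr5\t999\t2000\tX\t0\t+",
               "chr5\t4999\t6000\tY\t0\t-"), coords)
  writeLines(c("Chr\tStart\tEnd\ts1\ts2",
               "chr5\t999\t2000\t2\t3",
               "chr5\t4999\t6000\t1\t0"), counts)
  catalog <- load_circ_calls(coords, dialect = "dcc", counts_path = counts)
  expect_equal(catalog$start, c(1000L, 5000L))  # 0-based in, 1-based internal
  expect_equal(catalog$read_count, c(5, 1))
  expect_equal(catalog$strand, c("+", "-"))
})

test_that("assign_host_genes requires containment and matching strand", {
  genes <- fixture_genes()
  catalog <- fixture_catalog(list(
    c("chr14", 90404455, 90404514, "+", 10),  # inside CALM1 (+)
    c("chr14", 90404455, 90404514, "-", 10),  # wrong strand
    c("chrX", 10, 20, "+", 1),                # no gene on chrX
    c("chr14", 90404455, 90409000, "+", 1)))  # crosses the CALM1 3' end
  catalog <- assign_host_genes(catalog, genes)
  get <- function(id) catalog$host_gene_id[catalog$circ_id == id &
                                             !is.na(catalog$host_gene_id)]
  byrow <- split(catalog$host_gene_id, paste(catalog$circ_id, catalog$strand))
  expect_equal(unname(byrow[["14:90404455-90404514 +"]]), "CALM1")
  expect_true(is.na(byrow[["14:90404455-90404514 -"]]))
  expect_true(is.na(byrow[["X:10-20 +"]]))
  expect_true(is.na(byrow[["14:90404455-90409000 +"]]))
})

test_that("nested same-strand genes resolve to the inner (shorter) gene", {
  genes <- fixture_genes()
  catalog <- fixture_catalog(list(c("chr2", 10000, 15000, "+", 5)))
  catalog <- assign_host_genes(catalog, genes)
  expect_equal(catalog$host_gene_id, "INNER")

  # a '.' record strand matches either gene strand
  dotted <- fixture_catalog(list(c("chr2", 10000, 15000, ".", 5)))
  expect_equal(assign_host_genes(dotted, genes)$host_gene_id, "INNER")

  # determinism: repeated assignment gives identical output
  again <- assign_host_genes(fixture_catalog(
    list(c("chr2", 10000, 15000, "+", 5))), genes)
  expect_identical(again$host_gene_id, catalog$host_gene_id)
})

test_that("spliced length sums exon intersections with span fallback", {
  path <- write_gtf_text(c(
    gtf_line("chr1", "gene", 500, 3000, "+", gene_attrs("h")),
    gtf_line("chr1", "exon", 1000, 1200, "+", gene_attrs("h", transcript = "t")),
    gtf_line("chr1", "exon", 2000, 2200, "+", gene_attrs("h", transcript = "t"))))
  genes <- parse_gtf(path)
  catalog <- fixture_catalog(list(
    c("chr1", 1000, 2200, "+", 1),   # spans both exons: 201 + 201
    c("chr1", 1300, 1900, "+", 1),   # fully intronic: span fallback
    c("chr9", 100, 199, "+", 1)))    # intergenic: span fallback
  catalog <- compute_spliced_lengths(assign_host_genes(catalog, genes), genes)
  sl <- stats::setNames(catalog$spliced_length, catalog$circ_id)
  expect_equal(unname(sl["1:1000-2200"]), 402L)
  expect_equal(unname(sl["1:1300-1900"]), 601L)
  expect_equal(unname(sl["9:100-199"]), 100L)
})

test_that("spliced_length never exceeds the genomic span (synthetic bundles)", {
  pip <- cached_pipeline(11)
  expect_true(all(pip$catalog$spliced_length <=
                    pip$catalog$end - pip$catalog$start + 1L))
})

test_that("match_known respects coordinate tolerance and strand", {
  db_path <- tempfile(fileext = ".bed")
  writeLines(c("chr11\t33307958\t33309057\thsa_circ_0000284\t0\t+",
               "chr3\t100\t200\thsa_circ_0099999\t0\t-"), db_path)
  db <- load_known_db(db_path)
  expect_equal(db$start[1], 33307959L)  # BED 0-based converted

  catalog <- fixture_catalog(list(
    c("chr11", 33307959, 33309057, "+", 9),
    c("chr11", 33307960, 33309057, "+", 9),    # offset by 1
    c("chr13", 110213926, 110214015, "+", 2))) # novel: no chr13 entry
  m0 <- match_known(catalog, db, tolerance = 0)
  ids0 <- stats::setNames(m0$known_ids, m0$circ_id)
  expect_equal(ids0[["11:33307959-33309057"]], "hsa_circ_0000284")
  expect_equal(ids0[["11:33307960-33309057"]], character(0))
  expect_equal(ids0[["13:110213926-110214015"]], character(0))
  expect_true(m0$novel[m0$circ_id == "13:110213926-110214015"])

  m1 <- match_known(catalog, db, tolerance = 1)
  ids1 <- stats::setNames(m1$known_ids, m1$circ_id)
  expect_equal(ids1[["11:33307960-33309057"]], "hsa_circ_0000284")

  # known + novel partition the catalog
  expect_equal(sum(lengths(m0$known_ids) > 0) + sum(m0$novel), nrow(m0))
})

test_that("summarize_catalog counts the baseline characteristics", {
  empty <- summarize_catalog(empty_circ_catalog())
  expect_equal(empty$n_total, 0L)
  expect_equal(empty$n_over_read_threshold, 0L)

  # 10 records, 7 in the db, 4 with count > 5; all hosts protein-coding
  path <- write_gtf_text(
    gtf_line("chr1", "gene", 1, 100000, "+", gene_attrs("host")))
  genes <- parse_gtf(path)
  rows <- lapply(1:10, function(i) c("chr1", i * 1000, i * 1000 + 500, "+",
                                     c(1, 2, 3, 4, 6, 7, 8, 9, 5, 2)[i]))
  catalog <- fixture_catalog(rows)
  db_path <- tempfile(fileext = ".bed")
  writeLines(vapply(1:7, function(i) {
    sprintf("chr1\t%d\t%d\tdb_%d\t0\t+", i * 1000 - 1, i * 1000 + 500, i)
  }, ""), db_path)
  catalog <- annotate_catalog(catalog, genes, load_known_db(db_path))
  linear <- c(host = 1)
  s <- summarize_catalog(catalog, linear, read_threshold = 5, fold_window = 2)
  expect_equal(s$n_total, 10L)
  expect_equal(s$n_known, 7L)
  expect_equal(s$n_in_protein_coding, 10L)
  expect_equal(s$n_over_read_threshold, 4L)
  # every count bounded by the total
  expect_true(all(unlist(s[c("n_known", "n_in_protein_coding",
                             "n_over_read_threshold",
                             "n_more_abundant_than_linear")]) <= s$n_total))
})
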