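make_de <- function(df, condition = "test") {
  attr(df, "condition") <- condition
  class(df) <- c("de_table", "data.frame")
  df
}

test_that("flag_upregulated applies padj and fold-change thresholds", {
  de <- make_de(data.frame(
    circ_id = c("c1", "c2", "c3", "c4"),
    log2fc = c(1.2, -2.0, 0.8, 2.0),
    pvalue = c(0.001, 0.0001, 0.2, 0.01),
    padj = c(0.01, 0.001, 0.6, NaN)))
  expect_equal(flag_upregulated(de), "c1")
  expect_equal(flag_upregulated(de, lfc_min = Inf), character(0))
  expect_equal(flag_upregulated(make_de(de[0, ])), character(0))
})

test_that("genomewide_average_ratio averages over the chosen scope", {
  genes <- data.frame(gene_id = c("a", "b", "c"),
                      genomic_length = c(2000, 9000, 100),
                      exon_count = c(2L, 3L, 1L),
                      ratio = c(1000, 3000, 100))
  expect_equal(genomewide_average_ratio(genes, "all_genes"),
               mean(c(1000, 3000, 100)))
  catalog <- data.frame(host_gene_id = c("a", "b", "a"))
  expect_equal(genomewide_average_ratio(genes, "host_genes", catalog), 2000)
  expect_equal(genomewide_average_ratio(genes[2, ], "all_genes"), 3000)
  expect_error(genomewide_average_ratio(genes[0, ], "all_genes"),
               class = "circkit_insufficient_data")
})

test_that("chi_squared_2x2 matches hand-computed statistics", {
  flat <- chi_squared_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$stat, 0)
  expect_equal(flat$p_value, 1)

  # E = 20 in every cell; stat = 4 * (100 / 20) = 20
  skew <- chi_squared_2x2(matrix(c(30, 10, 10, 30), 2))
  expect_equal(skew$stat, 20)
  expect_equal(skew$p_value, stats::pchisq(20, 1, lower.tail = FALSE))

  yates <- chi_squared_2x2(matrix(c(30, 10, 10, 30), 2), continuity = TRUE)
  expect_lt(yates$stat, 20)
  expect_equal(yates$stat, 4 * (9.5^2 / 20))

  expect_error(chi_squared_2x2(matrix(c(0, 0, 5, 5), 2)),
               regexp = "margin", class = "circkit_degenerate_table")
  expect_error(chi_squared_2x2(matrix(c(-1, 2, 3, 4), 2)),
               class = "circkit_validation_error")
})

test_that("chi_squared_2x2 equals the closed-form Pearson identity", {
  set.seed(5)
  for (i in 1:50) {
    m <- matrix(as.numeric(sample(1:40, 4, replace = TRUE)), 2)
    got <- chi_squared_2x2(m)$stat
    a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
    ref <- (a * d - b * c_)^2 * sum(m) /
      (sum(m[1, ]) * sum(m[2, ]) * sum(m[, 1]) * sum(m[, 2]))
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("ratio_enrichment recovers a planted effect and validates inputs", {
  sim <- simulate_ratio_experiment(500, 0.30, 0.05, seed = 321)
  res <- ratio_enrichment(sim$catalog, sim$genes, sim$de)
  expect_s3_class(res, "enrichment_result")
  expect_lt(res$avg_ratio_overexpressed, res$avg_ratio_stable)
  expect_lt(res$p_value, 0.05)
  expect_equal(sum(res$contingency), res$n_assessable)
  chk <- planted_enrichment_check(sim$truth, res)
  expect_true(chk$sign_matches)
  expect_true(chk$detected)

  # zero upregulated circRNAs -> degenerate table naming the empty margin
  de0 <- sim$de
  de0$padj <- 0.9
  expect_error(ratio_enrichment(sim$catalog, sim$genes, make_de(de0)),
               regexp = "margin", class = "circkit_degenerate_table")
})

test_that("ratio_enrichment is invariant to record and row order", {
  sim <- simulate_ratio_experiment(200, 0.30, 0.05, seed = 17)
  res1 <- ratio_enrichment(sim$catalog, sim$genes, sim$de)
  set.seed(1)
  cat2 <- sim$catalog[sample(nrow(sim$catalog)), ]
  class(cat2) <- class(sim$catalog)
  de2 <- sim$de[sample(nrow(sim$de)), ]
  attr(de2, "condition") <- attr(sim$de, "condition")
  class(de2) <- class(sim$de)
  res2 <- ratio_enrichment(cat2, sim$genes, de2)
  expect_equal(res2$contingency, res1$contingency)
  expect_equal(res2$chi2_stat, res1$chi2_stat)
  expect_equal(res2$avg_ratio_overexpressed, res1$avg_ratio_overexpressed)
})

test_that("permutation p-value agrees with the chi-squared p on clear effects", {
  sim <- simulate_ratio_experiment(400, 0.35, 0.05, seed = 55)
  set.seed(99)
  res <- ratio_enrichment(sim$catalog, sim$genes, sim$de, n_perm = 400L)
  expect_lt(res$perm_p_value, 0.05)
})

test_that("target_site_overlap counts intersections", {
  expect_equal(target_site_overlap(c("A", "B", "C"), c("B", "D")),
               list(n_de = 3L, n_with_site = 1L))
  expect_equal(target_site_overlap(c("A", "B"), character(0)),
               list(n_de = 2L, n_with_site = 0L))
  # planted 10% overlap: intersection near binomial expectation over seeds
  set.seed(303)
  hits <- replicate(50, {
    universe <- sprintf("g%d", 1:500)
    targets <- sample(universe, 50)        # 10% of the universe
    de_set <- sample(universe, 50)
    target_site_overlap(de_set, targets)$n_with_site
  })
  expect_gt(mean(hits), 2.5)
  expect_lt(mean(hits), 7.5)
})

test_that("recurrent_responders intersects significant host genes", {
  catalog <- data.frame(circ_id = c("c1", "c2", "c3"),
                        host_gene_id = c("A", "B", "C"))
  de1 <- make_de(data.frame(circ_id = c("c1", "c2"), log2fc = c(2, -2),
                            pvalue = c(0.001, 0.001), padj = c(0.01, 0.01)))
  de2 <- make_de(data.frame(circ_id = c("c2", "c3"), log2fc = c(1, 1),
                            pvalue = c(0.001, 0.001), padj = c(0.01, 0.01)))
  expect_equal(recurrent_responders(list(a = de1, b = de2), catalog), "B")

  de3 <- make_de(data.frame(circ_id = "c1", log2fc = 1, pvalue = 0.001,
                            padj = 0.01))
  de4 <- make_de(data.frame(circ_id = "c3", log2fc = 1, pvalue = 0.001,
                            padj = 0.01))
  expect_equal(recurrent_responders(list(a = de3, b = de4), catalog),
               character(0))
  expect_error(recurrent_responders(list(a = de1), catalog),
               class = "circkit_validation_error")
})

test_that("planted always-responders are recovered from a quiet bundle", {
  # background DE probabilities low enough that chance recurrence across all
  # three conditions is negligible: exactly the planted genes remain
  truth <- cached_bundle(5, n_genes = 300, p_up_low_ratio = 0.02,
                         p_up_high_ratio = 0.02, p_down = 0.01)
  genes <- parse_gtf(truth$paths$annotation)
  catalog <- annotate_catalog(load_circ_calls(truth$paths$circ_calls, "tsv"),
                              genes)
  de_list <- lapply(names(truth$paths$de), function(cn) {
    load_de_table(truth$paths$de[[cn]], cn)
  })
  got <- recurrent_responders(de_list, catalog)
  expect_equal(got, truth$responders)
  expect_length(got, 4L)
})
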