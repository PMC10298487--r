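test_that("classify_circ_vs_linear applies the pseudocounted fold window", {
  expect_equal(classify_circ_vs_linear(210, 10, 2), "higher")
  expect_equal(classify_circ_vs_linear(10, 10, 1), "equal")
  expect_equal(classify_circ_vs_linear(10, 10, 5), "equal")
  expect_equal(classify_circ_vs_linear(0, 0, 2), "equal")
  expect_equal(classify_circ_vs_linear(1, 100, 2), "lower")
  expect_error(classify_circ_vs_linear(-1, 5), class = "circkit_validation_error")
  expect_error(classify_circ_vs_linear(1, 5, fold_window = 0.5))
})

test_that("classification is antisymmetric in its arguments", {
  set.seed(7)
  a <- sample(0:500, 50, replace = TRUE)
  b <- sample(0:500, 50, replace = TRUE)
  ab <- classify_circ_vs_linear(a, b, 2)
  ba <- classify_circ_vs_linear(b, a, 2)
  expect_equal(ab == "higher", ba == "lower")
  expect_equal(ab == "equal", ba == "equal")
})

test_that("circ_linear_distribution partitions the catalog", {
  expect_equal(circ_linear_distribution(empty_circ_catalog(), c(g = 1)),
               list(lower = 0L, equal = 0L, higher = 0L, unassessed = 0L))

  genes <- parse_gtf(write_gtf_text(
    gtf_line("chr1", "gene", 1, 1e6, "+", gene_attrs("host"))))
  catalog <- fixture_catalog(lapply(1:5, function(i) {
    c("chr1", i * 1000, i * 1000 + 99, "+", c(100, 3, 10, 1, 50)[i])
  }))
  catalog <- assign_host_genes(catalog, genes)
  linear <- c(host = 10)
  d <- circ_linear_distribution(catalog, linear, 2)
  # by hand: ratios (101, 4, 11, 2, 51)/11 -> higher, lower, equal, lower, higher
  expect_equal(d, list(lower = 2L, equal = 1L, higher = 2L, unassessed = 0L))

  d2 <- circ_linear_distribution(catalog, c(other_gene = 5), 2)
  expect_equal(d2$unassessed, 5L)
  expect_equal(d2$lower + d2$equal + d2$higher, 0L)

  pip <- cached_pipeline(11)
  dd <- circ_linear_distribution(pip$catalog, pip$linear)
  expect_equal(dd$lower + dd$equal + dd$higher + dd$unassessed,
               nrow(pip$catalog))
})

test_that("spearman_rho reproduces the validation-table correlation", {
  x <- c(210, 67, 61, 54, 39, 35, 27, 11, 7, 6)
  y <- c(18.23, 19.14, 19.33, 20.50, 21.84, 21.39, 21.20, 26.65, 21.40, 26.22)
  expect_equal(round(spearman_rho(x, y), 4), -0.8667)
  # no-ties closed form with sum(d^2) = 308
  expect_equal(spearman_rho(x, y), 1 - 6 * 308 / (10 * 99))
  expect_equal(spearman_rho(1:8, (1:8)^3), 1)
})

test_that("spearman_rho uses mid-ranks under ties and validates input", {
  x <- c(1, 2, 2, 3)
  y <- c(10, 30, 20, 40)
  rx <- c(1, 2.5, 2.5, 4)
  ry <- c(1, 3, 2, 4)
  expect_equal(spearman_rho(x, y), stats::cor(rx, ry))
  expect_error(spearman_rho(1:3, 1:4), class = "circkit_validation_error")
  expect_error(spearman_rho(1, 1), class = "circkit_validation_error")
  expect_error(spearman_rho(rep(1, 5), 1:5),
               class = "circkit_undefined_correlation")
})

test_that("spearman_rho is invariant under monotone transforms", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    r <- spearman_rho(x, y)
    expect_equal(spearman_rho(exp(x), y), r)
    expect_equal(spearman_rho(x, 3 * y + 2), r)
    expect_equal(spearman_rho(-x, y), -r)
  }
})

test_that("spearman_pvalue: exact small-sample and t-approximation branches", {
  expect_equal(spearman_pvalue(0, 10)$p_value, 1.0)
  expect_equal(spearman_pvalue(0, 10)$method, "exact")
  # n = 5, perfectly monotone decreasing: 2 of 120 permutations as extreme
  p5 <- spearman_pvalue(-1, 5)
  expect_equal(p5$p_value, 2 / 120)
  expect_equal(round(p5$p_value, 4), 0.0167)
  # t branch
  p20 <- spearman_pvalue(0.6, 20)
  t_ref <- 0.6 * sqrt(18 / (1 - 0.36))
  expect_equal(p20$p_value, 2 * stats::pt(-t_ref, 18))
  expect_equal(p20$method, "t-approximation")
  # |rho| = 1 under the approximation: most extreme enumerable bin
  expect_equal(spearman_pvalue(1, 15)$p_value, 2 / factorial(15))
  expect_error(spearman_pvalue(0.5, 2), class = "circkit_validation_error")
})

test_that("concordance reproduces the printed validation table", {
  q <- load_qpcr(system.file("extdata", "endothelial_qpcr10.tsv",
                             package = "circkit"))
  res <- concordance(NULL, q)
  expect_equal(res$n, 10L)
  expect_equal(round(res$rho, 4), -0.8667)
  expect_equal(round(res$p_value, 4), 0.0022)
  expect_equal(res$method, "exact")
})

test_that("concordance matches by catalog id or known id and validates overlap", {
  genes <- parse_gtf(write_gtf_text(
    gtf_line("chr1", "gene", 1, 1e6, "+", gene_attrs("host"))))
  catalog <- fixture_catalog(lapply(1:5, function(i) {
    c("chr1", i * 1000, i * 1000 + 99, "+", c(200, 60, 30, 10, 4)[i])
  }))
  db_path <- tempfile(fileext = ".bed")
  writeLines(sprintf("chr1\t%d\t%d\thsa_circ_%07d\t0\t+",
                     (1:5) * 1000 - 1, (1:5) * 1000 + 99, 1:5), db_path)
  catalog <- annotate_catalog(catalog, genes, load_known_db(db_path))

  qpcr <- data.frame(
    circ_id = c("hsa_circ_0000001", "1:2000-2099", "hsa_circ_0000003",
                "hsa_circ_0000004", "hsa_circ_0000005"),
    delta_ct = 30 - 1.6 * log2(c(200, 60, 30, 10, 4) + 1))
  res <- concordance(catalog, qpcr)
  expect_equal(res$n, 5L)
  expect_equal(res$rho, -1)

  bad <- data.frame(circ_id = c("nope1", "nope2", "nope3"), delta_ct = 1:3)
  expect_error(suppressWarnings(concordance(catalog, bad)),
               class = "circkit_insufficient_data")
})

test_that("generated qPCR data yields strongly negative concordance", {
  set.seed(99)
  for (i in 1:10) {
    counts <- pmax(1L, stats::rnbinom(12, mu = 40, size = 1))
    qpcr <- data.frame(circ_id = sprintf("c%d", 1:12),
                       delta_ct = 31 - 1.7 * log2(counts + 1) + rnorm(12, 0, 0.5))
    res <- concordance(data.frame(circ_id = sprintf("c%d", 1:12),
                                  read_count = counts), qpcr)
    expect_lt(res$rho, -0.5)
  }
})
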