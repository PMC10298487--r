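# Circular-versus-linear abundance comparison and RNA-seq/qPCR concordance.
#
# Spearman correlation is computed as the Pearson correlation of mid-ranks.
# For small samples without ties the two-sided p-value comes from the exact
# permutation null of rho, enumerated through the distribution of
# S = sum(i * pi(i)) over all n! permutations (a subset dynamic program);
# larger samples use the t approximation with n - 2 degrees of freedom.

#' Load per-gene linear transcript abundance
#'
#' @param path TSV with header columns `gene_id` and `abundance`
#' @return named numeric vector (names are gene ids)
#' @export
load_linear_quant <- function(path) {
  assert_that(file.exists(path), "linear quantification file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  assert_that(all(c("gene_id", "abundance") %in% names(dt)),
              "linear quantification needs columns gene_id, abundance",
              class = "circkit_parse_error")
  assert_that(!anyDuplicated(dt$gene_id), "duplicate gene_id in linear quant",
              class = "circkit_validation_error")
  assert_that(all(dt$abundance >= 0), "negative linear abundance",
              class = "circkit_validation_error")
  stats::setNames(as.numeric(dt$abundance), as.character(dt$gene_id))
}

#' Classify circular versus linear abundance
#'
#' With a pseudocount added to both values, the ratio
#' `r = (circ + 1) / (linear + 1)` is compared against a symmetric fold
#' window: `r > fold_window` is `"higher"`, `r < 1/fold_window` is
#' `"lower"`, anything in between is `"equal"` ("approximately equal"
#' expression). Vectorized over its first two arguments.
#'
#' @param circ_count non-negative circRNA read count(s)
#' @param linear_count non-negative linear abundance value(s)
#' @param fold_window symmetric fold window, `>= 1` (default 2)
#' @param pseudocount added to both values before forming the ratio
#' @return character vector in `c("lower", "equal", "higher")`
#' @export
classify_circ_vs_linear <- function(circ_count, linear_count, fold_window = 2,
                                    pseudocount = 1) {
  assert_that(fold_window >= 1, "fold_window must be >= 1")
  assert_that(all(circ_count >= 0) && all(linear_count >= 0),
              "abundances must be non-negative",
              class = "circkit_validation_error")
  r <- (circ_count + pseudocount) / (linear_count + pseudocount)
  ifelse(r > fold_window, "higher", ifelse(r < 1 / fold_window, "lower", "equal"))
}

#' Distribution of circular-versus-linear classes over a catalog
#'
#' Records with a host gene present in the linear quantification are
#' classified by [classify_circ_vs_linear()]; all others (intergenic, or host
#' not quantified) are counted as `unassessed`.
#'
#' @param catalog an annotated `circ_catalog`
#' @param linear named numeric vector of per-gene linear abundance
#' @param fold_window passed to the classifier
#' @return list with counts `lower`, `equal`, `higher`, `unassessed`
#' @export
circ_linear_distribution <- function(catalog, linear, fold_window = 2) {
  out <- list(lower = 0L, equal = 0L, higher = 0L, unassessed = 0L)
  if (nrow(catalog) == 0L) return(out)
  has <- !is.na(catalog$host_gene_id) & catalog$host_gene_id %in% names(linear)
  out$unassessed <- sum(!has)
  if (any(has)) {
    cls <- classify_circ_vs_linear(catalog$read_count[has],
                                   linear[catalog$host_gene_id[has]],
                                   fold_window)
    out$lower <- sum(cls == "lower")
    out$equal <- sum(cls == "equal")
    out$higher <- sum(cls == "higher")
  }
  out
}

#' Spearman rank correlation coefficient
#'
#' Pearson correlation of mid-ranks (average ranks on ties); without ties this
#' equals `1 - 6 * sum(d^2) / (n * (n^2 - 1))`.
#'
#' @param x,y numeric vectors of equal length, `n >= 2`
#' @return the correlation in `[-1, 1]`
#' @export
spearman_rho <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must have equal length",
              class = "circkit_validation_error")
  assert_that(length(x) >= 2L, "need at least 2 observations",
              class = "circkit_validation_error")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  assert_that(stats::var(rx) > 0 && stats::var(ry) > 0,
              "correlation undefined: zero rank variance",
              class = "circkit_undefined_correlation")
  stats::cor(rx, ry)
}

# Exact null distribution of rho for untied ranks 1..n, via the distribution
# of S = sum(i * pi(i)) over all permutations (DP over rank subsets).
# Returns list(rho = sorted values, prob = probabilities).
.spearman_null_cache <- new.env(parent = emptyenv())

exact_spearman_null <- function(n) {
  key <- as.character(n)
  if (!is.null(.spearman_null_cache[[key]])) return(.spearman_null_cache[[key]])
  assert_that(n >= 2L && n <= 12L, "exact null implemented for 2 <= n <= 12")
  maxS <- sum((1:n)^2)
  f <- vector("list", 2^n)
  f[[1]] <- c(1, rep(0, maxS))
  bits <- bitwShiftL(1L, 0:(n - 1L))
  for (mask in 0:(2^n - 2L)) {
    v <- f[[mask + 1L]]
    if (is.null(v)) next
    i <- sum(bitwAnd(mask, bits) != 0L) + 1L
    for (j in seq_len(n)) {
      if (bitwAnd(mask, bits[j]) == 0L) {
        nm <- bitwOr(mask, bits[j])
        add <- i * j
        w <- f[[nm + 1L]]
        if (is.null(w)) w <- numeric(maxS + 1L)
        idx <- (add + 1L):(maxS + 1L)
        w[idx] <- w[idx] + v[seq_len(maxS + 1L - add)]
        f[[nm + 1L]] <- w
      }
    }
    f[[mask + 1L]] <- numeric(0)  # free memory, keep slot non-NULL
  }
  dist <- f[[2^n]]
  s_vals <- which(dist > 0) - 1
  cnt <- dist[dist > 0]
  rho <- (s_vals - n * (n + 1)^2 / 4) / (n * (n^2 - 1) / 12)
  res <- list(rho = rho, prob = cnt / sum(cnt))
  .spearman_null_cache[[key]] <- res
  res
}

#' Two-sided Spearman p-value
#'
#' For `n <= 10` (untied ranks) the p-value is exact: the permutation null of
#' rho over all `n!` rank permutations, enumerated via the sum-of-products
#' distribution. For `n > 10` the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees of freedom is
#' used; `|rho| = 1` under the approximation returns the most extreme
#' enumerable bin `2 / n!` instead of dividing by zero.
#'
#' @param rho observed correlation
#' @param n number of paired observations (`>= 3`)
#' @return list with `p_value` and `method` (`"exact"` or
#'   `"t-approximation"`)
#' @export
spearman_pvalue <- function(rho, n) {
  assert_that(n >= 3L, "need n >= 3 for a p-value",
              class = "circkit_validation_error")
  assert_that(abs(rho) <= 1 + 1e-12, "|rho| must be <= 1")
  if (n <= 10L) {
    null <- exact_spearman_null(n)
    p <- sum(null$prob[abs(null$rho) >= abs(rho) - 1e-9])
    return(list(p_value = min(1, p), method = "exact"))
  }
  if (abs(rho) >= 1 - 1e-12) {
    return(list(p_value = min(1, 2 * exp(-lfactorial(n))),
                method = "t-approximation"))
  }
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(p_value = 2 * stats::pt(-abs(t_stat), df = n - 2),
       method = "t-approximation")
}

# All permutations of 1..n as a matrix (n! rows); internal, n <= 8.
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- perm_matrix(n - 1L)
  out <- matrix(0L, factorial(n), n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * nrow(sub) + 1L):(i * nrow(sub))
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix((seq_len(n)[-i])[sub], nrow(sub), n - 1L)
  }
  out
}

#' Spearman correlation test
#'
#' Computes [spearman_rho()] and a two-sided p-value. Without ties the exact
#' small-sample machinery of [spearman_pvalue()] applies directly. With ties
#' and `n <= 7` the p-value is an exact enumeration over all `n!`
#' permutations of the tied mid-ranks; with ties and `n > 7` the
#' t approximation is used.
#'
#' @param x,y numeric vectors of equal length
#' @return list with `n`, `rho`, `p_value`, `method`
#' @export
spearman_test <- function(x, y) {
  rho <- spearman_rho(x, y)
  n <- length(x)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  tied <- anyDuplicated(rx) > 0L || anyDuplicated(ry) > 0L
  if (!tied || n > 10L) {
    pv <- spearman_pvalue(rho, n)
  } else if (n <= 7L) {
    pm <- perm_matrix(n)
    ryc <- ry - mean(ry)
    rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rho_perm <- (matrix(ryc[pm], nrow(pm), n) %*% rxc) / denom
    pv <- list(p_value = mean(abs(rho_perm) >= abs(rho) - 1e-9),
               method = "exact-permutation-ties")
  } else {
    t_stat <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    pv <- list(p_value = 2 * stats::pt(-abs(t_stat), df = n - 2),
               method = "t-approximation-ties")
  }
  list(n = n, rho = rho, p_value = pv$p_value, method = pv$method)
}

#' Load a qPCR result table
#'
#' @param path TSV with header columns `circ_id` and `delta_ct` (an optional
#'   `read_count` column is carried through, allowing a self-contained
#'   concordance input)
#' @return data frame with the available columns
#' @export
load_qpcr <- function(path) {
  assert_that(file.exists(path), "qPCR file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  assert_that(all(c("circ_id", "delta_ct") %in% names(dt)),
              "qPCR table needs columns circ_id, delta_ct",
              class = "circkit_parse_error")
  as.data.frame(dt)
}

#' RNA-seq / qPCR concordance
#'
#' Pairs RNA-seq read counts with qPCR delta-Ct values by circRNA identifier
#' and reports the Spearman correlation with its p-value. Since delta-Ct is
#' inversely monotone in abundance, concordant measurements give a strongly
#' negative rho. When `counts` is a catalog, a qPCR id matches a record
#' either by its coordinate `circ_id` or by any of its `known_ids` (database
#' identifiers). Unmatched qPCR ids are reported with a warning.
#'
#' @param counts an annotated `circ_catalog`, or a data frame with columns
#'   `circ_id` and `read_count`
#' @param qpcr data frame with columns `circ_id`, `delta_ct` (see
#'   [load_qpcr()]); if it also carries `read_count` and `counts` is `NULL`,
#'   the table is used as a self-contained input
#' @return a `concordance_result` list: `n`, `rho`, `p_value`, `method`,
#'   `unmatched`
#' @export
concordance <- function(counts, qpcr) {
  if (is.null(counts)) {
    assert_that("read_count" %in% names(qpcr),
                "counts = NULL requires a read_count column in the qPCR table")
    counts <- qpcr[, c("circ_id", "read_count")]
  }
  if (inherits(counts, "circ_catalog")) {
    id_map <- stats::setNames(counts$read_count, counts$circ_id)
    if ("known_ids" %in% names(counts)) {
      extra_ids <- unlist(counts$known_ids)
      extra_cnt <- rep(counts$read_count, lengths(counts$known_ids))
      id_map <- c(id_map, stats::setNames(extra_cnt, extra_ids))
    }
  } else {
    id_map <- stats::setNames(counts$read_count, counts$circ_id)
  }
  hit <- qpcr$circ_id %in% names(id_map)
  unmatched <- qpcr$circ_id[!hit]
  if (length(unmatched) > 0L) {
    warning("qPCR ids not found in catalog: ", paste(unmatched, collapse = ", "))
  }
  assert_that(sum(hit) >= 3L,
              "fewer than 3 circRNA ids shared between catalog and qPCR table",
              class = "circkit_insufficient_data")
  x <- as.numeric(id_map[qpcr$circ_id[hit]])
  y <- as.numeric(qpcr$delta_ct[hit])
  st <- spearman_test(x, y)
  structure(list(n = st$n, rho = st$rho, p_value = st$p_value,
                 method = st$method, unmatched = unmatched),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("RNA-seq/qPCR concordance: n = %d, rho = %.4f, p = %.4g (%s)\n",
              x$n, x$rho, x$p_value, x$method))
  invisible(x)
}
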