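# Seeded synthetic-data generator. Emits a complete, internally consistent
# input bundle (gene annotation, junction calls, linear quantification,
# known-circRNA database, per-condition DE tables, qPCR table, microRNA
# target lists) with recoverable ground truth, so every pipeline stage is
# testable without external downloads.
#
# The stated world: ~1000 genes on 22 chromosomes with log-normal genomic
# lengths and geometric exon counts; a subset of genes host circRNAs with a
# per-gene multiplicity distribution matching the observed catalog shape
# (587:126:32:12:4:2:3:2 for k = 1..8); junction read counts are negative
# binomial with mean 8 and a heavy right tail (~1.6% above 50 reads); linear
# abundance exceeds circular for the vast majority of hosts (log2 circ/linear
# ~ N(-5, 2.7^2)); a known-database coverage of 1055/1068; and a planted
# upregulation probability per host-gene ratio class (0.30 below the average
# ratio vs 0.05 above) in each of three microRNA-mimic conditions.

#' Build a synthetic-bundle configuration
#'
#' All defaults describe the generator's stated world (see the methods
#' vignette); any field can be overridden.
#'
#' @param seed integer RNG seed; the same config yields byte-identical bundles
#' @param n_chromosomes number of chromosomes (`chr1..chrN`)
#' @param n_genes number of annotated genes
#' @param gene_length_median,gene_length_sigma log-normal genomic-length model
#'   (median in nt, log-sd)
#' @param exon_count_mean mean of the shifted-geometric exon-count model
#' @param frac_protein_coding proportion of protein-coding genes
#' @param frac_genes_hosting proportion of genes hosting at least one circRNA
#' @param multiplicity_weights distribution over circRNAs-per-gene k = 1..8
#' @param count_mean,count_dispersion negative-binomial junction-read model
#'   (`mu`, `size`)
#' @param circ_linear_logratio_mean,circ_linear_logratio_sd normal model of
#'   log2(circular/linear) abundance per host gene (mean < 0)
#' @param known_db_coverage proportion of circRNAs present in the known DB
#' @param p_up_low_ratio,p_up_high_ratio planted per-condition upregulation
#'   probability for circRNAs of low- and high-ratio host genes
#' @param p_down planted downregulation probability (both classes)
#' @param frac_intergenic proportion of additional intergenic junctions
#' @param frac_exonic probability a hosted junction snaps to exon boundaries
#'   (otherwise it falls inside an intron)
#' @param qpcr_n,qpcr_intercept,qpcr_slope,qpcr_noise_sd qPCR model:
#'   `delta_ct = intercept - slope * log2(count + 1) + noise`
#' @param n_recurrent number of planted always-responding host genes
#' @param conditions stimulation condition labels
#' @param n_targets microRNA target-list size per condition
#' @param alpha significance level the planted DE tables are built around
#' @return a `synth_config` list
#' @export
synth_config <- function(seed = 1L,
                         n_chromosomes = 22L,
                         n_genes = 1000L,
                         gene_length_median = 20000,
                         gene_length_sigma = 1.0,
                         exon_count_mean = 9,
                         frac_protein_coding = 0.9,
                         frac_genes_hosting = 0.7,
                         multiplicity_weights =
                           c(587, 126, 32, 12, 4, 2, 3, 2) / 768,
                         count_mean = 8,
                         count_dispersion = 0.45,
                         circ_linear_logratio_mean = -5,
                         circ_linear_logratio_sd = 2.7,
                         known_db_coverage = 1055 / 1068,
                         p_up_low_ratio = 0.30,
                         p_up_high_ratio = 0.05,
                         p_down = 0.05,
                         frac_intergenic = 0.02,
                         frac_exonic = 0.9,
                         qpcr_n = 10L,
                         qpcr_intercept = 30.8,
                         qpcr_slope = 1.63,
                         qpcr_noise_sd = 1.5,
                         n_recurrent = 4L,
                         conditions = c("miR-191", "miR-126", "miR-21-5p"),
                         n_targets = 300L,
                         alpha = 0.05) {
  cfg <- as.list(environment())
  assert_that(cfg$n_genes >= 1L, "n_genes must be >= 1")
  props <- c(cfg$frac_protein_coding, cfg$frac_genes_hosting,
             cfg$known_db_coverage, cfg$p_up_low_ratio, cfg$p_up_high_ratio,
             cfg$p_down, cfg$frac_intergenic, cfg$frac_exonic)
  assert_that(all(props >= 0 & props <= 1), "proportions must be in [0, 1]")
  assert_that(abs(sum(cfg$multiplicity_weights) - 1) < 1e-8,
              "multiplicity_weights must sum to 1")
  structure(cfg, class = "synth_config")
}

# Relative union-exon layout for a gene of length L with k exons: exon 1
# starts at 1, exon k ends at L, introns get ~8x the slack so the structure
# is intron-dominated like real genes. Returns a 2-column matrix.
build_exon_layout <- function(L, k) {
  if (k == 1L) return(cbind(start = 1L, end = as.integer(L)))
  min_e <- 50L; min_i <- 60L
  slack <- L - min_e * k - min_i * (k - 1L)
  w <- c(stats::rexp(k, rate = 8), stats::rexp(k - 1L, rate = 1))
  extra <- floor(slack * w / sum(w))
  e_len <- min_e + extra[seq_len(k)]
  i_len <- min_i + extra[k + seq_len(k - 1L)]
  i_len[k - 1L] <- i_len[k - 1L] + (slack - sum(extra))
  starts <- 1L + cumsum(c(0L, e_len[-k] + i_len))
  cbind(start = as.integer(starts), end = as.integer(starts + e_len - 1L))
}

# Sample the annotated genome: chromosomes, non-overlapping gene spans,
# biotypes, and union-exon structures. Returns a gene_models data frame.
sample_gene_structures <- function(cfg) {
  n <- cfg$n_genes
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  chrom <- sample(chroms, n, replace = TRUE, prob = rev(seq_len(cfg$n_chromosomes)))
  L <- pmax(500L, as.integer(round(stats::rlnorm(
    n, meanlog = log(cfg$gene_length_median), sdlog = cfg$gene_length_sigma))))
  k <- pmin(stats::rgeom(n, prob = 1 / cfg$exon_count_mean) + 1L,
            pmax(1L, L %/% 120L))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  biotype <- ifelse(stats::runif(n) < cfg$frac_protein_coding, "protein_coding",
                    sample(c("lncRNA", "antisense", "processed_pseudogene"),
                           n, replace = TRUE))
  start <- integer(n)
  for (ch in chroms) {
    idx <- which(chrom == ch)
    if (length(idx) == 0L) next
    gaps <- as.integer(round(stats::runif(length(idx), 2000, 20000)))
    pos <- 0L
    for (j in seq_along(idx)) {
      start[idx[j]] <- pos + gaps[j] + 1L
      pos <- start[idx[j]] + L[idx[j]] - 1L
    }
  }
  df <- data.frame(
    gene_id = sprintf("SGENE%05d", seq_len(n)),
    gene_name = sprintf("G%d", seq_len(n)),
    chrom = chrom, strand = strand, start = start, end = start + L - 1L,
    biotype = biotype, stringsAsFactors = FALSE)
  df$exons <- lapply(seq_len(n), function(i) {
    rel <- build_exon_layout(L[i], k[i])
    cbind(start = rel[, 1] + start[i] - 1L, end = rel[, 2] + start[i] - 1L)
  })
  df$exon_count <- k
  df$genomic_length <- L
  df$ratio <- L / k
  new_gene_models(df)
}

# Sample hosted junctions for one gene: m distinct junctions, exonic (snap
# to boundaries of a consecutive exon run) with probability frac_exonic,
# otherwise inside an intron. Returns a data frame (possibly < m rows when
# the gene has too few distinct placements).
sample_gene_junctions <- function(gene_row, exons, m, frac_exonic) {
  k <- nrow(exons)
  runs <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  runs <- runs[runs[, 1] <= runs[, 2], , drop = FALSE]  # (i, j) exon runs
  n_exonic_wanted <- sum(stats::runif(m) < frac_exonic | k < 2L)
  n_exonic <- min(n_exonic_wanted, nrow(runs))
  pick <- if (n_exonic > 0L) {
    runs[sample.int(nrow(runs), n_exonic), , drop = FALSE]
  } else matrix(integer(0), 0, 2)
  out <- list()
  for (r in seq_len(nrow(pick))) {
    i <- pick[r, 1]; j <- pick[r, 2]
    out[[length(out) + 1L]] <- data.frame(
      start = exons[i, 1], end = exons[j, 2],
      spliced_length = sum(exons[i:j, 2] - exons[i:j, 1] + 1L),
      exonic = TRUE)
  }
  n_intronic <- m - n_exonic
  if (n_intronic > 0L && k >= 2L) {
    for (r in seq_len(n_intronic)) {
      ii <- sample.int(k - 1L, 1L)
      lo <- exons[ii, 2] + 1L
      hi <- exons[ii + 1L, 1] - 1L
      if (hi - lo < 80L) next
      s <- lo + as.integer(floor(stats::runif(1, 0, (hi - lo) * 0.4)))
      e <- min(hi, s + as.integer(floor(stats::runif(1, 30, (hi - lo) * 0.5))))
      out[[length(out) + 1L]] <- data.frame(
        start = s, end = e, spliced_length = e - s + 1L, exonic = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  res <- unique(do.call(rbind, out))
  res$chrom <- gene_row$chrom
  res$strand <- gene_row$strand
  res$host_gene_id <- gene_row$gene_id
  res
}

# Sample the full synthetic world in memory (genes, circs, linear counts,
# DE status per condition, qPCR, targets). Used by generate_bundle().
sample_world <- function(cfg) {
  genes <- sample_gene_structures(cfg)
  n_host <- round(cfg$frac_genes_hosting * cfg$n_genes)

  circs <- NULL
  if (n_host > 0L) {
    host_idx <- sort(sample.int(cfg$n_genes, n_host))
    mult <- sample(seq_along(cfg$multiplicity_weights), n_host,
                   replace = TRUE, prob = cfg$multiplicity_weights)
    pieces <- vector("list", n_host)
    for (h in seq_len(n_host)) {
      gi <- host_idx[h]
      pieces[[h]] <- sample_gene_junctions(genes[gi, ], genes$exons[[gi]],
                                           mult[h], cfg$frac_exonic)
    }
    circs <- do.call(rbind, pieces)
  }
  if (is.null(circs)) {
    circs <- data.frame(start = integer(0), end = integer(0),
                        spliced_length = integer(0), exonic = logical(0),
                        chrom = character(0), strand = character(0),
                        host_gene_id = character(0), stringsAsFactors = FALSE)
  }

  # intergenic junctions beyond the last gene of a chromosome
  n_inter <- round(cfg$frac_intergenic * nrow(circs))
  if (n_inter > 0L) {
    chroms <- unique(genes$chrom)
    ich <- sample(chroms, n_inter, replace = TRUE)
    inter <- lapply(seq_len(n_inter), function(j) {
      ch <- ich[j]
      base <- max(genes$end[genes$chrom == ch]) + 50000L + j * 10000L
      len <- as.integer(round(stats::runif(1, 100, 2000)))
      data.frame(start = base, end = base + len, spliced_length = len + 1L,
                 exonic = FALSE, chrom = ch,
                 strand = sample(c("+", "-"), 1L),
                 host_gene_id = NA_character_, stringsAsFactors = FALSE)
    })
    circs <- rbind(circs, do.call(rbind, inter))
  }

  circs <- circs[!duplicated(circs[, c("chrom", "start", "end", "strand")]), ]
  circs$read_count <- pmax(1L, stats::rnbinom(nrow(circs), mu = cfg$count_mean,
                                              size = cfg$count_dispersion))
  circs$circ_id <- make_circ_id(circs$chrom, circs$start, circs$end)
  ord <- order(circs$chrom, circs$start, circs$end)
  circs <- circs[ord, , drop = FALSE]
  rownames(circs) <- NULL

  # per-gene linear abundance: hosts scale from total circ reads through the
  # circ/linear log-ratio; non-hosts get an independent NB level
  host_tot <- tapply(circs$read_count, circs$host_gene_id, sum)
  logratio <- stats::rnorm(cfg$n_genes, cfg$circ_linear_logratio_mean,
                           cfg$circ_linear_logratio_sd)
  linear <- data.frame(gene_id = genes$gene_id,
                       abundance = pmax(0, stats::rnbinom(
                         cfg$n_genes, mu = 200, size = 0.8)),
                       stringsAsFactors = FALSE)
  hm <- match(names(host_tot), linear$gene_id)
  hm_ok <- !is.na(hm)
  linear$abundance[hm[hm_ok]] <-
    round(as.numeric(host_tot[hm_ok]) * 2^(-logratio[hm[hm_ok]]))

  # known-database membership, exact coordinates
  n_known <- round(cfg$known_db_coverage * nrow(circs))
  known_rows <- if (nrow(circs) > 0L) sort(sample.int(nrow(circs), n_known))
  else integer(0)
  circs$known_id <- rep(NA_character_, nrow(circs))
  circs$known_id[known_rows] <- sprintf("hsa_circ_%07d", seq_along(known_rows))

  # planted DE status per condition
  hosting_ids <- unique(circs$host_gene_id)
  hosting_ids <- hosting_ids[!is.na(hosting_ids)]
  responders <- if (cfg$n_recurrent > 0L && length(hosting_ids) > 0L) {
    sort(sample(hosting_ids, min(cfg$n_recurrent, length(hosting_ids))))
  } else character(0)
  gmatch <- match(circs$host_gene_id, genes$gene_id)
  host_ratio <- genes$ratio[gmatch]
  avg_ratio <- if (length(hosting_ids) > 0L) {
    mean(genes$ratio[match(hosting_ids, genes$gene_id)])
  } else NA_real_
  low <- !is.na(host_ratio) & host_ratio < avg_ratio
  p_up <- ifelse(is.na(host_ratio), cfg$p_up_high_ratio,
                 ifelse(low, cfg$p_up_low_ratio, cfg$p_up_high_ratio))

  de_status <- lapply(cfg$conditions, function(cond) {
    sample_condition_de(circs$circ_id, p_up, cfg$p_down, cfg$alpha,
                        force_sig = !is.na(circs$host_gene_id) &
                          circs$host_gene_id %in% responders)
  })
  names(de_status) <- cfg$conditions

  # qPCR subset spanning the count range; prefer database ids when available
  qn <- min(cfg$qpcr_n, nrow(circs))
  qpcr <- NULL
  if (qn >= 1L) {
    ord_cnt <- order(circs$read_count, circs$circ_id)
    sel <- ord_cnt[unique(round(seq(1, nrow(circs), length.out = qn)))]
    qid <- ifelse(is.na(circs$known_id[sel]), circs$circ_id[sel],
                  circs$known_id[sel])
    qpcr <- data.frame(
      circ_id = qid,
      delta_ct = round(cfg$qpcr_intercept -
                         cfg$qpcr_slope * log2(circs$read_count[sel] + 1) +
                         stats::rnorm(length(sel), 0, cfg$qpcr_noise_sd), 2),
      stringsAsFactors = FALSE)
  }

  targets <- lapply(cfg$conditions, function(cond) {
    sort(sample(genes$gene_id, min(cfg$n_targets, cfg$n_genes)))
  })
  names(targets) <- cfg$conditions

  list(genes = genes, circs = circs, linear = linear, de_status = de_status,
       qpcr = qpcr, targets = targets, responders = responders,
       genomewide_avg_ratio = avg_ratio, low_ratio = low)
}

# One condition's DE results: planted up/down/stable status plus log2fc and
# padj consistent with the flags (padj < alpha strictly for planted records).
sample_condition_de <- function(circ_ids, p_up, p_down, alpha, force_sig) {
  n <- length(circ_ids)
  u <- stats::runif(n)
  status <- ifelse(u < p_up, "up", ifelse(u < p_up + p_down, "down", "stable"))
  if (any(force_sig)) {
    forced_dir <- sample(c("up", "down"), sum(force_sig), replace = TRUE)
    status[force_sig] <- forced_dir
  }
  log2fc <- stats::rnorm(n, 0, 0.3)
  padj <- stats::runif(n, alpha, 1)
  sig <- status != "stable"
  padj[sig] <- stats::runif(sum(sig), 1e-6, alpha * 0.98)
  log2fc[status == "up"] <- 0.5 + abs(stats::rnorm(sum(status == "up"), 1.2, 0.6))
  log2fc[status == "down"] <- -0.5 - abs(stats::rnorm(sum(status == "down"), 1.2, 0.6))
  data.frame(circ_id = circ_ids, status = status,
             log2fc = round(log2fc, 4), pvalue = padj * stats::runif(n, 0.2, 1),
             padj = padj, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic input bundle
#'
#' Writes, under `out_dir`: `annotation.gtf`, `circ_calls.tsv` (tsv dialect),
#' `linear_quant.tsv`, `known_db.bed`, one `de_<condition>.tsv` per
#' condition (deseq2-results-compatible header), `qpcr.tsv`,
#' `targets_<condition>.txt`, and `truth.json`. Identical configs (including
#' the seed) produce byte-identical bundles.
#'
#' @param config a [synth_config()]
#' @param out_dir output directory (created if missing)
#' @return the ground truth, invisibly: a `synth_truth` list with elements
#'   `genes`, `circs`, `linear`, `de_status`, `responders`,
#'   `genomewide_avg_ratio`, `qpcr`, `targets`, `config`, `paths`
#' @export
generate_bundle <- function(config, out_dir) {
  assert_that(inherits(config, "synth_config"), "config must be a synth_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(out_dir), "cannot create output directory ", out_dir)
  set.seed(config$seed)
  world <- sample_world(config)

  paths <- list(
    annotation = file.path(out_dir, "annotation.gtf"),
    circ_calls = file.path(out_dir, "circ_calls.tsv"),
    linear_quant = file.path(out_dir, "linear_quant.tsv"),
    known_db = file.path(out_dir, "known_db.bed"),
    qpcr = file.path(out_dir, "qpcr.tsv"),
    truth = file.path(out_dir, "truth.json"))

  write_gtf(world$genes, paths$annotation)
  write_tsv(data.frame(chrom = world$circs$chrom, start = world$circs$start,
                       end = world$circs$end, strand = world$circs$strand,
                       count = world$circs$read_count),
            paths$circ_calls)
  write_tsv(world$linear, paths$linear_quant)

  known <- world$circs[!is.na(world$circs$known_id), , drop = FALSE]
  # 20 decoy database entries at shifted coordinates (never exact matches)
  decoy_n <- min(20L, nrow(known))
  decoys <- if (decoy_n > 0L) {
    d <- known[seq_len(decoy_n), , drop = FALSE]
    d$start <- d$start + 12345L; d$end <- d$end + 12345L
    d$known_id <- sprintf("hsa_circ_9%06d", seq_len(decoy_n))
    d
  } else known[0, ]
  db <- rbind(known, decoys)
  bed <- data.frame(db$chrom, db$start - 1L, db$end, db$known_id,
                    rep(0L, nrow(db)), db$strand)
  write_tsv(bed, paths$known_db, col.names = FALSE)

  if (!is.null(world$qpcr)) write_tsv(world$qpcr, paths$qpcr)

  paths$de <- list(); paths$targets <- list()
  for (cond in config$conditions) {
    tag <- gsub("[^A-Za-z0-9]+", "_", cond)
    de_path <- file.path(out_dir, paste0("de_", tag, ".tsv"))
    st <- world$de_status[[cond]]
    write_tsv(data.frame(circ_id = st$circ_id, log2FoldChange = st$log2fc,
                         pvalue = signif(st$pvalue, 6),
                         padj = signif(st$padj, 6)),
              de_path)
    tg_path <- file.path(out_dir, paste0("targets_", tag, ".txt"))
    writeLines(world$targets[[cond]], tg_path)
    paths$de[[cond]] <- de_path
    paths$targets[[cond]] <- tg_path
  }

  gene_tab <- world$genes[, setdiff(names(world$genes), "exons")]
  class(gene_tab) <- "data.frame"
  truth <- structure(list(
    genes = gene_tab,
    circs = world$circs,
    linear = world$linear,
    de_status = world$de_status,
    qpcr = world$qpcr,
    targets = world$targets,
    responders = world$responders,
    genomewide_avg_ratio = world$genomewide_avg_ratio,
    config = unclass(config),
    paths = paths), class = "synth_truth")

  truth_json <- unclass(truth)
  truth_json$paths <- lapply(paths, function(p) {
    if (is.list(p)) lapply(p, basename) else basename(p)
  })
  write_json_file(truth_json, paths$truth)
  invisible(truth)
}

#' Catalog summary computed directly from ground truth
#'
#' Independent of the file-parsing pipeline: counts are taken from the truth
#' tables of a [generate_bundle()] run. Used to verify truth round-trips.
#'
#' @param truth a `synth_truth`
#' @param read_threshold,fold_window as in [summarize_catalog()]
#' @return a `catalog_summary` list
#' @export
truth_catalog_summary <- function(truth, read_threshold = 50L, fold_window = 2) {
  circs <- truth$circs
  lin <- stats::setNames(truth$linear$abundance, truth$linear$gene_id)
  gene_bt <- stats::setNames(truth$genes$biotype, truth$genes$gene_id)
  has <- !is.na(circs$host_gene_id) & circs$host_gene_id %in% names(lin)
  n_higher <- if (any(has)) {
    sum(classify_circ_vs_linear(circs$read_count[has],
                                lin[circs$host_gene_id[has]],
                                fold_window) == "higher")
  } else 0L
  structure(list(
    n_total = nrow(circs),
    n_known = sum(!is.na(circs$known_id)),
    n_in_protein_coding = sum(!is.na(circs$host_gene_id) &
                                gene_bt[circs$host_gene_id] == "protein_coding",
                              na.rm = TRUE),
    n_over_read_threshold = sum(circs$read_count > read_threshold),
    read_threshold = as.integer(read_threshold),
    n_more_abundant_than_linear = n_higher), class = "catalog_summary")
}

#' Multiplicity distribution computed directly from ground truth
#'
#' @param truth a `synth_truth`
#' @return data frame with columns `k`, `n_genes`
#' @export
truth_multiplicity <- function(truth) {
  hosted <- truth$circs[!is.na(truth$circs$host_gene_id), ]
  per_gene <- table(hosted$host_gene_id)
  dist <- table(as.integer(per_gene))
  tab <- data.frame(k = as.integer(names(dist)), n_genes = as.integer(dist))
  tab[order(tab$k), , drop = FALSE]
}

#' Recurrent responders computed directly from ground truth
#'
#' A host gene is a truth-level responder when, in every condition, at least
#' one of its circRNAs has planted status `up` or `down`.
#'
#' @param truth a `synth_truth`
#' @return sorted character vector of gene ids
#' @export
truth_responders <- function(truth) {
  per_cond <- lapply(truth$de_status, function(st) {
    sig <- st$circ_id[st$status != "stable"]
    hosts <- truth$circs$host_gene_id[match(sig, truth$circs$circ_id)]
    unique(hosts[!is.na(hosts)])
  })
  sort(Reduce(intersect, per_cond))
}

#' Fast in-memory simulation of the ratio-index experiment
#'
#' Generates only what [ratio_enrichment()] consumes: a gene table with
#' length/exon ratios, a catalog of hosted circRNAs, and a DE table with a
#' planted per-ratio-class upregulation probability. No recurrent responders
#' are planted, isolating the enrichment signal. Intended for power and
#' type-I calibration loops.
#'
#' @param n_circ number of circRNAs (default 500)
#' @param p_up_low,p_up_high planted upregulation probabilities for circRNAs
#'   of low- and high-ratio host genes
#' @param p_down planted downregulation probability
#' @param gene_length_median,gene_length_sigma,exon_count_mean gene model
#' @param seed optional RNG seed
#' @return list with `catalog`, `genes`, `de`, and `truth`
#'   (`low_ratio`, `status`, `avg_ratio`, `p_up_low`, `p_up_high`)
#' @export
simulate_ratio_experiment <- function(n_circ = 500L, p_up_low = 0.30,
                                      p_up_high = 0.05, p_down = 0.05,
                                      gene_length_median = 20000,
                                      gene_length_sigma = 1.0,
                                      exon_count_mean = 9,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_genes <- max(2L, ceiling(n_circ * 0.75))
  L <- pmax(500L, as.integer(round(stats::rlnorm(
    n_genes, log(gene_length_median), gene_length_sigma))))
  k <- pmin(stats::rgeom(n_genes, 1 / exon_count_mean) + 1L,
            pmax(1L, L %/% 120L))
  genes <- data.frame(gene_id = sprintf("SGENE%05d", seq_len(n_genes)),
                      genomic_length = L, exon_count = k, ratio = L / k,
                      stringsAsFactors = FALSE)
  host <- sample.int(n_genes, n_circ, replace = TRUE)
  catalog <- data.frame(
    circ_id = sprintf("SCIRC%05d", seq_len(n_circ)),
    chrom = "chr1", start = seq_len(n_circ) * 10L,
    end = seq_len(n_circ) * 10L + 5L, strand = "+",
    read_count = 1L, host_gene_id = genes$gene_id[host],
    stringsAsFactors = FALSE)
  class(catalog) <- c("circ_catalog", "data.frame")
  avg <- mean(genes$ratio[unique(host)])
  low <- genes$ratio[host] < avg
  de <- sample_condition_de(catalog$circ_id,
                            p_up = ifelse(low, p_up_low, p_up_high),
                            p_down = p_down, alpha = 0.05,
                            force_sig = rep(FALSE, n_circ))
  de_tab <- de[, c("circ_id", "log2fc", "pvalue", "padj")]
  attr(de_tab, "condition") <- "simulated"
  class(de_tab) <- c("de_table", "data.frame")
  list(catalog = catalog, genes = genes, de = de_tab,
       truth = list(low_ratio = low, status = de$status, avg_ratio = avg,
                    p_up_low = p_up_low, p_up_high = p_up_high))
}

#' Check recovery of a planted enrichment effect
#'
#' Compares an [ratio_enrichment()] result against the planted truth: does
#' the sign of `avg_ratio_overexpressed - avg_ratio_stable` match the planted
#' direction, and is the association significant at `alpha`?
#'
#' @param truth either a `synth_truth` from [generate_bundle()] or the
#'   `truth` element of [simulate_ratio_experiment()]
#' @param result an `enrichment_result`
#' @param alpha significance level
#' @return list with `expected_sign`, `observed_sign`, `sign_matches`,
#'   `detected`, `p_value`
#' @export
planted_enrichment_check <- function(truth, result, alpha = 0.05) {
  assert_that(inherits(result, "enrichment_result"),
              "result must be an enrichment_result")
  if (inherits(truth, "synth_truth")) {
    assert_that(result$condition %in% truth$config$conditions,
                "enrichment result condition '", result$condition,
                "' not among the truth's conditions",
                class = "circkit_validation_error")
    p_low <- truth$config$p_up_low_ratio
    p_high <- truth$config$p_up_high_ratio
  } else {
    p_low <- truth$p_up_low
    p_high <- truth$p_up_high
  }
  expected_sign <- -sign(p_low - p_high)
  observed_sign <- sign(result$avg_ratio_overexpressed -
                          result$avg_ratio_stable)
  list(expected_sign = expected_sign, observed_sign = observed_sign,
       sign_matches = if (expected_sign == 0) NA else
         identical(expected_sign, observed_sign),
       detected = result$p_value < alpha,
       p_value = result$p_value)
}
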