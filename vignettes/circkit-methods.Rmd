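---
title: "circkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the choices
made where the design was genuinely open, and what its tests do and do not
establish. Every number quoted here is computed by the test suite or shown in
the README's worked example; nothing is asserted that the code does not
verify.

## The analysis model

A circRNA is identified with its back-splice junction: chromosome, 1-based
inclusive start/end, and strand. All coordinates are handled internally as
1-based inclusive; BED inputs (known database, BED-dialect calls) are 0-based
half-open and converted on load, and DCC coordinate tables are read with
0-based starts per the build contract for that dialect. Duplicate junctions
are collapsed by summing read counts, which conserves the total.

**Gene models.** A gene is reduced to its span, biotype, and the *union* of
all its transcripts' exons (merged, with bookended intervals joined). Two
conventions had to be fixed because upstream definitions are loose:

- *Exon count* is the number of union exon intervals across all transcripts,
  not any single transcript's count. This is transcript-model independent and
  reproducible from any GTF.
- *Genomic length* is the gene-feature span `end - start + 1`, not the sum of
  exon lengths — the ratio index deliberately contrasts genomic extent
  (intron-inclusive) with exon structure.

Genes without a biotype attribute default to `"unknown"`; they stay in the
catalog but do not count as protein-coding.

**Host assignment.** A gene hosts a junction when its span fully contains the
junction interval, with strand agreement when the record strand is known
(`.` matches either). Containment, rather than any partial-overlap rule, was
chosen because exonic back-splice junctions lie within the gene body and
partial overlaps are ambiguous. Ties (nested or overlapping genes) are broken
by (1) larger reciprocal overlap between the gene's union exons and the
junction interval — computed as `min(I/len_circle, I/len_exon_union)` with
`I` the intersection length, the usual symmetric-coverage definition — then
(2) smaller genomic length, then (3) lexicographic gene id. The ordering is
total, so assignment is deterministic.

**Spliced length** is the summed intersection of the host's union exons with
the junction interval. Fully intronic circles (zero exon overlap) and
intergenic circles fall back to the genomic span; the observed length
distribution of real catalogs, which reaches beyond 15 kb, is consistent with
span-based values for part of the records, and no exon model exists for such
circles anyway.

**Known/novel.** A database entry matches when both coordinates agree within
a `tolerance` (default 0 nt) on the same chromosome with compatible strand.
The tolerance is exposed because public databases were built on multiple
annotation releases and callers differ by a nucleotide in junction
conventions.

**Circular vs linear.** With pseudocount 1 on both sides,
`r = (circ + 1) / (linear + 1)` against a symmetric window `w` (default 2):
`r > w` higher, `r < 1/w` lower, else "approximately equal". The window is a
parameter because "approximately equal" has no standard definition; the
pseudocount guards zero-abundance genes. Counts are compared on the raw
read-count scale without length normalization — a documented limitation, as
junction reads and transcript-level estimates have different length biases.

**Spearman correlation.** rho is the Pearson correlation of mid-ranks. For
`n <= 10` without ties the two-sided p-value is exact: the permutation null
of rho over all `n!` rank assignments, enumerated via the distribution of
`S = sum(i * pi(i))` with a subset dynamic program (1024 x 386 states at
n = 10, exact to the last permutation). With ties and `n <= 7` the package
enumerates all `n!` permutations of the tied mid-ranks directly; with ties
and `8 <= n <= 10` it falls back to the t approximation, because the
sum-of-products program requires integer ranks. For `n > 10`,
`t = rho * sqrt((n-2)/(1-rho^2))` with `n - 2` df; at `|rho| = 1` the most
extreme enumerable bin `2/n!` is returned instead of dividing by zero. The
acceptance suite checks the exact branch against an independent brute-force
enumeration (Heap's algorithm) for every achievable rho at `n <= 7`.

**The ratio index.** For host gene `g`, `R(g) = genomic_length / exon_count`
(nt per exon). The genome-wide average defaults to the mean over the
catalog's host genes, each counted once; an all-genes scope is available.
The host-genes default follows from the observation that published
stable-group averages sit near the implied threshold, suggesting the
original average was taken over the assessed pool. Each assessable circRNA
(hosted, with a DE row) is cross-classified by `R(host) < mean R` and by
upregulation (`padj < alpha`, `log2fc > lfc_min`; NA/NaN `padj` is
non-significant), and the 2x2 table is tested with Pearson's chi-squared,
df = 1. The continuity correction defaults off, matching a bare "chi-squared
test"; it is available by flag. For severely unbalanced groups an optional
label-permutation p-value (seeded, `n_perm` resamples of the upregulation
labels) is provided, since no specific "multiple random test" procedure is
standard. Group mean ratios are reported per circRNA record (not per unique
gene), mirroring how the published group averages are labelled ("...of
overexpressed circRNAs").

**Recurrent responders** are host genes with at least one significantly
altered circRNA (`padj < alpha`, either direction) in *every* condition. The
operation takes the catalog explicitly because the circ-to-host map is not
part of a DE table.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `read_threshold` | 50 | reads | the conventional "more than 50 reads" catalog row; strict `>` |
| `fold_window` | 2 | fold | symmetric, conventional definition of "approximately equal" |
| `pseudocount` | 1 | reads | guards zeros; negligible for counts >> 1 |
| `alpha` | 0.05 | — | the upstream DE tool's customary threshold |
| `lfc_min` | 0 | log2 fold | "upregulated" = any positive significant change |
| `tolerance` | 0 | nt | exact database matching unless relaxed |
| `continuity` | FALSE | — | bare Pearson chi-squared by default |
| `average_scope` | host_genes | — | see above |

## The synthetic world

`generate_bundle()` emits a complete input bundle from one seed, with the
truth recorded alongside. Its defaults are the stated world and are not
tuned per run:

- ~1000 genes on 22 chromosomes, gene counts decaying across chromosomes;
  genomic lengths log-normal (median 20 kb, log-sd 1), union exon counts
  shifted-geometric (mean 9), intron-dominated layouts (introns receive ~8x
  the slack of exons), 90% protein-coding.
- 70% of genes host circRNAs, with per-gene multiplicity drawn from the
  observed catalog distribution (weights 587:126:32:12:4:2:3:2 for
  k = 1..8). Junctions snap to union-exon boundaries with probability 0.9
  and otherwise fall inside an intron, exercising both spliced-length
  branches; ~2% additional intergenic junctions exercise the unassessed
  path.
- Read counts are NB(mu = 8, size = 0.45), putting ~1.6% of records above 50
  reads — the small minority a real catalog shows (17/1068).
- Host linear abundance is the gene's summed circular reads scaled by
  `2^(-logratio)` with `log2(circ/linear) ~ N(-5, 2.7^2)`, reproducing the
  observed trichotomy shape: the vast majority lower, a few percent equal or
  higher.
- The known database covers a 1055/1068 fraction of junctions at exact
  coordinates, plus decoy entries at shifted coordinates.
- DE tables are generated at the *results* level (log2fc, padj) — the DE
  model itself is out of scope — with planted upregulation probability 0.30
  for circRNAs of low-ratio hosts vs 0.05 for high-ratio hosts per
  condition, 5% planted downregulation, stable padj ~ U(0.05, 1), and four
  planted always-responding host genes.
- qPCR: `delta_ct = 30.8 - 1.63 * log2(count + 1) + N(0, 1.5)`, the line
  implied by the printed 10-point validation table's range.

Identical configs produce byte-identical bundles (tested). What the
generator does **not** emulate: sequence content, read-level noise,
annotation errors, overlapping genes (synthetic gene spans are disjoint per
chromosome, so host assignment is unambiguous by construction — tie-breaks
are tested on hand-built nested fixtures instead), inter-sample variability,
and any dependence of counts on gene structure (deliberately independent, so
the structure-abundance null property can be tested). A green truth
round-trip therefore establishes the pipeline's bookkeeping, not the realism
of any biological effect size.

`simulate_ratio_experiment()` strips the world down to what the enrichment
test consumes (gene ratios, host assignment, DE flags) and plants no
recurrent responders, isolating the enrichment signal for power and
calibration loops; the full generator keeps them, where they add a handful
of ratio-class-independent upregulated records.

## Numerical choices and degenerate inputs

- Exact-p comparisons use an absolute 1e-9 slack when thresholding
  `|rho_perm| >= |rho_obs|`, so float noise cannot flip a permutation count.
- Chi-squared with an empty margin raises a typed degenerate-table error
  naming the margin; `run_enrich()` converts it into a per-condition flag
  without aborting other conditions.
- Fewer than 3 shared qPCR ids, fewer than 4 chromosomes, or fewer than 4
  hosted records raise typed insufficient-data errors.
- Zero rank variance (constant vector) raises a typed
  undefined-correlation error rather than returning NaN.
- `circ_id` is `chrom:start-end` with an ASCII hyphen (the published format
  uses an en dash) and a stripped `chr` prefix, so ids are stable across
  annotation styles.
- Type-I calibration of the enrichment test uses equal upregulation
  probabilities of 0.15 per class, chosen a priori so expected contingency
  cells stay around 20+, where the chi-squared(1) reference is reliable; the
  acceptance band (5% +/- 2 points over 1000 runs) is met without a
  continuity correction.
- The 20-seed truth round-trip in the acceptance suite runs bundles at 400
  genes instead of 1000 to stay well inside the test-time budget; every
  other generator default is untouched, and single-seed tests elsewhere use
  full-size bundles.

## Known limitations

- No transcript-isoform modeling: spliced length uses union exons, which
  overestimates circles built from a subset of overlapping isoform exons.
- No GFF3 input; no circRNA detection or DE fitting (their outputs are this
  package's inputs).
- Circular and linear abundances are compared without length or library-size
  normalization.
- The exact Spearman p with ties is limited to n <= 7; tied samples of 8-10
  get the t approximation.
- Catalog multiplicity is computed over hosted records only; published
  per-gene tables need not sum to the full catalog size, and the package
  makes that scoping explicit rather than reconciling it.
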