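#' Merge 1-based inclusive intervals into a disjoint sorted union
#'
#' Overlapping and bookended intervals (where one ends at `s` and the next
#' starts at `s + 1`) are merged, so the result is sorted, pairwise disjoint
#' and non-adjacent. This is the canonical form used for union exon structures.
#'
#' @param intervals two-column matrix (or coercible) of start/end positions,
#'   1-based inclusive; zero rows allowed
#' @return integer matrix with columns `start`, `end`
#' @export
#' @examples
#' merge_intervals(rbind(c(100, 200), c(150, 300)))
#' merge_intervals(rbind(c(1, 2), c(3, 4)))  # bookended -> one interval
merge_intervals <- function(intervals) {
  m <- as.matrix(intervals)
  if (length(m) == 0L || nrow(m) == 0L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  assert_that(ncol(m) == 2L, "intervals must have two columns (start, end)")
  storage.mode(m) <- "integer"
  assert_that(!anyNA(m), "intervals contain NA coordinates")
  assert_that(all(m[, 1] <= m[, 2]),
              "invalid interval: start > end", class = "circkit_validation_error")
  r <- IRanges::reduce(IRanges::IRanges(start = m[, 1], end = m[, 2]))
  cbind(start = IRanges::start(r), end = IRanges::end(r))
}

# Total overlap (in nucleotides, 1-based inclusive) between the interval
# [s, e] and a set of disjoint intervals given as a 2-column matrix.
interval_intersection_length <- function(exons, s, e) {
  if (is.null(exons) || nrow(exons) == 0L) return(0L)
  sum(pmax(0L, pmin(exons[, 2], e) - pmax(exons[, 1], s) + 1L))
}
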