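# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ck <- function(..., class = "circkit_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' @noRd
assert_that <- function(ok, ..., class = "circkit_error") {
  if (!isTRUE(ok)) stop_ck(..., class = class)
  invisible(TRUE)
}

#' Build the catalog identifier of a back-splice junction
#'
#' Identifiers follow the `chrom:start-end` convention (a leading `chr` prefix
#' is dropped so that `chr14` and `14` inputs produce the same id).
#'
#' @param chrom chromosome name(s)
#' @param start,end 1-based inclusive junction coordinates
#' @return character vector of identifiers
#' @export
#' @examples
#' make_circ_id("chr14", 90404455, 90404514)
make_circ_id <- function(chrom, start, end) {
  sprintf("%s:%d-%d", sub("^chr", "", as.character(chrom)),
          as.integer(start), as.integer(end))
}

# Deterministic TSV writer (fixed quoting/eol so reruns are byte-identical).
write_tsv <- function(x, path, col.names = TRUE) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names, eol = "\n")
  invisible(path)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

# seed derived from a base seed and a small offset, kept inside 32-bit range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(k) * 7919) %% 2147483647)
}
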