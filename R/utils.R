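#' Reverse-complement character vectors
#'
#' Vectorised reverse complement for plain character DNA sequences.
#' Empty strings are returned unchanged.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- character(length(x))
  nz <- nzchar(x)
  if (any(nz)) {
    out[nz] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x[nz])))
  }
  out
}

## Polynomial string hash in double arithmetic (exact below 2^53).
## Used only to derive per-stage RNG seeds deterministically.
str_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% (2^31 - 1)
  as.integer(h)
}

#' Derive a per-stage seed from a global seed
#'
#' Stable fan-out of one global integer seed into independent stage seeds,
#' kept below 2^31.
#'
#' @param seed global integer seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) + str_hash(stage)) %% (2^31 - 1))
}

## Split equal-width strings into a width x n character matrix.
char_matrix <- function(x, width) {
  if (length(x) == 0L) return(matrix(character(0), nrow = width, ncol = 0))
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = width)
}

## Collapse a width x n character matrix back to n strings (C-level paste0).
collapse_rows <- function(m) {
  if (ncol(m) == 0L) return(character(0))
  do.call(paste0, lapply(seq_len(nrow(m)), function(i) m[i, ]))
}

## Pad strings with trailing '.' to a common width (for char_matrix use).
pad_to <- function(x, width) {
  need <- width - nchar(x)
  paste0(x, strrep(".", pmax(need, 0L)))
}

## Hamming distance between equal-length strings and one reference string.
hamming_to <- function(x, ref) {
  pm <- char_matrix(x, nchar(ref))
  rchars <- strsplit(ref, "", fixed = TRUE)[[1]]
  as.integer(colSums(pm != rchars))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

## Validate a set of intervals against contig lengths (0-based half-open).
check_intervals <- function(iv, contig_len, what = "interval") {
  if (is.null(iv) || nrow(iv) == 0L) return(invisible(TRUE))
  for (i in seq_len(nrow(iv))) {
    ctg <- iv$contig[i]
    if (!ctg %in% names(contig_len))
      stopf("%s %d: unknown contig '%s'", what, i, ctg)
    if (iv$start[i] < 0 || iv$end[i] > contig_len[[ctg]] ||
        iv$start[i] >= iv$end[i])
      stopf("%s '%s' [%d,%d) lies outside contig '%s' (length %d)",
            what, iv$name[i] %||% as.character(i), iv$start[i], iv$end[i],
            ctg, contig_len[[ctg]])
  }
  invisible(TRUE)
}
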