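#' Default in-line barcode set
#'
#' Eight 8-nt in-line barcodes with pairwise Hamming distance of at
#' least 3, so that single-mismatch assignment is unambiguous.
#'
#' @return character vector of 8 barcodes.
#' @export
default_barcodes <- function() {
  c("AAAACTCC", "ATGTGTAA", "CTCCGGAA", "GTAGAATC",
    "TTGCACTC", "GGCCTTTC", "CATATCTC", "GTGAACCC")
}

#' Define a barcode set for demultiplexing
#'
#' In-line barcodes are read as the first bases of R1; dual-index pairs
#' are consumed as pool labels only (index hopping is out of scope).
#' Together, `length(barcodes) * length(index_pairs)` distinct cell
#' labels can be multiplexed; at the defaults (8 barcodes x 768 dual
#' unique index pairs) that is 6,144 cells.
#'
#' @param barcodes character vector of equal-length barcodes.
#' @param max_mismatch maximum Hamming distance for assignment.
#' @param index_pairs character vector of dual-index pair labels.
#' @return object of class `barcode_set`.
#' @export
barcode_set <- function(barcodes = default_barcodes(), max_mismatch = 1L,
                        index_pairs = sprintf("i%03d", 1:768)) {
  stopifnot(length(barcodes) >= 1L, max_mismatch >= 0L)
  if (length(unique(nchar(barcodes))) != 1L)
    stopf("barcodes must all have the same length")
  ## unambiguous assignment requires pairwise distance > 2 * max_mismatch
  if (length(barcodes) > 1L) {
    d <- outer(barcodes, barcodes,
               Vectorize(function(a, b) hamming_to(a, b)))
    mind <- min(d[upper.tri(d)])
    if (mind <= 2L * max_mismatch)
      stopf(paste0("barcode set rejected: minimum pairwise Hamming ",
                   "distance %d is not > 2*max_mismatch = %d"),
            mind, 2L * max_mismatch)
  }
  structure(list(barcodes = barcodes, max_mismatch = as.integer(max_mismatch),
                 index_pairs = index_pairs,
                 barcode_length = nchar(barcodes[1])),
            class = "barcode_set")
}

#' Distinct multiplexable cell labels
#'
#' @param bs a [barcode_set()].
#' @return character vector of `barcodes x index_pairs` combined labels.
#' @export
cell_labels <- function(bs = barcode_set()) {
  as.vector(outer(bs$barcodes, bs$index_pairs,
                  function(b, i) paste(i, b, sep = ":")))
}

#' Demultiplex read pairs by in-line barcode
#'
#' Assigns each pair to the unique barcode within `max_mismatch` of the
#' R1 prefix (else `"unassigned"`), and removes the barcode bases from
#' R1. Assignment is a partition: counts sum to the input pair count.
#'
#' @param reads data.table/data.frame with columns `pair_id`, `r1`, `r2`
#'   (one sequencing pool's reads).
#' @param bs a [barcode_set()].
#' @return list with `reads` (assigned pairs, barcode stripped, with a
#'   `barcode` column), `unassigned` (pairs left untouched) and `counts`
#'   (data.table of pair counts per barcode incl. unassigned).
#' @export
demultiplex <- function(reads, bs = barcode_set()) {
  reads <- as.data.table(reads)
  blen <- bs$barcode_length
  n <- nrow(reads)
  counts <- data.table(barcode = c(bs$barcodes, "unassigned"),
                       n = 0L)
  if (n == 0L) {
    return(list(reads = reads[, c("pair_id", "r1", "r2"), with = FALSE][
                  , barcode := character(0)][],
                unassigned = reads, counts = counts))
  }
  if (any(nchar(reads$r1) < blen))
    stopf("R1 reads shorter than the barcode length %d", blen)
  prefix <- substr(reads$r1, 1L, blen)
  dmat <- vapply(bs$barcodes, function(b) hamming_to(prefix, b),
                 integer(n))
  if (is.null(dim(dmat))) dmat <- matrix(dmat, nrow = 1L)
  best <- max.col(-dmat, ties.method = "first")
  bestd <- dmat[cbind(seq_len(n), best)]
  ok <- bestd <= bs$max_mismatch
  assigned <- reads[ok]
  assigned[, barcode := bs$barcodes[best[ok]]]
  assigned[, r1 := substr(r1, blen + 1L, nchar(r1))]
  tab <- table(factor(bs$barcodes[best[ok]], levels = bs$barcodes))
  counts$n <- c(as.integer(tab), sum(!ok))
  list(reads = assigned[], unassigned = reads[!ok], counts = counts)
}

#' Trimming policy
#'
#' Controls adapter removal, R2 Adaptase-tail detection, fixed end trims
#' (16 bp from both ends of both reads by default, the standard trimming
#' for these libraries), and the insert-length cutoff below which a pair
#' is classified as adapter dimer / short insert.
#'
#' @param fixed_5p_r1,fixed_3p_r1,fixed_5p_r2,fixed_3p_r2 fixed trims
#'   (bp) applied after adapter and tail removal.
#' @param r2_extra_5p additional R2 5' trim (bp) for libraries whose
#'   tails defeat fixed trimming; default 0.
#' @param adapter_r1,adapter_r2 adapter sequences removed from 3' ends.
#' @param min_insert pairs with less than this much insert remaining
#'   after adapter removal are classified `dimer_or_short`.
#' @param detect_tail logical: detect and remove the low-complexity R2
#'   5' tail.
#' @param tail_alphabet the two bases the tail is made of, as observed
#'   on R2 (default G/T, the complement of an A/C tailed strand).
#' @param tail_max maximum tail length considered (bp).
#' @return object of class `trim_policy`.
#' @export
trim_policy <- function(fixed_5p_r1 = 16L, fixed_3p_r1 = 16L,
                        fixed_5p_r2 = 16L, fixed_3p_r2 = 16L,
                        r2_extra_5p = 0L,
                        adapter_r1 = ADAPTER_R1, adapter_r2 = ADAPTER_R2,
                        min_insert = 30L, detect_tail = TRUE,
                        tail_alphabet = c("G", "T"), tail_max = 50L) {
  p <- as.list(environment())
  lens <- c(fixed_5p_r1, fixed_3p_r1, fixed_5p_r2, fixed_3p_r2,
            r2_extra_5p)
  if (any(lens < 0L)) stopf("trim lengths must be >= 0")
  if (min_insert < 1L) stopf("min_insert must be >= 1")
  structure(p, class = "trim_policy")
}

## Position of the earliest adapter occurrence (1-based; NA if none).
## Exact matching: a 12-mer adapter prefix anywhere, or a terminal
## overlap of 5-11 bases.
adapter_position <- function(reads, adapter) {
  probe <- substr(adapter, 1L, 12L)
  at <- regexpr(probe, reads, fixed = TRUE)
  at <- ifelse(at > 0L, as.integer(at), NA_integer_)
  len <- nchar(reads)
  for (k in 11:5) {
    pre <- substr(adapter, 1L, k)
    hit <- is.na(at) & len >= k & endsWith(reads, pre)
    at[hit] <- len[hit] - k + 1L
  }
  at
}

## Low-complexity tail detector: greedy scan of the R2 prefix. In-alphabet
## bases extend the tail; an out-of-alphabet base (a sequencing error
## inside the tail, or the start of genomic sequence) is absorbed only
## when the cumulative in-alphabet fraction stays >= 0.9 AND the next
## five bases are all in-alphabet (clear evidence the tail continues);
## otherwise the scan stops and the tail is trimmed back to the last
## in-alphabet position. Capped at tail_max. Returns lengths per read.
detect_tail_len <- function(r2, alphabet, tail_max) {
  n <- length(r2)
  if (n == 0L) return(integer(0))
  W <- min(tail_max, max(nchar(r2)))
  K <- 5L
  m <- char_matrix(pad_to(substr(r2, 1L, W + K), W + K), W + K)
  inab <- matrix(m %in% alphabet, nrow = W + K)
  valid <- matrix(seq_len(W + K), W + K, n) <=
    rep(pmin(nchar(r2), W + K), each = W + K)
  inab <- inab & valid
  runk <- matrix(TRUE, W, n)        # runk[i,]: i..i+K-1 all in-alphabet
  for (d in 0L:(K - 1L)) runk <- runk & inab[seq_len(W) + d, , drop = FALSE]
  tl <- integer(n)
  cnt <- numeric(n)       # in-alphabet count so far
  alive <- rep(TRUE, n)   # still scanning
  for (i in seq_len(W)) {
    hit <- inab[i, ]
    cnt <- cnt + hit
    absorb <- !hit & (cnt / i) >= 0.9 &
      (if (i < W) runk[i + 1L, ] else FALSE)
    stop_now <- alive & ((!hit & !absorb) | !valid[i, ])
    alive <- alive & !stop_now
    tl[alive & hit] <- i
  }
  tl
}

#' Trim read pairs
#'
#' Removes adapter read-through from 3' ends (exact overlap match),
#' detects and removes the low-complexity Adaptase tail from R2 5' ends,
#' applies the fixed end trims, and classifies each pair: pairs whose
#' remaining insert (R1 length after adapter removal) is shorter than
#' `min_insert` are `dimer_or_short`, the rest `keep`. Trimming never
#' produces negative lengths and never increases a read's length.
#'
#' @param reads data.table with columns `pair_id`, `r1`, `r2` (R1
#'   barcode already removed by [demultiplex()]).
#' @param policy a [trim_policy()].
#' @return data.table: input columns plus trimmed `r1`, `r2`,
#'   `tail_len`, and `trim_class` (`"keep"` or `"dimer_or_short"`).
#' @export
trim_reads <- function(reads, policy = trim_policy()) {
  reads <- as.data.table(reads)
  out <- copy(reads)
  if (nrow(out) == 0L) {
    out[, `:=`(tail_len = integer(0), trim_class = character(0))]
    return(out[])
  }
  if (any(nchar(out$r1) == 0L | nchar(out$r2) == 0L))
    stopf("reads must be non-empty")
  ## 3' adapter removal
  a1 <- adapter_position(out$r1, policy$adapter_r1)
  out[!is.na(a1), r1 := substr(r1, 1L, a1[!is.na(a1)] - 1L)]
  a2 <- adapter_position(out$r2, policy$adapter_r2)
  out[!is.na(a2), r2 := substr(r2, 1L, a2[!is.na(a2)] - 1L)]
  insert_est <- nchar(out$r1)
  ## R2 5' tail
  if (policy$detect_tail) {
    tl <- detect_tail_len(out$r2, policy$tail_alphabet, policy$tail_max)
  } else {
    tl <- integer(nrow(out))
  }
  out[, tail_len := tl]
  out[, r2 := substr(r2, tail_len + 1L, nchar(r2))]
  ## fixed trims
  out[, r1 := substr(r1, policy$fixed_5p_r1 + 1L,
                     pmax(nchar(r1) - policy$fixed_3p_r1, 0L))]
  r2_5p <- policy$fixed_5p_r2 + policy$r2_extra_5p
  out[, r2 := substr(r2, r2_5p + 1L,
                     pmax(nchar(r2) - policy$fixed_3p_r2, 0L))]
  out[, trim_class := ifelse(insert_est < policy$min_insert,
                             "dimer_or_short", "keep")]
  out[]
}

#' Trim a single read pair
#'
#' Convenience wrapper around [trim_reads()] for one pair.
#'
#' @param r1,r2 character scalars.
#' @param policy a [trim_policy()].
#' @return list with `r1`, `r2`, `tail_len`, `class`.
#' @export
trim_pair <- function(r1, r2, policy = trim_policy()) {
  res <- trim_reads(data.table(pair_id = "pair", r1 = r1, r2 = r2), policy)
  list(r1 = res$r1, r2 = res$r2, tail_len = res$tail_len,
       class = res$trim_class)
}

#' Per-position base composition profile
#'
#' Exact base frequencies at each read position over all reads; reads
#' shorter than a position are excluded from that position's denominator.
#'
#' @param reads character vector of read sequences.
#' @param positions number of positions to profile.
#' @return data.table with columns `pos`, `A`, `C`, `G`, `T`, `N`, `n`
#'   (denominator); zero rows (flagged via attribute `empty`) on empty
#'   input.
#' @export
composition_profile <- function(reads, positions = 30L) {
  stopifnot(positions >= 1L)
  if (length(reads) == 0L) {
    out <- data.table(pos = integer(0), A = numeric(0), C = numeric(0),
                      G = numeric(0), T = numeric(0), N = numeric(0),
                      n = integer(0))
    attr(out, "empty") <- TRUE
    return(out)
  }
  W <- min(positions, max(nchar(reads)))
  m <- char_matrix(pad_to(substr(reads, 1L, W), W), W)
  len <- nchar(reads)
  rows <- lapply(seq_len(W), function(i) {
    use <- m[i, len >= i]
    nn <- length(use)
    freq <- vapply(c("A", "C", "G", "T", "N"),
                   function(b) sum(use == b) / nn, numeric(1))
    data.table(pos = i, A = freq[["A"]], C = freq[["C"]], G = freq[["G"]],
               T = freq[["T"]], N = freq[["N"]], n = nn)
  })
  out <- rbindlist(rows)
  attr(out, "empty") <- FALSE
  out
}

#' Expected post-bisulfite read composition
#'
#' Closed-form expectation of the C and T frequencies of bisulfite
#' sequencing reads: with cytosine fraction `f_c`, thymine fraction
#' `f_t`, methylated fraction of cytosine basecalls `m_bar` and
#' conversion rate `conversion_rate`,
#' `expected_c = f_c * (m_bar + (1 - m_bar) * (1 - conversion_rate))`
#' and `expected_t = f_t + f_c * (1 - m_bar) * conversion_rate`. In
#' mammalian neurons this works out to roughly 1% C and ~50% T; an
#' elevated C frequency at R2 starts is the signature of dNTP-carryover
#' contamination.
#'
#' @param f_c,f_t base fractions of the read strand.
#' @param m_bar methylated fraction of cytosine basecalls.
#' @param conversion_rate bisulfite conversion rate.
#' @return list with `expected_c` and `expected_t`.
#' @export
expected_composition <- function(f_c, f_t, m_bar, conversion_rate) {
  stopifnot(f_c >= 0, f_t >= 0, m_bar >= 0, m_bar <= 1,
            conversion_rate >= 0, conversion_rate <= 1)
  list(expected_c = f_c * (m_bar + (1 - m_bar) * (1 - conversion_rate)),
       expected_t = f_t + f_c * (1 - m_bar) * conversion_rate)
}

#' Composition anomaly flag
#'
#' Flags a profile whose maximum C frequency over the first `k`
#' positions exceeds the model expectation by more than `margin`
#' (default 0.02), separating the contaminated from the clean regime
#' with margin to spare.
#'
#' @param profile a [composition_profile()].
#' @param expected_c model-expected C frequency.
#' @param k positions to scan.
#' @param margin tolerance above `expected_c`.
#' @return logical flag.
#' @export
composition_anomaly <- function(profile, expected_c, k = 10L,
                                margin = 0.02) {
  if (nrow(profile) == 0L) return(NA)
  max(profile$C[profile$pos <= k]) > expected_c + margin
}
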