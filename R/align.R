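#' Build a three-letter (bisulfite-converted) k-mer index
#'
#' Indexes two converted reference frames for seed-and-extend alignment:
#' the genome with C collapsed to T (CT frame, matching reads that carry
#' the C-to-T signature of their source strand) and with G collapsed to A
#' (GA frame). Every position of length >= k is indexed in both frames;
#' k-mers are packed 2 bits/base into doubles for compact exact lookup.
#'
#' @param genome an `snmc_genome`.
#' @param k seed length (bp), default 16.
#' @return object of class `converted_index`.
#' @export
converted_index <- function(genome, k = 16L) {
  stopifnot(inherits(genome, "snmc_genome"), k >= 8L, k <= 24L)
  conv <- list(
    CT = vapply(genome$sequences, function(s) chartr("C", "T", s), ""),
    GA = vapply(genome$sequences, function(s) chartr("G", "A", s), ""))
  idx <- lapply(conv, function(frameseqs) {
    tabs <- lapply(names(frameseqs), function(ctg) {
      keys <- kmer_keys(frameseqs[[ctg]], k)
      data.table(kmer = keys, ctg = ctg, hit_pos = seq_along(keys))
    })
    tab <- rbindlist(tabs)
    setkey(tab, kmer)
    tab
  })
  structure(list(genome = genome, conv = conv, tables = idx, k = k),
            class = "converted_index")
}

#' @export
print.converted_index <- function(x, ...) {
  cat("converted_index: k =", x$k, "over",
      nrow(x$genome$contigs), "contig(s),",
      nrow(x$tables$CT), "positions per frame\n")
  invisible(x)
}

## 2-bit packed k-mer keys over all start positions of a sequence
## (numeric; exact since 4^k <= 2^48 for k <= 24). N maps to A: harmless,
## seed hits are verified by extension.
kmer_keys <- function(s, k) {
  b <- utf8ToInt(s)
  code <- integer(max(b))
  code[utf8ToInt("A")] <- 0L; code[utf8ToInt("C")] <- 1L
  code[utf8ToInt("G")] <- 2L; code[utf8ToInt("T")] <- 3L
  v <- code[b]
  n <- length(v) - k + 1L
  if (n < 1L) return(numeric(0))
  key <- numeric(n)
  for (i in 0:(k - 1L)) key <- key + v[(1L + i):(n + i)] * 4^(k - 1L - i)
  key
}

#' Align reads with three-letter seed-and-extend
#'
#' Each read is converted to its bisulfite frame (R1: C collapsed to T;
#' R2: G collapsed to A) and looked up, together with its reverse
#' complement, against the matching converted reference frame by exact
#' k-mer seeds at non-overlapping offsets, then extended without gaps
#' over the full read length. The best-scoring locus is reported with
#' `score = matches - mismatches` and
#' `mapq = min(60, 2 * (best - second_best))` (`second_best = 0` for a
#' unique locus; ties give mapq 0). Loci with mismatch fraction above
#' `max_mismatch_frac` are discarded; reads with no surviving locus are
#' unmapped and absent from the result.
#'
#' @param reads data.table with columns `pair_id`, `seq`, `mate`
#'   (1 or 2), and optionally `cell`. See [reads_long()] for building
#'   this from a trimmed library.
#' @param index a [converted_index()].
#' @param max_mismatch_frac maximum tolerated mismatch fraction.
#' @return data.table of hits: `pair_id`, `mate`, `cell`, `ctg`,
#'   `start0` (0-based), `strand` (+/-), `frame` (CT/GA), `qlen`,
#'   `score`, `mm`, `mapq`, `oriented` (read sequence in genome-forward
#'   orientation).
#' @export
align_reads <- function(reads, index, max_mismatch_frac = 0.1) {
  stopifnot(inherits(index, "converted_index"))
  reads <- as.data.table(reads)
  if (!"cell" %in% names(reads)) reads[, cell := NA_character_]
  k <- index$k
  reads <- reads[nchar(seq) >= k]
  if (nrow(reads) == 0L) return(empty_hits())
  reads[, read_id := .I]

  ## probes: mate 1 -> CT conversion, search CT frame fwd and (as revcomp)
  ## GA frame; mate 2 -> GA conversion, search GA fwd and CT revcomp.
  probes <- rbindlist(list(
    reads[mate == 1L, .(read_id, probe = chartr("C", "T", seq),
                        frame = "CT", orient = "+")],
    reads[mate == 1L, .(read_id, probe = revcomp(chartr("C", "T", seq)),
                        frame = "GA", orient = "-")],
    reads[mate == 2L, .(read_id, probe = chartr("G", "A", seq),
                        frame = "GA", orient = "+")],
    reads[mate == 2L, .(read_id, probe = revcomp(chartr("G", "A", seq)),
                        frame = "CT", orient = "-")]))
  probes[, qlen := nchar(probe)]

  ## seed positions: non-overlapping k-mers plus the final window
  cand <- rbindlist(lapply(c("CT", "GA"), function(fr) {
    pp <- probes[frame == fr]
    if (nrow(pp) == 0L) return(NULL)
    seeds <- pp[, {
      offs <- unique(c(seq.int(1L, qlen - k + 1L, by = k), qlen - k + 1L))
      .(offset = offs, kmer = kmer_keys(probe, k)[offs])
    }, by = .(read_id, orient, qlen)]
    hits <- index$tables[[fr]][seeds, on = "kmer", nomatch = NULL,
                               allow.cartesian = TRUE]
    if (nrow(hits) == 0L) return(NULL)
    hits[, diag0 := hit_pos - offset + 1L]
    hits[, frame := fr]
    unique(hits[, .(read_id, orient, frame, qlen, ctg, diag0)])
  }))
  if (is.null(cand) || nrow(cand) == 0L) return(empty_hits())

  ## clip candidates extending beyond contig ends
  clen <- stats::setNames(index$genome$contigs$length,
                          index$genome$contigs$name)
  cand <- cand[diag0 >= 1L & diag0 + qlen - 1L <= clen[ctg]]
  if (nrow(cand) == 0L) return(empty_hits())

  ## ungapped extension: mismatch counts in converted space
  pid <- paste(cand$read_id, cand$orient, cand$frame)
  qid <- paste(probes$read_id, probes$orient, probes$frame)
  pseq <- probes$probe[match(pid, qid)]
  convmap <- unlist(index$conv)   # names like "CT.chr1"
  rseq <- substring(convmap[paste(cand$frame, cand$ctg, sep = ".")],
                    cand$diag0, cand$diag0 + cand$qlen - 1L)
  cand[, mm := mismatch_count(pseq, rseq)]
  cand <- cand[mm <= max_mismatch_frac * qlen]
  if (nrow(cand) == 0L) return(empty_hits())
  cand[, score := qlen - 2L * mm]

  ## best and second-best locus per read
  setorder(cand, read_id, -score)
  best <- cand[, .(ctg = ctg[1L], diag0 = diag0[1L], orient = orient[1L],
                   frame = frame[1L], qlen = qlen[1L], mm = mm[1L],
                   score = score[1L],
                   second = if (.N > 1L) score[2L] else 0L,
                   tie = .N > 1L && score[2L] == score[1L]),
               by = read_id]
  best[, mapq := ifelse(tie, 0L, pmin(60L, 2L * (score - second)))]

  out <- best[, .(read_id, ctg, start0 = diag0 - 1L, strand = orient,
                  frame, qlen, score, mm, mapq)]
  out[, pair_id := reads$pair_id[read_id]]
  out[, mate := reads$mate[read_id]]
  out[, cell := reads$cell[read_id]]
  out[, oriented := ifelse(strand == "+", reads$seq[read_id],
                           revcomp(reads$seq[read_id]))]
  out[, read_id := NULL]
  setcolorder(out, c("pair_id", "mate", "cell", "ctg", "start0", "strand",
                     "frame", "qlen", "score", "mm", "mapq", "oriented"))
  out[]
}

empty_hits <- function() {
  data.table(pair_id = character(0), mate = integer(0),
             cell = character(0), ctg = character(0), start0 = integer(0),
             strand = character(0), frame = character(0), qlen = integer(0),
             score = integer(0), mm = integer(0), mapq = integer(0),
             oriented = character(0))
}

## Vectorised mismatch count between equal-length string pairs,
## grouped by length so comparisons run on character matrices.
mismatch_count <- function(a, b) {
  stopifnot(length(a) == length(b))
  out <- integer(length(a))
  lens <- nchar(a)
  for (L in unique(lens)) {
    i <- which(lens == L)
    ma <- char_matrix(a[i], L)
    mb <- char_matrix(b[i], L)
    out[i] <- as.integer(colSums(ma != mb))
  }
  out
}

#' Convert a demultiplexed/trimmed library to long read form
#'
#' Reshapes a pair table (columns `pair_id`, `r1`, `r2`, optional
#' `cell`) into the one-row-per-read form that [align_reads()] expects,
#' dropping reads shorter than `min_len`.
#'
#' @param reads pair-level data.table.
#' @param min_len minimum read length to keep.
#' @return data.table with `pair_id`, `mate`, `seq`, `cell`.
#' @export
reads_long <- function(reads, min_len = 1L) {
  reads <- as.data.table(reads)
  if (!"cell" %in% names(reads)) reads[, cell := NA_character_]
  long <- rbindlist(list(
    reads[, .(pair_id, mate = 1L, seq = r1, cell)],
    reads[, .(pair_id, mate = 2L, seq = r2, cell)]))
  long[nchar(seq) >= min_len]
}

#' Filter alignments by mapping quality and collapse clonal reads
#'
#' Retains hits with `mapq > mapq_min` (strict inequality, so a hit at
#' exactly the threshold is removed), then collapses clonal reads --
#' reads from the same cell mapping to the same (contig, start, frame)
#' are PCR duplicates of one molecule -- keeping the highest-scoring
#' representative (ties broken deterministically by pair id).
#'
#' @param hits data.table from [align_reads()].
#' @param mapq_min MAPQ threshold (default 10; hits must exceed it).
#' @param collapse_clonal collapse duplicates (default TRUE).
#' @return filtered hits data.table.
#' @export
filter_alignments <- function(hits, mapq_min = 10L,
                              collapse_clonal = TRUE) {
  out <- as.data.table(hits)[mapq > mapq_min]
  if (collapse_clonal && nrow(out) > 0L) {
    setorder(out, cell, ctg, start0, frame, -score, pair_id, mate)
    out <- unique(out, by = c("cell", "ctg", "start0", "frame"))
  }
  out[]
}

#' Mapping rate by mate
#'
#' @param hits alignment data.table (one row per mapped read).
#' @param input_r1,input_r2 input read counts per mate.
#' @return data.table with rows R1, R2 and combined: mapped, input,
#'   rate (NA when input is zero).
#' @export
mapping_rate <- function(hits, input_r1, input_r2) {
  hits <- as.data.table(hits)
  m1 <- sum(hits$mate == 1L); m2 <- sum(hits$mate == 2L)
  data.table(
    mate = c("R1", "R2", "combined"),
    mapped = c(m1, m2, m1 + m2),
    input = c(input_r1, input_r2, input_r1 + input_r2),
    rate = c(if (input_r1 > 0) m1 / input_r1 else NA_real_,
             if (input_r2 > 0) m2 / input_r2 else NA_real_,
             if (input_r1 + input_r2 > 0) (m1 + m2) / (input_r1 + input_r2)
             else NA_real_))
}

#' Export alignments as SAM text
#'
#' Minimal mandatory-column SAM (header plus one line per hit; flag 0/16
#' for forward/reverse orientation, CIGAR all-match, MAPQ populated,
#' 1-based positions). Written with a plain text writer as no installed
#' package writes SAM records from a table.
#'
#' @param hits alignment data.table.
#' @param genome the `snmc_genome` aligned against.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
export_sam <- function(hits, genome, file) {
  hd <- c("@HD\tVN:1.6\tSO:unknown",
          sprintf("@SQ\tSN:%s\tLN:%d", genome$contigs$name,
                  genome$contigs$length),
          sprintf("@PG\tID:snmcpipe\tPN:snmcpipe\tVN:%s",
                  as.character(utils::packageVersion("snmcpipe"))))
  hits <- as.data.table(hits)
  body <- sprintf("%s/%d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                  hits$pair_id, hits$mate,
                  ifelse(hits$strand == "+", 0L, 16L),
                  hits$ctg, hits$start0 + 1L, hits$mapq, hits$qlen,
                  hits$oriented)
  writeLines(c(hd, body), file)
  invisible(file)
}
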