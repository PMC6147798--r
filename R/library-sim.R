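## Illumina-style adapter sequences seen at read 3' ends on read-through.
ADAPTER_R1 <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"
ADAPTER_R2 <- "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT"

#' Library simulation parameters
#'
#' Parameters of the paired-end post-bisulfite library simulator. The
#' defaults are the bundled study conditions: per-cytosine bisulfite
#' conversion probability 0.995 for unmethylated C, a low-complexity
#' Adaptase tail on R2 5' ends drawn from a geometric distribution with
#' mean 8 bp truncated (renormalised) at 50 bp over a two-letter alphabet
#' (A/C on the tailed strand, observed as G/T at R2 starts), 6% adapter
#' dimers, 10% PCR duplicates, a 1% unmethylated lambda spike-in, and a
#' uniform substitution error rate of 1e-3 applied after conversion.
#'
#' @param conversion_rate probability an unmethylated C reads as T.
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd insert-size distribution (bp, normal,
#'   clamped at 60 bp and the contig length).
#' @param dimer_fraction fraction of pairs that are adapter dimers.
#' @param tail_mean,tail_max Adaptase tail length: geometric mean and
#'   hard maximum (bp).
#' @param tail_alphabet_weights named base weights of the tail on the
#'   tailed strand; default two-letter `c(A = .5, C = .5)`. Use
#'   `c(A = .25, C = .25, G = .25, T = .25)` to emulate dNTP-carryover
#'   contamination (four-letter, high-complexity tails).
#' @param duplicate_rate fraction of pairs that are PCR duplicates of
#'   another pair.
#' @param seq_error_rate uniform substitution error rate per base.
#' @param lambda_spike_fraction fraction of genomic molecules drawn from
#'   the lambda spike-in contig.
#' @param cgi_bias relative over-sampling of fragments starting inside
#'   CGIs (1 = unbiased); models the CGI enrichment of PBAT libraries.
#' @param barcode_length in-line barcode length (bp).
#' @return object of class `library_params`.
#' @export
library_params <- function(conversion_rate = 0.995, read_length = 100L,
                           insert_mean = 250, insert_sd = 50,
                           dimer_fraction = 0.06, tail_mean = 8,
                           tail_max = 50,
                           tail_alphabet_weights = c(A = 0.5, C = 0.5),
                           duplicate_rate = 0.10, seq_error_rate = 0.001,
                           lambda_spike_fraction = 0.01, cgi_bias = 1,
                           barcode_length = 8L) {
  p <- as.list(environment())
  rates <- c(conversion_rate, dimer_fraction, duplicate_rate,
             seq_error_rate, lambda_spike_fraction)
  if (any(rates < 0 | rates > 1)) stopf("all rates must lie in [0,1]")
  if (!(tail_max >= tail_mean && tail_mean >= 0))
    stopf("need tail_max >= tail_mean >= 0")
  if (abs(sum(tail_alphabet_weights) - 1) > 1e-8)
    stopf("tail_alphabet_weights must sum to 1")
  if (!all(names(tail_alphabet_weights) %in% c("A", "C", "G", "T")))
    stopf("tail_alphabet_weights must be named with A/C/G/T")
  structure(p, class = "library_params")
}

#' @export
print.library_params <- function(x, ...) {
  cat(sprintf(paste0(
    "library_params: conversion %.3f, read length %d, insert %g+-%g\n",
    "  tail: geometric mean %g bp, max %g bp, alphabet {%s}\n",
    "  dimers %.3f, duplicates %.3f, lambda %.3f, error %g, CGI bias %g\n"),
    x$conversion_rate, x$read_length, x$insert_mean, x$insert_sd,
    x$tail_mean, x$tail_max,
    paste(names(x$tail_alphabet_weights), collapse = "/"),
    x$dimer_fraction, x$duplicate_rate, x$lambda_spike_fraction,
    x$seq_error_rate, x$cgi_bias))
  invisible(x)
}

## Geometric tail lengths (mean m) truncated at mx by resampling
## (i.e. the renormalised conditional distribution).
rtail <- function(n, m, mx) {
  if (m <= 0) return(integer(n))
  t <- rgeom(n, prob = 1 / (1 + m))
  while (any(bad <- t > mx)) t[bad] <- rgeom(sum(bad), prob = 1 / (1 + m))
  t
}

#' Simulate a paired-end single-cell bisulfite library
#'
#' Emits paired reads reproducing the artifact chemistry of post-bisulfite
#' adapter-tagged libraries. R1 begins with the cell's 8-nt in-line
#' barcode followed by bisulfite-converted genomic sequence; R2 begins
#' with a low-complexity Adaptase tail followed by the converted
#' reverse-complement mate. Both original genomic strands are sampled
#' with equal probability; conversion (unmethylated C to T on the
#' molecule's strand) is applied once per molecule so that overlapping
#' mates agree; PCR duplicates copy a previous molecule (identical
#' coordinates and conversion outcomes, fresh sequencing errors); adapter
#' dimers carry no genomic insert; lambda molecules are fully
#' unmethylated.
#'
#' @param genome an `snmc_genome`.
#' @param methylome an `snmc_methylome` for the same genome (the truth
#'   states that conversion respects).
#' @param params a [library_params()].
#' @param n_pairs number of read pairs to emit.
#' @param cells optional character vector restricting which cells emit
#'   reads (default: all cells in `methylome`).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return object of class `snmc_library` with elements `reads`
#'   (data.table: `pair_id`, `r1`, `r2`, `cell`, `pool`, `barcode`) and
#'   `truth` (one row per pair: source coordinates, strand, tail length,
#'   dimer/duplicate/lambda flags).
#' @export
simulate_library <- function(genome, methylome, params, n_pairs,
                             cells = NULL, seed = 1L) {
  stopifnot(inherits(genome, "snmc_genome"),
            inherits(methylome, "snmc_methylome"),
            inherits(params, "library_params"), n_pairs >= 1)
  cellmeta <- methylome$cells
  if (!is.null(cells)) cellmeta <- cellmeta[cell %in% cells]
  if (nrow(cellmeta) == 0L) stopf("no cells to simulate")
  bad_bc <- setdiff(cellmeta$barcode, default_barcodes())
  if (length(bad_bc))
    stopf("cell barcode(s) not in the configured set: %s",
          paste(bad_bc, collapse = ", "))

  L <- params$read_length
  L1 <- L - params$barcode_length
  clen <- stats::setNames(genome$contigs$length, genome$contigs$name)
  goff <- stats::setNames(c(0, cumsum(as.double(clen)))[seq_along(clen)],
                          names(clen))
  ## site lookup: genomic position -> row of the truth state matrix
  lu <- site_lookup(methylome$sites, clen, goff)
  ad1_fill <- strrep(ADAPTER_R1, ceiling(L / nchar(ADAPTER_R1)))
  ad2_fill <- strrep(ADAPTER_R2, ceiling(L / nchar(ADAPTER_R2)))

  withr::with_seed(seed, {
    n_dup <- rbinom(1L, n_pairs, params$duplicate_rate)
    if (n_dup >= n_pairs) n_dup <- n_pairs - 1L
    n_new <- n_pairs - n_dup

    cell_i <- sample.int(nrow(cellmeta), n_new, replace = TRUE)
    is_dimer <- runif(n_new) < params$dimer_fraction
    has_lambda <- !is.null(genome$lambda_contig)
    is_lambda <- !is_dimer & has_lambda &
      runif(n_new) < params$lambda_spike_fraction

    ## source coordinates for genomic molecules
    auto <- genome$contigs$name
    if (has_lambda) auto <- setdiff(auto, genome$lambda_contig)
    contig <- rep(NA_character_, n_new)
    genomic <- !is_dimer
    n_auto <- sum(genomic & !is_lambda)
    contig[genomic & !is_lambda] <-
      sample(auto, n_auto, replace = TRUE, prob = clen[auto])
    contig[is_lambda] <- genome$lambda_contig

    ins <- as.integer(round(rnorm(n_new, params$insert_mean,
                                  params$insert_sd)))
    ins <- pmax(ins, 60L)
    ins[genomic] <- pmin(ins[genomic], clen[contig[genomic]] - 1L)
    ins[is_dimer] <- 0L
    start <- rep(NA_integer_, n_new)
    start[genomic] <- sample_starts(contig[genomic], ins[genomic], clen,
                                    genome$cgi, params$cgi_bias)
    strand <- sample(c("+", "-"), n_new, replace = TRUE)
    strand[is_dimer] <- NA_character_

    ## converted molecule sequences (genomic molecules only)
    mol <- rep("", n_new)
    gidx <- which(genomic)
    if (length(gidx)) {
      mol[gidx] <- convert_molecules(
        genome, contig[gidx], start[gidx], ins[gidx], strand[gidx],
        cellcol = match(cellmeta$cell[cell_i[gidx]],
                        colnames(methylome$states)),
        states = methylome$states, lu = lu, goff = goff,
        conversion_rate = params$conversion_rate)
    }

    ## Adaptase tails, as observed at R2 starts (complement of the
    ## tail-strand alphabet)
    tl <- rtail(n_new, params$tail_mean, params$tail_max)
    compl <- c(A = "T", C = "G", G = "C", T = "A")
    w2 <- stats::setNames(as.numeric(params$tail_alphabet_weights),
                          compl[names(params$tail_alphabet_weights)])
    tails <- make_tails(tl, w2, params$tail_max)

    ## assemble reads
    r1 <- paste0(cellmeta$barcode[cell_i],
                 substr(paste0(mol, ad1_fill), 1L, L1))
    rcmol <- mol
    rcmol[gidx] <- revcomp(mol[gidx])
    r2 <- substr(paste0(tails, rcmol, ad2_fill), 1L, L)

    ## PCR duplicates copy molecules (reads before sequencing error)
    src <- if (n_dup > 0L) sample.int(n_new, n_dup, replace = TRUE)
           else integer(0)
    all_i <- c(seq_len(n_new), src)
    perm <- sample.int(n_pairs)
    all_i <- all_i[perm]
    is_dup <- c(rep(FALSE, n_new), rep(TRUE, n_dup))[perm]

    r1 <- apply_seq_errors(r1[all_i], params$seq_error_rate)
    r2 <- apply_seq_errors(r2[all_i], params$seq_error_rate)

    pid <- sprintf("SIM%07d", seq_len(n_pairs))
    reads <- data.table(
      pair_id = pid, r1 = r1, r2 = r2,
      cell = cellmeta$cell[cell_i[all_i]],
      pool = cellmeta$pool[cell_i[all_i]],
      barcode = cellmeta$barcode[cell_i[all_i]])
    truth <- data.table(
      pair_id = pid,
      cell = cellmeta$cell[cell_i[all_i]],
      contig = contig[all_i],
      start0 = start[all_i] - 1L,
      insert_len = ins[all_i],
      strand = strand[all_i],
      tail_len = tl[all_i],
      is_dimer = is_dimer[all_i],
      is_duplicate = is_dup,
      is_lambda = is_lambda[all_i])
    structure(list(reads = reads, truth = truth, params = params,
                   cells = cellmeta), class = "snmc_library")
  })
}

#' @export
print.snmc_library <- function(x, ...) {
  cat("snmc_library:", nrow(x$reads), "read pairs from",
      nrow(x$cells), "cell(s)\n")
  cat(sprintf("  dimers %.1f%%, duplicates %.1f%%, lambda %.1f%%, mean tail %.2f bp\n",
              100 * mean(x$truth$is_dimer), 100 * mean(x$truth$is_duplicate),
              100 * mean(x$truth$is_lambda, na.rm = TRUE),
              mean(x$truth$tail_len)))
  invisible(x)
}

## position -> state-matrix row lookup, one slot per (genomic pos, strand)
site_lookup <- function(sites, clen, goff) {
  total <- sum(as.double(clen))
  lu_p <- integer(total); lu_m <- integer(total)
  gpos <- goff[sites$contig] + sites$pos
  plus <- sites$strand == "+"
  lu_p[gpos[plus]] <- sites$site[plus]
  lu_m[gpos[!plus]] <- sites$site[!plus]
  list(p = lu_p, m = lu_m)
}

## Sample fragment start positions (1-based), optionally CGI-biased.
sample_starts <- function(contig, ins, clen, cgi, bias) {
  n <- length(contig)
  maxstart <- clen[contig] - ins + 1L
  start <- as.integer(floor(runif(n) * maxstart)) + 1L
  if (bias > 1 && nrow(cgi) > 0L) {
    lcgi <- stats::setNames(numeric(length(clen)), names(clen))
    agg <- tapply(cgi$end - cgi$start, cgi$contig, sum)
    lcgi[names(agg)] <- agg
    q <- pmin(1, bias * lcgi[contig] / clen[contig])
    pick <- runif(n) < q
    for (i in which(pick)) {
      iv <- cgi[cgi$contig == contig[i], , drop = FALSE]
      if (nrow(iv) == 0L) next
      r <- iv[sample.int(nrow(iv), 1L), ]
      s <- r$start + sample.int(max(r$end - r$start, 1L), 1L)
      start[i] <- min(max(1L, as.integer(s) - ins[i] %/% 2L), maxstart[i])
    }
  }
  start
}

## Bisulfite-convert genomic windows per molecule. Works on the
## genome-forward window; Watson molecules convert unmethylated C -> T,
## Crick molecules (whose cytosines are genome G) convert G -> A. Returns
## the molecule sequence in molecule orientation (5'->3').
convert_molecules <- function(genome, contig, start, len, strand, cellcol,
                              states, lu, goff, conversion_rate) {
  n <- length(contig)
  W <- max(len)
  frag <- substring(genome$sequences[contig], start, start + len - 1L)
  m <- char_matrix(pad_to(frag, W), W)
  rowi <- matrix(seq_len(W), nrow = W, ncol = n)
  valid <- rowi <= rep(len, each = W)
  isplus <- rep(strand == "+", each = W)
  cyt <- valid & ((m == "C" & isplus) | (m == "G" & !isplus))
  idx <- which(cyt)
  if (length(idx)) {
    jj <- ((idx - 1L) %/% W) + 1L
    ii <- ((idx - 1L) %% W) + 1L
    gpos <- goff[contig[jj]] + start[jj] + ii - 1L
    site <- ifelse(strand[jj] == "+", lu$p[gpos], lu$m[gpos])
    meth <- logical(length(idx))
    known <- site > 0L
    meth[known] <- states[cbind(site[known], cellcol[jj[known]])] != as.raw(0)
    flip <- !meth & (runif(length(idx)) < conversion_rate)
    m[idx[flip]] <- ifelse(strand[jj[flip]] == "+", "T", "A")
  }
  conv <- substr(collapse_rows(m), 1L, len)
  out <- conv
  minus <- strand == "-"
  out[minus] <- revcomp(conv[minus])
  out
}

## R2-observed tail strings of given lengths from base weights.
make_tails <- function(tl, w, tail_max) {
  n <- length(tl)
  if (n == 0L || tail_max == 0L) return(rep("", n))
  bm <- matrix(sample(names(w), tail_max * n, replace = TRUE, prob = w),
               nrow = tail_max)
  bm[matrix(seq_len(tail_max), tail_max, n) > rep(tl, each = tail_max)] <- ""
  collapse_rows(bm)
}

## Uniform substitution errors at the given rate.
apply_seq_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  L <- nchar(reads)
  total <- sum(L)
  k <- rbinom(1L, total, rate)
  if (k == 0L) return(reads)
  at <- sort(sample.int(total, k))
  ends <- cumsum(L)
  ri <- findInterval(at - 1L, ends) + 1L
  off <- at - c(0L, ends)[ri]
  bases <- c("A", "C", "G", "T")
  for (x in seq_len(k)) {
    cur <- substr(reads[ri[x]], off[x], off[x])
    if (!cur %in% bases) next
    sub <- sample(setdiff(bases, cur), 1L)
    substr(reads[ri[x]], off[x], off[x]) <- sub
  }
  reads
}
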