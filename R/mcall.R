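#' Call per-cytosine methylation from filtered alignments
#'
#' For CT-frame hits, genomic cytosines on the Watson strand covered by
#' the read contribute a basecall: read base C increments both `mc` and
#' `cov` (the molecule escaped conversion, i.e. was methylated), read
#' base T increments `cov` only; other bases at the position are
#' ignored. GA-frame hits are the symmetric case for Crick-strand
#' cytosines (genomic G; read base G methylated, A unmethylated).
#' Where the two mates of a pair overlap the same cytosine, R1's
#' basecall is kept. Context comes from the genome's trinucleotide on
#' the cytosine's own strand; sites with undefined context are excluded
#' (they are absent from the genome's site table).
#'
#' @param hits filtered alignments from [filter_alignments()].
#' @param genome the `snmc_genome` aligned against.
#' @param conversion_rate assumed conversion rate for the convenience
#'   methylated-call flag (binomial test at p < 0.01 against a
#'   non-methylated site read with this conversion rate).
#' @return allc-style data.table, one row per (cell, cytosine):
#'   `cell`, `contig`, `pos` (1-based), `strand`, `context`
#'   (trinucleotide), `cls` (`CG`/`CH`), `mc`, `cov`, `methylated`
#'   (flag; convenience only).
#' @export
call_methylation <- function(hits, genome, conversion_rate = 0.995) {
  hits <- as.data.table(hits)
  if (nrow(hits) == 0L) return(empty_allc())
  sites <- genome$sites
  ## read orientation is irrelevant here: the frame alone says which
  ## strand's cytosines the read reports
  h <- hits[, .(pair_id, mate, cell, ctg, frame, oriented,
                start1 = start0 + 1L, end1 = start0 + qlen)]
  setkey(h, ctg, start1, end1)
  sv <- sites[, .(ctg = contig, start1 = pos, end1 = pos, site, pos,
                  strand, context, cls)]
  setkey(sv, ctg, start1, end1)
  ov <- foverlaps(sv, h, type = "within", nomatch = NULL)
  if (nrow(ov) == 0L) return(empty_allc())
  ## frame determines which strand's cytosines a read reports
  ov <- ov[(frame == "CT" & strand == "+") | (frame == "GA" & strand == "-")]
  ov[, base := substr(oriented, pos - start1 + 1L, pos - start1 + 1L)]
  ov <- ov[(strand == "+" & base %in% c("C", "T")) |
             (strand == "-" & base %in% c("G", "A"))]
  ## mate-overlap: keep R1's basecall for the same cytosine of one pair
  setorder(ov, cell, pair_id, pos, strand, mate)
  ov <- unique(ov, by = c("cell", "pair_id", "ctg", "pos", "strand"))
  ov[, mc := as.integer(base %in% c("C", "G"))]
  allc <- ov[, .(mc = sum(mc), cov = .N),
             by = .(cell, contig = ctg, pos, strand, context, cls)]
  allc[, methylated := pbinom(mc - 1L, cov, 1 - conversion_rate,
                              lower.tail = FALSE) < 0.01]
  setorder(allc, cell, contig, pos, strand)
  allc[]
}

empty_allc <- function() {
  data.table(cell = character(0), contig = character(0), pos = integer(0),
             strand = character(0), context = character(0),
             cls = character(0), mc = integer(0), cov = integer(0),
             methylated = logical(0))
}

#' Estimate bisulfite conversion rate from the lambda spike-in
#'
#' The lambda spike-in is fully unmethylated, so any cytosine basecall
#' read as C on the lambda contig is a conversion failure:
#' `rate = 1 - sum(mc) / sum(cov)` over all lambda cytosines. A library
#' passes when the rate is at least 0.99 (the >99% conversion regime).
#'
#' @param allc allc table from [call_methylation()].
#' @param lambda_contig name of the spike-in contig.
#' @param per_cell estimate per cell (default) or pooled.
#' @return data.table with `nonconverted`, `total`, `rate`,
#'   `passes_threshold`; `rate` is NA (flagged) when total is zero.
#' @export
estimate_conversion <- function(allc, lambda_contig = "lambda",
                                per_cell = TRUE) {
  allc <- as.data.table(allc)
  lam <- allc[contig == lambda_contig]
  by <- if (per_cell) "cell" else character(0)
  out <- lam[, .(nonconverted = sum(mc), total = sum(cov)), by = by]
  if (nrow(out) == 0L)
    out <- data.table(nonconverted = 0L, total = 0L)
  out[, rate := ifelse(total > 0L, 1 - nonconverted / total, NA_real_)]
  out[, passes_threshold := !is.na(rate) & rate >= 0.99]
  out[]
}

#' Global mCG and mCH levels per cell
#'
#' Methylation level is the number of methylated basecalls divided by
#' the number of total basecalls, computed separately over CG-class and
#' CH-class records. Levels are reported raw (no conversion-failure
#' correction); see [correct_conversion()] for the optional adjustment.
#'
#' @param allc allc table from [call_methylation()].
#' @param exclude_contigs contigs to exclude (the lambda spike-in by
#'   default would bias genomic levels downward).
#' @return data.table per cell: `mcg`, `mcg_cov`, `mch`, `mch_cov`;
#'   levels are NA (flagged) for a cell with zero coverage in a class.
#' @export
global_levels <- function(allc, exclude_contigs = "lambda") {
  allc <- as.data.table(allc)[!contig %in% exclude_contigs]
  if (nrow(allc) == 0L)
    return(data.table(cell = character(0), mcg = numeric(0),
                      mcg_cov = integer(0), mch = numeric(0),
                      mch_cov = integer(0)))
  wide <- allc[, .(mc = sum(mc), cov = sum(cov)), by = .(cell, cls)]
  out <- dcast(wide, cell ~ cls, value.var = c("mc", "cov"), fill = 0L)
  for (col in c("mc_CG", "cov_CG", "mc_CH", "cov_CH"))
    if (!col %in% names(out)) out[, (col) := 0L]
  out[, .(cell,
          mcg = ifelse(cov_CG > 0L, mc_CG / cov_CG, NA_real_),
          mcg_cov = cov_CG,
          mch = ifelse(cov_CH > 0L, mc_CH / cov_CH, NA_real_),
          mch_cov = cov_CH)]
}

#' Correct a methylation level for incomplete conversion
#'
#' At conversion rate `c < 1` the apparent level of a set of cytosines
#' with true level `m` is `m + (1 - m)(1 - c)`; inverting gives
#' `m = (apparent - (1 - c)) / c`, clipped to `[0, 1]`. Reported levels
#' elsewhere in the package are raw; this utility is optional.
#'
#' @param apparent apparent (raw) methylation level(s).
#' @param conversion_rate estimated conversion rate.
#' @return corrected level(s).
#' @export
correct_conversion <- function(apparent, conversion_rate) {
  stopifnot(conversion_rate > 0, conversion_rate <= 1)
  pmin(1, pmax(0, (apparent - (1 - conversion_rate)) / conversion_rate))
}

#' Write allc-style tables to TSV
#'
#' One file per cell (7 columns: contig, position, strand,
#' trinucleotide context, methylated basecalls, total basecalls,
#' methylated flag), optionally gzipped.
#'
#' @param allc allc table.
#' @param dir output directory.
#' @param gzip compress output.
#' @return named vector of file paths, invisibly.
#' @export
write_allc <- function(allc, dir, gzip = TRUE) {
  allc <- as.data.table(allc)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- unique(allc$cell)
  paths <- vapply(cells, function(cl) {
    f <- file.path(dir, paste0("allc_", cl, ".tsv", if (gzip) ".gz"))
    sub <- allc[cell == cl, .(contig, pos, strand, context, mc, cov,
                              methylated = as.integer(methylated))]
    fwrite(sub, f, sep = "\t", compress = if (gzip) "gzip" else "none")
    f
  }, character(1))
  invisible(paths)
}

#' Read allc-style tables
#'
#' @param files vector of files written by [write_allc()]; cell ids are
#'   recovered from file names.
#' @return combined allc data.table with a `cls` column re-derived from
#'   the context trinucleotide.
#' @export
read_allc <- function(files) {
  out <- rbindlist(lapply(files, function(f) {
    con <- if (endsWith(f, ".gz")) gzfile(f) else file(f)
    dt <- as.data.table(utils::read.table(con, sep = "\t", header = TRUE,
                                          colClasses = c(
                                            contig = "character",
                                            strand = "character",
                                            context = "character")))
    dt[, cell := sub("^allc_(.*)\\.tsv(\\.gz)?$", "\\1", basename(f))]
    dt
  }))
  out[, cls := ifelse(substr(context, 2L, 2L) == "G", "CG", "CH")]
  out[, methylated := as.logical(methylated)]
  setcolorder(out, c("cell", "contig", "pos", "strand", "context", "cls",
                     "mc", "cov", "methylated"))
  out[]
}
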