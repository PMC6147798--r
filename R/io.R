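#' Write a genome to FASTA
#'
#' @param genome an `snmc_genome`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(genome, file) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$sequences), file)
  invisible(file)
}

#' Read a genome from FASTA (with optional BED annotation)
#'
#' @param file FASTA path.
#' @param cgi,genes optional BED paths (see [read_bed()]).
#' @param lambda_contig optional spike-in contig name.
#' @return an `snmc_genome`.
#' @export
read_genome_fasta <- function(file, cgi = NULL, genes = NULL,
                              lambda_contig = NULL) {
  ss <- Biostrings::readDNAStringSet(file)
  seqs <- stats::setNames(as.character(ss),
                          sub("\\s.*$", "", names(ss)))
  genome_from_sequences(
    seqs,
    cgi = if (!is.null(cgi)) read_bed(cgi),
    genes = if (!is.null(genes)) read_bed(genes),
    lambda_contig = lambda_contig)
}

#' Write intervals as BED6
#'
#' 0-based half-open intervals via rtracklayer.
#'
#' @param intervals data.frame with `contig`, `start`, `end` and
#'   optionally `name`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(intervals, file) {
  iv <- as.data.frame(intervals)
  gr <- GenomicRanges::GRanges(
    seqnames = iv$contig,
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end),
    strand = "*")
  if (!is.null(iv$name)) names(gr) <- iv$name
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' Read BED intervals
#'
#' @param file BED path.
#' @return data.table with `contig`, `start` (0-based), `end`, `name`.
#' @export
read_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  data.table(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else
               paste0("iv", seq_along(gr)))
}

#' Write a simulated library as paired FASTQ
#'
#' One gzipped pair of files per sequencing pool, Illumina-style
#' `/1`-`/2` read naming, constant quality.
#'
#' @param lib an `snmc_library`.
#' @param dir output directory.
#' @param quality_char constant Phred quality character.
#' @return data.table of pool, r1/r2 paths, invisibly.
#' @export
write_fastq <- function(lib, dir, quality_char = "I") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reads <- lib$reads
  out <- rbindlist(lapply(unique(reads$pool), function(pl) {
    sub <- reads[pool == pl]
    f1 <- file.path(dir, paste0(pl, "_R1.fastq.gz"))
    f2 <- file.path(dir, paste0(pl, "_R2.fastq.gz"))
    write_one_fastq(sub$r1, paste0(sub$pair_id, "/1"), f1, quality_char)
    write_one_fastq(sub$r2, paste0(sub$pair_id, "/2"), f2, quality_char)
    data.table(pool = pl, r1 = f1, r2 = f2)
  }))
  invisible(out)
}

write_one_fastq <- function(seqs, ids, file, quality_char = "I") {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  q <- Biostrings::BStringSet(strrep(quality_char, nchar(seqs)))
  Biostrings::writeXStringSet(x, file, format = "fastq", qualities = q,
                              compress = endsWith(file, ".gz"))
  invisible(file)
}

#' Read a FASTQ pair into pair-table form
#'
#' @param r1,r2 FASTQ paths (plain or gzipped).
#' @return data.table with `pair_id`, `r1`, `r2`.
#' @export
read_fastq_pair <- function(r1, r2) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
  id1 <- sub("/1$", "", sub("\\s.*$", "", names(s1)))
  id2 <- sub("/2$", "", sub("\\s.*$", "", names(s2)))
  if (!identical(id1, id2)) stopf("R1/R2 read ids do not match")
  data.table(pair_id = id1, r1 = as.character(s1), r2 = as.character(s2))
}
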