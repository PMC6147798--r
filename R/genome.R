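#' Specify a synthetic genome
#'
#' Describes a small multi-contig genome for the read simulator: contig
#' names and lengths, background GC fraction, CpG-island (CGI) intervals
#' with elevated GC and CG-dinucleotide density, gene models carrying
#' marker flags, and an optional unmethylated lambda spike-in contig.
#' All intervals are 0-based half-open (BED convention).
#'
#' @param contigs data.frame with columns `name`, `length` (bp); contig
#'   lengths must be at least 10 kb.
#' @param gc_fraction background GC fraction in `[0, 1]`.
#' @param cgi optional data.frame of CGI intervals with columns `contig`,
#'   `start`, `end` and optionally `name`.
#' @param genes optional data.frame of gene bodies with columns `contig`,
#'   `start`, `end`, `name` and optionally logical `marker`.
#' @param lambda_contig name of the contig acting as the unmethylated
#'   spike-in control, or `NULL`.
#' @param seed integer seed making sequence generation reproducible.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(contigs, gc_fraction = 0.42, cgi = NULL,
                        genes = NULL, lambda_contig = NULL, seed = 1L) {
  contigs <- as.data.frame(contigs)
  stopifnot(all(c("name", "length") %in% names(contigs)))
  if (any(contigs$length < 10000L))
    stopf("contig lengths must be >= 10 kb (got %s)",
          paste(contigs$length[contigs$length < 10000L], collapse = ", "))
  if (gc_fraction < 0 || gc_fraction > 1)
    stopf("gc_fraction must lie in [0,1]")
  clen <- stats::setNames(as.integer(contigs$length), contigs$name)
  cgi <- normalize_intervals(cgi, "cgi")
  genes <- normalize_intervals(genes, "gene")
  check_intervals(cgi, clen, "CGI interval")
  check_intervals(genes, clen, "gene interval")
  if (!is.null(lambda_contig) && !lambda_contig %in% contigs$name)
    stopf("lambda_contig '%s' is not a declared contig", lambda_contig)
  structure(list(contigs = contigs, gc_fraction = gc_fraction,
                 cgi = cgi, genes = genes, lambda_contig = lambda_contig,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

normalize_intervals <- function(iv, kind) {
  if (is.null(iv)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      stringsAsFactors = FALSE))
  }
  iv <- as.data.frame(iv)
  stopifnot(all(c("contig", "start", "end") %in% names(iv)))
  if (is.null(iv$name)) iv$name <- paste0(kind, seq_len(nrow(iv)))
  if (kind == "gene" && is.null(iv$marker)) iv$marker <- FALSE
  iv$start <- as.integer(iv$start); iv$end <- as.integer(iv$end)
  iv
}

#' Simulate a genome from a specification
#'
#' Draws each contig i.i.d. from the background base composition implied
#' by `gc_fraction`, then rewrites CGI intervals with elevated GC and
#' explicitly planted CG dinucleotides so that measured CG density inside
#' CGIs strictly exceeds the genome background. Deterministic for a fixed
#' `spec$seed`.
#'
#' @param spec a [genome_spec()].
#' @return an object of class `snmc_genome`: contig sequences, interval
#'   sets, and a precomputed per-cytosine site table (see
#'   [cytosine_sites()]).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  gc <- spec$gc_fraction
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- withr::with_seed(spec$seed, {
    out <- lapply(seq_len(nrow(spec$contigs)), function(i) {
      n <- spec$contigs$length[i]
      s <- sample(names(p), n, replace = TRUE, prob = p)
      s
    })
    names(out) <- spec$contigs$name
    ## rewrite CGI intervals: higher GC plus planted CG dinucleotides
    if (nrow(spec$cgi) > 0L) {
      gc_cgi <- min(gc + 0.25, 0.75)
      p2 <- c(A = (1 - gc_cgi) / 2, C = gc_cgi / 2,
              G = gc_cgi / 2, T = (1 - gc_cgi) / 2)
      for (i in seq_len(nrow(spec$cgi))) {
        ctg <- spec$cgi$contig[i]
        idx <- (spec$cgi$start[i] + 1L):spec$cgi$end[i]
        w <- length(idx)
        s <- sample(names(p2), w, replace = TRUE, prob = p2)
        ## plant CG dinucleotides at ~8% of positions
        at <- which(runif(w - 1L) < 0.08)
        if (length(at)) { s[at] <- "C"; s[at + 1L] <- "G" }
        out[[ctg]][idx] <- s
      }
    }
    lapply(out, paste, collapse = "")
  })
  seqs <- unlist(seqs)
  build_genome(seqs, spec)
}

#' Construct a genome object from explicit sequences
#'
#' Escape hatch for tests and small worked examples: wraps plain character
#' sequences (with optional interval annotation) into the same container
#' that [simulate_genome()] returns.
#'
#' @param sequences named character vector of contig sequences.
#' @param cgi,genes optional interval data.frames as in [genome_spec()].
#' @param lambda_contig optional spike-in contig name.
#' @return an `snmc_genome` object.
#' @export
genome_from_sequences <- function(sequences, cgi = NULL, genes = NULL,
                                  lambda_contig = NULL) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  clen <- stats::setNames(nchar(sequences), names(sequences))
  cgi <- normalize_intervals(cgi, "cgi")
  genes <- normalize_intervals(genes, "gene")
  check_intervals(cgi, as.list(clen), "CGI interval")
  check_intervals(genes, as.list(clen), "gene interval")
  spec <- list(contigs = data.frame(name = names(sequences),
                                    length = as.integer(clen)),
               gc_fraction = NA_real_, cgi = cgi, genes = genes,
               lambda_contig = lambda_contig, seed = NA_integer_)
  build_genome(sequences, spec)
}

build_genome <- function(seqs, spec) {
  g <- structure(list(
    sequences = seqs,
    contigs = data.frame(name = names(seqs),
                         length = as.integer(nchar(seqs))),
    cgi = spec$cgi, genes = spec$genes,
    lambda_contig = spec$lambda_contig,
    spec = spec), class = "snmc_genome")
  g$sites <- cytosine_sites(g)
  g
}

#' @export
print.snmc_genome <- function(x, ...) {
  cat("snmc_genome:", nrow(x$contigs), "contig(s),",
      sum(x$contigs$length), "bp total\n")
  cat("  contigs:", paste0(x$contigs$name, " (", x$contigs$length, " bp)",
                           collapse = ", "), "\n")
  cat("  CGIs:", nrow(x$cgi), " genes:", nrow(x$genes), "\n")
  if (!is.null(x$lambda_contig))
    cat("  lambda spike-in contig:", x$lambda_contig, "\n")
  cat("  callable cytosine sites:", nrow(x$sites), "\n")
  invisible(x)
}

#' Per-cytosine site table for a genome
#'
#' Enumerates every callable cytosine on both strands: Watson cytosines are
#' `C` bases on the forward sequence, Crick cytosines are `G` bases
#' (reported on the minus strand). Context is collapsed to the two classes
#' used throughout (`CG` vs `CH`); sites whose dinucleotide context runs
#' off the contig end or contains `N` are uncallable and excluded.
#'
#' @param genome an `snmc_genome`.
#' @return data.table with columns `contig`, `pos` (1-based), `strand`,
#'   `context` (trinucleotide where defined), `cls` (`"CG"`/`"CH"`),
#'   `in_cgi`, `gene` (gene name or `NA`), and `site` (row index).
#' @export
cytosine_sites <- function(genome) {
  out <- lapply(genome$contigs$name, function(ctg) {
    s <- genome$sequences[[ctg]]
    n <- nchar(s)
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    ## Watson: C at pos, trinucleotide pos..pos+2; any N or truncation
    ## makes the context undefined and the site uncallable
    wpos <- which(b == "C")
    wpos <- wpos[wpos + 2L <= n]
    wtri <- paste0("C", b[wpos + 1L], b[wpos + 2L])
    wok <- grepl("^C[ACGT]{2}$", wtri)
    wpos <- wpos[wok]; wtri <- wtri[wok]
    wnext <- substr(wtri, 2L, 2L)
    ## Crick: G at pos on forward = C on reverse; trinucleotide runs
    ## pos, pos-1, pos-2 complemented
    cpos <- which(b == "G")
    cpos <- cpos[cpos - 2L >= 1L]
    comp_lu <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    ctri <- paste0("C", comp_lu[b[cpos - 1L]], comp_lu[b[cpos - 2L]])
    cok <- grepl("^C[ACGT]{2}$", ctri)
    cpos <- cpos[cok]; ctri <- ctri[cok]
    cprev <- b[cpos - 1L]
    dt <- data.table(
      contig = ctg,
      pos = c(wpos, cpos),
      strand = rep(c("+", "-"), c(length(wpos), length(cpos))),
      context = c(wtri, ctri),
      cls = c(ifelse(wnext == "G", "CG", "CH"),
              ifelse(cprev == "C", "CG", "CH")))
    setorder(dt, pos, strand)
    ## region annotation
    dt[, in_cgi := FALSE]
    cg <- genome$cgi[genome$cgi$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(cg)))
      dt[pos > cg$start[i] & pos <= cg$end[i], in_cgi := TRUE]
    dt[, gene := NA_character_]
    gn <- genome$genes[genome$genes$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(gn)))
      dt[pos > gn$start[i] & pos <= gn$end[i], gene := gn$name[i]]
    dt
  })
  dt <- rbindlist(out)
  dt[, site := .I]
  dt[]
}

## Measured CG-dinucleotide density (per bp) inside a set of intervals,
## or over the remainder of the genome when complement = TRUE.
cg_density <- function(genome, intervals, complement = FALSE) {
  total_cg <- 0; total_bp <- 0
  for (ctg in genome$contigs$name) {
    s <- genome$sequences[[ctg]]
    n <- nchar(s)
    iv <- intervals[intervals$contig == ctg, , drop = FALSE]
    mask <- rep(FALSE, n)
    for (i in seq_len(nrow(iv))) mask[(iv$start[i] + 1L):iv$end[i]] <- TRUE
    if (complement) mask <- !mask
    cg_at <- IRanges::start(
      Biostrings::matchPattern("CG", Biostrings::DNAString(s)))
    total_cg <- total_cg + sum(mask[cg_at])
    total_bp <- total_bp + sum(mask)
  }
  if (total_bp == 0) return(NA_real_)
  total_cg / total_bp
}

#' Example genome specification
#'
#' The bundled demonstration genome: two 300 kb autosome-like contigs with
#' CGIs and six gene bodies (three of them marker genes standing in for
#' Cux1, Satb2 and Rorb), plus a 10 kb synthetic unmethylated lambda
#' spike-in contig. Marker gene bodies are 40 kb so that their
#' non-CG-methylation signal is visible at 100 kb bin resolution.
#'
#' @param seed integer seed.
#' @return a `genome_spec`.
#' @export
example_genome_spec <- function(seed = 7L) {
  contigs <- data.frame(
    name = c("chr1", "chr2", "lambda"),
    length = c(300000L, 300000L, 10000L))
  genes <- data.frame(
    contig = c("chr1", "chr1", "chr2", "chr1", "chr2", "chr2"),
    start  = c(20000L, 120000L, 20000L, 220000L, 120000L, 220000L),
    end    = c(60000L, 160000L, 60000L, 260000L, 160000L, 260000L),
    name   = c("Cux1", "Satb2", "Rorb", "GeneA", "GeneB", "GeneC"),
    marker = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  cgi <- data.frame(
    contig = c("chr1", "chr1", "chr2", "chr2"),
    start  = c(19000L, 119000L, 19000L, 199000L),
    end    = c(21000L, 121000L, 21000L, 201000L),
    name   = paste0("CGI", 1:4))
  genome_spec(contigs, gc_fraction = 0.42, cgi = cgi, genes = genes,
              lambda_contig = "lambda", seed = seed)
}
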