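#' Duplication histogram of mapped positions
#'
#' Counts, per cell, how many genomic positions (cell, contig, start,
#' frame keys) were observed exactly j times among mapped reads before
#' clonal collapse -- the substrate of library-complexity extrapolation.
#' Satisfies `sum(j * n_j) == total mapped reads`.
#'
#' @param hits alignments from [align_reads()] after the MAPQ filter but
#'   before clonal collapse (use
#'   `filter_alignments(hits, collapse_clonal = FALSE)`).
#' @param by_cell one histogram per cell (default) or pooled.
#' @return data.table with columns `cell` (if `by_cell`), `j`, `n_j`.
#' @export
duplication_histogram <- function(hits, by_cell = TRUE) {
  hits <- as.data.table(hits)
  keys <- if (by_cell) "cell" else character(0)
  dup <- hits[, .(times = .N), by = c(keys, "ctg", "start0", "frame")]
  out <- dup[, .(n_j = .N), by = c(keys, "times")]
  setnames(out, "times", "j")
  out[order(j)]
}

#' Good-Toulmin library-complexity extrapolation
#'
#' Predicts how many distinct genomic positions would be observed after
#' sequencing `target_reads` total reads, from the duplication histogram
#' of the reads in hand. With fold `t = target_reads / total_reads`, the
#' expected number of new distinct positions is the alternating series
#' `Delta(t) = sum_j (-1)^(j+1) (t-1)^j n_j`. The raw series diverges
#' for `t > 2`; there the sum is evaluated through its Euler
#' transformation (`sum_k (-1)^k Delta^k b_0 / 2^(k+1)` over the padded
#' term sequence), the classical smoothing for this estimator. The
#' defaults mirror the conventional extrapolation grid (bound 5e9,
#' step 1e7) and reference depth of 50 million read pairs.
#'
#' @param hist duplication histogram: data.table with columns `j`,
#'   `n_j` (one cell's histogram), or a named numeric vector
#'   (`names = j`).
#' @param target_reads total reads at which to predict (scalar or
#'   vector); must be at least the observed total.
#' @param method `"auto"` (direct sum for t <= 2, Euler beyond),
#'   `"direct"` (refused for t > 2 where the raw series diverges) or
#'   `"euler"`.
#' @param genome_size optional bound: predictions are capped at this
#'   many positions, and a `fraction_genome` column is added using
#'   `read_len`.
#' @param read_len read length used to convert distinct positions to
#'   covered bases for `fraction_genome` (approximate: ignores overlap
#'   between reads).
#' @param max_extrapolation upper bound on `target_reads` (default 5e9).
#' @param max_fold largest extrapolation fold evaluated; targets beyond
#'   `max_fold * total` are truncated to it (the series carries no
#'   information that far) and flagged in the `capped` column.
#' @return data.table with `target`, `fold`, `expected_distinct`,
#'   `capped`, and `fraction_genome` when `genome_size` is given.
#' @export
extrapolate_complexity <- function(hist, target_reads,
                                   method = c("auto", "euler", "direct"),
                                   genome_size = NULL, read_len = NULL,
                                   max_extrapolation = 5e9,
                                   max_fold = 100) {
  method <- match.arg(method)
  if (is.data.frame(hist)) {
    h <- as.data.table(hist)
    nj <- stats::setNames(as.numeric(h$n_j), h$j)
  } else nj <- stats::setNames(as.numeric(hist), names(hist))
  jj <- as.integer(names(nj))
  stopifnot(all(jj >= 1L), all(nj >= 0))
  total <- sum(jj * nj)
  distinct <- sum(nj)
  if (total == 0) stopf("empty duplication histogram")
  target_reads <- pmin(target_reads, max_extrapolation)
  if (any(target_reads < total))
    stopf("target_reads must be >= observed total reads (%d)", total)
  full <- numeric(max(jj)); full[jj] <- nj
  out <- rbindlist(lapply(target_reads, function(tg) {
    t <- tg / total
    capped <- t > max_fold
    if (capped) t <- max_fold
    x <- t - 1
    delta <- if (x == 0) 0
    else if (method == "direct" || (method == "auto" && x <= 1)) {
      if (x > 1)
        stopf(paste0("direct Good-Toulmin series diverges for ",
                     "target > 2x observed; use the Euler-transformed ",
                     "mode (method = 'euler' or 'auto')"))
      sum((-1)^(seq_along(full) + 1) * x^seq_along(full) * full)
    } else {
      euler_alt_sum(full * x^seq_along(full))
    }
    ed <- distinct + max(delta, 0)
    if (!is.null(genome_size)) ed <- min(ed, genome_size)
    data.table(target = tg, fold = tg / total,
               expected_distinct = ed, capped = capped)
  }))
  if (!is.null(genome_size) && !is.null(read_len))
    out[, fraction_genome := pmin(1, expected_distinct * read_len /
                                    genome_size)]
  out[]
}

## Euler transformation of the alternating series a_1 - a_2 + a_3 - ...
## (terms passed positive): sum_k (-1)^k Delta^k b_0 / 2^(k+1) with
## b = a padded with zeros; truncated when terms stop contributing.
euler_alt_sum <- function(a, kmax = 400L, tol = 1e-12) {
  d <- c(a, numeric(kmax + 1L))
  S <- 0
  for (k in 0:kmax) {
    term <- (-1)^k * d[1L] / 2^(k + 1)
    S <- S + term
    if (k > length(a) && abs(term) < tol * max(1, abs(S))) break
    d <- d[-1L] - d[-length(d)]
  }
  S
}

## Normalise hit tables / coverage tracks to interval form.
to_intervals <- function(x) {
  x <- as.data.table(x)
  if (all(c("ctg", "start0", "qlen") %in% names(x)))
    return(x[, .(contig = ctg, start1 = start0 + 1L, end1 = start0 + qlen)])
  if (all(c("contig", "start", "end") %in% names(x)))
    return(x[, .(contig, start1 = start + 1L, end1 = end)])
  stopf("cannot interpret coverage input: need hit or interval columns")
}

#' Coverage-uniformity and CGI-enrichment statistics
#'
#' Computes, from mapped read intervals: mean and SD of per-CG-site
#' depth over covered CG sites (depth >= 1), the coefficient of
#' variation of read-base counts in 1 kb and 10 kb genomic bins, and
#' CGI enrichment (mean per-base coverage inside CGIs divided by the
#' genome-wide mean). Uniform libraries have low bin CVs and CGI
#' enrichment near 1; CGI-biased chemistry inflates both.
#'
#' @param x alignments from [filter_alignments()] or an interval track
#'   (`contig`, `start`, `end`, 0-based half-open).
#' @param genome the `snmc_genome`.
#' @param bin_sizes bin widths (bp) for the CV statistics.
#' @return list: `cg_depth_mean`, `cg_depth_sd`, `cg_sites_covered`,
#'   `bin_cv` (named by bin size), `cgi_enrichment`, `mean_coverage`,
#'   `flag_no_coverage`.
#' @export
coverage_uniformity <- function(x, genome, bin_sizes = c(1000L, 10000L)) {
  iv <- to_intervals(x)
  clen <- stats::setNames(genome$contigs$length, genome$contigs$name)
  covs <- lapply(names(clen), function(ctg) {
    sub <- iv[contig == ctg]
    IRanges::coverage(IRanges::IRanges(sub$start1, sub$end1),
                      width = clen[[ctg]])
  })
  names(covs) <- names(clen)
  total_bases <- sum(vapply(covs, function(r) sum(as.numeric(r)), 1))
  mean_cov <- total_bases / sum(as.numeric(clen))
  if (total_bases == 0) {
    return(list(cg_depth_mean = NA_real_, cg_depth_sd = NA_real_,
                cg_sites_covered = 0L,
                bin_cv = stats::setNames(rep(NA_real_, length(bin_sizes)),
                                         bin_sizes),
                cgi_enrichment = NA_real_, mean_coverage = 0,
                flag_no_coverage = TRUE))
  }
  ## per-CG-site depth (CpG dinucleotide starts: Watson-strand CG sites)
  cgpos <- genome$sites[cls == "CG" & strand == "+", .(contig, pos)]
  depth <- unlist(lapply(names(clen), function(ctg) {
    p <- cgpos[contig == ctg, pos]
    if (!length(p)) return(numeric(0))
    as.numeric(covs[[ctg]][p])
  }))
  covered <- depth[depth >= 1]
  ## bin CVs over read-base counts
  bin_cv <- vapply(bin_sizes, function(bw) {
    sums <- unlist(lapply(names(clen), function(ctg) {
      n <- clen[[ctg]]
      starts <- seq.int(1L, n, by = bw)
      ends <- pmin(starts + bw - 1L, n)
      keep <- (ends - starts + 1L) == bw   # drop ragged terminal bin
      if (!any(keep)) return(numeric(0))
      as.numeric(IRanges::viewSums(
        IRanges::Views(covs[[ctg]], start = starts[keep],
                       end = ends[keep])))
    }))
    if (length(sums) < 2L || mean(sums) == 0) return(NA_real_)
    stats::sd(sums) / mean(sums)
  }, numeric(1))
  names(bin_cv) <- bin_sizes
  ## CGI enrichment
  enr <- NA_real_
  if (nrow(genome$cgi) > 0L) {
    cgi_bases <- 0; cgi_len <- 0
    for (i in seq_len(nrow(genome$cgi))) {
      ctg <- genome$cgi$contig[i]
      v <- IRanges::Views(covs[[ctg]], start = genome$cgi$start[i] + 1L,
                          end = genome$cgi$end[i])
      cgi_bases <- cgi_bases + as.numeric(IRanges::viewSums(v))
      cgi_len <- cgi_len + (genome$cgi$end[i] - genome$cgi$start[i])
    }
    enr <- (cgi_bases / cgi_len) / mean_cov
  }
  list(cg_depth_mean = if (length(covered)) mean(covered) else NA_real_,
       cg_depth_sd = if (length(covered) > 1) stats::sd(covered)
                     else NA_real_,
       cg_sites_covered = length(covered),
       bin_cv = bin_cv, cgi_enrichment = enr, mean_coverage = mean_cov,
       flag_no_coverage = FALSE)
}

#' Assemble the per-cell QC table
#'
#' Joins the per-stage outputs into one row per cell: input/assigned
#' pairs, adapter-dimer fraction (dimer-or-short pairs over assigned
#' pairs), per-mate and combined mapping rates (mapped reads over reads
#' submitted), retained non-clonal reads, conversion rate, global
#' mCG/mCH, distinct positions and extrapolated coverage fraction at
#' the reference depth. Cells with a missing stage get flagged missing
#' fields rather than being dropped.
#'
#' @param cells character vector of cell ids the table should cover.
#' @param trimmed trimmed pair table from [trim_reads()] with a `cell`
#'   column.
#' @param hits alignments (post-MAPQ filter, pre-collapse).
#' @param retained clonal-collapsed alignments from
#'   [filter_alignments()].
#' @param conversion per-cell table from [estimate_conversion()].
#' @param levels per-cell table from [global_levels()].
#' @param genome the `snmc_genome` (for complexity bounds); optional.
#' @param reference_pairs reference depth for the complexity field
#'   (default 50e6 read pairs).
#' @return data.table, one row per cell.
#' @export
assemble_qc <- function(cells, trimmed, hits, retained, conversion,
                        levels, genome = NULL, reference_pairs = 50e6) {
  trimmed <- as.data.table(trimmed)
  hits <- as.data.table(hits)
  retained <- as.data.table(retained)
  base <- data.table(cell = cells)
  tstat <- trimmed[, .(assigned = .N,
                       kept = sum(trim_class == "keep"),
                       dimer_or_short = sum(trim_class == "dimer_or_short")),
                   by = cell]
  base <- merge(base, tstat, by = "cell", all.x = TRUE)
  base[, dimer_fraction := ifelse(assigned > 0, dimer_or_short / assigned,
                                  NA_real_)]
  mstat <- hits[, .(mapped_r1 = sum(mate == 1L),
                    mapped_r2 = sum(mate == 2L)), by = cell]
  base <- merge(base, mstat, by = "cell", all.x = TRUE)
  for (col in c("mapped_r1", "mapped_r2"))
    base[is.na(get(col)), (col) := 0L]
  base[, `:=`(map_rate_r1 = ifelse(assigned > 0, mapped_r1 / assigned,
                                   NA_real_),
              map_rate_r2 = ifelse(assigned > 0, mapped_r2 / assigned,
                                   NA_real_),
              map_rate = ifelse(assigned > 0,
                                (mapped_r1 + mapped_r2) / (2 * assigned),
                                NA_real_))]
  rstat <- retained[, .(retained_nonclonal = .N), by = cell]
  base <- merge(base, rstat, by = "cell", all.x = TRUE)
  conv <- as.data.table(conversion)
  if ("cell" %in% names(conv))
    base <- merge(base, conv[, .(cell, conversion_rate = rate)],
                  by = "cell", all.x = TRUE)
  lv <- as.data.table(levels)
  if (nrow(lv))
    base <- merge(base, lv[, .(cell, mcg, mch)], by = "cell", all.x = TRUE)
  ## library complexity at the reference depth
  base[, `:=`(distinct_positions = NA_real_, coverage_at_ref = NA_real_)]
  if (nrow(hits) > 0L) {
    gsize <- if (!is.null(genome)) sum(genome$contigs$length) else NULL
    rl <- if (nrow(hits)) as.integer(round(mean(hits$qlen))) else NULL
    dh <- duplication_histogram(hits)
    for (cl in unique(dh$cell)) {
      h <- dh[cell == cl, .(j, n_j)]
      obs <- sum(h$j * h$n_j)
      ex <- extrapolate_complexity(h, max(2 * reference_pairs, obs),
                                   genome_size = gsize, read_len = rl)
      base[cell == cl,
           `:=`(distinct_positions = sum(h$n_j),
                coverage_at_ref = if (!is.null(gsize))
                  ex$fraction_genome[1] else ex$expected_distinct[1])]
    }
  }
  base[, flag_missing := is.na(assigned) | is.na(conversion_rate) |
         is.na(mch)]
  base[]
}

#' Compare a QC metric between two groups of libraries
#'
#' Welch two-sample t-test (unequal variances), the standard comparison
#' for per-library QC metrics between protocols. Degenerate input with
#' zero variance in both groups and equal means returns p = 1 by
#' convention; zero variance with different means returns p = 0.
#'
#' @param values numeric metric values.
#' @param groups group labels (exactly two levels, >= 2 values each).
#' @return list with `difference` (mean group2 - group1 in label
#'   order), `t`, `p`, `groups`.
#' @export
compare_groups <- function(values, groups) {
  groups <- as.factor(groups)
  lev <- levels(groups)
  if (length(lev) != 2L) stopf("need exactly two groups")
  x <- values[groups == lev[1]]
  y <- values[groups == lev[2]]
  if (length(x) < 2L || length(y) < 2L)
    stopf("need at least two values per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(difference = mean(y) - mean(x),
                t = if (eq) 0 else Inf,
                p = if (eq) 1 else 0, groups = lev))
  }
  tt <- stats::t.test(y, x, var.equal = FALSE)
  list(difference = unname(tt$estimate[1] - tt$estimate[2]),
       t = unname(tt$statistic), p = tt$p.value, groups = lev)
}
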