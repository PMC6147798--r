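#' Genome-anchored bin definitions
#'
#' Non-overlapping tiles of `bin_size` bp per contig (bin i covers
#' `[i * bin_size, (i + 1) * bin_size)`, 0-based half-open; the terminal
#' partial tile is included).
#'
#' @param genome an `snmc_genome`.
#' @param bin_size tile width in bp (default 100 kb).
#' @param exclude_contigs contigs to exclude (lambda spike-in by
#'   default).
#' @return data.table: `bin` (id), `contig`, `start`, `end`.
#' @export
genome_bins <- function(genome, bin_size = 100000L,
                        exclude_contigs = "lambda") {
  ctgs <- genome$contigs[!genome$contigs$name %in% exclude_contigs, ]
  out <- rbindlist(lapply(seq_len(nrow(ctgs)), function(i) {
    n <- ctgs$length[i]
    starts <- seq.int(0L, n - 1L, by = bin_size)
    data.table(contig = ctgs$name[i], start = starts,
               end = pmin(starts + bin_size, n))
  }))
  out[, bin := sprintf("%s:%d-%d", contig, start, end)]
  setcolorder(out, c("bin", "contig", "start", "end"))
  out[]
}

#' Cell-by-bin CH methylation count matrix
#'
#' Aggregates CH-class allc records into non-overlapping genomic bins
#' (100 kb by default): per cell and bin, the methylated and total
#' basecall counts whose ratio is the bin's mCH level. Totals are
#' conserved: summing over bins recovers each cell's CH totals on the
#' binned contigs.
#'
#' @param allc allc table from [call_methylation()].
#' @param genome the `snmc_genome`.
#' @param bin_size bin width (bp).
#' @param cls context class to aggregate (default `"CH"`).
#' @param exclude_contigs contigs excluded from binning.
#' @return object of class `bin_matrix`: `mc` and `cov` integer
#'   matrices (cells x bins) plus the bin table.
#' @export
bin_mch <- function(allc, genome, bin_size = 100000L, cls = "CH",
                    exclude_contigs = "lambda") {
  allc <- as.data.table(allc)
  bins <- genome_bins(genome, bin_size, exclude_contigs)
  cls_ <- cls
  use <- allc[cls == cls_ & !contig %in% exclude_contigs]
  use[, bin := sprintf("%s:%d-%d", contig,
                       ((pos - 1L) %/% bin_size) * bin_size,
                       pmin(((pos - 1L) %/% bin_size) * bin_size +
                              bin_size,
                            stats::setNames(genome$contigs$length,
                                            genome$contigs$name)[contig]))]
  agg <- use[, .(mc = sum(mc), cov = sum(cov)), by = .(cell, bin)]
  cells <- sort(unique(allc$cell))
  mcM <- matrix(0L, length(cells), nrow(bins),
                dimnames = list(cells, bins$bin))
  covM <- mcM
  ii <- cbind(match(agg$cell, cells), match(agg$bin, bins$bin))
  mcM[ii] <- agg$mc
  covM[ii] <- agg$cov
  structure(list(mc = mcM, cov = covM, bins = bins,
                 bin_size = as.integer(bin_size)),
            class = "bin_matrix")
}

#' @export
print.bin_matrix <- function(x, ...) {
  cat("bin_matrix:", nrow(x$mc), "cells x", ncol(x$mc), "bins (",
      x$bin_size, "bp )\n")
  invisible(x)
}

#' Filter bins by coverage breadth
#'
#' Keeps a bin only if the number of cells with more than
#' `min_basecalls` total basecalls in it exceeds
#' `min_cell_fraction * n_cells` -- both inequalities strict, so a bin
#' covered with exactly `min_basecalls` calls, or in exactly the
#' threshold fraction of cells, is dropped. Idempotent.
#'
#' @param bm a [bin_mch()] matrix.
#' @param min_basecalls coverage threshold per (cell, bin); default 100.
#' @param min_cell_fraction required fraction of cells; default 0.975.
#' @return filtered `bin_matrix`.
#' @export
filter_bins <- function(bm, min_basecalls = 100L,
                        min_cell_fraction = 0.975) {
  stopifnot(inherits(bm, "bin_matrix"))
  n_cells <- nrow(bm$cov)
  ok <- colSums(bm$cov > min_basecalls) > min_cell_fraction * n_cells
  if (!any(ok))
    stopf(paste0("no bins pass the coverage filter (>%d basecalls in ",
                 "more than %.1f%% of cells); lower min_basecalls or ",
                 "min_cell_fraction, or increase sequencing depth"),
          min_basecalls, 100 * min_cell_fraction)
  structure(list(mc = bm$mc[, ok, drop = FALSE],
                 cov = bm$cov[, ok, drop = FALSE],
                 bins = bm$bins[ok], bin_size = bm$bin_size),
            class = "bin_matrix")
}

#' Normalise bin ratios and embed with PCA
#'
#' Bin-level methylation ratios (`mc / cov`) are divided by each cell's
#' global mCH level, removing per-cell global-methylation scale so that
#' clustering reflects relative (regional) differences. Entries with
#' zero coverage in a kept bin are imputed with the bin's across-cell
#' mean normalised ratio; columns are centred (not scaled) and the top
#' `min(n_pcs, rank)` principal components returned.
#'
#' @param bm a filtered [bin_mch()] matrix.
#' @param global_mch per-cell global mCH: data.table from
#'   [global_levels()] or a named numeric vector.
#' @param n_pcs number of principal components requested (default 150).
#' @return object of class `mch_embedding`: `pcs` (cells x components),
#'   `normalized` matrix, `sdev`, and the cells excluded for zero
#'   global mCH.
#' @export
normalize_and_embed <- function(bm, global_mch, n_pcs = 150L) {
  stopifnot(inherits(bm, "bin_matrix"))
  if (is.data.frame(global_mch)) {
    gm <- stats::setNames(global_mch$mch, global_mch$cell)
  } else gm <- global_mch
  cells <- rownames(bm$mc)
  gm <- gm[cells]
  excluded <- cells[is.na(gm) | gm <= 0]
  if (length(excluded))
    warning("excluding cell(s) with zero/missing global mCH: ",
            paste(excluded, collapse = ", "))
  keep <- setdiff(cells, excluded)
  mc <- bm$mc[keep, , drop = FALSE]
  cov <- bm$cov[keep, , drop = FALSE]
  ratio <- ifelse(cov > 0, mc / cov, NA_real_)
  norm <- ratio / gm[keep]
  ## impute missing entries with the bin's across-cell mean
  bin_mean <- colMeans(norm, na.rm = TRUE)
  bin_mean[is.nan(bin_mean)] <- 0
  miss <- which(is.na(norm), arr.ind = TRUE)
  if (nrow(miss)) norm[miss] <- bin_mean[miss[, 2L]]
  pc <- stats::prcomp(norm, center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  structure(list(pcs = pc$x[, seq_len(k), drop = FALSE],
                 normalized = norm, sdev = pc$sdev[seq_len(k)],
                 excluded = excluded, n_pcs = k),
            class = "mch_embedding")
}

#' @export
print.mch_embedding <- function(x, ...) {
  cat("mch_embedding:", nrow(x$pcs), "cells x", x$n_pcs,
      "principal components\n")
  if (length(x$excluded))
    cat("  excluded cells:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Hierarchical clustering of the embedding
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances over
#' the principal components), cut to `k` clusters. When `k` is omitted
#' it is chosen at the largest gap between successive merge heights.
#' Deterministic given its inputs.
#'
#' @param embedding an [normalize_and_embed()] result (or a plain
#'   numeric matrix, cells in rows).
#' @param k number of clusters; `NULL` for the merge-height-gap choice.
#' @return object of class `cluster_assignment`: `clusters` (named
#'   integer vector), `k`, `hclust` tree, `annotation` (empty until
#'   [annotate_clusters()]).
#' @export
cluster_cells <- function(embedding, k = NULL) {
  m <- if (inherits(embedding, "mch_embedding")) embedding$pcs
       else as.matrix(embedding)
  if (!all(is.finite(m))) stopf("embedding contains non-finite values")
  n <- nrow(m)
  if (!is.null(k) && k > n) stopf("k = %d exceeds %d cells", k, n)
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  if (is.null(k)) {
    h <- hc$height
    if (length(h) < 2L) k <- 1L
    else {
      gaps <- diff(h)
      k <- n - which.max(gaps)
    }
  }
  cl <- stats::cutree(hc, k = k)
  structure(list(clusters = cl, k = as.integer(k), hclust = hc,
                 annotation = data.table(cluster = integer(0),
                                         label = character(0))),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment:", length(x$clusters), "cells in", x$k,
      "cluster(s)\n")
  print(table(x$clusters))
  if (nrow(x$annotation)) print(x$annotation)
  invisible(x)
}

#' Gene-body methylation per cluster
#'
#' Pooled `sum(mc) / sum(cov)` over the records of one context class
#' falling in each gene body, per cluster.
#'
#' @param assignment a [cluster_cells()] result.
#' @param allc allc table.
#' @param genome the `snmc_genome` (gene intervals).
#' @param genes gene names to evaluate (default: all annotated genes).
#' @param cls context class (default `"CH"`).
#' @return data.table: `cluster`, `gene`, `mc`, `cov`, `level`.
#' @export
cluster_gene_levels <- function(assignment, allc, genome, genes = NULL,
                                cls = "CH") {
  allc <- as.data.table(allc)
  gn <- genome$genes
  if (!is.null(genes)) gn <- gn[gn$name %in% genes, , drop = FALSE]
  cl <- data.table(cell = names(assignment$clusters),
                   cluster = as.integer(assignment$clusters))
  cls_ <- cls
  out <- rbindlist(lapply(seq_len(nrow(gn)), function(i) {
    sub <- allc[cls == cls_ & contig == gn$contig[i] &
                  pos > gn$start[i] & pos <= gn$end[i]]
    sub <- merge(sub, cl, by = "cell")
    sub[, .(gene = gn$name[i], mc = sum(mc), cov = sum(cov)),
        by = cluster]
  }))
  out[, level := ifelse(cov > 0, mc / cov, NA_real_)]
  out[]
}

#' Annotate clusters by marker gene-body mCH
#'
#' Applies marker rules of the form "low mCH at genes X, Y and high mCH
#' at gene Z": a cluster satisfies the rule when its pooled gene-body
#' mCH is strictly below the across-cluster median for every "low"
#' marker and strictly above it for every "high" marker. Exactly one
#' satisfying cluster receives the label; several satisfying clusters
#' are all labelled and marked ambiguous; none leaves all clusters
#' unlabelled. The default rule identifies layer 2/3 excitatory
#' neurons: low at Cux1 and Satb2, high at Rorb.
#'
#' @param assignment a [cluster_cells()] result.
#' @param allc allc table.
#' @param genome the `snmc_genome`.
#' @param rules named list of rules; each rule is
#'   `list(low = <genes>, high = <genes>)`.
#' @return the assignment with `annotation` (cluster, label, ambiguous)
#'   and `marker_levels` (cluster x marker mCH evidence) filled in.
#' @export
annotate_clusters <- function(assignment, allc, genome,
                              rules = list(`L2/3 excitatory` =
                                list(low = c("Cux1", "Satb2"),
                                     high = "Rorb"))) {
  all_genes <- unique(unlist(lapply(rules, unlist)))
  missing <- setdiff(all_genes, genome$genes$name)
  if (length(missing))
    stopf("marker gene(s) absent from the gene annotation: %s",
          paste(missing, collapse = ", "))
  lv <- cluster_gene_levels(assignment, allc, genome, genes = all_genes)
  ann <- rbindlist(lapply(names(rules), function(lab) {
    rule <- rules[[lab]]
    ok <- rep(TRUE, assignment$k)
    for (gene_ in rule$low) {
      x <- lv[gene == gene_][match(seq_len(assignment$k), cluster), level]
      med <- stats::median(x, na.rm = TRUE)
      ok <- ok & !is.na(x) & x < med
    }
    for (gene_ in rule$high) {
      x <- lv[gene == gene_][match(seq_len(assignment$k), cluster), level]
      med <- stats::median(x, na.rm = TRUE)
      ok <- ok & !is.na(x) & x > med
    }
    hits <- which(ok)
    if (length(hits) == 0L)
      return(data.table(cluster = integer(0), label = character(0),
                        ambiguous = logical(0)))
    data.table(cluster = hits, label = lab,
               ambiguous = length(hits) > 1L)
  }))
  assignment$annotation <- ann
  assignment$marker_levels <- lv
  assignment
}

#' Aggregate clusters and correlate methylation across datasets
#'
#' Pools `mc`/`cov` per interval (optionally restricted to one cluster)
#' in each of two allc datasets and reports the Pearson correlation of
#' the interval-level methylation ratios over intervals covered in
#' both, with its two-sided p-value. Used to compare protocols or
#' replicates over 1 kb bins or DMR-like interval sets.
#'
#' @param allc_x,allc_y the two allc tables.
#' @param intervals data.table of intervals (`contig`, `start`, `end`,
#'   0-based half-open), e.g. from [genome_bins()] or a BED file.
#' @param cls context class to pool (default `"CH"`).
#' @param cells_x,cells_y optional cell subsets (e.g. one cluster's
#'   cells).
#' @param min_shared minimum number of intervals covered in both
#'   datasets (default 3; fewer is refused).
#' @return list: `r`, `p`, `n_intervals`, and the per-interval pooled
#'   ratio table.
#' @export
aggregate_and_correlate <- function(allc_x, allc_y, intervals,
                                    cls = "CH", cells_x = NULL,
                                    cells_y = NULL, min_shared = 3L) {
  iv <- as.data.table(intervals)
  if (!"bin" %in% names(iv))
    iv[, bin := sprintf("%s:%d-%d", contig, start, end)]
  cls_ <- cls
  pool <- function(allc, cells_use) {
    a <- as.data.table(allc)[cls == cls_]
    if (!is.null(cells_use)) a <- a[cell %in% cells_use]
    setkey(iv, contig, start, end)
    a[, `:=`(start = pos - 1L, end = pos)]
    ov <- foverlaps(a, iv[, .(contig, start, end, bin)],
                    type = "within", nomatch = NULL)
    ov[, .(mc = sum(mc), cov = sum(cov)), by = bin]
  }
  px <- pool(allc_x, cells_x)
  py <- pool(allc_y, cells_y)
  m <- merge(px[cov > 0], py[cov > 0], by = "bin",
             suffixes = c("_x", "_y"))
  if (nrow(m) < min_shared)
    stopf("only %d interval(s) covered in both datasets (need >= %d)",
          nrow(m), min_shared)
  rx <- m$mc_x / m$cov_x
  ry <- m$mc_y / m$cov_y
  ct <- stats::cor.test(rx, ry, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_intervals = nrow(m),
       table = m[, .(bin, ratio_x = rx, ratio_y = ry)])
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between cluster assignments; 1 for
#' identical partitions, ~0 for independent ones.
#'
#' @param a,b cluster label vectors of equal length.
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
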