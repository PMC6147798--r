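#' Define a per-cell-type methylome model
#'
#' For each cell type the model gives: the fraction of CG-context
#' cytosines methylated globally and inside CGIs (CGIs are typically
#' hypomethylated), the global fraction of CH-context cytosines methylated
#' (mCH, the neuronal cell-type signature), and per-gene relative mCH
#' multipliers for gene bodies. Gene-body mCH anticorrelates with
#' expression, so a marker gene expressed in a type gets a multiplier
#' below 1 there.
#'
#' @param types named list; each element a list with fields `mcg`
#'   (global CG level), `mcg_cgi` (CG level inside CGIs; defaults to
#'   `mcg`), `mch` (global CH level), and `gene_mult` (named numeric
#'   vector of per-gene mCH multipliers; genes absent default to 1).
#' @return object of class `methylome_model`.
#' @export
methylome_model <- function(types) {
  stopifnot(is.list(types), length(types) >= 1L, !is.null(names(types)))
  types <- lapply(types, function(ty) {
    ty$mcg_cgi <- ty$mcg_cgi %||% ty$mcg
    ty$gene_mult <- ty$gene_mult %||% numeric(0)
    for (f in c("mcg", "mcg_cgi", "mch"))
      if (is.null(ty[[f]]) || ty[[f]] < 0 || ty[[f]] > 1)
        stopf("methylation level '%s' must be given and lie in [0,1]", f)
    ty
  })
  structure(list(types = types), class = "methylome_model")
}

#' @export
print.methylome_model <- function(x, ...) {
  cat("methylome_model:", length(x$types), "cell type(s)\n")
  for (nm in names(x$types)) {
    ty <- x$types[[nm]]
    cat(sprintf("  %s: mCG %.2f (CGI %.2f), mCH %.3f", nm, ty$mcg,
                ty$mcg_cgi, ty$mch))
    if (length(ty$gene_mult))
      cat("; gene mult:", paste0(names(ty$gene_mult), "=",
                                 ty$gene_mult, collapse = ", "))
    cat("\n")
  }
  invisible(x)
}

#' Example methylome model
#'
#' Three cortical-flavoured cell types distinguished by gene-body mCH at
#' the bundled marker genes, mirroring how layer 2/3 excitatory neurons
#' are recognised: the L2/3-like type has low mCH multipliers at Cux1 and
#' Satb2 and a high multiplier at Rorb; the L4-like type is low at all
#' three; the inhibitory-like type is high at Cux1/Satb2.
#'
#' @return a `methylome_model` with types `L23`, `L4`, `Inh`.
#' @export
example_methylome_model <- function() {
  methylome_model(list(
    L23 = list(mcg = 0.75, mcg_cgi = 0.10, mch = 0.030,
               gene_mult = c(Cux1 = 0.30, Satb2 = 0.30, Rorb = 1.60,
                             GeneA = 1.00, GeneB = 0.60, GeneC = 1.40)),
    L4  = list(mcg = 0.78, mcg_cgi = 0.10, mch = 0.035,
               gene_mult = c(Cux1 = 0.40, Satb2 = 0.35, Rorb = 0.30,
                             GeneA = 1.40, GeneB = 1.00, GeneC = 0.60)),
    Inh = list(mcg = 0.72, mcg_cgi = 0.10, mch = 0.045,
               gene_mult = c(Cux1 = 1.50, Satb2 = 1.50, Rorb = 1.00,
                             GeneA = 0.60, GeneB = 1.50, GeneC = 1.00))))
}

#' Simulate per-cell truth methylation states
#'
#' Assigns every callable cytosine in every cell a binary methylation
#' state by an independent Bernoulli draw at the level appropriate to its
#' context class (CG vs CH), region (CGI override for CG; gene-body
#' multiplier for CH) and the cell's type. Cytosines on the lambda
#' spike-in contig are always unmethylated.
#'
#' @param genome an `snmc_genome`.
#' @param model a [methylome_model()].
#' @param n_cells integer: cells per type (scalar or named per-type).
#' @param seed integer seed.
#' @return object of class `snmc_methylome`: the site table, a
#'   sites x cells raw 0/1 state matrix, and a cell metadata table with
#'   assigned in-line barcode and dual-index pool labels.
#' @export
simulate_methylome <- function(genome, model, n_cells = 4L, seed = 1L) {
  stopifnot(inherits(genome, "snmc_genome"),
            inherits(model, "methylome_model"))
  tnames <- names(model$types)
  if (length(n_cells) == 1L)
    n_cells <- stats::setNames(rep(as.integer(n_cells), length(tnames)),
                               tnames)
  cells <- data.table(
    type = rep(tnames, n_cells[tnames]))
  cells[, cell := sprintf("%s_%02d", type, seq_len(.N)), by = type]
  bcs <- default_barcodes()
  cells[, barcode := bcs[((seq_len(nrow(cells)) - 1L) %% length(bcs)) + 1L]]
  cells[, pool := sprintf("pool%02d",
                          ((seq_len(nrow(cells)) - 1L) %/% length(bcs)) + 1L)]
  sites <- genome$sites
  p_by_type <- vapply(tnames, function(tn) {
    site_meth_prob(sites, model$types[[tn]], genome$lambda_contig)
  }, numeric(nrow(sites)))
  states <- withr::with_seed(seed, {
    m <- matrix(raw(1), nrow = nrow(sites), ncol = nrow(cells))
    for (j in seq_len(nrow(cells))) {
      p <- p_by_type[, cells$type[j]]
      m[, j] <- as.raw(runif(nrow(sites)) < p)
    }
    m
  })
  colnames(states) <- cells$cell
  structure(list(sites = sites, states = states, cells = cells,
                 model = model, genome_contigs = genome$contigs),
            class = "snmc_methylome")
}

## Per-site methylation probability for one cell type.
site_meth_prob <- function(sites, ty, lambda_contig) {
  p <- numeric(nrow(sites))
  cg <- sites$cls == "CG"
  p[cg] <- ifelse(sites$in_cgi[cg], ty$mcg_cgi, ty$mcg)
  ch <- !cg
  mult <- rep(1, nrow(sites))
  known <- !is.na(sites$gene) & sites$gene %in% names(ty$gene_mult)
  mult[known] <- ty$gene_mult[sites$gene[known]]
  p[ch] <- pmin(1, ty$mch * mult[ch])
  if (!is.null(lambda_contig)) p[sites$contig == lambda_contig] <- 0
  p
}

#' @export
print.snmc_methylome <- function(x, ...) {
  cat("snmc_methylome:", nrow(x$cells), "cells x", nrow(x$sites),
      "cytosine sites\n")
  print(x$cells[, .N, by = type])
  invisible(x)
}

#' Truth methylation levels aggregated from a simulated methylome
#'
#' Averages the binary truth states over a chosen set of sites and cells;
#' the reference against which callers and the clustering stages are
#' validated.
#'
#' @param methylome an `snmc_methylome`.
#' @param cls context class (`"CG"`, `"CH"`, or `NULL` for all).
#' @param gene restrict to one gene body (optional).
#' @param cells character vector of cell ids (default all).
#' @return data.table with per-cell mean truth level and site count.
#' @export
truth_levels <- function(methylome, cls = NULL, gene = NULL, cells = NULL) {
  keep <- rep(TRUE, nrow(methylome$sites))
  if (!is.null(cls)) keep <- keep & methylome$sites$cls == cls
  if (!is.null(gene)) keep <- keep & !is.na(methylome$sites$gene) &
      methylome$sites$gene == gene
  cells <- cells %||% methylome$cells$cell
  sub <- methylome$states[keep, cells, drop = FALSE]
  data.table(cell = cells,
             level = colMeans(sub != as.raw(0)),
             n_sites = sum(keep))
}
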