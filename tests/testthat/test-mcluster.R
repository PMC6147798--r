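## A small genome object whose contigs tile into few 100 kb bins.
toy_genome <- function() {
  memo("toy_genome", function() {
    spec <- genome_spec(data.frame(name = c("c1", "c2"),
                                   length = c(250000L, 150000L)),
                        gc_fraction = 0.4, seed = 17L)
    simulate_genome(spec)
  })
}

toy_allc <- function(recs) {
  data.table::data.table(
    cell = recs$cell, contig = recs$contig, pos = recs$pos,
    strand = "+", context = "CAT", cls = recs$cls %||% "CH",
    mc = recs$mc, cov = recs$cov, methylated = FALSE)
}

test_that("bin ratios and boundary assignment conserve totals", {
  g <- toy_genome()
  allc <- toy_allc(list(
    cell = rep("k1", 3),
    contig = c("c1", "c1", "c1"),
    pos = c(5000L, 100000L, 100001L),   # bin 0, bin 0 (last bp), bin 1
    mc = c(3L, 2L, 7L), cov = c(10L, 4L, 14L)))
  bm <- bin_mch(allc, g)
  expect_equal(unname(bm$mc["k1", "c1:0-100000"]), 5L)
  expect_equal(unname(bm$cov["k1", "c1:0-100000"]), 14L)
  expect_equal(unname(bm$mc["k1", "c1:100000-200000"]), 7L)
  ## single-record ratio
  expect_equal(unname(bm$mc["k1", "c1:100000-200000"] /
                        bm$cov["k1", "c1:100000-200000"]), 0.5)
  ## conservation over all bins
  expect_equal(sum(bm$mc), sum(allc$mc))
  expect_equal(sum(bm$cov), sum(allc$cov))
  ## bins tile contigs without overlap
  expect_equal(sum(bm$bins$end - bm$bins$start),
               sum(g$contigs$length))
})

test_that("bin totals equal allc CH totals per cell in a real run", {
  res <- fix_pipeline()
  bm <- bin_mch(res$allc, res$genome)
  ch <- res$allc[cls == "CH" & contig != "lambda",
                 .(mc = sum(mc), cov = sum(cov)), by = cell]
  for (cl in ch$cell) {
    expect_equal(sum(bm$mc[cl, ]), ch[cell == cl, mc])
    expect_equal(sum(bm$cov[cl, ]), ch[cell == cl, cov])
  }
})

test_that("filter_bins applies strict inequalities at both levels", {
  mk <- function(covmat) {
    structure(list(mc = covmat * 0L, cov = covmat,
                   bins = data.table::data.table(
                     bin = colnames(covmat), contig = "c1",
                     start = 0L, end = 1L)[seq_len(ncol(covmat))],
                   bin_size = 100000L), class = "bin_matrix")
  }
  ## all cells above threshold: kept
  m1 <- matrix(101L, nrow = 10, ncol = 2,
               dimnames = list(paste0("c", 1:10), c("b1", "b2")))
  expect_equal(ncol(filter_bins(mk(m1))$cov), 2L)
  ## coverage exactly 100 in every cell: dropped (needs > 100)
  m2 <- m1; m2[, 2] <- 100L
  expect_error(f2 <- filter_bins(mk(m2[, 2, drop = FALSE])), "no bins")
  ## 39 of 40 cells = 97.5% exactly: dropped (needs more than 97.5%)
  m3 <- matrix(101L, nrow = 40, ncol = 2,
               dimnames = list(paste0("c", 1:40), c("b1", "b2")))
  m3[1, 2] <- 0L
  f3 <- filter_bins(mk(m3))
  expect_equal(colnames(f3$cov), "b1")
  ## idempotence
  f3b <- filter_bins(f3)
  expect_equal(f3b$cov, f3$cov)
})

test_that("normalisation divides by global mCH and imputes missing bins", {
  cov <- matrix(1000L, 2, 3,
                dimnames = list(c("a", "b"), c("b1", "b2", "b3")))
  mc <- matrix(rep(c(40L, 80L), 3), 2, 3, dimnames = dimnames(cov))
  bm <- structure(list(mc = mc, cov = cov,
                       bins = data.table::data.table(
                         bin = colnames(cov), contig = "c1",
                         start = 0L, end = 1L),
                       bin_size = 100000L), class = "bin_matrix")
  ## cell a: every bin ratio 0.04 = its global mCH -> row of ones
  emb <- normalize_and_embed(bm, c(a = 0.04, b = 0.08), n_pcs = 10L)
  expect_equal(unname(emb$normalized["a", ]), rep(1, 3))
  expect_equal(unname(emb$normalized["b", ]), rep(1, 3))
  ## rank clipping: no failure when n_pcs exceeds the rank
  expect_lte(emb$n_pcs, 3L)
  ## a cov-0 entry is imputed with the bin's across-cell mean
  cov2 <- cov; cov2["a", "b2"] <- 0L
  bm2 <- bm; bm2$cov <- cov2
  emb2 <- normalize_and_embed(bm2, c(a = 0.04, b = 0.08), n_pcs = 2L)
  expect_equal(unname(emb2$normalized["a", "b2"]),
               unname(emb2$normalized["b", "b2"]))
  ## zero global mCH excludes the cell with a warning
  expect_warning(emb3 <- normalize_and_embed(bm, c(a = 0.04, b = 0)),
                 "excluding")
  expect_equal(rownames(emb3$pcs), "a")
})

test_that("cluster structure is invariant to scaling a cell's methylome", {
  cov <- matrix(10000L, 3, 4)
  rownames(cov) <- c("a", "b", "c")
  colnames(cov) <- paste0("b", 1:4)
  ratios <- rbind(c(.02, .04, .03, .05),
                  c(.05, .02, .04, .03),
                  c(.03, .05, .02, .04))
  mk <- function(scale_a) {
    r <- ratios; r[1, ] <- r[1, ] * scale_a
    structure(list(mc = round(r * cov), cov = cov,
                   bins = data.table::data.table(
                     bin = colnames(cov), contig = "c1", start = 0L,
                     end = 1L),
                   bin_size = 100000L), class = "bin_matrix")
  }
  gm <- function(scale_a) c(a = 0.035 * scale_a, b = 0.035, c = 0.035)
  n1 <- normalize_and_embed(mk(1), gm(1), n_pcs = 3L)$normalized
  n2 <- normalize_and_embed(mk(2), gm(2), n_pcs = 3L)$normalized
  expect_equal(n1, n2, tolerance = 1e-12)
})

test_that("clustering recovers three simulated types at high ARI", {
  ## bin-level simulation: 3 types x 20 cells over 40 bins with
  ## type-specific relative mCH profiles
  n_bins <- 40L; per_type <- 20L
  truth <- rep(1:3, each = per_type)
  profiles <- lapply(1:3, function(t)
    0.04 * exp(0.35 * sin(seq_len(n_bins) / 2 + 2 * t)))
  ## mc[i, j] ~ Binom(cov[i, j], profile[truth[i]][j])
  p_cell <- t(vapply(truth, function(t) profiles[[t]], numeric(n_bins)))
  withr::with_seed(78, {
    cov <- matrix(rpois(3 * per_type * n_bins, 2000) + 200L,
                  nrow = 3 * per_type)
    mc <- matrix(rbinom(length(cov), as.vector(cov), as.vector(p_cell)),
                 nrow = nrow(cov))
  })
  dimnames(cov) <- dimnames(mc) <-
    list(sprintf("cell%02d", seq_len(nrow(cov))),
         sprintf("b%02d", seq_len(n_bins)))
  bm <- structure(list(mc = mc, cov = cov,
                       bins = data.table::data.table(
                         bin = colnames(cov), contig = "c1",
                         start = seq_len(n_bins), end = seq_len(n_bins) + 1L),
                       bin_size = 100000L), class = "bin_matrix")
  bm <- filter_bins(bm)
  gm <- stats::setNames(rowSums(mc) / rowSums(cov), rownames(cov))
  emb150 <- normalize_and_embed(bm, gm, n_pcs = 150L)
  cl150 <- cluster_cells(emb150, k = 3L)
  ari <- adjusted_rand_index(cl150$clusters, truth)
  expect_gte(ari, 0.9)
  ## robust to the number of principal components
  emb10 <- normalize_and_embed(bm, gm, n_pcs = 10L)
  cl10 <- cluster_cells(emb10, k = 3L)
  expect_gte(adjusted_rand_index(cl150$clusters, cl10$clusters), 0.9)
  ## own ARI agrees with the mclust reference implementation
  expect_equal(ari, mclust::adjustedRandIndex(cl150$clusters, truth),
               tolerance = 1e-12)
  expect_equal(adjusted_rand_index(truth, truth), 1)
})

test_that("degenerate embeddings cluster sensibly", {
  m <- matrix(1, nrow = 6, ncol = 3,
              dimnames = list(paste0("c", 1:6), NULL))
  cl <- cluster_cells(m, k = 2L)
  ## identical rows: all merge heights zero -> one effective cluster
  expect_true(all(cl$hclust$height < 1e-12))
  expect_error(cluster_cells(m, k = 10L), "exceeds")
  expect_error(cluster_cells(m * NA), "non-finite")
})

test_that("marker rules label, refuse ties, and flag ambiguity", {
  g <- genome_from_sequences(
    c(c1 = strrep("ACAT", 7500)),
    genes = data.frame(contig = "c1", start = c(0L, 10000L, 20000L),
                       end = c(10000L, 20000L, 30000L),
                       name = c("Cux1", "Satb2", "Rorb"),
                       marker = TRUE))
  mk_allc <- function(levels_by_cluster) {
    ## levels_by_cluster: list of c(cux1, satb2, rorb) per cluster
    rbindlist(lapply(seq_along(levels_by_cluster), function(k) {
      lv <- levels_by_cluster[[k]]
      toy_allc(list(cell = rep(sprintf("cell%d", k), 3),
                    contig = rep("c1", 3),
                    pos = c(5000L, 15000L, 25000L),
                    mc = as.integer(round(lv * 1000)),
                    cov = rep(1000L, 3)))
    }))
  }
  mk_assign <- function(n) {
    structure(list(clusters = stats::setNames(seq_len(n),
                                              sprintf("cell%d", seq_len(n))),
                   k = n, hclust = NULL,
                   annotation = data.table::data.table()),
              class = "cluster_assignment")
  }
  ## 3 clusters; cluster 1 low/low/high
  a1 <- annotate_clusters(mk_assign(3),
                          mk_allc(list(c(.01, .01, .06),
                                       c(.03, .03, .04),
                                       c(.05, .05, .02))),
                          g)
  expect_equal(a1$annotation$cluster, 1L)
  expect_false(a1$annotation$ambiguous)
  ## identical marker levels: median rule unsatisfiable, no label
  a2 <- annotate_clusters(mk_assign(3),
                          mk_allc(rep(list(c(.03, .03, .03)), 3)), g)
  expect_equal(nrow(a2$annotation), 0L)
  ## 4 clusters, two satisfying: both reported, flagged ambiguous
  a3 <- annotate_clusters(mk_assign(4),
                          mk_allc(list(c(.01, .01, .06),
                                       c(.015, .015, .055),
                                       c(.05, .05, .02),
                                       c(.06, .06, .01))),
                          g)
  expect_equal(sort(a3$annotation$cluster), c(1L, 2L))
  expect_true(all(a3$annotation$ambiguous))
  ## unknown marker gene rejected
  expect_error(annotate_clusters(mk_assign(3), mk_allc(list(
    c(.01, .01, .06), c(.03, .03, .04), c(.05, .05, .02))), g,
    rules = list(x = list(low = "Nope", high = "Rorb"))), "Nope")
})

test_that("correlation behaves on identical, complementary and replicate data", {
  g <- toy_genome()
  iv <- genome_bins(g, 1000L)
  withr::with_seed(91, {
    pos <- sort(sample(2000:240000, 400))
    cov <- rep(2000L, 400)
    p <- runif(400, 0.01, 0.09)
    allc_x <- toy_allc(list(cell = rep("r1", 400), contig = rep("c1", 400),
                            pos = pos, mc = rbinom(400, cov, p), cov = cov))
    allc_y <- toy_allc(list(cell = rep("r2", 400), contig = rep("c1", 400),
                            pos = pos, mc = rbinom(400, cov, p), cov = cov))
  })
  self <- aggregate_and_correlate(allc_x, allc_x, iv)
  expect_equal(self$r, 1.0)
  compl <- data.table::copy(allc_x)[, mc := cov - mc]
  anti <- aggregate_and_correlate(allc_x, compl, iv)
  expect_equal(anti$r, -1.0)
  rep2 <- aggregate_and_correlate(allc_x, allc_y, iv)
  expect_gt(rep2$r, 0.9)
  expect_lt(rep2$p, 1e-6)
  ## too few shared intervals refused
  expect_error(aggregate_and_correlate(allc_x[1:2], allc_y[1:2], iv),
               "interval")
})
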