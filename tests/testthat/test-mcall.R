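test_that("single-read basecalls produce the expected allc records", {
  ## genome with one CG and one CH cytosine inside the read
  g <- genome_from_sequences(c(c1 = "AACGTACATTTTTTTTTTTT"))
  ## read covers positions 1-12, reports Watson cytosines (CT frame):
  ## C at 3 (CG context) kept as C -> methylated; C at 7 (CA) read as T
  hit <- data.table::data.table(
    pair_id = "p1", mate = 1L, cell = "k1", ctg = "c1", start0 = 0L,
    strand = "+", frame = "CT", qlen = 12L, score = 12L, mm = 0L,
    mapq = 60L, oriented = "AACGTATATTTT")
  allc <- call_methylation(hit, g)
  cg <- allc[pos == 3L]
  expect_equal(cg$mc, 1L); expect_equal(cg$cov, 1L)
  expect_equal(cg$cls, "CG"); expect_equal(cg$strand, "+")
  ch <- allc[pos == 7L]
  expect_equal(ch$mc, 0L); expect_equal(ch$cov, 1L)
  expect_equal(ch$cls, "CH")
})

test_that("basecalls accumulate to mc/cov ratios over reads", {
  g <- genome_from_sequences(c(c1 = "AACATACATTTTTTTTTTTT"))
  ## CH cytosine at pos 3; 10 reads, 3 retained as C
  hits <- data.table::data.table(
    pair_id = sprintf("p%02d", 1:10), mate = 1L, cell = "k1", ctg = "c1",
    start0 = 0L, strand = "+", frame = "CT", qlen = 12L, score = 12L,
    mm = 0L, mapq = 60L,
    oriented = c(rep("AACATATATTTT", 3), rep("AATATATATTTT", 7)))
  allc <- call_methylation(hits, g)
  rec <- allc[pos == 3L]
  expect_equal(rec$mc, 3L)
  expect_equal(rec$cov, 10L)
  expect_equal(rec$mc / rec$cov, 0.3)
})

test_that("GA-frame hits report Crick cytosines on the minus strand", {
  g <- genome_from_sequences(c(c1 = "AATGTACGTTTTTTTTTTTT"))
  ## Crick cytosine at Watson G position 8 (CG context); read retains G
  hit <- data.table::data.table(
    pair_id = "p1", mate = 2L, cell = "k1", ctg = "c1", start0 = 0L,
    strand = "+", frame = "GA", qlen = 12L, score = 12L, mm = 0L,
    mapq = 60L, oriented = "AATGTACGTTTT")
  allc <- call_methylation(hit, g)
  ## minus-strand cytosines at Watson-G positions 4 (CH) and 8 (CG)
  expect_equal(allc$pos, c(4L, 8L))
  expect_true(all(allc$strand == "-"))
  rec <- allc[pos == 8L]
  expect_equal(rec$cls, "CG")
  expect_equal(rec$mc, 1L)
})

test_that("overlapping mates contribute one basecall, R1's", {
  g <- genome_from_sequences(c(c1 = "AACGTACATTTTTTTTTTTT"))
  hits <- data.table::data.table(
    pair_id = "p1", mate = c(1L, 2L), cell = "k1", ctg = "c1",
    start0 = 0L, strand = c("+", "-"), frame = "CT", qlen = 12L,
    score = 12L, mm = 0L, mapq = 60L,
    oriented = c("AACGTATATTTT",   # R1: C at the CG site
                 "AATGTATATTTT"))  # R2 disagrees (T)
  allc <- call_methylation(hits, g)
  rec <- allc[pos == 3L]
  expect_equal(rec$cov, 1L)
  expect_equal(rec$mc, 1L)   # R1's basecall wins
})

test_that("calls equal the truth exactly at conversion 1 and zero error", {
  g <- fix_genome(); me <- fix_methylome()
  p <- library_params(conversion_rate = 1, seq_error_rate = 0,
                      dimer_fraction = 0, duplicate_rate = 0,
                      lambda_spike_fraction = 0)
  lib <- simulate_library(g, me, p, 1200L, seed = 44L)
  dm <- demultiplex(lib$reads[, .(pair_id, r1, r2)], barcode_set())
  dm$reads[, cell := stats::setNames(me$cells$cell,
                                     me$cells$barcode)[barcode]]
  tr <- trim_reads(dm$reads, trim_policy())
  fh <- filter_alignments(
    align_reads(reads_long(tr[trim_class == "keep"]), fix_index()), 10L)
  allc <- call_methylation(fh, g, conversion_rate = 1)
  chk <- merge(allc, me$sites[, .(contig, pos, strand, site)],
               by = c("contig", "pos", "strand"))
  expect_equal(nrow(chk), nrow(allc))   # every record is a known site
  ts <- me$states[cbind(chk$site,
                        match(chk$cell, colnames(me$states)))] != as.raw(0)
  expect_true(all(ifelse(ts, chk$mc == chk$cov, chk$mc == 0L)))
})

test_that("conversion-rate estimation follows its definition", {
  allc <- data.table::data.table(
    cell = "k1", contig = c("lambda", "lambda", "chr1"),
    pos = c(10L, 20L, 5L), strand = "+", context = "CAT", cls = "CH",
    mc = c(2L, 4L, 50L), cov = c(400L, 600L, 60L), methylated = FALSE)
  est <- estimate_conversion(allc, "lambda")
  expect_equal(est$nonconverted, 6L)
  expect_equal(est$total, 1000L)
  expect_equal(est$rate, 0.994)
  expect_true(est$passes_threshold)
  ## complete conversion
  allc2 <- data.table::copy(allc)[contig == "lambda", mc := 0L]
  expect_equal(estimate_conversion(allc2, "lambda")$rate, 1.0)
  ## zero lambda coverage flags the cell
  est0 <- estimate_conversion(allc[contig == "chr1"], "lambda")
  expect_true(is.na(est0$rate))
  expect_false(est0$passes_threshold)
})

test_that("global levels sum the context classes independently", {
  allc <- data.table::data.table(
    cell = "k1", contig = "chr1", pos = 1:4, strand = "+",
    context = c("CGA", "CGT", "CAT", "CTT"),
    cls = c("CG", "CG", "CH", "CH"),
    mc = c(8L, 2L, 1L, 0L), cov = c(10L, 10L, 20L, 20L),
    methylated = FALSE)
  gl <- global_levels(allc)
  expect_equal(gl$mcg, 0.5)     # (8+2)/20
  expect_equal(gl$mch, 0.025)   # 1/40
  expect_equal(gl$mcg_cov, 20L)
  expect_equal(gl$mch_cov, 40L)
})

test_that("Watson and Crick mCG agree within binomial error", {
  res <- fix_pipeline()
  cg <- res$allc[cls == "CG" & contig != "lambda"]
  by_strand <- cg[, .(m = sum(mc) / sum(cov), n = sum(cov)), by = strand]
  expect_equal(nrow(by_strand), 2L)
  p_hat <- sum(cg$mc) / sum(cg$cov)
  se <- sqrt(p_hat * (1 - p_hat) * sum(1 / by_strand$n))
  expect_lt(abs(diff(by_strand$m)), 4 * se + 0.02)
})

test_that("apparent mCH tracks true mCH plus conversion failure", {
  g <- fix_genome(); me <- fix_methylome()
  p <- library_params(conversion_rate = 0.95, seq_error_rate = 0,
                      dimer_fraction = 0, duplicate_rate = 0,
                      lambda_spike_fraction = 0)
  lib <- simulate_library(g, me, p, 1500L, seed = 45L)
  dm <- demultiplex(lib$reads[, .(pair_id, r1, r2)], barcode_set())
  dm$reads[, cell := stats::setNames(me$cells$cell,
                                     me$cells$barcode)[barcode]]
  tr <- trim_reads(dm$reads, trim_policy())
  fh <- filter_alignments(
    align_reads(reads_long(tr[trim_class == "keep"]), fix_index()), 10L)
  allc <- call_methylation(fh, g, conversion_rate = 0.95)
  gl <- global_levels(allc)
  truth <- truth_levels(me, cls = "CH")
  m <- merge(gl, truth, by = "cell")
  expected <- m$level + (1 - m$level) * 0.05
  se <- sqrt(expected * (1 - expected) / m$mch_cov)
  expect_true(all(abs(m$mch - expected) < 4 * se))
})

test_that("the methylated-call flag behaves at its binomial threshold", {
  g <- genome_from_sequences(c(c1 = "AACGTACATTTTTTTTTTTT"))
  mk <- function(base, n) data.table::data.table(
    pair_id = sprintf("p%d", 1:n), mate = 1L, cell = "k", ctg = "c1",
    start0 = 0L, strand = "+", frame = "CT", qlen = 12L, score = 12L,
    mm = 0L, mapq = 60L,
    oriented = rep(sub("x", base, "AAxGTATATTTT"), n))
  ## 5/5 C at conversion .995: p = (1-.995)^5 << .01 -> flagged
  a1 <- call_methylation(mk("C", 5), g, 0.995)
  expect_true(a1[pos == 3L, methylated])
  ## 0/5 C: never flagged
  a2 <- call_methylation(mk("T", 5), g, 0.995)
  expect_false(a2[pos == 3L, methylated])
})

test_that("allc tables survive a write/read round trip", {
  res <- fix_pipeline()
  dir <- file.path(tempdir(), "allc_rt")
  paths <- write_allc(res$allc, dir)
  back <- read_allc(paths)
  orig <- data.table::copy(res$allc)
  data.table::setorder(orig, cell, contig, pos, strand)
  data.table::setorder(back, cell, contig, pos, strand)
  expect_equal(back$mc, orig$mc)
  expect_equal(back$cov, orig$cov)
  expect_equal(back$cls, orig$cls)
})
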