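test_that("the default multiplexing configuration yields 6144 cell labels", {
  labs <- cell_labels(barcode_set())
  expect_length(labs, 6144L)
  expect_equal(anyDuplicated(labs), 0L)
})

test_that("ambiguous barcode sets are rejected at load", {
  ## distance 2 with max_mismatch 1 violates d > 2 * max_mismatch
  expect_error(barcode_set(c("AAAAAAAA", "AAAAAATT"), max_mismatch = 1L),
               "Hamming")
  ## fine at max_mismatch 0
  expect_silent(barcode_set(c("AAAAAAAA", "AAAAAATT"), max_mismatch = 0L))
})

test_that("demultiplexing partitions reads and strips barcodes", {
  bs <- barcode_set()
  withr::with_seed(11, {
    bcs <- sample(bs$barcodes, 92, replace = TRUE)
    body <- replicate(92, rand_dna(40))
    reads <- data.table::data.table(
      pair_id = sprintf("p%03d", 1:100),
      r1 = c(paste0(bcs, body), character(8)),
      r2 = strrep("A", 48))
    ## 5 reads with exactly one substitution in the barcode
    sub1 <- sample(bs$barcodes, 5, replace = TRUE)
    for (i in seq_len(5)) {
      pos <- sample(8, 1)
      old <- substr(sub1[i], pos, pos)
      substr(sub1[i], pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    reads$r1[93:97] <- paste0(sub1, rand_dna(40))
    ## 3 reads with prefixes at distance >= 2 from every barcode
    far <- character(0)
    while (length(far) < 3) {
      cand <- rand_dna(8)
      if (min(vapply(bs$barcodes,
                     function(b) sum(hamming_to(cand, b)), 1L)) > 1)
        far <- c(far, cand)
    }
    reads$r1[98:100] <- paste0(far, rand_dna(40))
  })
  dm <- demultiplex(reads, bs)
  expect_equal(sum(dm$counts$n), 100L)
  expect_equal(nrow(dm$reads), 97L)
  expect_equal(nrow(dm$unassigned), 3L)
  expect_true(all(nchar(dm$reads$r1) == 40L))
  ## no read assigned twice
  expect_equal(anyDuplicated(dm$reads$pair_id), 0L)
})

test_that("empty input demultiplexes to zero counts everywhere", {
  dm <- demultiplex(data.table::data.table(pair_id = character(0),
                                           r1 = character(0),
                                           r2 = character(0)),
                    barcode_set())
  expect_true(all(dm$counts$n == 0L))
  expect_equal(nrow(dm$reads), 0L)
})

test_that("a planted 12-nt tail is recovered and the genomic part kept intact", {
  genomic <- "ACAACCACAATACCAAACCATACAACCATAACACCAATAC"  # G/T-free
  tail12 <- "GTGGTTGTTGGT"
  pol <- trim_policy(fixed_5p_r1 = 0L, fixed_3p_r1 = 0L,
                     fixed_5p_r2 = 0L, fixed_3p_r2 = 0L)
  res <- trim_pair(r1 = strrep("A", 40), r2 = paste0(tail12, genomic),
                   policy = pol)
  expect_equal(res$tail_len, 12L)
  expect_equal(res$r2, genomic)
  expect_equal(res$class, "keep")
})

test_that("adapter-only pairs are classified dimer_or_short", {
  pol <- trim_policy()
  ad <- snmcpipe:::ADAPTER_R1
  res <- trim_pair(r1 = substr(strrep(ad, 4), 1, 92),
                   r2 = substr(strrep(snmcpipe:::ADAPTER_R2, 4), 1, 100),
                   policy = pol)
  expect_equal(res$class, "dimer_or_short")
})

test_that("trimming never increases read length and respects tail_max", {
  g <- fix_genome(); me <- fix_methylome()
  lib <- simulate_library(g, me, library_params(), 500L, seed = 2L)
  tr <- trim_reads(lib$reads, trim_policy())
  expect_true(all(nchar(tr$r1) <= nchar(lib$reads$r1)))
  expect_true(all(nchar(tr$r2) <= nchar(lib$reads$r2)))
  expect_true(all(tr$tail_len <= 50L))
})

test_that("dimer-free tail-free input with long inserts is all kept", {
  g <- fix_genome(); me <- fix_methylome()
  p <- library_params(dimer_fraction = 0, tail_mean = 0,
                      seq_error_rate = 0)
  lib <- simulate_library(g, me, p, 400L, seed = 6L)
  tr <- trim_reads(lib$reads, trim_policy())
  expect_true(all(tr$trim_class == "keep"))
})

test_that("composition profiles match hand counts and sum to one", {
  p1 <- composition_profile(rep("AAAA", 3), 4L)
  expect_equal(p1$A, rep(1, 4))
  p2 <- composition_profile(c("ACGT", "AAGT"), 4L)
  expect_equal(p2$C[2], 0.5)
  expect_equal(p2$A[2], 0.5)
  expect_equal(p2[, A + C + G + T + N], rep(1, 4), tolerance = 1e-9)
  ## short reads drop out of later positions' denominators
  p3 <- composition_profile(c("ACGT", "AC"), 4L)
  expect_equal(p3$n, c(2L, 2L, 1L, 1L))
  p0 <- composition_profile(character(0), 4L)
  expect_true(attr(p0, "empty"))
})

test_that("expected post-bisulfite composition follows the closed form", {
  e1 <- expected_composition(f_c = 0.2, f_t = 0.3, m_bar = 0,
                             conversion_rate = 1)
  expect_equal(e1$expected_c, 0)
  expect_equal(e1$expected_t, 0.5)
  ## the ~1% C regime of a mammalian neuronal genome
  e2 <- expected_composition(f_c = 0.21, f_t = 0.29, m_bar = 0.057,
                             conversion_rate = 1)
  expect_equal(e2$expected_c, 0.21 * 0.057)
  expect_lt(abs(e2$expected_c - 0.012), 5e-4)
})

test_that("the closed form matches simulated interior R1 composition", {
  g <- fix_genome(); me <- fix_methylome()
  p <- library_params(seq_error_rate = 0, dimer_fraction = 0,
                      duplicate_rate = 0, lambda_spike_fraction = 0)
  lib <- simulate_library(g, me, p, 4000L, seed = 14L)
  ## R1 is the converted-sense read: beyond the 8-nt barcode its
  ## interior positions sample the genome approximately uniformly
  body <- substr(lib$reads$r1, 9L, 100L)
  prof <- composition_profile(body, 80L)
  obs_c <- mean(prof$C[10:80]); obs_t <- mean(prof$T[10:80])
  ## plug-in expectation from genome composition and truth methylation
  auto <- g$sequences[c("chr1", "chr2")]
  f <- function(b) mean(vapply(auto, function(s)
    lengths(gregexpr(b, s)) / nchar(s), numeric(1)))
  f_c <- (f("C") + f("G")) / 2   # read strand averages the two strands
  f_t <- (f("T") + f("A")) / 2
  cg <- truth_levels(me, cls = "CG"); ch <- truth_levels(me, cls = "CH")
  m_bar <- (mean(cg$level) * cg$n_sites[1] +
              mean(ch$level) * ch$n_sites[1]) /
    (cg$n_sites[1] + ch$n_sites[1])
  e <- expected_composition(f_c, f_t, m_bar, p$conversion_rate)
  expect_lt(abs(obs_c - e$expected_c), 0.005)
  expect_lt(abs(obs_t - e$expected_t), 0.005)
})

test_that("the anomaly flag separates contaminated from clean R2 profiles", {
  g <- fix_genome(); me <- fix_methylome()
  cont <- library_params(seq_error_rate = 0,
                         tail_alphabet_weights = c(A = .25, C = .25,
                                                   G = .25, T = .25))
  lib_x <- simulate_library(g, me, cont, 2000L, seed = 15L)
  lib_c <- simulate_library(g, me, library_params(seq_error_rate = 0),
                            2000L, seed = 15L)
  ## frame-appropriate baseline for R2 starts: the molecule's G
  ## frequency (~GC/2), which is what a tail-free R2 base reads as C
  f_exp <- 0.21
  expect_true(composition_anomaly(composition_profile(lib_x$reads$r2, 10L),
                                  expected_c = f_exp))
  expect_false(composition_anomaly(composition_profile(lib_c$reads$r2, 10L),
                                   expected_c = f_exp))
})
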