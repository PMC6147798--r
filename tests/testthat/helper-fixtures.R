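## Shared fixtures, built once per test session and memoised.
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

## The bundled demonstration genome (2 x 300 kb + 10 kb lambda).
fix_genome <- function() memo("genome", function() {
  simulate_genome(example_genome_spec())
})

fix_methylome <- function() memo("methylome", function() {
  simulate_methylome(fix_genome(), example_methylome_model(),
                     n_cells = 2L, seed = 101L)
})

fix_index <- function() memo("index", function() {
  converted_index(fix_genome())
})

## A small genome (two 12 kb contigs, no lambda) for aligner oracles.
fix_small_genome <- function() memo("small_genome", function() {
  spec <- genome_spec(
    data.frame(name = c("ctgA", "ctgB"), length = c(12000L, 10000L)),
    gc_fraction = 0.42, seed = 31L)
  simulate_genome(spec)
})

## One full default-condition pipeline run (the end-to-end fixture).
fix_pipeline <- function() memo("pipeline", function() {
  cfg <- pipeline_config(list(
    simulate = list(n_cells = 4L, n_pairs_per_cell = 400L)))
  run_pipeline(cfg, quiet = TRUE)
})

## Random DNA string helper for constructed cases.
rand_dna <- function(n, seed = NULL, prob = c(.29, .21, .21, .29)) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, TRUE,
                                  prob = prob), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
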