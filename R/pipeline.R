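PIPELINE_STAGES <- c("simulate", "demux", "trim", "align", "call", "qc",
                     "cluster")

default_config <- function() {
  list(
    seed = 1L,
    stages = PIPELINE_STAGES,
    simulate = list(n_cells = 4L, n_pairs_per_cell = 300L,
                    genome_seed = 7L),
    library = list(conversion_rate = 0.995, read_length = 100L,
                   insert_mean = 250, insert_sd = 50,
                   dimer_fraction = 0.06, tail_mean = 8, tail_max = 50,
                   duplicate_rate = 0.10, seq_error_rate = 0.001,
                   lambda_spike_fraction = 0.01, cgi_bias = 1),
    demux = list(max_mismatch = 1L),
    trim = list(fixed_5p_r1 = 16L, fixed_3p_r1 = 16L, fixed_5p_r2 = 16L,
                fixed_3p_r2 = 16L, r2_extra_5p = 0L, min_insert = 30L,
                detect_tail = TRUE),
    align = list(k = 16L, mapq_min = 10L),
    call = list(),
    qc = list(reference_pairs = 50e6),
    cluster = list(bin_size = 100000L, min_basecalls = 100L,
                   min_cell_fraction = 0.975, n_pcs = 150L, k = NULL),
    log_level = "info")
}

#' Build and validate a pipeline configuration
#'
#' Merges user settings over the defaults, which reproduce the standard
#' parameters of the protocol's analysis: 16 bp fixed trims, MAPQ > 10,
#' 100 kb bins filtered at >100 basecalls in more than 97.5% of cells,
#' 150 principal components, and a 50-million-read-pair reference depth
#' for complexity. Unknown keys (at either level) are rejected before
#' any stage runs. Configurations can be read from and written to YAML.
#'
#' @param config named list of overrides, or a YAML file path.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config()
  bad <- setdiff(names(config), names(base))
  if (length(bad))
    stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  for (k in names(config)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      bad2 <- setdiff(names(config[[k]]), names(base[[k]]))
      if (length(bad2))
        stopf("unknown config key(s) under '%s': %s", k,
              paste(bad2, collapse = ", "))
      base[[k]][names(config[[k]])] <- config[[k]]
    } else {
      base[[k]] <- config[[k]]
    }
  }
  if (!all(base$stages %in% PIPELINE_STAGES))
    stopf("unknown stage(s): %s",
          paste(setdiff(base$stages, PIPELINE_STAGES), collapse = ", "))
  ## stages must form a prefix of the fixed order
  base$stages <- PIPELINE_STAGES[seq_len(
    max(match(base$stages, PIPELINE_STAGES)))]
  structure(base, class = "pipeline_config")
}

#' Run the pipeline
#'
#' Executes the stages in order (simulate, demux, trim, align, call,
#' qc, cluster; any prefix via `config$stages`), carrying all
#' intermediate results in the returned list together with a run
#' manifest (package version, seeds, parameter digest). Reruns with the
#' same configuration are bit-identical through alignment and
#' deterministic thereafter; per-stage seeds are fanned out from the
#' global seed by stable hashing.
#'
#' @param config a [pipeline_config()] (or override list / YAML path).
#' @param genome optionally, a pre-built `snmc_genome` (skips genome
#'   simulation).
#' @param model optionally, a `methylome_model` (default
#'   [example_methylome_model()]).
#' @param quiet suppress progress messages.
#' @return list of stage outputs: `genome`, `methylome`, `library`,
#'   `demux`, `trimmed`, `hits`, `filtered`, `allc`, `conversion`,
#'   `levels`, `qc`, `bins`, `embedding`, `clusters`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), genome = NULL,
                         model = NULL, quiet = FALSE) {
  if (!inherits(config, "pipeline_config"))
    config <- pipeline_config(config)
  say <- function(...) if (!quiet) message("[snmcpipe] ", ...)
  t0 <- Sys.time()
  stages <- config$stages
  res <- list(config = config)
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  ## simulate
  say("simulate: genome, methylome, library")
  res$genome <- genome %||%
    run_stage("simulate",
              function() simulate_genome(
                example_genome_spec(seed = config$simulate$genome_seed)))
  mdl <- model %||% example_methylome_model()
  res$methylome <- run_stage("simulate", function()
    simulate_methylome(res$genome, mdl,
                       n_cells = config$simulate$n_cells,
                       seed = stage_seed(config$seed, "methylome")))
  lp <- do.call(library_params, config$library)
  n_pairs <- config$simulate$n_pairs_per_cell *
    nrow(res$methylome$cells)
  res$library <- run_stage("simulate", function()
    simulate_library(res$genome, res$methylome, lp, n_pairs,
                     seed = stage_seed(config$seed, "library")))
  if (!"demux" %in% stages) return(finish_manifest(res, t0, quiet))

  ## demux (per pool; the dual index is the pool label)
  say("demux")
  bs <- barcode_set(max_mismatch = config$demux$max_mismatch)
  res$demux <- run_stage("demux", function() {
    parts <- lapply(split(res$library$reads[, .(pair_id, r1, r2, pool)],
                          res$library$reads$pool), function(sub) {
      dm <- demultiplex(sub[, .(pair_id, r1, r2)], bs)
      dm$reads[, pool := sub$pool[1L]]
      dm
    })
    reads <- rbindlist(lapply(parts, `[[`, "reads"))
    ## cell identity = pool x barcode
    key <- res$methylome$cells[, paste(pool, barcode)]
    reads[, cell := res$methylome$cells$cell[
      match(paste(pool, barcode), key)]]
    counts <- rbindlist(lapply(names(parts), function(p)
      parts[[p]]$counts[, .(pool = p, barcode, n)]))
    list(reads = reads, counts = counts,
         unassigned = rbindlist(lapply(parts, `[[`, "unassigned")))
  })
  if (!"trim" %in% stages) return(finish_manifest(res, t0, quiet))

  ## trim
  say("trim")
  tp <- do.call(trim_policy, config$trim)
  res$trimmed <- run_stage("trim", function()
    trim_reads(res$demux$reads, tp))
  if (!"align" %in% stages) return(finish_manifest(res, t0, quiet))

  ## align
  say("align")
  res$index <- run_stage("align", function()
    converted_index(res$genome, k = config$align$k))
  res$hits <- run_stage("align", function()
    align_reads(reads_long(res$trimmed[trim_class == "keep"],
                           min_len = config$align$k), res$index))
  res$hits_filtered_preclonal <- run_stage("align", function()
    filter_alignments(res$hits, config$align$mapq_min,
                      collapse_clonal = FALSE))
  res$filtered <- run_stage("align", function()
    filter_alignments(res$hits, config$align$mapq_min))
  if (!"call" %in% stages) return(finish_manifest(res, t0, quiet))

  ## call
  say("call methylation")
  res$allc <- run_stage("call", function()
    call_methylation(res$filtered, res$genome,
                     conversion_rate = config$library$conversion_rate))
  res$conversion <- run_stage("call", function()
    estimate_conversion(res$allc,
                        res$genome$lambda_contig %||% "lambda"))
  res$levels <- run_stage("call", function() global_levels(
    res$allc, exclude_contigs = res$genome$lambda_contig %||% character(0)))
  if (!"qc" %in% stages) return(finish_manifest(res, t0, quiet))

  ## qc
  say("qc")
  res$qc <- run_stage("qc", function()
    assemble_qc(res$methylome$cells$cell, res$trimmed,
                res$hits_filtered_preclonal, res$filtered,
                res$conversion, res$levels, res$genome,
                reference_pairs = config$qc$reference_pairs))
  res$uniformity <- run_stage("qc", function()
    coverage_uniformity(res$filtered, res$genome))
  if (!"cluster" %in% stages) return(finish_manifest(res, t0, quiet))

  ## cluster
  say("cluster")
  res$bins <- run_stage("cluster", function()
    filter_bins(bin_mch(res$allc, res$genome,
                        bin_size = config$cluster$bin_size),
                config$cluster$min_basecalls,
                config$cluster$min_cell_fraction))
  res$embedding <- run_stage("cluster", function()
    normalize_and_embed(res$bins, res$levels,
                        n_pcs = config$cluster$n_pcs))
  res$clusters <- run_stage("cluster", function()
    annotate_clusters(cluster_cells(res$embedding,
                                    k = config$cluster$k),
                      res$allc, res$genome))
  finish_manifest(res, t0, quiet)
}

finish_manifest <- function(res, t0, quiet) {
  cfg <- unclass(res$config)
  res$manifest <- list(
    package = "snmcpipe",
    version = as.character(utils::packageVersion("snmcpipe")),
    seed = res$config$seed,
    stage_seeds = stats::setNames(
      lapply(PIPELINE_STAGES, function(s) stage_seed(cfg$seed, s)),
      PIPELINE_STAGES),
    parameter_hash = str_hash(paste(deparse(cfg), collapse = "")),
    stages_run = cfg$stages,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"))
  if (!quiet) message(sprintf("[snmcpipe] done in %.1fs",
                              res$manifest$elapsed_sec))
  res
}
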