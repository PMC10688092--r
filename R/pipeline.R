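# End-to-end orchestration: ingest -> fragment reconstruction / RDR ->
# phasing / BAF -> segmentation -> purity/ploidy/state fit -> optional
# evaluation, with per-stage artifacts and full provenance (parameters and
# seed echoed into every output header).

#' Run the full copy-number pipeline
#'
#' @param reads Well-read tibble (see [read_well_reads()]).
#' @param snps Retained heterozygous SNP tibble (see [read_het_snps()]).
#' @param allele_obs Per-well allele observations at the SNPs.
#' @param windows Window tibble with `germline_reads` (see
#'   [read_germline_depths()]).
#' @param genome Genome tibble.
#' @param truth Optional truth profile; when given, evaluation metrics are
#'   computed.
#' @param max_gap Fragment-chaining gap (default 100 kb).
#' @param block_gap Maximum inter-SNP gap per haplotype block (500 kb).
#' @param block_snps Maximum SNPs per block (100).
#' @param lambda Segmentation penalty (0.1).
#' @param min_span Minimum segment span (5 Mb).
#' @param restarts Greedy restarts (default 10,000).
#' @param subclonal Allow sub-clonal states.
#' @param kappa Pronounced-minimum threshold for the grid search.
#' @param phi_grid,psi_grid Purity/ploidy grids.
#' @param seed Mandatory seed for the stochastic stages.
#' @param out_dir Optional directory for per-stage TSV artifacts.
#' @return List with `rlfs`, `rdr`, `baf`, `segments`, `fit`, `profile`,
#'   and (given truth) `metrics`.
#' @export
run_pipeline <- function(reads, snps, allele_obs, windows, genome,
                         truth = NULL, max_gap = 1e5, block_gap = 5e5,
                         block_snps = 100, lambda = 0.1, min_span = 5e6,
                         restarts = 10000, subclonal = TRUE, kappa = 1.2,
                         phi_grid = seq(0.05, 1, by = 0.01),
                         psi_grid = seq(1, 8, by = 0.05),
                         seed, out_dir = NULL) {
  check_that(!missing(seed), "a seed is mandatory")
  params <- list(max_gap = max_gap, block_gap = block_gap,
                 block_snps = block_snps, lambda = lambda,
                 min_span = min_span, restarts = restarts,
                 subclonal = subclonal, kappa = kappa, seed = seed)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
    message(sprintf("[wellcnv] %-10s done at %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  rlfs <- stage("rlf", reconstruct_rlfs(reads, max_gap = max_gap))
  rdr <- stage("rdr", {
    window_interval_depth(rlfs, windows) |>
      compute_raw_rdr() |>
      correct_rdr()
  })
  baf <- stage("phase", {
    genotypes <- build_well_genotypes(snps, allele_obs)
    phase_baf(snps, genotypes, max_gap = block_gap, max_snps = block_snps)
  })
  segments <- stage("segment",
    segment_genome(baf, rdr, genome, lambda = lambda, min_span = min_span,
                   restarts = restarts, seed = seed))
  fit <- stage("fit",
    fit_copy_number(segments, phi_grid = phi_grid, psi_grid = psi_grid,
                    kappa = kappa, subclonal = subclonal))
  profile <- cn_profile(fit)
  out <- list(rlfs = rlfs, rdr = rdr, baf = baf, segments = segments,
              fit = fit, profile = profile, params = params)
  if (!is.null(truth)) {
    out$metrics <- stage("evaluate", list(
      exact_match = exact_match_fraction(profile, truth),
      ploidy_error = ploidy_error(profile, truth),
      events = event_metrics(profile, truth)
    ))
  }
  if (!is.null(out_dir)) write_stage_artifacts(out, out_dir, params)
  out
}

# per-stage TSVs with provenance headers; no stage mutates another stage's
# artifact
write_stage_artifacts <- function(out, out_dir, params) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- paste0("# ", names(params), "=",
                vapply(params, function(p) paste(format(p), collapse = ","), ""))
  emit <- function(tb, file) {
    path <- file.path(out_dir, file)
    writeLines(hdr, path)
    suppressWarnings(
      utils::write.table(tb, path, sep = "\t", row.names = FALSE,
                         quote = FALSE, append = TRUE))
    path
  }
  emit(out$rlfs, "rlfs.tsv")
  emit(out$rdr, "rdr.tsv")
  emit(out$baf, "baf.tsv")
  emit(select(out$segments, -dplyr::any_of("mse_s")), "segments.tsv")
  write_profile(out$profile, file.path(out_dir, "profile.bed"),
                summary = c(list(purity = out$fit$phi, ploidy = out$fit$psi,
                                 mse = out$fit$mse), params))
  invisible(out_dir)
}

#' Run the pipeline on a simulated sample
#'
#' Convenience wrapper: simulates well-level data from `config`, runs
#' [run_pipeline()] against it, and evaluates against the simulation truth.
#'
#' @param config A [sim_config()] object.
#' @param ... Passed to [run_pipeline()].
#' @param seed Pipeline seed (defaults to the simulation seed).
#' @return The [run_pipeline()] result, plus `sim` (the simulated data).
#' @export
run_simulated <- function(config, ..., seed = config$seed) {
  sim <- simulate_well_data(config)
  res <- run_pipeline(sim$reads, sim$snps, sim$allele_obs, sim$windows,
                      config$genome, truth = sim$truth, seed = seed, ...)
  res$sim <- sim
  res
}
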