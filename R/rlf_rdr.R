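# Read-depth-ratio de-noising: reconstruct the original large input DNA
# fragments in silico from co-local reads within each well, compute the
# window-level read depth ratio from the fragment depth, and correct it for
# GC content and mappability.

#' Reconstruct large fragments from per-well reads
#'
#' Within each well and chromosome, read pairs are chained into one
#' reconstructed large fragment (RLF) while the gap from the previous read
#' is strictly less than `max_gap`; the fragment spans from the start of its
#' first read to the end of its last read. Reads in different wells are
#' never merged.
#'
#' @param reads Well-read tibble (`well_id`, `chrom`, `start`, `end`).
#' @param max_gap Chaining threshold in bp (default 100 kb). The gap is
#'   `next start - previous end`; a gap `>= max_gap` starts a new fragment.
#' @return Tibble `well_id`, `chrom`, `start`, `end`, `n_reads`, one row per
#'   RLF.
#' @export
#' @examples
#' reads <- tibble::tibble(well_id = "w1", chrom = "chr1",
#'                         start = c(1000, 50000), end = c(1150, 50150))
#' reconstruct_rlfs(reads)   # one fragment spanning 1000-50150
reconstruct_rlfs <- function(reads, max_gap = 1e5) {
  reads <- arrange(as_tibble(reads), .data$well_id, .data$chrom, .data$start)
  if (nrow(reads) == 0L) {
    return(tibble(well_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), n_reads = integer()))
  }
  reads |>
    group_by(.data$well_id, .data$chrom) |>
    mutate(
      prev_end = lag(cummax(.data$end)),
      new_frag = is.na(.data$prev_end) | .data$start - .data$prev_end >= max_gap,
      frag = cumsum(.data$new_frag)
    ) |>
    group_by(.data$well_id, .data$chrom, .data$frag) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_reads = dplyr::n(), .groups = "drop") |>
    select("well_id", "chrom", "start", "end", "n_reads") |>
    arrange(.data$well_id, .data$chrom, .data$start)
}

#' Mean fragment depth per window
#'
#' For each window, the mean over its bases of the number of intervals
#' (RLFs, or reads for the raw short-read comparison) overlapping that base,
#' i.e. total overlapping base pairs divided by window width.
#'
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @param windows Window tibble from [tile_windows()].
#' @return `windows` with a `depth` column.
#' @export
window_interval_depth <- function(intervals, windows) {
  bp <- overlap_bp_by_window(intervals, windows)
  mutate(windows, depth = bp / (.data$end - .data$start))
}

#' Raw read depth ratio per window
#'
#' `r = 100 * mean_fragment_depth / germline_reads`. Windows with zero (or
#' missing) germline reads are masked and excluded from all downstream
#' computation; an input where every window is masked is a fatal error.
#'
#' @param depth Per-window mean RLF depth (vector, or the output of
#'   [window_interval_depth()]).
#' @param germline_reads Per-window germline read counts.
#' @return If `depth` is a tibble, the tibble with `raw_r` and `masked`
#'   columns; otherwise a list with `raw_r` and `masked` vectors.
#' @export
compute_raw_rdr <- function(depth, germline_reads) {
  tb <- NULL
  if (is.data.frame(depth)) {
    tb <- depth
    depth <- depth$depth
    if (missing(germline_reads) && "germline_reads" %in% names(tb)) {
      germline_reads <- tb$germline_reads
    }
  }
  check_that(length(depth) == length(germline_reads),
             "depth and germline_reads differ in length")
  masked <- is.na(germline_reads) | germline_reads <= 0 | is.na(depth)
  check_that(!all(masked), "all windows are masked (no usable germline depth)")
  raw_r <- if_else(masked, NA_real_, 100 * depth / germline_reads)
  if (is.null(tb)) return(list(raw_r = raw_r, masked = masked))
  mutate(tb, raw_r = raw_r, masked = masked)
}

#' Correct the RDR for GC content and mappability
#'
#' An ordinary-least-squares model `r ~ gc + mappability` is fitted on the
#' unmasked autosomal windows and removed multiplicatively:
#' `corrected = r * mean(fitted) / fitted`, then recentred so the genome-wide
#' mean of the corrected values equals that of the raw values. The
#' multiplicative form keeps depth non-negative. A degenerate design (both
#' covariates constant) skips the correction with a warning; masked windows
#' stay masked.
#'
#' @param rdr Tibble with `raw_r`, `masked`, `gc`, `mappability`, `chrom`.
#' @param min_windows Minimum unmasked windows required to attempt a fit.
#' @param use_sex_chromosomes Include sex chromosomes in the fit and in the
#'   genome-wide mean (default `FALSE`).
#' @return `rdr` with a `corrected_r` column.
#' @export
correct_rdr <- function(rdr, min_windows = 50, use_sex_chromosomes = FALSE) {
  fit_ok <- !rdr$masked
  if (!use_sex_chromosomes) fit_ok <- fit_ok & is_autosome(rdr$chrom)
  dat <- rdr[fit_ok, ]
  corrected <- rdr$raw_r
  skip <- FALSE
  if (nrow(dat) < min_windows) {
    warn(sprintf("only %d unmasked windows (< %d); GC/mappability correction skipped",
                 nrow(dat), min_windows))
    skip <- TRUE
  } else if (var(dat$gc) < 1e-12 && var(dat$mappability) < 1e-12) {
    warn("constant GC and mappability covariates; correction skipped")
    skip <- TRUE
  }
  if (!skip) {
    keep <- c(var(dat$gc) >= 1e-12, var(dat$mappability) >= 1e-12)
    form <- stats::as.formula(paste(
      "raw_r ~", paste(c("gc", "mappability")[keep], collapse = " + ")))
    fit <- lm(form, data = dat)
    fitted_all <- predict(fit, newdata = rdr)
    fitted_all <- pmax(fitted_all, 1e-8 * mean(dat$raw_r))
    corrected <- rdr$raw_r * mean(fitted_all[fit_ok]) / fitted_all
    # multiplicative recentring: preserve the genome-wide mean exactly
    corrected <- corrected * mean(rdr$raw_r[fit_ok]) / mean(corrected[fit_ok])
  }
  corrected[rdr$masked] <- NA_real_
  mutate(rdr, corrected_r = pmax(corrected, 0))
}

#' Genome-wide mean of the corrected RDR
#'
#' The unweighted mean of `corrected_r` over unmasked autosomal windows
#' (sex chromosomes excluded by default).
#'
#' @inheritParams correct_rdr
#' @return Scalar mean, `r_bar`.
#' @export
rdr_mean <- function(rdr, use_sex_chromosomes = FALSE) {
  ok <- !rdr$masked
  if (!use_sex_chromosomes) ok <- ok & is_autosome(rdr$chrom)
  r_bar <- mean(rdr$corrected_r[ok])
  check_that(is.finite(r_bar) && r_bar > 0, "genome-wide mean RDR must be positive")
  r_bar
}

#' Predicted fraction of bi-allelic wells
#'
#' Binomial model for fragment collisions: with `c = input_pg /
#' pg_per_genome` genome copies per parental allele, each copy covering a
#' locus lands uniformly in one of `n_wells` wells. A specific allele is
#' present in a given well with probability `q = 1 - (1 - 1/W)^c`, so the
#' fraction of covered wells holding both alleles is
#' `q^2 / (1 - (1 - 1/W)^(2c))`. More wells at equal input means fewer
#' collisions.
#'
#' @param n_wells Number of wells (e.g. 384 per plate).
#' @param input_pg Input DNA in picograms.
#' @param pg_per_genome Picograms per diploid genome (default 6.6).
#' @return Expected bi-allelic fraction among wells covering a locus.
#' @export
#' @examples
#' predict_biallelic_fraction(384, 240)
predict_biallelic_fraction <- function(n_wells, input_pg, pg_per_genome = 6.6) {
  check_that(n_wells >= 1, "n_wells must be >= 1")
  check_that(all(input_pg >= 0), "input_pg must be non-negative")
  cc <- input_pg / pg_per_genome
  miss <- (1 - 1 / n_wells)^cc          # P(well holds no copy of one allele)
  q <- 1 - miss
  covered <- 1 - miss^2                 # P(well holds >= 1 fragment at locus)
  if_else(covered > 0, q^2 / covered, 0)
}
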