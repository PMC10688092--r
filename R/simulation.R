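# Synthetic well-data generation with known truth. The well-level simulator
# emulates the sequencing platform: large (~100 kb) input DNA fragments
# drawn per haplotype in proportion to local copy number, mixed with diploid
# normal DNA at 1 - phi, distributed uniformly over wells, amplified with
# per-fragment log-normal depth noise, and tiled with short reads; SNP
# allele observations follow each fragment's haplotype, so wells are
# mono-allelic except where fragments collide. A lighter track-level
# simulator draws the de-noised RDR/BAF tracks directly from the
# copy-number model for segmentation- and fit-level experiments.

#' Simulation configuration
#'
#' Defaults mirror the platform: 384 wells per plate, 240 pg input DNA
#' (about 40 cells at 6 pg per cell; 6.6 pg per diploid genome), ~100 kb
#' mean fragment length, log-normal per-fragment amplification depth.
#'
#' @param genome Genome tibble from [make_genome()].
#' @param karyotype Tibble `chrom`, `start`, `end`, `n_A`, `n_B`, `chi` of
#'   tumour copy-number regions; uncovered genome defaults to the modal
#'   state.
#' @param phi Tumour purity in (0, 1].
#' @param n_wells Number of wells (default one 384-well plate).
#' @param input_pg Input DNA in picograms (default 240).
#' @param pg_per_genome Picograms per diploid genome (default 6.6).
#' @param fragment_mean Mean input fragment length in bp (default 100 kb).
#' @param fragment_sdlog Log-sd of the fragment length distribution.
#' @param amp_sdlog Log-sd of per-fragment amplification depth (mean 1).
#' @param read_spacing Mean spacing between read pairs within a fragment at
#'   unit amplification (bp).
#' @param read_span Genomic span of one read pair (bp).
#' @param snp_spacing Mean spacing of heterozygous SNPs (bp).
#' @param snp_depth Mean reads covering a SNP per covering fragment at unit
#'   amplification.
#' @param germline_depth Mean germline reads per window.
#' @param window Window width (default 1 Mb).
#' @param modal_state Background state carried by tumour cells without a
#'   sub-clonal CNA and by uncovered genome (default `c(1, 1)`).
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome, karyotype, phi = 1, n_wells = 384,
                       input_pg = 240, pg_per_genome = 6.6,
                       fragment_mean = 1e5, fragment_sdlog = 0.35,
                       amp_sdlog = 0.7, read_spacing = 2e4, read_span = 500,
                       snp_spacing = 5e4, snp_depth = 2,
                       germline_depth = 200, window = 1e6,
                       modal_state = c(1, 1), seed) {
  check_that(!missing(seed) && is.numeric(seed), "a seed is mandatory")
  check_that(phi > 0 && phi <= 1, "phi must be in (0, 1]")
  karyotype <- complete_karyotype(karyotype, genome, modal_state)
  structure(list(
    genome = genome, karyotype = karyotype, phi = phi, n_wells = n_wells,
    input_pg = input_pg, pg_per_genome = pg_per_genome,
    fragment_mean = fragment_mean, fragment_sdlog = fragment_sdlog,
    amp_sdlog = amp_sdlog, read_spacing = read_spacing,
    read_span = read_span, snp_spacing = snp_spacing, snp_depth = snp_depth,
    germline_depth = germline_depth, window = window,
    modal_state = modal_state, seed = as.integer(seed)
  ), class = "sim_config")
}

# fill karyotype gaps with the modal state; validate non-overlap
complete_karyotype <- function(karyotype, genome, modal_state = c(1, 1)) {
  karyotype <- as_tibble(karyotype)
  if (!"chi" %in% names(karyotype)) karyotype$chi <- 1
  out <- list()
  for (ci in seq_len(nrow(genome))) {
    ch <- genome$chrom[ci]
    len <- genome$length[ci]
    k <- arrange(karyotype[karyotype$chrom == ch, ], .data$start)
    if (nrow(k) > 1L) {
      check_that(all(k$start[-1L] >= k$end[-nrow(k)]),
                 "karyotype regions overlap")
    }
    bounds <- unique(pmin(pmax(c(0, rbind(k$start, k$end), len), 0), len))
    bounds <- sort(bounds)
    iv <- tibble(chrom = ch, start = bounds[-length(bounds)], end = bounds[-1L])
    mid <- (iv$start + iv$end) / 2
    idx <- findInterval(mid, k$start)
    hit <- idx >= 1L & mid < k$end[pmax(idx, 1L)]
    iv$n_A <- if_else(hit, k$n_A[pmax(idx, 1L)], modal_state[1L])
    iv$n_B <- if_else(hit, k$n_B[pmax(idx, 1L)], modal_state[2L])
    iv$chi <- if_else(hit, k$chi[pmax(idx, 1L)], 1)
    out[[ci]] <- iv
  }
  ky <- list_rbind(out)
  check_that(all(ky$n_A >= ky$n_B), "karyotype must have n_A >= n_B")
  ky
}

#' Truth profile implied by a simulation configuration
#'
#' @param config A `sim_config`, or a completed karyotype tibble plus `phi`.
#' @param phi Purity (when passing a karyotype directly).
#' @param modal_state Background state for the non-CNA tumour fraction.
#' @return Profile tibble with attributes `phi` and `psi` (length-weighted
#'   mean tumour total copy number, counting sub-clonal regions at their
#'   tumour-cell average).
#' @export
truth_profile <- function(config, phi = NULL, modal_state = c(1, 1)) {
  if (inherits(config, "sim_config")) {
    ky <- config$karyotype
    phi <- config$phi
    modal_state <- config$modal_state
  } else {
    ky <- config
    check_that(!is.null(phi), "phi is required with a bare karyotype")
  }
  out <- tibble(chrom = ky$chrom, start = ky$start, end = ky$end,
                n_A = ky$n_A, n_B = ky$n_B, clonality = ky$chi)
  len <- out$end - out$start
  tot <- out$clonality * (out$n_A + out$n_B) +
    (1 - out$clonality) * sum(modal_state)
  attr(out, "phi") <- phi
  attr(out, "psi") <- sum(len * tot) / sum(len)
  out
}

# chop K copies of a region of length L into fragments; returns tibble with
# relative start/end
chop_copies <- function(L, K, mean_len, sdlog) {
  if (K <= 0L || L <= 0) {
    return(tibble(copy = integer(), start = numeric(), end = numeric()))
  }
  meanlog <- log(mean_len) - sdlog^2 / 2
  nf <- ceiling(L / mean_len * 1.7) + 8L
  repeat {
    lens <- matrix(rlnorm(K * nf, meanlog, sdlog), nrow = nf)
    cs <- apply(lens, 2L, cumsum)
    if (all(cs[nf, ] >= L)) break
    nf <- nf * 2L
  }
  starts <- rbind(0, cs[-nf, , drop = FALSE])
  keep <- starts < L
  tibble(
    copy = rep.int(seq_len(K), colSums(keep)),
    start = starts[keep],
    end = pmin(cs[keep], L)
  )
}

#' Simulate well-level sequencing data with known truth
#'
#' Generates input fragments, per-well read pairs, germline window depths,
#' heterozygous SNPs with per-well allele observations, and the truth
#' profile, all reproducibly from the config seed.
#'
#' @param config A [sim_config()] object.
#' @return List with `reads` (well-read tibble), `snps`, `allele_obs`,
#'   `windows` (with `germline_reads`), `truth`, `fragments`, and the
#'   `config`.
#' @export
simulate_well_data <- function(config) {
  check_that(inherits(config, "sim_config"), "config must come from sim_config()")
  with_seed(config$seed, {
    ky <- config$karyotype
    n_cells <- max(1L, round(config$input_pg / config$pg_per_genome))
    n_t <- round(config$phi * n_cells)
    n_n <- n_cells - n_t
    frags <- list()
    for (i in seq_len(nrow(ky))) {
      L <- ky$end[i] - ky$start[i]
      carriers <- round(ky$chi[i] * n_t)
      for (hap in c("A", "B")) {
        n_h <- if (hap == "A") ky$n_A[i] else ky$n_B[i]
        m_h <- if (hap == "A") config$modal_state[1L] else config$modal_state[2L]
        K <- carriers * n_h + (n_t - carriers) * m_h + n_n * 1L
        fr <- chop_copies(L, K, config$fragment_mean, config$fragment_sdlog)
        if (nrow(fr) == 0L) next
        frags[[length(frags) + 1L]] <- tibble(
          chrom = ky$chrom[i],
          start = ky$start[i] + fr$start,
          end = ky$start[i] + fr$end,
          hap = hap
        )
      }
    }
    fragments <- list_rbind(frags)
    nf <- nrow(fragments)
    fragments$well_id <- sprintf("W%04d", sample.int(config$n_wells, nf, replace = TRUE))
    fragments$amp <- rlnorm(nf, -config$amp_sdlog^2 / 2, config$amp_sdlog)
    # tile read pairs within fragments
    flen <- fragments$end - fragments$start
    n_reads <- rpois(nf, fragments$amp * flen / config$read_spacing)
    fi <- rep.int(seq_len(nf), n_reads)
    span <- config$read_span
    u <- runif(length(fi))
    rstart <- fragments$start[fi] + u * pmax(flen[fi] - span, 0)
    reads <- tibble(
      well_id = fragments$well_id[fi],
      chrom = fragments$chrom[fi],
      start = rstart,
      end = pmin(rstart + span, fragments$end[fi])
    ) |>
      arrange(.data$well_id, .data$chrom, .data$start)
    # heterozygous SNPs and per-well allele observations
    snps <- list()
    for (ci in seq_len(nrow(config$genome))) {
      len <- config$genome$length[ci]
      pos <- seq(config$snp_spacing / 2, len - 1, by = config$snp_spacing)
      pos <- round(pos + runif(length(pos), -0.25, 0.25) * config$snp_spacing)
      pos <- sort(unique(pmin(pmax(pos, 1), len - 1)))
      depth <- rpois(length(pos), 40)
      alt_d <- rbinom(length(pos), depth, 0.5)
      snps[[ci]] <- tibble(
        chrom = config$genome$chrom[ci], pos = pos,
        ref = "A", alt = "C",
        germline_depth = depth,
        germline_af = if_else(depth > 0, alt_d / depth, NA_real_),
        alt_hap = sample(c("A", "B"), length(pos), replace = TRUE)
      )
    }
    snps <- filter_het_snps(list_rbind(snps))
    allele_obs <- fragment_snp_obs(fragments, snps, config)
    windows <- tile_windows(config$genome, width = config$window)
    windows$germline_reads <- rpois(nrow(windows), config$germline_depth)
    list(reads = reads, snps = select(snps, -"alt_hap"),
         snp_truth = select(snps, "chrom", "pos", "alt_hap"),
         allele_obs = allele_obs, windows = windows,
         fragments = fragments, truth = truth_profile(config),
         config = config)
  })
}

# per-well read support at SNPs: fragments covering a SNP contribute reads
# of their haplotype's allele
fragment_snp_obs <- function(fragments, snps, config) {
  obs <- list()
  for (ch in unique(snps$chrom)) {
    sp <- snps[snps$chrom == ch, ]
    fr <- fragments[fragments$chrom == ch, ]
    if (nrow(fr) == 0L || nrow(sp) == 0L) next
    lo <- findInterval(fr$start - 0.5, sp$pos) + 1L   # first SNP >= start
    hi <- findInterval(fr$end - 0.5, sp$pos)          # last SNP < end
    nsnp <- pmax(hi - lo + 1L, 0L)
    keep <- nsnp > 0L
    if (!any(keep)) next
    fidx <- rep.int(which(keep), nsnp[keep])
    sidx <- sequence(nsnp[keep], from = lo[keep])
    reads <- rpois(length(fidx), fr$amp[fidx] * config$snp_depth)
    ok <- reads > 0L
    if (!any(ok)) next
    is_alt <- fr$hap[fidx[ok]] == sp$alt_hap[sidx[ok]]
    obs[[length(obs) + 1L]] <- tibble(
      chrom = ch,
      pos = sp$pos[sidx[ok]],
      well_id = fr$well_id[fidx[ok]],
      ref_count = if_else(is_alt, 0L, reads[ok]),
      alt_count = if_else(is_alt, reads[ok], 0L)
    )
  }
  if (length(obs) == 0L) {
    return(tibble(chrom = character(), pos = numeric(), well_id = character(),
                  ref_count = integer(), alt_count = integer()))
  }
  list_rbind(obs) |>
    group_by(.data$chrom, .data$pos, .data$well_id) |>
    summarise(ref_count = sum(.data$ref_count),
              alt_count = sum(.data$alt_count), .groups = "drop")
}

#' Read-count BAF at SNPs (the noisy baseline)
#'
#' Aggregates per-well read counts into a per-SNP alternative-allele
#' fraction, the conventional short-read BAF used as the comparison point
#' for the de-noised well-count BAF.
#'
#' @param allele_obs Per-well allele observation tibble.
#' @return Tibble `chrom`, `pos`, `b`, `weight` (weight 1 per SNP).
#' @export
read_count_baf <- function(allele_obs) {
  allele_obs |>
    group_by(.data$chrom, .data$pos) |>
    summarise(b = sum(.data$alt_count) /
                sum(.data$alt_count + .data$ref_count),
              .groups = "drop") |>
    filter(!is.na(.data$b)) |>
    mutate(weight = 1L)
}

#' Simulate de-noised RDR/BAF tracks directly from the copy-number model
#'
#' Draws per-window corrected RDR and per-point BAF around their model
#' expectations with Gaussian noise — the post-de-noising view of a genome
#' with a known karyotype, for segmentation and fitting experiments at
#' scales where well-level simulation is unnecessary.
#'
#' @param genome Genome tibble.
#' @param karyotype Karyotype tibble (`chrom`, `start`, `end`, `n_A`,
#'   `n_B`, optional `chi`).
#' @param phi Purity.
#' @param r_bar Genome-wide mean corrected RDR level (default 2).
#' @param sigma_r Per-window RDR noise sd (default 0.16).
#' @param sigma_b Per-point BAF noise sd (default 0.02).
#' @param window Window width (default 1 Mb).
#' @param baf_spacing Spacing of BAF points (default 250 kb).
#' @param weight_mean Mean haplotype-group size (BAF point weight).
#' @param modal_state Background state for sub-clonal regions.
#' @param seed Integer seed.
#' @return List with `rdr` (windows with `corrected_r`, `masked`), `baf`
#'   (`chrom`, `pos`, `b`, `weight`), `truth`, `r_bar`, `phi`, `psi`.
#' @export
simulate_cn_tracks <- function(genome, karyotype, phi = 1, r_bar = 2,
                               sigma_r = 0.16, sigma_b = 0.02,
                               window = 1e6, baf_spacing = 2.5e5,
                               weight_mean = 4, modal_state = c(1, 1),
                               seed) {
  check_that(!missing(seed), "a seed is mandatory")
  ky <- complete_karyotype(karyotype, genome, modal_state)
  truth <- truth_profile(ky, phi = phi, modal_state = modal_state)
  psi <- attr(truth, "psi")
  with_seed(seed, {
    windows <- tile_windows(genome, width = window)
    mid <- (windows$start + windows$end) / 2
    st <- karyotype_state_at(ky, windows$chrom, mid)
    r_hat <- expected_rdr(st$n_A, st$n_B, phi, psi, r_bar, st$chi,
                          modal_state[1L], modal_state[2L])
    rdr <- mutate(windows,
                  raw_r = pmax(r_hat + rnorm(length(r_hat), 0, sigma_r), 0),
                  corrected_r = .data$raw_r,
                  masked = FALSE)
    pts <- list()
    for (ci in seq_len(nrow(genome))) {
      pos <- seq(baf_spacing / 2, genome$length[ci] - 1, by = baf_spacing)
      pts[[ci]] <- tibble(chrom = genome$chrom[ci], pos = pos)
    }
    baf <- list_rbind(pts)
    stb <- karyotype_state_at(ky, baf$chrom, baf$pos)
    b_hat <- expected_baf(stb$n_A, stb$n_B, phi, stb$chi,
                          modal_state[1L], modal_state[2L])
    b_hat[is.na(b_hat)] <- 0
    side <- runif(nrow(baf)) < 0.5
    b <- if_else(side, b_hat, 1 - b_hat) + rnorm(nrow(baf), 0, sigma_b)
    baf$b <- pmin(pmax(b, 0), 1)
    baf$weight <- 1L + rpois(nrow(baf), max(weight_mean - 1, 0))
    list(rdr = rdr, baf = baf, truth = truth, r_bar = r_bar,
         phi = phi, psi = psi)
  })
}

# karyotype state at given positions
karyotype_state_at <- function(ky, chrom, pos) {
  n_A <- n_B <- chi <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    k <- arrange(ky[ky$chrom == ch, ], .data$start)
    sel <- which(chrom == ch)
    idx <- findInterval(pos[sel], k$start)
    inside <- idx >= 1L & pos[sel] < k$end[pmax(idx, 1L)]
    n_A[sel[inside]] <- k$n_A[idx[inside]]
    n_B[sel[inside]] <- k$n_B[idx[inside]]
    chi[sel[inside]] <- k$chi[idx[inside]]
  }
  tibble(n_A = n_A, n_B = n_B, chi = chi)
}

#' Per-state track statistics from a fully clonal solution
#'
#' Mean and within-segment variance of the corrected RDR and the mirrored
#' BAF for each fitted clonal copy-number state — the ingredients of the
#' sub-clonal spike-in.
#'
#' @param rdr RDR window tibble.
#' @param baf BAF point tibble.
#' @param segments Segment tibble with fitted clonal `n_A`, `n_B` (e.g.
#'   `tidy(fit)` of a clonal fit).
#' @return Tibble per state: `n_A`, `n_B`, `r_mean`, `r_var`, `b_mean`,
#'   `b_var`, `n_windows`.
#' @export
state_stats <- function(rdr, baf, segments) {
  segs <- segments[!is.na(segments$n_A) & segments$chi == 1, ]
  segs <- summarize_segments(segs, rdr, baf,
                             r_bar = attr(segments, "r_bar") %||% 1)
  segs$n_A <- segments$n_A[!is.na(segments$n_A) & segments$chi == 1]
  segs$n_B <- segments$n_B[!is.na(segments$n_A) & segments$chi == 1]
  segs |>
    group_by(.data$n_A, .data$n_B) |>
    summarise(
      r_mean = sum(.data$r_mean * .data$n_r) / sum(.data$n_r),
      r_var = max(sum(.data$r_sse) / max(sum(.data$n_r) - dplyr::n(), 1), 1e-8),
      b_mean = sum(.data$b_mean * .data$n_b) / sum(.data$n_b),
      b_var = max(sum(.data$b_sse) / max(sum(.data$n_b) - dplyr::n(), 1), 1e-8),
      n_windows = sum(.data$n_r),
      .groups = "drop"
    )
}

#' Spike a simulated sub-clonal CNA into track data
#'
#' A randomly chosen eligible segment's RDR values are overwritten with
#' draws from `chi * N(mean_CNA, var_CNA) + (1 - chi) * N(mean_modal,
#' var_modal)`. The default reads the expression literally as a sum of two
#' scaled independent normals — i.e. normal with mean
#' `chi*m1 + (1-chi)*m2` and variance `chi^2*v1 + (1-chi)^2*v2`;
#' `method = "mixture"` instead draws each point from one component with
#' probability `chi`. BAF values are overwritten analogously on the
#' mirrored scale using the per-state BAF statistics.
#'
#' @param rdr,baf Track tibbles.
#' @param segments Segment tibble (with `seg_id`).
#' @param stats Per-state statistics from [state_stats()].
#' @param state `c(n_A, n_B)` of the CNA to spike (must appear in `stats`).
#' @param chi Clonality of the spiked CNA.
#' @param modal Modal state `c(m_A, m_B)` (must appear in `stats`).
#' @param seed Optional seed.
#' @param method `"scaled-sum"` (default) or `"mixture"`.
#' @param min_windows Minimum RDR windows for a segment to be eligible.
#' @return List `rdr`, `baf` (modified copies) and `truth`
#'   (`seg_id`, `n_A`, `n_B`, `chi`).
#' @export
spike_in_subclonal <- function(rdr, baf, segments, stats, state, chi,
                               modal = c(1, 1), seed = NULL,
                               method = c("scaled-sum", "mixture"),
                               min_windows = 5L) {
  method <- match.arg(method)
  cna <- stats[stats$n_A == state[1L] & stats$n_B == state[2L], ]
  bg <- stats[stats$n_A == modal[1L] & stats$n_B == modal[2L], ]
  check_that(nrow(cna) == 1L, "spiked state absent from stats")
  check_that(nrow(bg) == 1L, "modal state absent from stats")
  eligible <- segments$seg_id[segments$n_r >= min_windows & segments$n_b >= 1L]
  check_that(length(eligible) > 0L, "no segment long enough to spike")
  with_seed(seed, {
    sid <- eligible[sample.int(length(eligible), 1L)]
    seg <- segments[segments$seg_id == sid, ]
    wsel <- which(!rdr$masked & rdr$chrom == seg$chrom &
                    (rdr$start + rdr$end) / 2 >= seg$start &
                    (rdr$start + rdr$end) / 2 < seg$end)
    bsel <- which(baf$chrom == seg$chrom & baf$pos >= seg$start &
                    baf$pos < seg$end)
    rdr$corrected_r[wsel] <- mixture_draw(length(wsel), chi,
                                          cna$r_mean, cna$r_var,
                                          bg$r_mean, bg$r_var, method)
    bdraw <- mixture_draw(length(bsel), chi, cna$b_mean, cna$b_var,
                          bg$b_mean, bg$b_var, method)
    baf$b[bsel] <- pmin(pmax(bdraw, 0), 0.5)   # mirrored scale
    list(rdr = rdr, baf = baf,
         truth = list(seg_id = sid, n_A = state[1L], n_B = state[2L],
                      chi = chi))
  })
}

mixture_draw <- function(n, chi, m1, v1, m2, v2, method) {
  if (method == "scaled-sum") {
    rnorm(n, chi * m1 + (1 - chi) * m2, sqrt(chi^2 * v1 + (1 - chi)^2 * v2))
  } else {
    pick <- runif(n) < chi
    if_else(pick, rnorm(n, m1, sqrt(v1)), rnorm(n, m2, sqrt(v2)))
  }
}

#' Sensitivity of sub-clonal CNA detection by spike-in
#'
#' Repeatedly spikes a random CNA (a random non-modal state from `stats`) at
#' each clonality into a random segment and refits that segment's state at
#' the background purity/ploidy. A success is the spiked segment being
#' assigned the spiked `{n_A, n_B}` with clonality below 1.
#'
#' @param rdr,baf Background track tibbles.
#' @param fit Background `cnv_fit` (fully clonal states define the modal
#'   state and noise).
#' @param stats Per-state statistics from [state_stats()].
#' @param chi_values Clonalities to test (default 0.5--0.9).
#' @param n_sims Spikes per clonality (default 200).
#' @param seed Integer seed.
#' @param chis Clonality grid offered to the fit.
#' @param penalty Sub-clonal penalty.
#' @return Tibble `chi`, `n`, `successes`, `sensitivity`, `ci_lo`, `ci_hi`
#'   (95% binomial CI).
#' @export
subclonal_sensitivity <- function(rdr, baf, fit, stats,
                                  chi_values = seq(0.5, 0.9, by = 0.1),
                                  n_sims = 200L, seed = NULL,
                                  chis = seq(0.5, 0.9, by = 0.1),
                                  penalty = 1) {
  if (n_sims == 0L) {
    return(tibble(chi = numeric(), n = integer(), successes = integer(),
                  sensitivity = numeric(), ci_lo = numeric(),
                  ci_hi = numeric()))
  }
  segments <- fit$segments
  modal <- fit$modal
  cand <- stats[!(stats$n_A == modal[1L] & stats$n_B == modal[2L]), ]
  check_that(nrow(cand) > 0L, "stats contain only the modal state")
  n_max <- max(stats$n_A + stats$n_B) + 2L
  states <- bind_rows(mutate(enumerate_states(n_max), chi = 1),
                      tidyr::expand_grid(enumerate_states(n_max), chi = chis))
  out <- list()
  with_seed(seed, {
    for (cv in chi_values) {
      succ <- 0L
      for (k in seq_len(n_sims)) {
        st <- cand[sample.int(nrow(cand), 1L), ]
        sp <- spike_in_subclonal(rdr, baf, segments, stats,
                                 c(st$n_A, st$n_B), cv, modal = modal)
        seg <- summarize_segments(
          segments[segments$seg_id == sp$truth$seg_id, ],
          sp$rdr, sp$baf, r_bar = fit$r_bar)
        m <- state_mse_matrix(seg, states, fit$phi, fit$psi, fit$r_bar,
                              fit$sigma2_r, fit$sigma2_b, modal = modal,
                              penalty = penalty)
        pick <- pick_states(m, states)
        hit <- states$n_A[pick] == st$n_A & states$n_B[pick] == st$n_B &
          states$chi[pick] < 1
        succ <- succ + as.integer(hit)
      }
      ci <- stats::binom.test(succ, n_sims)$conf.int
      out[[length(out) + 1L]] <- tibble(
        chi = cv, n = n_sims, successes = succ,
        sensitivity = succ / n_sims, ci_lo = ci[1L], ci_hi = ci[2L])
    }
  })
  list_rbind(out)
}
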