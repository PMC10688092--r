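# The synthetic-data generators: well-level simulator, track-level
# simulator, spike-in mixture, and their internal consistency with the
# copy-number model.

small_cfg <- function(seed = 5, ...) {
  ky <- tibble::tribble(
    ~chrom, ~start, ~end, ~n_A, ~n_B,
    "chr1", 10e6, 30e6, 2, 0,
    "chr1", 50e6, 70e6, 2, 1,
    "chr2", 30e6, 50e6, 1, 0
  )
  sim_config(small_genome(), ky, phi = 1, input_pg = 60,
             snp_spacing = 5e4, seed = seed, ...)
}

test_that("well simulation is byte-identical under a fixed seed", {
  s1 <- simulate_well_data(small_cfg())
  s2 <- simulate_well_data(small_cfg())
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$allele_obs, s2$allele_obs)
  expect_identical(s1$windows, s2$windows)
  s3 <- simulate_well_data(small_cfg(seed = 6))
  expect_false(identical(s1$reads, s3$reads))
})

test_that("truth ploidy is the length-weighted mean total copy number", {
  cfg <- small_cfg()
  truth <- truth_profile(cfg)
  len <- truth$end - truth$start
  expect_equal(attr(truth, "psi"),
               sum(len * (truth$n_A + truth$n_B)) / sum(len))
  # sub-clonal regions count at the tumour-cell average
  ky <- tibble::tibble(chrom = "chr1", start = 0, end = 80e6,
                       n_A = 3, n_B = 1, chi = 0.5)
  t2 <- truth_profile(ky, phi = 1)
  expect_equal(attr(t2, "psi"), 0.5 * 4 + 0.5 * 2)
})

test_that("fragment coverage scales with local copy number and phi", {
  sim <- simulate_well_data(small_cfg())
  fr <- sim$fragments
  # mean per-base fragment depth in a total-3 region vs total-2 background
  dep <- function(ch, lo, hi) {
    f <- fr[fr$chrom == ch & fr$start < hi & fr$end > lo, ]
    sum(pmin(f$end, hi) - pmax(f$start, lo)) / (hi - lo)
  }
  d_bg <- dep("chr1", 72e6, 80e6)       # {1,1}
  d_gain <- dep("chr1", 52e6, 68e6)     # {2,1}
  d_loss <- dep("chr2", 32e6, 48e6)     # {1,0}
  expect_equal(d_gain / d_bg, 1.5, tolerance = 0.12)
  expect_equal(d_loss / d_bg, 0.5, tolerance = 0.12)
})

test_that("observed bi-allelic well fraction matches the binomial model", {
  cfg <- small_cfg()
  sim <- simulate_well_data(cfg)
  # restrict to the diploid background so local copy number is 2
  obs <- sim$allele_obs[sim$allele_obs$chrom == "chr2" &
                          sim$allele_obs$pos < 25e6, ]
  bi <- obs$ref_count > 0 & obs$alt_count > 0
  pred <- predict_biallelic_fraction(cfg$n_wells, cfg$input_pg)
  se <- sqrt(pred * (1 - pred) / nrow(obs))
  # allele dropout (unread fragments) can only lower the observed fraction
  expect_lt(abs(mean(bi) - pred), max(3 * se, 0.35 * pred))
})

test_that("well-count BAF of simulated regions matches the model expectation", {
  sim <- simulate_well_data(small_cfg())
  g <- build_well_genotypes(sim$snps, sim$allele_obs)
  baf <- phase_baf(sim$snps, g)
  # {2,0} region: mirrored BAF near 0 at phi = 1
  loh <- baf[baf$chrom == "chr1" & baf$pos >= 12e6 & baf$pos < 28e6, ]
  expect_lt(mean(mirror_baf(loh$b)), 0.05)
  # balanced background: both groups near 0.5
  bg <- baf[baf$chrom == "chr2" & baf$pos < 25e6, ]
  expect_equal(mean(bg$b), 0.5, tolerance = 0.05)
})

test_that("track simulator means close the loop with the estimators", {
  genome <- test_genome()
  ky <- test_karyotype()
  tr <- simulate_cn_tracks(genome, ky, phi = 0.7, r_bar = 2,
                           sigma_r = 0.1, sigma_b = 0.02, seed = 61)
  psi <- tr$psi
  for (i in seq_len(nrow(ky))) {
    sel <- tr$rdr$chrom == ky$chrom[i] &
      (tr$rdr$start + tr$rdr$end) / 2 >= ky$start[i] &
      (tr$rdr$start + tr$rdr$end) / 2 < ky$end[i]
    want <- expected_rdr(ky$n_A[i], ky$n_B[i], 0.7, psi, 2)
    n <- sum(sel)
    expect_lt(abs(mean(tr$rdr$corrected_r[sel]) - want), 3 * 0.1 / sqrt(n))
    bsel <- tr$baf$chrom == ky$chrom[i] & tr$baf$pos >= ky$start[i] &
      tr$baf$pos < ky$end[i]
    want_b <- expected_baf(ky$n_A[i], ky$n_B[i], 0.7)
    got_b <- mean(mirror_baf(tr$baf$b[bsel]))
    # mirroring folds noise at the boundary, biasing b downward slightly
    expect_lt(abs(got_b - want_b), 3 * 0.02 / sqrt(sum(bsel)) + 0.02)
  }
})

test_that("spike-in draws have the stated mixture moments", {
  stats <- tibble::tibble(n_A = c(1, 2), n_B = c(1, 1),
                          r_mean = c(2, 3), r_var = c(0.04, 0.09),
                          b_mean = c(0.48, 0.35), b_var = c(4e-4, 4e-4),
                          n_windows = c(100, 50))
  segs <- tibble::tibble(seg_id = 1L, chrom = "chr1", arm = "p",
                         start = 0, end = 50e6, length = 50e6,
                         n_r = 50L, n_b = 100L)
  rdr <- tile_windows(make_genome("chr1", 50e6, 25e6))
  rdr <- dplyr::mutate(rdr, corrected_r = 2, masked = FALSE)
  baf <- tibble::tibble(chrom = "chr1", pos = seq(5e5, 49.5e6, by = 5e5),
                        b = 0.48, weight = 4L)
  # chi = 1 collapses to the CNA component
  sp1 <- spike_in_subclonal(rdr, baf, segs, stats, state = c(2, 1), chi = 1,
                            modal = c(1, 1), seed = 1)
  expect_equal(mean(sp1$rdr$corrected_r), 3, tolerance = 3 * 0.3 / sqrt(50))
  # chi = 0 collapses to the modal component
  sp0 <- spike_in_subclonal(rdr, baf, segs, stats, state = c(2, 1), chi = 0,
                            modal = c(1, 1), seed = 2)
  expect_equal(mean(sp0$rdr$corrected_r), 2, tolerance = 3 * 0.2 / sqrt(50))
  # mixture mean and reduced variance of the scaled-sum reading
  set.seed(3)
  draws <- wellcnv:::mixture_draw(1e4, 0.6, 3, 0.09, 2, 0.04, "scaled-sum")
  expect_equal(mean(draws), 0.6 * 3 + 0.4 * 2, tolerance = 0.02)
  expect_equal(var(draws), 0.36 * 0.09 + 0.16 * 0.04, tolerance = 0.05)
  # the mixture alternative has the same mean but larger spread
  draws2 <- wellcnv:::mixture_draw(1e4, 0.6, 3, 0.09, 2, 0.04, "mixture")
  expect_equal(mean(draws2), 2.6, tolerance = 0.03)
  expect_gt(var(draws2), var(draws))
  expect_equal(sp1$truth$n_A, 2)
})

test_that("zero spike simulations return an empty result", {
  fit <- structure(list(), class = "cnv_fit")
  out <- subclonal_sensitivity(NULL, NULL, fit, NULL, n_sims = 0L)
  expect_equal(nrow(out), 0L)
})
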