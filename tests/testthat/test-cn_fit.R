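# Copy-number model estimators, noise pooling, grid search and state
# fitting.

test_that("estimators reproduce closed forms and hand arithmetic", {
  r_bar <- 2.3
  expect_equal(expected_rdr(1, 1, phi = 1, psi = 2, r_bar = r_bar), r_bar)
  expect_equal(expected_rdr(1, 0, phi = 1, psi = 2, r_bar = r_bar), r_bar / 2)
  expect_equal(expected_baf(1, 1, phi = 1), 0.5)
  expect_equal(expected_baf(1, 0, phi = 1), 0)
  # hand arithmetic on the printed formulas
  expect_equal(expected_rdr(2, 1, phi = 0.6, psi = 2, r_bar = 1),
               (0.6 * 3 + 0.8) / (0.6 * 2 + 0.8))
  expect_equal(expected_baf(2, 1, phi = 0.5), (0.5 + 0.5) / (0.5 * 3 + 1))
  # pure-normal limit
  expect_equal(expected_baf(5, 0, phi = 1e-12), 0.5, tolerance = 1e-9)
  # undefined at {0,0} with phi = 1
  expect_true(is.na(expected_baf(0, 0, phi = 1)))
})

test_that("sub-clonal estimators reduce to clonal ones at chi = 1", {
  set.seed(41)
  n_A <- sample(0:6, 1000, TRUE)
  n_B <- pmin(n_A, sample(0:6, 1000, TRUE))
  phi <- runif(1000, 0.05, 1)
  psi <- runif(1000, 1, 8)
  d_r <- expected_rdr(n_A, n_B, phi, psi, 2, chi = 1, m_A = 3, m_B = 1) -
    expected_rdr(n_A, n_B, phi, psi, 2)
  d_b <- expected_baf(n_A, n_B, phi, chi = 1, m_A = 3, m_B = 1) -
    expected_baf(n_A, n_B, phi)
  expect_lt(max(abs(d_r)), 1e-12)
  expect_lt(max(abs(d_b)), 1e-12)
})

test_that("noise pooling is length-weighted and floored", {
  expect_equal(estimate_noise(rep(1, 5), rep(1, 5)), 1e-6)
  # two segments: pooled SSE / (N - S)
  x <- c(1, 2, 3, 10, 12)
  seg <- c(1, 1, 1, 2, 2)
  want <- (sum((x[1:3] - 2)^2) + sum((x[4:5] - 11)^2)) / (5 - 2)
  expect_equal(estimate_noise(x, seg), want)
  set.seed(42)
  x <- rnorm(1000, rep(c(0, 5, 9), c(400, 300, 300)), 0.1)
  expect_equal(estimate_noise(x, rep(1:3, c(400, 300, 300))), 0.01,
               tolerance = 0.2)
})

test_that("maximum total copy number tracks the observed RDR", {
  # flat diploid at phi = 1: small bound
  expect_lte(max_total_copy(2.05, phi = 1, psi = 2, r_bar = 2), 4L)
  # a genome with an 8-copy segment needs at least 8
  r8 <- expected_rdr(5, 3, phi = 1, psi = 2, r_bar = 2)
  expect_gte(max_total_copy(r8, phi = 1, psi = 2, r_bar = 2), 8L)
  # monotone in the maximum segment mean
  caps <- vapply(c(2, 3, 4, 6), max_total_copy, 0L, phi = 1, psi = 2, r_bar = 2)
  expect_true(all(diff(caps) >= 0))
})

make_segstats <- function(states, phi, psi, r_bar, n_r = 30L, n_b = 60L,
                          len = 30e6, sse_r = 0, sse_b = 0) {
  tibble::tibble(
    seg_id = seq_len(nrow(states)), chrom = "chr1", arm = "p",
    start = (seq_len(nrow(states)) - 1) * len, end = seq_len(nrow(states)) * len,
    length = len, n_r = n_r,
    r_mean = expected_rdr(states$n_A, states$n_B, phi, psi, r_bar),
    r_sse = sse_r, n_b = n_b,
    b_mean = expected_baf(states$n_A, states$n_B, phi),
    b_sse = sse_b
  )
}

test_that("segment MSE matches a brute-force evaluation of the printed sums", {
  set.seed(43)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    r <- rnorm(n, 2, 0.3)
    b <- runif(n, 0, 0.5)
    seg <- tibble::tibble(
      seg_id = 1L, chrom = "c", arm = "p", start = 0, end = 1e6,
      length = 1e6, n_r = n, r_mean = mean(r),
      r_sse = sum((r - mean(r))^2),
      n_b = n, b_mean = mean(b), b_sse = sum((b - mean(b))^2)
    )
    phi <- runif(1, 0.3, 1)
    psi <- runif(1, 1.5, 4)
    s2r <- runif(1, 0.01, 0.2)
    s2b <- runif(1, 0.001, 0.01)
    got <- segment_mse(seg, n_A = 2, n_B = 1, phi = phi, psi = psi,
                       r_bar = 2, sigma2_r = s2r, sigma2_b = s2b)
    r_hat <- expected_rdr(2, 1, phi, psi, 2)
    b_hat <- wellcnv:::folded_baf_mean(expected_baf(2, 1, phi), sqrt(s2b))
    want <- mean((r - r_hat)^2) / s2r + mean((b - b_hat)^2) / s2b
    expect_equal(got, want, tolerance = 1e-9)
    # data exactly at the expectations: zero for clonal, penalty for sub-clonal
    seg0 <- seg
    seg0$r_mean <- r_hat
    seg0$r_sse <- 0
    seg0$b_mean <- b_hat
    seg0$b_sse <- 0
    expect_equal(segment_mse(seg0, 2, 1, phi, psi, 2, s2r, s2b), 0,
                 tolerance = 1e-9)
    expect_equal(segment_mse(seg0, 2, 1, phi, psi, 2, s2r, s2b,
                             chi = 0.5, modal = c(2, 1)), 1,
                 tolerance = 1e-9)
  }
})

test_that("one RDR point one sigma from its expectation gives unit MSE", {
  r_hat <- expected_rdr(1, 1, 1, 2, 2)
  seg <- tibble::tibble(seg_id = 1L, chrom = "c", arm = "p", start = 0,
                        end = 1e6, length = 1e6, n_r = 1L,
                        r_mean = r_hat + 0.3, r_sse = 0, n_b = 1L,
                        b_mean = wellcnv:::folded_baf_mean(0.5, 0.1), b_sse = 0)
  expect_equal(segment_mse(seg, 1, 1, 1, 2, 2, sigma2_r = 0.09,
                           sigma2_b = 0.01), 1, tolerance = 1e-9)
})

test_that("grid search recovers noise-free parameters exactly on-grid", {
  states <- tibble::tibble(n_A = c(1, 2, 2, 1, 3), n_B = c(1, 1, 0, 0, 2))
  segs <- make_segstats(states, phi = 0.8, psi = 2, r_bar = 2,
                        sse_r = 30 * 0.01, sse_b = 60 * 1e-4)
  attr(segs, "r_bar") <- 2
  fit <- grid_search(segs, phi_grid = seq(0.5, 1, by = 0.05),
                     psi_grid = seq(1.5, 4, by = 0.25))
  expect_equal(fit$phi, 0.8)
  expect_equal(fit$psi, 2)
  # single segment: genome MSE equals that segment's own MSE
  one <- segs[1, ]
  attr(one, "r_bar") <- 2
  f1 <- grid_search(one, phi_grid = 1, psi_grid = seq(1.5, 3, 0.25))
  noise <- wellcnv:::noise_from_segstats(one)
  m <- segment_mse(one, 1, 1, phi = 1, psi = 2, r_bar = 2,
                   sigma2_r = noise$sigma2_r, sigma2_b = noise$sigma2_b)
  expect_equal(min(f1$grid$mse), m, tolerance = 1e-9)
})

test_that("state fitting finds exact states and breaks ties toward clonality", {
  states <- tibble::tibble(n_A = c(1, 2, 2, 1, 1), n_B = c(1, 1, 0, 0, 1))
  segs <- make_segstats(states, phi = 0.7, psi = 2, r_bar = 2,
                        sse_r = 30 * 0.01, sse_b = 60 * 1e-4)
  attr(segs, "r_bar") <- 2
  fit <- fit_states(segs, phi = 0.7, psi = 2, r_bar = 2)
  expect_equal(fit$segments$n_A, states$n_A)
  expect_equal(fit$segments$n_B, states$n_B)
  expect_true(all(fit$segments$chi == 1))
  expect_equal(fit$modal, c(1, 1))
})

test_that("a segment halfway between states goes sub-clonal only under tight noise", {
  phi <- 0.8
  r_bar <- 2
  # halfway between clonal {1,1} and {2,1} at chi = 0.5 with modal {1,1}
  r_mid <- mean(expected_rdr(c(1, 2), c(1, 1), phi, 2, r_bar))
  b_mid <- mean(expected_baf(c(1, 2), c(1, 1), phi))
  base <- make_segstats(tibble::tibble(n_A = c(1, 2, 1), n_B = c(1, 1, 0)),
                        phi, 2, r_bar, sse_r = 30 * 1e-4, sse_b = 60 * 1e-6)
  mid <- base
  mid$r_mean[2] <- r_mid
  mid$b_mean[2] <- b_mid
  attr(mid, "r_bar") <- r_bar
  tight <- fit_states(mid, phi = phi, psi = 2, r_bar = r_bar,
                      sigma2_r = 1e-4, sigma2_b = 1e-4)
  expect_equal(tight$segments$chi[2], 0.5)
  expect_equal(tight$segments$n_A[2], 2)
  loose <- fit_states(mid, phi = phi, psi = 2, r_bar = r_bar,
                      sigma2_r = 1, sigma2_b = 1)
  expect_equal(loose$segments$chi[2], 1)   # penalty dominates
})

test_that("genome MSE is invariant to segment order and to splitting", {
  states <- tibble::tibble(n_A = c(1, 2, 2), n_B = c(1, 1, 0))
  segs <- make_segstats(states, phi = 0.9, psi = 2, r_bar = 2,
                        sse_r = 30 * 0.01, sse_b = 60 * 1e-4)
  attr(segs, "r_bar") <- 2
  f1 <- fit_states(segs, phi = 0.9, psi = 2, r_bar = 2,
                   sigma2_r = 0.01, sigma2_b = 1e-3)
  perm <- segs[c(3, 1, 2), ]
  attr(perm, "r_bar") <- 2
  f2 <- fit_states(perm, phi = 0.9, psi = 2, r_bar = 2,
                   sigma2_r = 0.01, sigma2_b = 1e-3)
  expect_equal(f1$mse, f2$mse, tolerance = 1e-12)
  # splitting one segment into two identical halves leaves the MSE unchanged
  split <- dplyr::bind_rows(segs, segs[3, ])
  split$length[c(3, 4)] <- segs$length[3] / 2
  attr(split, "r_bar") <- 2
  f3 <- fit_states(split, phi = 0.9, psi = 2, r_bar = 2,
                   sigma2_r = 0.01, sigma2_b = 1e-3)
  expect_equal(f3$mse, f1$mse, tolerance = 1e-12)
})

test_that("tidy and glance expose the fit in broom shape", {
  states <- tibble::tibble(n_A = c(1, 2), n_B = c(1, 0))
  segs <- make_segstats(states, phi = 1, psi = 1.5, r_bar = 2,
                        sse_r = 30 * 0.01, sse_b = 60 * 1e-4)
  attr(segs, "r_bar") <- 2
  fit <- fit_copy_number(segs, phi_grid = c(0.9, 1),
                         psi_grid = seq(1, 3, by = 0.25))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("n_A", "n_B", "chi") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("phi", "psi", "mse") %in% names(gl)))
  prof <- cn_profile(fit)
  expect_true(all(prof$n_A >= prof$n_B))
})
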