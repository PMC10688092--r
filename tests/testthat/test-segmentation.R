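# Loss function, exact DP, stochastic greedy search, and the two-pass
# genome segmentation.

test_that("mirroring and normalisation behave as stated", {
  expect_equal(mirror_baf(c(0.3, 0.7, 0.5, 0, 1)), c(0.3, 0.3, 0.5, 0, 0))
  b <- runif(20)
  expect_equal(mirror_baf(b), mirror_baf(1 - b))
  expect_equal(normalize_rdr(c(2, 0, 4), 2), c(0.25, 0, 0.5))
  expect_error(normalize_rdr(1, 0), "positive")
})

test_that("segmentation loss reproduces hand-computed values", {
  x <- c(1, 1, 1, 5, 5, 5)
  expect_equal(segment_loss(x, cuts = integer(0)), 24 + 0.1)
  expect_equal(segment_loss(x, cuts = 3L), 0 + 0.2)
  # all-equal data: loss is the pure segment penalty
  expect_equal(segment_loss(rep(2, 8), cuts = c(2L, 5L)), 0.3)
  expect_error(segment_loss(x, cuts = c(3L, 3L, 6L)))
  # adding a cut never increases the SSE term and adds exactly lambda
  set.seed(31)
  y <- rnorm(30)
  l0 <- segment_loss(y, cuts = 10L)
  l1 <- segment_loss(y, cuts = c(10L, 20L))
  expect_lte(l1 - l0, 0.1 + 1e-12)
})

test_that("the literal printed weight form is available as an option", {
  x <- c(1, 2, 3)
  w <- c(2, 1, 1)
  xbar <- sum(w * x) / sum(w)
  expect_equal(segment_loss(x, w, lambda = 0),
               sum(w * (x - xbar)^2))
  expect_equal(segment_loss(x, w, lambda = 0, literal_weights = TRUE),
               sum((w * x - xbar)^2))
})

test_that("greedy search recovers a clear two-level split", {
  x <- c(1, 1, 1, 5, 5, 5)
  pos <- seq(0, by = 6e6, length.out = 6)
  res <- greedy_segment(x, pos_start = pos, pos_end = pos + 1e6,
                        restarts = 50, seed = 1)
  expect_equal(res$cuts, 3L)
  # pure noise well below the penalty: single segment
  set.seed(32)
  noise <- rnorm(15, 0, 0.01)
  posn <- seq(0, by = 6e6, length.out = 15)
  res2 <- greedy_segment(noise, pos_start = posn, pos_end = posn + 1e6,
                         restarts = 50, seed = 2)
  expect_equal(res2$cuts, integer(0))
})

test_that("greedy attains the exact DP minimum on small arms", {
  set.seed(33)
  hits <- 0
  for (rep in 1:40) {
    n <- sample(5:20, 1)
    pos <- sort(runif(n, 0, 60e6))
    x <- rnorm(n, 0.3, 0.03) + cumsum(sample(c(0, 0, 0.12), n, TRUE))
    w <- 1 + rpois(n, 2)
    d <- dp_segment(x, w, pos, pos)
    g <- greedy_segment(x, w, pos, pos, restarts = 200, seed = rep)
    hits <- hits + (g$loss <= d$loss + 1e-9)
    expect_gte(g$loss, d$loss - 1e-9)   # DP is the true minimum
  }
  expect_gte(hits, 39)
})

test_that("every emitted segment honours the minimum span", {
  set.seed(34)
  for (rep in 1:20) {
    n <- 30
    pos <- sort(runif(n, 0, 80e6))
    x <- rnorm(n, 0, 0.5)
    res <- greedy_segment(x, pos_start = pos, pos_end = pos,
                          min_span = 5e6, restarts = 100, seed = rep)
    bounds <- c(0L, res$cuts, n)
    for (s in seq_len(length(bounds) - 1)) {
      idx <- (bounds[s] + 1):bounds[s + 1]
      if (length(bounds) > 2) {
        expect_gte(pos[max(idx)] - pos[min(idx)], 5e6)
      }
    }
  }
  # an arm shorter than the minimum span stays one segment
  short <- greedy_segment(c(0, 5, 0, 5), pos_start = (0:3) * 1e6,
                          pos_end = (0:3) * 1e6 + 1, restarts = 50, seed = 1)
  expect_equal(short$cuts, integer(0))
})

test_that("segmentation is deterministic given the seed", {
  set.seed(35)
  x <- rnorm(50) + rep(c(0, 1, 0), c(20, 15, 15))
  pos <- seq(0, by = 2e6, length.out = 50)
  a <- greedy_segment(x, pos_start = pos, pos_end = pos + 1e6,
                      restarts = 100, seed = 99)
  b <- greedy_segment(x, pos_start = pos, pos_end = pos + 1e6,
                      restarts = 100, seed = 99)
  expect_identical(a, b)
})

test_that("fixed breakpoints are kept and only additions are allowed", {
  x <- c(rep(0, 10), rep(1, 10))
  pos <- seq(0, by = 6e6, length.out = 20)
  res <- greedy_segment(x, pos_start = pos, pos_end = pos + 1e6,
                        restarts = 50, seed = 3, fixed_cuts = 5L)
  expect_true(5L %in% res$cuts)      # fixed cut survives although useless
  expect_true(10L %in% res$cuts)     # true breakpoint added
})

test_that("two-pass genome segmentation uses BAF first, then RDR", {
  genome <- make_genome("chr1", 120e6, 60e6)
  win <- tile_windows(genome)
  # RDR stepped at 30 Mb on the p arm, BAF flat
  rdr <- dplyr::mutate(win,
    corrected_r = dplyr::if_else(start < 30e6, 3, 2), masked = FALSE)
  baf <- tibble::tibble(chrom = "chr1", pos = seq(1e6, 119e6, by = 2e6),
                        b = 0.5, weight = 4L)
  segs <- segment_genome(baf, rdr, genome, restarts = 100, seed = 4,
                         r_bar = 2)
  p <- segs[segs$arm == "p", ]
  expect_equal(nrow(p), 2L)
  expect_equal(sort(p$start), c(0, 30e6))

  # BAF stepped at 30 Mb, RDR flat: breakpoint from the BAF pass alone
  rdr2 <- dplyr::mutate(win, corrected_r = 2, masked = FALSE)
  baf2 <- dplyr::mutate(baf, b = dplyr::if_else(pos < 30e6, 0.2, 0.5))
  segs2 <- segment_genome(baf2, rdr2, genome, restarts = 100, seed = 4,
                          r_bar = 2)
  p2 <- segs2[segs2$arm == "p", ]
  expect_equal(nrow(p2), 2L)
  expect_equal(sort(p2$start)[2], 30e6, tolerance = 0.05)
})

test_that("segments never span the centromere", {
  genome <- make_genome("chr1", 100e6, 45e6)
  win <- tile_windows(genome)
  rdr <- dplyr::mutate(win, corrected_r = 2, masked = FALSE)
  baf <- tibble::tibble(chrom = "chr1", pos = seq(1e6, 99e6, by = 2e6),
                        b = 0.5, weight = 4L)
  segs <- segment_genome(baf, rdr, genome, restarts = 50, seed = 5, r_bar = 2)
  expect_true(all(segs$end <= 45e6 | segs$start >= 45e6))
})
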