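# Segmentation of the de-noised tracks: the mirrored BAF is segmented first
# (it is the cleaner signal), then the RDR pass may only add breakpoints
# within the BAF segments. Each chromosome arm is segmented separately by
# minimising a penalized weighted least-squares loss with a restarted
# stochastic greedy search.

#' Mirror BAF values onto [0, 0.5]
#'
#' `b_mirr = 0.5 - |0.5 - b|`, so `b` and `1 - b` map to the same value.
#'
#' @param b BAF values in `[0, 1]`.
#' @return Mirrored values in `[0, 0.5]`.
#' @export
mirror_baf <- function(b) {
  check_that(all(b >= 0 & b <= 1, na.rm = TRUE), "b must lie in [0, 1]")
  0.5 - abs(0.5 - b)
}

#' Normalise RDR onto the mirrored-BAF scale
#'
#' `r_norm = r / (4 * r_bar)`, putting a window at the genome-wide mean at
#' 0.25 so that the two tracks are on comparable scales.
#'
#' @param r Corrected RDR values.
#' @param r_bar Genome-wide mean of the corrected RDR; must be positive.
#' @return Normalised values.
#' @export
normalize_rdr <- function(r, r_bar) {
  check_that(is.finite(r_bar) && r_bar > 0, "r_bar must be positive")
  r / (4 * r_bar)
}

#' Segmentation loss
#'
#' `L = sum_s sum_{i in s} w_i (x_i - xbar_s)^2 + lambda |S|` with weighted
#' per-segment means `xbar_s = sum w_i x_i / sum w_i`. With
#' `literal_weights = TRUE` the within-segment term is evaluated as
#' `(w_i x_i - xbar_s)^2` instead (the weight multiplying the data value
#' rather than the squared residual); the standard weighted least-squares
#' form is the default and is what the search optimises.
#'
#' @param x Data values on the arm.
#' @param w Positive weights (normalised to mean 1 by the caller).
#' @param cuts Integer breakpoints: a cut `c` ends a segment after data
#'   point `c` (so segments are `1..c1`, `c1+1..c2`, ...).
#' @param lambda Penalty per segment (default 0.1).
#' @param literal_weights See above.
#' @return The loss value.
#' @export
segment_loss <- function(x, w = rep(1, length(x)), cuts = integer(0),
                         lambda = 0.1, literal_weights = FALSE) {
  n <- length(x)
  cuts <- sort(unique(as.integer(cuts)))
  check_that(all(cuts >= 1 & cuts <= n - 1), "cuts must lie in 1..n-1")
  bounds <- c(0L, cuts, n)
  check_that(all(diff(bounds) > 0), "empty segment")
  L <- lambda * (length(cuts) + 1)
  for (s in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[s] + 1L):bounds[s + 1L]
    xbar <- sum(w[idx] * x[idx]) / sum(w[idx])
    L <- L + if (literal_weights) {
      sum((w[idx] * x[idx] - xbar)^2)
    } else {
      sum(w[idx] * (x[idx] - xbar)^2)
    }
  }
  L
}

#' Exact segmentation by dynamic programming
#'
#' Exhaustive minimisation of the loss of [segment_loss()] (standard
#' weighted form) under the minimum-span constraint, by O(n^2) dynamic
#' programming. Intended for small arms and as an independent check of the
#' stochastic search.
#'
#' @inheritParams segment_loss
#' @param pos_start,pos_end Genomic extent of each data point (bp).
#' @param min_span Minimum genomic span per segment (default 5 Mb); an arm
#'   shorter than this is returned as a single segment.
#' @return List with `cuts` and `loss`.
#' @export
dp_segment <- function(x, w = rep(1, length(x)), pos_start, pos_end,
                       lambda = 0.1, min_span = 5e6) {
  n <- length(x)
  w <- w / mean(w)   # same normalisation as the greedy search
  if (pos_end[n] - pos_start[1L] < min_span || n == 1L) {
    return(list(cuts = integer(0), loss = segment_loss(x, w, integer(0), lambda)))
  }
  cw <- cumsum(c(0, w))
  cwx <- cumsum(c(0, w * x))
  cwxx <- cumsum(c(0, w * x^2))
  sse <- function(a, b) {   # data points a..b inclusive (1-based)
    W <- cw[b + 1L] - cw[a]
    S <- cwx[b + 1L] - cwx[a]
    Q <- cwxx[b + 1L] - cwxx[a]
    max(Q - S^2 / W, 0)
  }
  best <- c(0, rep(Inf, n))
  prev <- integer(n)
  for (j in seq_len(n)) {
    for (a in seq_len(j)) {
      ok <- (a == 1L && j == n) || (pos_end[j] - pos_start[a]) >= min_span
      if (!ok) next
      cand <- best[a] + sse(a, j) + lambda
      if (cand < best[j + 1L]) {
        best[j + 1L] <- cand
        prev[j] <- a - 1L
      }
    }
  }
  cuts <- integer(0)
  j <- n
  while (j > 0L) {
    a <- prev[j]
    if (a > 0L) cuts <- c(a, cuts)
    j <- a
  }
  list(cuts = cuts, loss = best[n + 1L])
}

#' Segment one arm by restarted stochastic greedy search
#'
#' Each restart starts from the single-segment (plus any fixed breakpoints)
#' solution and repeatedly proposes a random move — add a breakpoint at a
#' random admissible position, remove a random free breakpoint, or shift a
#' free breakpoint by one data point — accepting only strict decreases of
#' the loss, and stops after 100 consecutive rejections. The best of all
#' restarts is returned. Weights are renormalised to mean 1 so the penalty
#' is comparable across arms and tracks.
#'
#' @inheritParams dp_segment
#' @param restarts Number of greedy restarts (default 10,000).
#' @param seed Optional seed for reproducibility.
#' @param fixed_cuts Breakpoints that are always present and immovable
#'   (used by the RDR pass to honour BAF-pass breakpoints).
#' @return List with `cuts` (including fixed ones) and `loss`.
#' @export
greedy_segment <- function(x, w = rep(1, length(x)), pos_start, pos_end,
                           lambda = 0.1, min_span = 5e6, restarts = 10000,
                           seed = NULL, fixed_cuts = integer(0)) {
  n <- length(x)
  check_that(n >= 1L, "arm has no data")
  check_that(all(w > 0), "weights must be positive")
  w <- w / mean(w)
  res <- with_seed(seed,
    .greedy_segment_cpp(as.numeric(x), as.numeric(w),
                        as.numeric(pos_start), as.numeric(pos_end),
                        lambda, min_span, as.integer(fixed_cuts),
                        as.integer(restarts))
  )
  list(cuts = sort(as.integer(res$cuts)), loss = res$loss)
}

#' Segment the genome from the BAF and RDR tracks
#'
#' Per chromosome arm: the mirrored BAF (weighted by haplotype-group size)
#' is segmented first; its breakpoints are snapped to window boundaries and
#' fixed; the normalised RDR pass may then only add breakpoints. Arms with
#' no data are skipped. No segment spans a centromere because arms are
#' segmented separately.
#'
#' @param baf BAF point tibble (`chrom`, `pos`, `b`, `weight`).
#' @param rdr RDR window tibble with `corrected_r` and `masked`.
#' @param genome Genome tibble from [make_genome()].
#' @param lambda Segment penalty (default 0.1).
#' @param min_span Minimum segment span in bp (default 5 Mb).
#' @param restarts Greedy restarts per arm and pass.
#' @param seed Seed for the stochastic search.
#' @param r_bar Genome-wide corrected-RDR mean; computed from `rdr` if
#'   missing.
#' @return Segment tibble `seg_id`, `chrom`, `arm`, `start`, `end` plus
#'   per-segment summaries from [summarize_segments()].
#' @export
segment_genome <- function(baf, rdr, genome, lambda = 0.1, min_span = 5e6,
                           restarts = 10000, seed = NULL, r_bar = NULL) {
  r_bar <- r_bar %||% rdr_mean(rdr)
  rdr <- mutate(rdr, r_norm = normalize_rdr(.data$corrected_r, r_bar))
  segs <- list()
  seeds <- with_seed(seed, sample.int(2^30, 2L * nrow(genome) * 2L))
  si <- 0L
  for (ci in seq_len(nrow(genome))) {
    ch <- genome$chrom[ci]
    cen <- genome$centromere[ci]
    for (arm in c("p", "q")) {
      bounds <- if (arm == "p") c(0, cen) else c(cen, genome$length[ci])
      if (bounds[2L] - bounds[1L] <= 0) next
      si <- si + 1L
      wv <- rdr[rdr$chrom == ch & !rdr$masked &
                  (rdr$start + rdr$end) / 2 >= bounds[1L] &
                  (rdr$start + rdr$end) / 2 < bounds[2L], ]
      bv <- baf[baf$chrom == ch & baf$pos >= bounds[1L] & baf$pos < bounds[2L], ]
      if (nrow(wv) == 0L && nrow(bv) == 0L) next
      # pass 1: BAF
      baf_cut_pos <- numeric(0)
      if (nrow(bv) >= 2L) {
        bv <- arrange(bv, .data$pos)
        res_b <- greedy_segment(mirror_baf(bv$b), bv$weight,
                                bv$pos, bv$pos, lambda, min_span,
                                restarts, seed = seeds[2L * si - 1L])
        if (length(res_b$cuts) > 0L) {
          baf_cut_pos <- (bv$pos[res_b$cuts] + bv$pos[res_b$cuts + 1L]) / 2
        }
      }
      if (nrow(wv) >= 1L) {
        wv <- arrange(wv, .data$start)
        # snap BAF cuts to window boundaries: cut after the last window whose
        # end does not exceed the BAF cut position
        fixed <- vapply(baf_cut_pos, function(p) sum(wv$end <= p), 0)
        fixed <- sort(unique(fixed[fixed >= 1 & fixed <= nrow(wv) - 1L]))
        res_r <- greedy_segment(wv$r_norm, rep(1, nrow(wv)),
                                wv$start, wv$end, lambda, min_span,
                                restarts, seed = seeds[2L * si],
                                fixed_cuts = fixed)
        cuts <- res_r$cuts
        seg_bounds <- c(bounds[1L],
                        if (length(cuts)) (wv$end[cuts] + wv$start[cuts + 1L]) / 2,
                        bounds[2L])
      } else {
        seg_bounds <- sort(unique(c(bounds, baf_cut_pos)))
      }
      segs[[length(segs) + 1L]] <- tibble(
        chrom = ch, arm = arm,
        start = seg_bounds[-length(seg_bounds)],
        end = seg_bounds[-1L]
      )
    }
  }
  check_that(length(segs) > 0L, "no arm has any data to segment")
  out <- mutate(list_rbind(segs), seg_id = row_number())
  summarize_segments(select(out, "seg_id", "chrom", "arm", "start", "end"),
                     rdr, baf, r_bar = r_bar)
}

#' Attach per-segment data summaries
#'
#' For each segment, summary statistics of the RDR windows (corrected scale)
#' and mirrored-BAF points falling inside it: point counts, means, and
#' within-segment sums of squared deviations. These are sufficient
#' statistics for the copy-number fit.
#'
#' @param segments Tibble `seg_id`, `chrom`, `arm`, `start`, `end`.
#' @param rdr RDR window tibble with `corrected_r`, `masked`.
#' @param baf BAF point tibble.
#' @param r_bar Genome-wide corrected-RDR mean.
#' @return `segments` with columns `length`, `n_r`, `r_mean`, `r_sse`,
#'   `n_b`, `b_mean`, `b_sse` and attribute `r_bar`.
#' @export
summarize_segments <- function(segments, rdr, baf, r_bar = NULL) {
  r_bar <- r_bar %||% rdr_mean(rdr)
  n <- nrow(segments)
  out <- mutate(segments, length = .data$end - .data$start,
                n_r = 0L, r_mean = NA_real_, r_sse = 0,
                n_b = 0L, b_mean = NA_real_, b_sse = 0)
  for (i in seq_len(n)) {
    wv <- rdr[!rdr$masked & rdr$chrom == out$chrom[i] &
                (rdr$start + rdr$end) / 2 >= out$start[i] &
                (rdr$start + rdr$end) / 2 < out$end[i], ]
    if (nrow(wv) > 0L) {
      out$n_r[i] <- nrow(wv)
      out$r_mean[i] <- mean(wv$corrected_r)
      out$r_sse[i] <- sum((wv$corrected_r - out$r_mean[i])^2)
    }
    bv <- baf[baf$chrom == out$chrom[i] & baf$pos >= out$start[i] &
                baf$pos < out$end[i], ]
    if (nrow(bv) > 0L) {
      bm <- mirror_baf(bv$b)
      out$n_b[i] <- nrow(bv)
      out$b_mean[i] <- mean(bm)
      out$b_sse[i] <- sum((bm - out$b_mean[i])^2)
    }
  }
  attr(out, "r_bar") <- r_bar
  out
}
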