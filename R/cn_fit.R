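# Purity/ploidy grid search and allele-specific copy-number state fitting.
# Expected RDR and BAF per state come from the standard mixture model with
# diploid non-cancer cells; states are fitted per segment by minimising a
# variance-normalised mean squared error, optionally over sub-clonal states
# carried by a fraction (clonality) of tumour cells, with the remaining
# tumour cells at the modal state of the fully clonal solution.

#' Expected RDR of a copy-number state
#'
#' Clonal (`chi = 1`):
#' `r_hat = r_bar * (phi*(n_A+n_B) + 2*(1-phi)) / (phi*psi + 2*(1-phi))`.
#' Sub-clonal: the tumour term mixes the CNA state (fraction `chi` of tumour
#' cells) with the modal state `{m_A, m_B}` (fraction `1-chi`); at `chi = 1`
#' the general form reduces exactly to the clonal one.
#'
#' @param n_A,n_B Major and minor copy numbers (vectorised).
#' @param phi Purity in (0, 1].
#' @param psi Tumour ploidy (> 0).
#' @param r_bar Genome-wide mean corrected RDR.
#' @param chi Clonality in (0, 1].
#' @param m_A,m_B Modal state (needed when `chi < 1`).
#' @return Expected corrected RDR.
#' @export
expected_rdr <- function(n_A, n_B, phi, psi, r_bar, chi = 1, m_A = 0, m_B = 0) {
  num <- phi * chi * (n_A + n_B) + phi * (1 - chi) * (m_A + m_B) + 2 * (1 - phi)
  r_bar * num / (phi * psi + 2 * (1 - phi))
}

#' Expected mirrored BAF of a copy-number state
#'
#' Clonal: `b_hat = (phi*n_B + (1-phi)) / (phi*(n_A+n_B) + 2*(1-phi))`.
#' Sub-clonal numerator `phi*chi*n_B + phi*(1-chi)*m_B + (1-phi)` with the
#' matching mixture denominator. Given `n_A >= n_B` (and `m_A >= m_B`) the
#' value is on the mirrored scale, at most 0.5. A zero denominator (state
#' `{0,0}` at `phi = 1`) yields `NA`: such a segment is fitted on the RDR
#' term alone.
#'
#' @inheritParams expected_rdr
#' @return Expected mirrored BAF, or `NA` where undefined.
#' @export
expected_baf <- function(n_A, n_B, phi, chi = 1, m_A = 0, m_B = 0) {
  num <- phi * chi * n_B + phi * (1 - chi) * m_B + (1 - phi)
  den <- phi * chi * (n_A + n_B) + phi * (1 - chi) * (m_A + m_B) + 2 * (1 - phi)
  if_else(den > 0, num / den, NA_real_)
}

#' Pooled within-segment variance
#'
#' Genome-wide noise estimate per track: deviations from per-segment means,
#' pooled across segments as `sum(SSE) / (N - S)` where `N` is the number of
#' data points and `S` the number of contributing segments. Floored at
#' `1e-6` to keep the MSE normalisation defined on degenerate input.
#'
#' @param x Data values.
#' @param segment Segment membership (any vector usable as a grouping key).
#' @return The pooled variance estimate.
#' @export
estimate_noise <- function(x, segment) {
  ok <- !is.na(x)
  x <- x[ok]
  segment <- segment[ok]
  if (length(x) == 0L) return(1e-6)
  sse <- tapply(x, segment, function(v) sum((v - mean(v))^2))
  ns <- tapply(x, segment, length)
  denom <- sum(ns) - length(ns)
  if (denom <= 0) return(1e-6)
  max(sum(sse) / denom, 1e-6)
}

noise_from_segstats <- function(segments) {
  sr <- segments[segments$n_r > 0L, ]
  sb <- segments[segments$n_b > 0L, ]
  dr <- sum(sr$n_r) - nrow(sr)
  db <- sum(sb$n_b) - nrow(sb)
  list(
    sigma2_r = if (dr > 0) max(sum(sr$r_sse) / dr, 1e-6) else 1e-6,
    sigma2_b = if (db > 0) max(sum(sb$b_sse) / db, 1e-6) else 1e-6
  )
}

#' Largest total copy number consistent with the observed RDR
#'
#' The smallest total copy number whose expected RDR at `(phi, psi)` exceeds
#' the maximum segment-mean corrected RDR; candidate states are all
#' `{n_A, n_B}` with `n_A >= n_B` and `n_A + n_B <= n_max`.
#'
#' @param max_r Maximum segment-mean corrected RDR (a vector is reduced to
#'   its maximum).
#' @inheritParams expected_rdr
#' @param cap Hard upper bound on the returned value (default 30).
#' @return Integer `n_max`.
#' @export
max_total_copy <- function(max_r, phi, psi, r_bar, cap = 30L) {
  max_r <- max(max_r, na.rm = TRUE)
  thr <- ((max_r / r_bar) * (phi * psi + 2 * (1 - phi)) - 2 * (1 - phi)) / phi
  n_max <- floor(thr + 1e-9) + 1L
  as.integer(min(max(n_max, 1L), cap))
}

# all states with n_A >= n_B and n_A + n_B <= n_total
enumerate_states <- function(n_total) {
  st <- tidyr::expand_grid(n_A = 0:n_total, n_B = 0:n_total)
  filter(st, .data$n_A >= .data$n_B, .data$n_A + .data$n_B <= n_total)
}

# Expected value of the mirrored BAF when points scatter around b_hat with
# sd sigma: mirroring folds the noise at 0.5, so a balanced state's mirrored
# mean sits sqrt(2/pi)*sigma below 0.5. b_eff is the folded-normal mean
# 0.5 - E|X|, X ~ N(0.5 - b_hat, sigma^2); far from the fold it equals b_hat.
folded_baf_mean <- function(b_hat, sigma) {
  if (sigma <= 0) return(b_hat)
  m <- 0.5 - b_hat
  eabs <- m * (2 * stats::pnorm(m / sigma) - 1) + 2 * sigma * stats::dnorm(m / sigma)
  0.5 - eabs
}

# segments x states MSE matrix from per-segment sufficient statistics.
# states: tibble with n_A, n_B, chi (and penalty applied for chi < 1).
state_mse_matrix <- function(segments, states, phi, psi, r_bar,
                             sigma2_r, sigma2_b, modal = c(0, 0),
                             penalty = 1, fold_correct = TRUE) {
  r_hat <- expected_rdr(states$n_A, states$n_B, phi, psi, r_bar,
                        states$chi, modal[1L], modal[2L])
  b_hat <- expected_baf(states$n_A, states$n_B, phi,
                        states$chi, modal[1L], modal[2L])
  if (fold_correct) b_hat <- folded_baf_mean(b_hat, sqrt(sigma2_b))
  nseg <- nrow(segments)
  has_r <- segments$n_r > 0L
  has_b <- segments$n_b > 0L
  mse <- matrix(0, nseg, nrow(states))
  if (any(has_r)) {
    base_r <- segments$r_sse[has_r] / segments$n_r[has_r]
    dev_r <- outer(segments$r_mean[has_r], r_hat, `-`)^2
    mse[has_r, ] <- mse[has_r, ] + (base_r + dev_r) / sigma2_r
  }
  if (any(has_b)) {
    base_b <- segments$b_sse[has_b] / segments$n_b[has_b]
    dev_b <- outer(segments$b_mean[has_b], b_hat, `-`)^2
    add_b <- (base_b + dev_b) / sigma2_b
    add_b[is.na(add_b)] <- 0   # undefined b_hat: fit that state on RDR alone
    mse[has_b, ] <- mse[has_b, ] + add_b
  }
  sweep(mse, 2L, if_else(states$chi < 1, penalty, 0), `+`)
}

#' Per-segment MSE of one copy-number state
#'
#' `MSE_s = MSE_s^(r) + MSE_s^(b) (+ penalty if chi < 1)` where each track
#' term is the mean squared deviation from the state's expectation,
#' normalised by the genome-wide noise estimate for that track. Computed
#' from the segment's sufficient statistics (`n`, mean, SSE per track).
#'
#' @param segment One-row segment tibble from [summarize_segments()].
#' @param n_A,n_B,chi The state.
#' @inheritParams expected_rdr
#' @param sigma2_r,sigma2_b Genome-wide noise estimates.
#' @param modal Modal state `c(m_A, m_B)` for sub-clonal states.
#' @param penalty Sub-clonal penalty added when `chi < 1` (default 1).
#' @return The segment MSE.
#' @export
segment_mse <- function(segment, n_A, n_B, phi, psi, r_bar,
                        sigma2_r, sigma2_b, chi = 1, modal = c(0, 0),
                        penalty = 1) {
  states <- tibble(n_A = n_A, n_B = n_B, chi = chi)
  drop(state_mse_matrix(segment, states, phi, psi, r_bar,
                        sigma2_r, sigma2_b, modal, penalty))
}

# deterministic tie-break: lower total, then higher clonality, then higher n_B
state_rank <- function(states) {
  order(order(states$n_A + states$n_B, -states$chi, -states$n_B))
}

pick_states <- function(mse, states) {
  rank <- state_rank(states)
  vapply(seq_len(nrow(mse)), function(i) {
    cand <- which(mse[i, ] <= min(mse[i, ]) + 1e-12)
    cand[which.min(rank[cand])]
  }, 0L)
}

#' Grid search for purity and ploidy
#'
#' For every `(phi, psi)` pair on the grid, each segment takes its best
#' clonal state and the genome MSE is the length-normalised sum of segment
#' MSEs. Local minima of the MSE surface (strictly smaller than all existing
#' grid neighbours) are identified; among minima with
#' `MSE <= kappa * global minimum`, the lowest-ploidy one is returned. This
#' guards against spuriously tetraploid solutions that fit marginally
#' better.
#'
#' @param segments Segment tibble from [summarize_segments()].
#' @param r_bar Genome-wide mean corrected RDR (defaults to the attribute
#'   left by [summarize_segments()]).
#' @param phi_grid,psi_grid Grids for purity and ploidy.
#' @param kappa Relative threshold defining a sufficiently pronounced
#'   minimum (default 1.2).
#' @param cap Upper bound on total copy number (default 30).
#' @return An object of class `cnv_fit` (see [fit_copy_number()]), without
#'   sub-clonal states.
#' @export
grid_search <- function(segments, r_bar = attr(segments, "r_bar"),
                        phi_grid = seq(0.05, 1, by = 0.01),
                        psi_grid = seq(1, 8, by = 0.05),
                        kappa = 1.2, cap = 30L) {
  check_that(length(phi_grid) > 0L && length(psi_grid) > 0L, "empty grid")
  check_that(!is.null(r_bar), "r_bar is required")
  usable <- segments[segments$n_r > 0L | segments$n_b > 0L, ]
  check_that(nrow(usable) > 0L, "no segment carries data")
  noise <- noise_from_segstats(usable)
  states_all <- mutate(enumerate_states(cap), chi = 1)
  totals <- states_all$n_A + states_all$n_B
  max_r <- max(usable$r_mean, na.rm = TRUE)
  len <- usable$length
  mse_grid <- matrix(NA_real_, length(phi_grid), length(psi_grid))
  for (i in seq_along(phi_grid)) {
    for (j in seq_along(psi_grid)) {
      phi <- phi_grid[i]
      psi <- psi_grid[j]
      n_max <- max_total_copy(max_r, phi, psi, r_bar, cap)
      st <- states_all[totals <= n_max, ]
      m <- state_mse_matrix(usable, st, phi, psi, r_bar,
                            noise$sigma2_r, noise$sigma2_b)
      seg_best <- apply(m, 1L, min)
      mse_grid[i, j] <- sum(len * seg_best) / sum(len)
    }
  }
  sol <- select_solution(mse_grid, phi_grid, psi_grid, kappa)
  fit <- structure(list(
    phi = sol$phi, psi = sol$psi, mse = sol$mse,
    grid = tibble(phi = rep(phi_grid, times = length(psi_grid)),
                  psi = rep(psi_grid, each = length(phi_grid)),
                  mse = as.vector(mse_grid)),
    segments = segments, r_bar = r_bar,
    sigma2_r = noise$sigma2_r, sigma2_b = noise$sigma2_b,
    kappa = kappa, cap = cap, modal = NULL, subclonal = FALSE
  ), class = "cnv_fit")
  fit
}

# Lowest-ploidy sufficiently pronounced local minimum of the MSE surface.
# A candidate must (a) beat all existing 8-neighbours strictly, (b) be
# pronounced: improve on its ploidy-direction neighbours by a relative
# margin, which excludes the flat low-purity ridge where an over-rich state
# set can mimic any data, and (c) lie within kappa of the global minimum.
select_solution <- function(mse_grid, phi_grid, psi_grid, kappa,
                            prominence = 1e-4) {
  P <- nrow(mse_grid)
  Q <- ncol(mse_grid)
  gmin <- min(mse_grid)
  minima <- list()
  interior <- if (Q >= 3L) 2:(Q - 1L) else integer(0)
  for (i in seq_len(P)) {
    # ploidy-boundary cells cannot be verified as minima and are skipped
    for (j in interior) {
      v <- mse_grid[i, j]
      if (v > kappa * gmin) next
      nb <- expand.grid(di = -1:1, dj = -1:1)
      nb <- nb[!(nb$di == 0 & nb$dj == 0), ]
      ii <- i + nb$di
      jj <- j + nb$dj
      ok <- ii >= 1 & ii <= P & jj >= 1 & jj <= Q
      if (!all(v < mse_grid[cbind(ii[ok], jj[ok])])) next
      psi_nb <- c(mse_grid[i, j - 1L], mse_grid[i, j + 1L])
      if (min(psi_nb) < v * (1 + prominence)) next
      minima[[length(minima) + 1L]] <- c(i = i, j = j, mse = v)
    }
  }
  if (length(minima) == 0L) {
    # fall back to the global minimum if the surface is flat or monotone
    idx <- which(mse_grid == gmin, arr.ind = TRUE)[1L, ]
    return(list(phi = phi_grid[idx[1L]], psi = psi_grid[idx[2L]], mse = gmin))
  }
  mm <- do.call(rbind, minima)
  best <- mm[order(psi_grid[mm[, "j"]], mm[, "mse"]), , drop = FALSE][1L, ]
  list(phi = phi_grid[best["i"]], psi = psi_grid[best["j"]],
       mse = unname(best["mse"]))
}

#' Fit per-segment copy-number states at fixed purity and ploidy
#'
#' Clonal pass: each segment takes the clonal state minimising its MSE; the
#' modal state is the genomic-length mode of that solution. When sub-clonal
#' states are allowed, the state set is expanded by clonalities
#' `chi` in `{0.5, ..., 0.9}` (with the unit penalty) and segments are
#' refitted. Ties prefer parsimony (lower total copy), then clonality, then
#' higher minor copy.
#'
#' @param fit A `cnv_fit` object from [grid_search()], or a segment tibble
#'   (then `phi`, `psi`, `r_bar` must be given).
#' @param subclonal Allow sub-clonal states (default `TRUE`).
#' @param chis Sub-clonal clonality grid.
#' @param penalty Sub-clonal penalty (default 1).
#' @param phi,psi,r_bar,sigma2_r,sigma2_b,cap Overrides when `fit` is a
#'   plain segment tibble.
#' @return The `cnv_fit` object with per-segment `n_A`, `n_B`, `chi`,
#'   `mse_s` columns, `modal` state and genome `mse` updated.
#' @export
fit_states <- function(fit, subclonal = TRUE,
                       chis = seq(0.5, 0.9, by = 0.1), penalty = 1,
                       phi = NULL, psi = NULL, r_bar = NULL,
                       sigma2_r = NULL, sigma2_b = NULL, cap = 30L) {
  if (!inherits(fit, "cnv_fit")) {
    segments <- fit
    check_that(!is.null(phi) && !is.null(psi), "phi and psi are required")
    r_bar <- r_bar %||% attr(segments, "r_bar")
    noise <- noise_from_segstats(segments[segments$n_r > 0L | segments$n_b > 0L, ])
    fit <- structure(list(
      phi = phi, psi = psi, mse = NA_real_, grid = NULL, segments = segments,
      r_bar = r_bar, sigma2_r = sigma2_r %||% noise$sigma2_r,
      sigma2_b = sigma2_b %||% noise$sigma2_b, kappa = NA_real_, cap = cap,
      modal = NULL, subclonal = FALSE
    ), class = "cnv_fit")
  }
  segs <- fit$segments
  usable <- segs$n_r > 0L | segs$n_b > 0L
  max_r <- max(segs$r_mean[usable], na.rm = TRUE)
  n_max <- max_total_copy(max_r, fit$phi, fit$psi, fit$r_bar, fit$cap)
  clonal <- mutate(enumerate_states(n_max), chi = 1)
  m <- state_mse_matrix(segs[usable, ], clonal, fit$phi, fit$psi, fit$r_bar,
                        fit$sigma2_r, fit$sigma2_b, penalty = penalty)
  pick <- pick_states(m, clonal)
  res <- tibble(n_A = clonal$n_A[pick], n_B = clonal$n_B[pick],
                chi = 1, mse_s = m[cbind(seq_along(pick), pick)])
  # modal state: genomic-length mode of the fully clonal solution
  key <- paste(res$n_A, res$n_B)
  len_by_state <- tapply(segs$length[usable], key, sum)
  modal_key <- names(len_by_state)[which.max(len_by_state)]
  modal <- as.numeric(strsplit(modal_key, " ")[[1L]])
  if (subclonal) {
    sub <- tidyr::expand_grid(enumerate_states(n_max), chi = chis)
    states <- bind_rows(clonal, sub)
    m <- state_mse_matrix(segs[usable, ], states, fit$phi, fit$psi, fit$r_bar,
                          fit$sigma2_r, fit$sigma2_b, modal = modal,
                          penalty = penalty)
    pick <- pick_states(m, states)
    res <- tibble(n_A = states$n_A[pick], n_B = states$n_B[pick],
                  chi = states$chi[pick],
                  mse_s = m[cbind(seq_along(pick), pick)])
  }
  segs$n_A <- segs$n_B <- segs$chi <- segs$mse_s <- NA_real_
  segs$n_A[usable] <- res$n_A
  segs$n_B[usable] <- res$n_B
  segs$chi[usable] <- res$chi
  segs$mse_s[usable] <- res$mse_s
  fit$segments <- segs
  fit$modal <- modal
  fit$subclonal <- subclonal
  fit$mse <- sum(segs$length[usable] * res$mse_s) / sum(segs$length[usable])
  fit
}

#' Fit allele-specific copy number end to end
#'
#' Estimates noise, runs the purity/ploidy grid search, and fits per-segment
#' states (clonal, then sub-clonal if allowed).
#'
#' @inheritParams grid_search
#' @inheritParams fit_states
#' @return A `cnv_fit` object: purity `phi`, ploidy `psi`, genome `mse`,
#'   the full MSE grid, per-segment states, the modal state, and the noise
#'   estimates. Use [cn_profile()], [tidy()] and [glance()] to extract
#'   results.
#' @export
#' @examples
#' \dontrun{
#' segs <- segment_genome(baf, rdr, genome, seed = 1)
#' fit <- fit_copy_number(segs)
#' glance(fit)
#' }
fit_copy_number <- function(segments, r_bar = attr(segments, "r_bar"),
                            phi_grid = seq(0.05, 1, by = 0.01),
                            psi_grid = seq(1, 8, by = 0.05),
                            kappa = 1.2, subclonal = TRUE,
                            chis = seq(0.5, 0.9, by = 0.1), penalty = 1,
                            cap = 30L) {
  fit <- grid_search(segments, r_bar = r_bar, phi_grid = phi_grid,
                     psi_grid = psi_grid, kappa = kappa, cap = cap)
  fit_states(fit, subclonal = subclonal, chis = chis, penalty = penalty)
}

#' Extract the copy-number profile from a fit
#'
#' @param fit A `cnv_fit` object with fitted states.
#' @return Profile tibble `chrom`, `start`, `end`, `n_A`, `n_B`,
#'   `clonality` (segments without data are dropped).
#' @export
cn_profile <- function(fit) {
  segs <- fit$segments
  check_that("n_A" %in% names(segs) && !all(is.na(segs$n_A)),
             "fit has no states; run fit_states() first")
  out <- segs[!is.na(segs$n_A), ]
  tibble(chrom = out$chrom, start = out$start, end = out$end,
         n_A = out$n_A, n_B = out$n_B, clonality = out$chi)
}

#' @export
print.cnv_fit <- function(x, ...) {
  cat("Allele-specific copy-number fit\n")
  cat(sprintf("  purity  phi = %.3f\n", x$phi))
  cat(sprintf("  ploidy  psi = %.3f\n", x$psi))
  cat(sprintf("  genome MSE  = %.4f\n", x$mse))
  if (!is.null(x$modal)) {
    cat(sprintf("  modal state = {%d,%d}\n", x$modal[1L], x$modal[2L]))
  }
  cat(sprintf("  segments    = %d\n", nrow(x$segments)))
  invisible(x)
}

#' Tidy a copy-number fit into per-segment rows
#'
#' @param x A `cnv_fit` object.
#' @param ... Unused.
#' @return One row per segment with coordinates, data summaries and fitted
#'   state.
#' @export
tidy.cnv_fit <- function(x, ...) {
  as_tibble(x$segments)
}

#' One-row summary of a copy-number fit
#'
#' @param x A `cnv_fit` object.
#' @param ... Unused.
#' @return Tibble with `phi`, `psi`, `mse`, `modal_A`, `modal_B`,
#'   `n_segments`, `sigma2_r`, `sigma2_b`.
#' @export
glance.cnv_fit <- function(x, ...) {
  tibble(phi = x$phi, psi = x$psi, mse = x$mse,
         modal_A = if (is.null(x$modal)) NA_real_ else x$modal[1L],
         modal_B = if (is.null(x$modal)) NA_real_ else x$modal[2L],
         n_segments = nrow(x$segments),
         sigma2_r = x$sigma2_r, sigma2_b = x$sigma2_b)
}
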