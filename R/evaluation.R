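# Benchmarking: event calling (amplification / deletion / LOH), base-count
# sensitivity/precision/F1 against a truth profile, exact-match fraction,
# ploidy error, signal-to-noise ratio of a track, and multi-caller
# consensus.

#' Length-weighted ploidy of a profile
#'
#' The genomic-length-weighted mean total copy number, counting sub-clonal
#' segments at their tumour-cell average.
#'
#' @param profile Profile tibble (`chrom`, `start`, `end`, `n_A`, `n_B`,
#'   `clonality`); a missing `clonality` column counts every segment as
#'   clonal.
#' @param modal Modal state used for the non-CNA fraction of sub-clonal
#'   segments (default `{1,1}`-free: the segment's own total is used when
#'   no modal state is supplied).
#' @return Scalar ploidy.
#' @export
profile_ploidy <- function(profile, modal = NULL) {
  len <- profile$end - profile$start
  tot <- profile$n_A + profile$n_B
  chi <- if ("clonality" %in% names(profile)) profile$clonality else rep(1, nrow(profile))
  if (!is.null(modal)) {
    tot <- chi * tot + (1 - chi) * (modal[1L] + modal[2L])
  }
  sum(len * tot) / sum(len)
}

#' Call amplification, deletion and LOH events from a profile
#'
#' The sample median total copy number `n_med` is the genomic-length-weighted
#' median of `n_A + n_B`. Amplifications are regions with total copy number
#' at least `2 * n_med`; deletions have total copy number 0; LOH is
#' `n_B = 0` with `n_A > 0` (so a deletion is never LOH).
#'
#' @param profile Profile tibble with canonical `n_A >= n_B`.
#' @return The profile with logical columns `amplification`, `deletion`,
#'   `loh`, and `n_med` in `attr(, "n_med")`.
#' @export
call_events <- function(profile) {
  profile <- as_tibble(profile)
  check_that(all(profile$n_A >= profile$n_B), "profile must have n_A >= n_B")
  tot <- profile$n_A + profile$n_B
  n_med <- weighted_median(tot, profile$end - profile$start)
  out <- mutate(profile,
                amplification = tot >= 2 * n_med,
                deletion = tot == 0,
                loh = .data$n_B == 0 & .data$n_A > 0)
  attr(out, "n_med") <- n_med
  out
}

# intersect two profiles into common intervals carrying both states
align_profiles <- function(p1, p2, suffixes = c("_call", "_truth")) {
  out <- list()
  for (ch in intersect(unique(p1$chrom), unique(p2$chrom))) {
    a <- arrange(p1[p1$chrom == ch, ], .data$start)
    b <- arrange(p2[p2$chrom == ch, ], .data$start)
    cuts <- sort(unique(c(a$start, a$end, b$start, b$end)))
    if (length(cuts) < 2L) next
    iv <- tibble(chrom = ch, start = cuts[-length(cuts)], end = cuts[-1L])
    mid <- (iv$start + iv$end) / 2
    ia <- findInterval(mid, a$start)
    ib <- findInterval(mid, b$start)
    in_a <- ia >= 1L & mid < a$end[pmax(ia, 1L)]
    in_b <- ib >= 1L & mid < b$end[pmax(ib, 1L)]
    keep <- in_a & in_b
    if (!any(keep)) next
    iv <- iv[keep, ]
    ia <- ia[keep]
    ib <- ib[keep]
    for (col in setdiff(names(a), c("chrom", "start", "end"))) {
      iv[[paste0(col, suffixes[1L])]] <- a[[col]][ia]
    }
    for (col in setdiff(names(b), c("chrom", "start", "end"))) {
      iv[[paste0(col, suffixes[2L])]] <- b[[col]][ib]
    }
    out[[length(out) + 1L]] <- iv
  }
  if (length(out) == 0L) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  list_rbind(out)
}

#' Event-level detection metrics against a truth profile
#'
#' Base-count metrics per event class, on the assessable bases (the
#' intersection of both profiles' covered genome): sensitivity is agreeing
#' bases over truth bases; `specificity_paper` is agreeing bases over called
#' bases (this quantity is a precision, named as the field reports it);
#' `F1 = 2*sens*spec / (sens+spec)`. An undefined ratio (no truth or no
#' called bases) is reported as `NA` with `F1 = 0`.
#'
#' @param calls,truth Profile tibbles.
#' @return Tibble with one row per event class.
#' @export
event_metrics <- function(calls, truth) {
  ec <- call_events(calls)
  et <- call_events(truth)
  al <- align_profiles(ec, et)
  len <- al$end - al$start
  out <- list()
  for (ev in c("amplification", "deletion", "loh")) {
    cc <- al[[paste0(ev, "_call")]]
    tt <- al[[paste0(ev, "_truth")]]
    agree <- sum(len[cc & tt])
    truth_b <- sum(len[tt])
    call_b <- sum(len[cc])
    sens <- if (truth_b > 0) agree / truth_b else NA_real_
    spec <- if (call_b > 0) agree / call_b else NA_real_
    f1 <- if (!is.na(sens) && !is.na(spec) && sens + spec > 0) {
      2 * sens * spec / (sens + spec)
    } else 0
    out[[ev]] <- tibble(event = ev, sensitivity = sens,
                        specificity_paper = spec, f1 = f1,
                        truth_bases = truth_b, called_bases = call_b,
                        agree_bases = agree)
  }
  list_rbind(out)
}

#' Fraction of the assessable genome with exactly matching states
#'
#' @param calls,truth Profile tibbles.
#' @return Fraction in `[0, 1]` of assessable bases where `{n_A, n_B}`
#'   agree exactly.
#' @export
exact_match_fraction <- function(calls, truth) {
  al <- align_profiles(calls, truth)
  check_that(nrow(al) > 0L, "profiles share no assessable bases")
  len <- al$end - al$start
  hit <- al$n_A_call == al$n_A_truth & al$n_B_call == al$n_B_truth
  sum(len[hit]) / sum(len)
}

#' Absolute ploidy error
#'
#' @param calls,truth Profile tibbles, or scalar ploidies.
#' @return `|psi - psi_truth|`.
#' @export
ploidy_error <- function(calls, truth) {
  p1 <- if (is.data.frame(calls)) profile_ploidy(calls) else calls
  p2 <- if (is.data.frame(truth)) profile_ploidy(truth) else truth
  abs(p1 - p2)
}

#' Consensus profile from several callers
#'
#' Per assessable base, the consensus major (minor) copy number is the
#' median of the inputs' majors (minors); with an even number of profiles
#' the lower median keeps states integral. Ploidies are matched by popular
#' vote on the rounded profile ploidy: profiles whose rounded ploidy
#' disagrees with the majority are flagged in the report (re-running the
#' dissenting caller with a forced ploidy is the caller's job).
#'
#' @param profiles List of at least two profile tibbles on one genome.
#' @return List with `profile` (consensus tibble) and `ploidy_report`
#'   (per-input ploidy, rounded value, and `flagged`).
#' @export
consensus_states <- function(profiles) {
  check_that(is.list(profiles) && length(profiles) >= 2L,
             "consensus needs at least two profiles")
  acc <- profiles[[1L]][, c("chrom", "start", "end", "n_A", "n_B")]
  names(acc)[4:5] <- c("n_A_1", "n_B_1")
  for (k in 2:length(profiles)) {
    pk <- profiles[[k]][, c("chrom", "start", "end", "n_A", "n_B")]
    acc <- align_profiles(acc, pk, suffixes = c("", paste0("_", k)))
    names(acc)[names(acc) == "n_A"] <- paste0("n_A_", k)
    names(acc)[names(acc) == "n_B"] <- paste0("n_B_", k)
  }
  na_cols <- as.matrix(acc[, paste0("n_A_", seq_along(profiles))])
  nb_cols <- as.matrix(acc[, paste0("n_B_", seq_along(profiles))])
  cons <- tibble(
    chrom = acc$chrom, start = acc$start, end = acc$end,
    n_A = apply(na_cols, 1L, lower_median),
    n_B = apply(nb_cols, 1L, lower_median),
    clonality = 1
  )
  ploidies <- vapply(profiles, profile_ploidy, 0)
  rounded <- round(ploidies)
  votes <- table(rounded)
  majority <- as.numeric(names(votes)[which.max(votes)])
  report <- tibble(profile = seq_along(profiles), ploidy = ploidies,
                   rounded = rounded, flagged = rounded != majority)
  list(profile = cons, ploidy_report = report)
}

#' Signal-to-noise ratio of a track against a truth profile
#'
#' Signal is the squared difference between the track means over bases the
#' truth assigns to states `{1,1}` and `{1,0}`; noise is the average
#' within-truth-segment variance of the track. Missing either state gives
#' `NA`; zero noise with nonzero signal is reported as the cap value.
#'
#' @param track Tibble with `chrom`, `pos`, `value` (one row per data
#'   point; for windows, use midpoints).
#' @param truth Truth profile tibble.
#' @param cap Sentinel for an infinite ratio (default `1e12`).
#' @return The SNR (scalar).
#' @export
snr <- function(track, truth, cap = 1e12) {
  truth <- arrange(as_tibble(truth), .data$chrom, .data$start)
  truth$seg <- seq_len(nrow(truth))
  pts <- track
  pts$seg <- NA_integer_
  for (ch in unique(truth$chrom)) {
    tt <- truth[truth$chrom == ch, ]
    sel <- which(pts$chrom == ch)
    if (length(sel) == 0L) next
    idx <- findInterval(pts$pos[sel], tt$start)
    inside <- idx >= 1L & pts$pos[sel] < tt$end[pmax(idx, 1L)]
    pts$seg[sel[inside]] <- tt$seg[idx[inside]]
  }
  pts <- pts[!is.na(pts$seg) & !is.na(pts$value), ]
  key <- paste(truth$n_A[pts$seg], truth$n_B[pts$seg])
  m11 <- pts$value[key == "1 1"]
  m10 <- pts$value[key == "1 0"]
  if (length(m11) == 0L || length(m10) == 0L) {
    warn("truth profile lacks {1,1} or {1,0} bases; SNR undefined")
    return(NA_real_)
  }
  signal <- (mean(m11) - mean(m10))^2
  vs <- tapply(pts$value, pts$seg, function(v) if (length(v) > 1L) var(v) else NA_real_)
  noise <- mean(vs, na.rm = TRUE)
  if (!is.finite(noise) || noise <= 0) {
    return(if (signal > 0) cap else 0)
  }
  min(signal / noise, cap)
}
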