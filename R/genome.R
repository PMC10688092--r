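# Genome coordinate conventions for the whole package:
# intervals are 0-based half-open [start, end) internally; VCF positions are
# 1-based on input; profile BED output is 0-based half-open.

#' Describe a genome as chromosome lengths and centromere positions
#'
#' @param chrom Character vector of chromosome names.
#' @param length Chromosome lengths in bp.
#' @param centromere Centromere position in bp, splitting each chromosome
#'   into a p and a q arm. Use `0` (or `length`) for acrocentric
#'   chromosomes with a single usable arm.
#' @return A tibble with columns `chrom`, `length`, `centromere`.
#' @export
#' @examples
#' make_genome(c("chr1", "chr2"), c(120e6, 90e6), c(60e6, 40e6))
make_genome <- function(chrom, length, centromere = length / 2) {
  check_that(length(chrom) == length(length), "chrom and length differ in length")
  check_that(all(length > 0), "chromosome lengths must be positive")
  check_that(all(centromere >= 0 & centromere <= length),
             "centromeres must lie within their chromosome")
  tibble(chrom = as.character(chrom), length = as.numeric(length),
         centromere = as.numeric(centromere))
}

#' Tile a genome into non-overlapping windows
#'
#' Windows tile each chromosome without overlap; the terminal window of a
#' chromosome may be shorter than `width`. Each window is assigned to the p
#' or q arm by its midpoint relative to the centromere.
#'
#' @param genome A genome tibble from [make_genome()].
#' @param width Window width in bp (default 1 Mb).
#' @param gc,mappability Optional per-window covariate vectors in `[0, 1]`,
#'   recycled checks applied; defaults are flat (0.5 and 1).
#' @return A tibble with `window_id`, `chrom`, `start`, `end`, `arm`, `gc`,
#'   `mappability`.
#' @export
tile_windows <- function(genome, width = 1e6, gc = NULL, mappability = NULL) {
  win <- purrr::pmap(list(genome$chrom, genome$length, genome$centromere),
                     function(chrom, len, cen) {
    starts <- seq(0, len - 1, by = width)
    ends <- pmin(starts + width, len)
    mid <- (starts + ends) / 2
    tibble(chrom = chrom, start = starts, end = ends,
           arm = if_else(mid < cen, "p", "q"))
  }) |> list_rbind()
  n <- nrow(win)
  win$gc <- check_covariate(gc %||% rep(0.5, n), n, "gc")
  win$mappability <- check_covariate(mappability %||% rep(1, n), n, "mappability")
  win$window_id <- seq_len(n)
  select(win, "window_id", "chrom", "start", "end", "arm", "gc", "mappability")
}

check_covariate <- function(x, n, name) {
  check_that(length(x) == n, paste0(name, " must have one value per window"))
  check_that(all(x >= 0 & x <= 1), paste0(name, " must lie in [0, 1]"))
  as.numeric(x)
}

#' Read genome track files into windows
#'
#' Reads plain TSV tracks (chromosome lengths, centromeres, and optional
#' per-window GC and mappability) and returns the tiled window table. Track
#' files carry a header line; GC/mappability files must have columns
#' `chrom`, `start`, `end`, `value` on the same tiling as `width`.
#'
#' @param chrom_lengths Path to a TSV with columns `chrom`, `length`.
#' @param centromeres Path to a TSV with columns `chrom`, `centromere`
#'   (optional; defaults to the chromosome midpoint).
#' @param gc,mappability Optional per-window track TSV paths.
#' @param width Window width in bp.
#' @return A list with elements `genome` and `windows`.
#' @export
read_genome_tracks <- function(chrom_lengths, centromeres = NULL,
                               gc = NULL, mappability = NULL, width = 1e6) {
  cl <- readr::read_tsv(chrom_lengths, show_col_types = FALSE)
  check_that(all(c("chrom", "length") %in% names(cl)),
             "chrom_lengths TSV needs columns chrom, length")
  cen <- cl$length / 2
  if (!is.null(centromeres)) {
    ce <- readr::read_tsv(centromeres, show_col_types = FALSE)
    check_that(all(c("chrom", "centromere") %in% names(ce)),
               "centromeres TSV needs columns chrom, centromere")
    cen <- ce$centromere[match(cl$chrom, ce$chrom)]
    check_that(!anyNA(cen), "centromere missing for some chromosome")
  }
  genome <- make_genome(cl$chrom, cl$length, cen)
  windows <- tile_windows(genome, width = width)
  for (trk in list(list(path = gc, col = "gc"),
                   list(path = mappability, col = "mappability"))) {
    if (is.null(trk$path)) next
    tb <- readr::read_tsv(trk$path, show_col_types = FALSE)
    check_that(all(c("chrom", "start", "end", "value") %in% names(tb)),
               "track TSV needs columns chrom, start, end, value")
    key_w <- paste(windows$chrom, windows$start)
    key_t <- paste(tb$chrom, tb$start)
    idx <- match(key_w, key_t)
    check_that(!anyNA(idx), paste0(trk$col, " track does not cover all windows"))
    windows[[trk$col]] <- check_covariate(tb$value[idx], nrow(windows), trk$col)
  }
  list(genome = genome, windows = windows)
}

# Sum of base-pair overlap of a set of intervals with each window, per
# chromosome, assuming windows are sorted and non-overlapping. Returns a
# vector aligned with rows of `windows`.
overlap_bp_by_window <- function(intervals, windows) {
  out <- numeric(nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    ws <- windows$start[wi]
    we <- windows$end[wi]
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0L) next
    # window index range touched by each interval
    lo <- findInterval(iv$start, ws)           # window containing start
    hi <- findInterval(pmax(iv$end - 1, iv$start), ws)
    lo <- pmax(lo, 1L)
    nwin <- hi - lo + 1L
    idx <- sequence(nwin, from = lo)           # expanded window indices
    ivx <- rep.int(seq_len(nrow(iv)), nwin)
    ov <- overlap_len(iv$start[ivx], iv$end[ivx], ws[idx], we[idx])
    acc <- rowsum(ov, idx)
    out[wi[as.integer(rownames(acc))]] <- out[wi[as.integer(rownames(acc))]] + acc[, 1L]
  }
  out
}
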