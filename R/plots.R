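# ggplot2 views of the de-noised tracks, the fitted profile, and the
# purity/ploidy MSE surface.

#' Plot the de-noised RDR and BAF tracks
#'
#' Windows and BAF points along the genome, optionally coloured by the
#' fitted total copy number of the overlapping profile segment.
#'
#' @param rdr RDR window tibble with `corrected_r`.
#' @param baf BAF point tibble.
#' @param profile Optional profile tibble.
#' @return A ggplot object (two panels: RDR and BAF).
#' @export
plot_cn_tracks <- function(rdr, baf, profile = NULL) {
  rp <- tibble(chrom = rdr$chrom, pos = (rdr$start + rdr$end) / 2,
               value = rdr$corrected_r, track = "RDR")
  bp <- tibble(chrom = baf$chrom, pos = baf$pos, b = baf$b,
               value = baf$b, track = "BAF")
  dat <- bind_rows(rp, bp)
  dat$total <- NA_real_
  if (!is.null(profile)) {
    for (ch in unique(profile$chrom)) {
      pr <- arrange(profile[profile$chrom == ch, ], .data$start)
      sel <- which(dat$chrom == ch)
      idx <- findInterval(dat$pos[sel], pr$start)
      inside <- idx >= 1L & dat$pos[sel] < pr$end[pmax(idx, 1L)]
      dat$total[sel[inside]] <- pr$n_A[idx[inside]] + pr$n_B[idx[inside]]
    }
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos / 1e6, y = .data$value))
  p <- if (is.null(profile)) {
    p + ggplot2::geom_point(size = 0.4, alpha = 0.6)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data$total)),
                            size = 0.4, alpha = 0.8) +
      ggplot2::labs(colour = "total CN")
  }
  p +
    ggplot2::facet_grid(track ~ chrom, scales = "free", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a copy-number fit
#'
#' `type = "grid"` draws the purity/ploidy MSE surface with the selected
#' solution; `type = "profile"` draws per-segment allele-specific states
#' along the genome.
#'
#' @param object A `cnv_fit`.
#' @param type `"grid"` or `"profile"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cnv_fit <- function(object, type = c("grid", "profile"), ...) {
  type <- match.arg(type)
  if (type == "grid") {
    g <- object$grid
    check_that(!is.null(g), "fit carries no MSE grid")
    return(
      ggplot2::ggplot(g, ggplot2::aes(x = .data$psi, y = .data$phi,
                                      fill = log10(.data$mse))) +
        ggplot2::geom_raster() +
        ggplot2::annotate("point", x = object$psi, y = object$phi,
                          colour = "red", shape = 4, size = 3) +
        ggplot2::scale_fill_viridis_c() +
        ggplot2::labs(x = "ploidy", y = "purity",
                      fill = "log10 MSE") +
        ggplot2::theme_minimal()
    )
  }
  segs <- object$segments[!is.na(object$segments$n_A), ]
  long <- bind_rows(
    tibble(chrom = segs$chrom, start = segs$start, end = segs$end,
           allele = "major", n = segs$n_A),
    tibble(chrom = segs$chrom, start = segs$start, end = segs$end,
           allele = "minor", n = segs$n_B)
  )
  ggplot2::ggplot(long) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$n, yend = .data$n, colour = .data$allele),
      linewidth = 1.5) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "copy number") +
    ggplot2::theme_minimal()
}
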