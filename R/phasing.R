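# Haplotype phasing and well-count BAF. SNPs are partitioned into blocks,
# each block's SNPs are assigned to the two haplotypes from the sign of the
# first singular vector of the SNP-SNP similarity matrix, and a de-noised
# B-allele frequency is computed per haplotype group from counts of wells
# rather than counts of reads.

#' Partition SNPs into phasable haplotype blocks
#'
#' Blocks are built in four steps: (1) contiguous runs where the gap from one
#' SNP to the next is at most `max_gap`; (2) runs of more than `max_snps`
#' SNPs are subdivided into contiguous near-equal chunks of at most
#' `max_snps`; (3) each chunk is split into the connected components of the
#' graph whose edges join SNPs sharing at least one covering well; (4)
#' singleton blocks are removed.
#'
#' @param snps Retained SNP tibble (position-sorted per chromosome).
#' @param genotypes Long genotype tibble from [build_well_genotypes()].
#' @param max_gap Maximum inter-SNP gap within a block (default 500 kb).
#' @param max_snps Maximum SNPs per block (default 100).
#' @return Tibble `block_id`, `snp_id`, `chrom`, `pos`, one row per SNP kept
#'   in a block.
#' @export
build_blocks <- function(snps, genotypes, max_gap = 5e5, max_snps = 100) {
  snps <- mutate(as_tibble(snps), snp_id = row_number())
  snps <- arrange(snps, .data$chrom, .data$pos)
  # step 1: gap runs per chromosome
  snps <- snps |>
    group_by(.data$chrom) |>
    mutate(run = cumsum(c(TRUE, diff(.data$pos) > max_gap))) |>
    ungroup()
  wells_by_snp <- split(genotypes$well_id, genotypes$snp_id)
  blocks <- list()
  bid <- 0L
  for (key in split(seq_len(nrow(snps)), paste(snps$chrom, snps$run))) {
    n <- length(key)
    # step 2: near-equal contiguous chunks of <= max_snps
    k <- ceiling(n / max_snps)
    sizes <- rep(n %/% k, k)
    if (n %% k > 0L) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
    chunk_of <- rep.int(seq_len(k), sizes)
    for (chunk in split(key, chunk_of)) {
      ids <- snps$snp_id[chunk]
      # step 3: connected components of the shared-well graph
      comp <- shared_well_components(ids, wells_by_snp)
      for (members in split(ids, comp)) {
        if (length(members) < 2L) next   # step 4: drop singletons
        bid <- bid + 1L
        blocks[[bid]] <- tibble(block_id = bid, snp_id = members)
      }
    }
  }
  if (length(blocks) == 0L) {
    return(tibble(block_id = integer(), snp_id = integer(),
                  chrom = character(), pos = numeric()))
  }
  out <- list_rbind(blocks)
  left_join(out, select(snps, "snp_id", "chrom", "pos"), by = "snp_id")
}

# connected components over SNPs sharing >= 1 covering well
shared_well_components <- function(snp_ids, wells_by_snp) {
  wl <- wells_by_snp[as.character(snp_ids)]
  wl[vapply(wl, is.null, TRUE)] <- list(character())
  n <- length(snp_ids)
  if (n == 1L) return(1L)
  # bipartite SNP-well incidence; SNPs are connected through shared wells
  all_wells <- unique(unlist(wl))
  if (length(all_wells) == 0L) return(seq_len(n))
  edges <- tibble(
    snp = rep.int(seq_len(n), lengths(wl)),
    well = n + match(unlist(wl), all_wells)
  )
  g <- igraph::make_empty_graph(n + length(all_wells), directed = FALSE)
  g <- igraph::add_edges(g, rbind(edges$snp, edges$well))
  comp <- igraph::components(g)$membership[seq_len(n)]
  # uncovered SNPs form their own components already (no edges)
  as.integer(comp)
}

#' SNP-SNP similarity matrix of a block
#'
#' `M_ij = sum_k G_ik G_jk / sum_l |G_il| |G_jl|` over wells `k`, where `G`
#' holds +1 (well supports the alternative allele at the SNP), -1 (reference)
#' or 0 (no coverage). Under the exact mono-allelic property `M = h h'` for
#' the haplotype sign vector `h`. Pairs with no co-covering well (zero
#' denominator) are set to 0: they contribute no phasing signal. The
#' diagonal is 1 wherever the SNP has any coverage.
#'
#' @param G Numeric SNP-by-well matrix with entries in `{-1, 0, +1}`.
#' @return Symmetric similarity matrix with entries in `[-1, 1]`.
#' @export
similarity_matrix <- function(G) {
  G <- as.matrix(G)
  check_that(all(G %in% c(-1, 0, 1)), "G entries must be in {-1, 0, +1}")
  num <- tcrossprod(G)
  den <- tcrossprod(abs(G))
  M <- ifelse(den > 0, num / den, 0)
  (M + t(M)) / 2
}

#' Assign SNPs in a block to the two haplotypes
#'
#' `h_i = sgn(h*_i)` where `h*` is the first singular vector (largest
#' singular value) of the similarity matrix. Zero entries map to +1, and the
#' global sign is flipped so the first entry is +1.
#'
#' @param M Similarity matrix from [similarity_matrix()].
#' @return Integer vector of +1/-1 haplotype assignments.
#' @export
assign_haplotypes <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) == 1L) return(1L)
  u1 <- svd(M, nu = 1L, nv = 0L)$u[, 1L]
  h <- sign(u1)
  h[h == 0] <- 1
  if (h[1L] < 0) h <- -h
  as.integer(h)
}

# dense SNP x well matrix for one block
block_genotype_matrix <- function(snp_ids, genotypes) {
  gsub <- genotypes[genotypes$snp_id %in% snp_ids, ]
  wells <- sort(unique(gsub$well_id))
  if (length(wells) == 0L) wells <- "none"
  G <- matrix(0, nrow = length(snp_ids), ncol = length(wells),
              dimnames = list(as.character(snp_ids), wells))
  if (nrow(gsub) > 0L) {
    G[cbind(match(as.character(gsub$snp_id), rownames(G)),
            match(gsub$well_id, wells))] <- gsub$g
  }
  G
}

#' Well-count BAF of a phased block
#'
#' SNPs are grouped by haplotype sign (alternative allele on haplotype A vs
#' B). For each non-empty group,
#' `b = (wells supporting alt, summed over the group's SNPs) /
#'      (wells covering, summed over the group's SNPs)`,
#' positioned at the median genomic coordinate of the group's SNPs and
#' weighted by the number of SNPs in the group.
#'
#' @param block_snps Tibble with `snp_id`, `chrom`, `pos` for one block.
#' @param h Haplotype assignment from [assign_haplotypes()], aligned with
#'   `block_snps` rows.
#' @param genotypes Long genotype tibble.
#' @return Tibble `chrom`, `pos`, `b`, `weight`, `haplotype` with at most
#'   two rows.
#' @export
compute_baf <- function(block_snps, h, genotypes) {
  check_that(length(h) == nrow(block_snps), "h must align with block SNPs")
  gsub <- genotypes[genotypes$snp_id %in% block_snps$snp_id, ]
  counts <- gsub |>
    group_by(.data$snp_id) |>
    summarise(alt_wells = sum(.data$g == 1L), cov_wells = dplyr::n(),
              .groups = "drop")
  dat <- left_join(mutate(block_snps, h = h), counts, by = "snp_id")
  dat$alt_wells[is.na(dat$alt_wells)] <- 0L
  dat$cov_wells[is.na(dat$cov_wells)] <- 0L
  out <- dat |>
    group_by(haplotype = .data$h) |>
    summarise(chrom = first(.data$chrom),
              pos = median(.data$pos),
              alt = sum(.data$alt_wells),
              cov = sum(.data$cov_wells),
              weight = dplyr::n(), .groups = "drop") |>
    filter(.data$cov > 0) |>
    mutate(b = .data$alt / .data$cov)
  select(out, "chrom", "pos", "b", "weight", "haplotype")
}

#' Phase all SNPs and compute the de-noised BAF track
#'
#' Runs block building, per-block similarity/SVD haplotype assignment, and
#' well-count BAF computation over the whole genome.
#'
#' @inheritParams build_blocks
#' @return Tibble `chrom`, `pos`, `b`, `weight`, `block_id`, `haplotype`,
#'   sorted by position, plus per-SNP assignments in
#'   `attr(, "haplotypes")` (`block_id`, `snp_id`, `h`).
#' @export
phase_baf <- function(snps, genotypes, max_gap = 5e5, max_snps = 100) {
  blocks <- build_blocks(snps, genotypes, max_gap = max_gap, max_snps = max_snps)
  pts <- list()
  haps <- list()
  for (b in unique(blocks$block_id)) {
    bl <- blocks[blocks$block_id == b, ]
    G <- block_genotype_matrix(bl$snp_id, genotypes)
    h <- assign_haplotypes(similarity_matrix(G))
    haps[[length(haps) + 1L]] <- tibble(block_id = b, snp_id = bl$snp_id, h = h)
    bp <- compute_baf(bl, h, genotypes)
    if (nrow(bp) > 0L) pts[[length(pts) + 1L]] <- mutate(bp, block_id = b)
  }
  out <- if (length(pts) > 0L) {
    arrange(list_rbind(pts), .data$chrom, .data$pos)
  } else {
    tibble(chrom = character(), pos = numeric(), b = numeric(),
           weight = integer(), haplotype = integer(), block_id = integer())
  }
  attr(out, "haplotypes") <- if (length(haps) > 0L) list_rbind(haps) else
    tibble(block_id = integer(), snp_id = integer(), h = integer())
  out
}
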