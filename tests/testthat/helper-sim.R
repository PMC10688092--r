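# Shared fixtures: small genomes, karyotypes with known truth, a
# mono-allelic block generator, and independent brute-force oracles used to
# check the package's implementations.

test_genome <- function() {
  make_genome(paste0("chr", 1:3), c(200e6, 150e6, 120e6), c(100e6, 60e6, 50e6))
}

small_genome <- function() {
  make_genome(c("chr1", "chr2"), c(80e6, 60e6), c(40e6, 25e6))
}

# four CNAs including LOH; diploid background
test_karyotype <- function() {
  tibble::tribble(
    ~chrom, ~start, ~end, ~n_A, ~n_B,
    "chr1", 20e6, 60e6, 2, 1,
    "chr1", 120e6, 160e6, 1, 0,
    "chr2", 0, 40e6, 3, 1,
    "chr3", 60e6, 90e6, 2, 0
  )
}

# variant without mid-level aliasing states, for spike-in experiments
spike_karyotype <- function() {
  tibble::tribble(
    ~chrom, ~start, ~end, ~n_A, ~n_B,
    "chr1", 20e6, 60e6, 2, 1,
    "chr1", 120e6, 160e6, 1, 0,
    "chr2", 0, 40e6, 2, 2,
    "chr3", 60e6, 90e6, 2, 0
  )
}

# G matrix of one mono-allelic block: every well carries exactly one
# haplotype, SNP entries follow the haplotype sign, with optional label
# flips and dropout
sim_monoallelic_block <- function(n_snp, n_well = 60, cover = 0.6,
                                  flip = 0, dropout = 0) {
  h_true <- sample(c(1L, -1L), n_snp, replace = TRUE)
  h_true[1L] <- 1L
  well_hap <- sample(c(1L, -1L), n_well, replace = TRUE)
  G <- matrix(0L, n_snp, n_well)
  for (k in seq_len(n_well)) {
    cov <- runif(n_snp) < cover
    G[cov, k] <- h_true[cov] * well_hap[k]
  }
  if (flip > 0) {
    fl <- matrix(runif(length(G)) < flip, nrow(G)) & G != 0L
    G[fl] <- -G[fl]
  }
  if (dropout > 0) {
    G[matrix(runif(length(G)) < dropout, nrow(G))] <- 0L
  }
  list(G = G, h = h_true)
}

# independent sort-and-scan interval merge (the RLF oracle)
merge_oracle <- function(start, end, gap) {
  o <- order(start)
  start <- start[o]
  end <- end[o]
  out_s <- start[1L]
  out_e <- end[1L]
  res <- list()
  for (i in seq_along(start)[-1L]) {
    if (start[i] - out_e < gap) {
      out_e <- max(out_e, end[i])
    } else {
      res[[length(res) + 1L]] <- c(out_s, out_e)
      out_s <- start[i]
      out_e <- end[i]
    }
  }
  res[[length(res) + 1L]] <- c(out_s, out_e)
  do.call(rbind, res)
}

# brute-force per-base interval depth over a window
per_base_depth_oracle <- function(intervals, wstart, wend) {
  bases <- seq(wstart, wend - 1L)
  counts <- vapply(bases, function(b) {
    sum(intervals$start <= b & intervals$end > b)
  }, 0)
  mean(counts)
}

# brute-force similarity matrix (double loop over the printed formula)
similarity_oracle <- function(G) {
  n <- nrow(G)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- sum(G[i, ] * G[j, ])
      den <- sum(abs(G[i, ]) * abs(G[j, ]))
      M[i, j] <- if (den > 0) num / den else 0
    }
  }
  M
}
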