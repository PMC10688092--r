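# IO contracts: well-read dialects, SNP retention filter, genotype scoring,
# profile round trip.

write_tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("TSV well reads parse, sort, and tolerate empty input", {
  path <- write_tmp_tsv(c("P1W002 chr2 500 650", "P1W001 chr1 1000 1150"))
  tb <- read_well_reads(path, dialect = "tsv")
  expect_equal(tb$well_id, c("P1W001", "P1W002"))
  expect_equal(tb$start, c(1000, 500))
  expect_equal(tb$end, c(1150, 650))

  empty <- write_tmp_tsv(character())
  expect_equal(nrow(read_well_reads(empty, dialect = "tsv")), 0L)

  hdr <- write_tmp_tsv(c("well chrom start end", "P1W001 chr1 10 20"))
  expect_equal(nrow(read_well_reads(hdr, dialect = "tsv")), 1L)
})

test_that("BAM mates merge to a union span and match the TSV dialect", {
  skip_if_not_installed("Rsamtools")
  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr2\tLN:1000000",
    "@RG\tID:P1W002",
    paste("pair1", "99", "chr2", "501", "60", "150M", "=", "901", "550",
          paste(rep("A", 150), collapse = ""), "*", "RG:Z:P1W002", sep = "\t"),
    paste("pair1", "147", "chr2", "901", "60", "150M", "=", "501", "-550",
          paste(rep("A", 150), collapse = ""), "*", "RG:Z:P1W002", sep = "\t")
  )
  sam_path <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, sam_path)
  bam <- Rsamtools::asBam(sam_path, overwrite = TRUE)
  tb <- read_well_reads(bam, dialect = "bam-rg")
  expect_equal(nrow(tb), 1L)
  expect_equal(tb$well_id, "P1W002")
  expect_equal(tb$start, 500)  # 0-based
  expect_equal(tb$end, 1050)

  tsv <- write_tmp_tsv("P1W002 chr2 500 1050")
  expect_equal(as.data.frame(read_well_reads(tsv, dialect = "tsv")),
               as.data.frame(tb))
})

test_that("BAM pairs wider than the fragment scale are split", {
  skip_if_not_installed("Rsamtools")
  sam <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000000",
    "@RG\tID:W1",
    paste("p1", "99", "chr1", "1001", "60", "100M", "=", "500001", "499100",
          paste(rep("A", 100), collapse = ""), "*", "RG:Z:W1", sep = "\t"),
    paste("p1", "147", "chr1", "500001", "60", "100M", "=", "1001", "-499100",
          paste(rep("A", 100), collapse = ""), "*", "RG:Z:W1", sep = "\t")
  )
  sam_path <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, sam_path)
  bam <- Rsamtools::asBam(sam_path, overwrite = TRUE)
  tb <- read_well_reads(bam, dialect = "bam-rg")
  expect_equal(nrow(tb), 2L)   # 499 kb span cannot be one input fragment
  expect_equal(tb$start, c(1000, 500000))
})

test_that("the SNP retention filter applies depth and AF bounds inclusively", {
  snps <- tibble::tibble(
    chrom = "chr1", pos = c(100, 200, 300, 400, 500),
    ref = c("A", "C", "G", "AT", "T"),
    alt = c("C", "T", "A", "A", "G"),
    germline_depth = c(19, 40, 40, 40, 40),
    germline_af = c(0.5, 0.24, 0.25, 0.5, 0.75)
  )
  kept <- filter_het_snps(snps)
  expect_equal(kept$pos, c(300, 500))  # depth 19 dropped, AF .24 dropped,
                                       # AF .25/.75 kept, indel dropped
  # idempotent and order-independent
  expect_equal(filter_het_snps(kept), kept)
  shuffled <- snps[sample.int(nrow(snps)), ]
  expect_equal(filter_het_snps(shuffled), kept)
})

test_that("VCF reading extracts germline allele depths and filters", {
  skip_if_not_installed("vcfR")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tGERMLINE",
    "chr1\t100\t.\tA\tC\t.\t.\t.\tAD\t20,20",   # depth 40, af 0.5 -> keep
    "chr1\t200\t.\tA\tC\t.\t.\t.\tAD\t10,9",    # depth 19 -> drop
    "chr1\t300\t.\tA\tC\t.\t.\t.\tAD\t30,10",   # af 0.25 -> keep
    "chr1\t400\t.\tAT\tA\t.\t.\t.\tAD\t20,20",  # indel -> drop
    "chr1\t500\t.\tG\tA,C\t.\t.\t.\tAD\t20,10"  # multi-allelic -> drop
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  snps <- read_het_snps(path)
  expect_equal(snps$pos, c(100, 300))
  expect_equal(snps$germline_af, c(0.5, 0.25))

  noad <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tGERMLINE",
    "chr1\t100\t.\tA\tC\t.\t.\t.\tGT\t0/1"
  )
  path2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(noad, path2)
  expect_error(read_het_snps(path2), "AD")
})

test_that("well genotypes score mono-allelic support and zero bi-allelic wells", {
  snps <- tibble::tibble(chrom = "chr1", pos = c(100, 200),
                         ref = "A", alt = "C",
                         germline_depth = 40, germline_af = 0.5)
  obs <- tibble::tibble(
    chrom = "chr1",
    pos = c(100, 100, 100, 200),
    well_id = c("w1", "w2", "w3", "w1"),
    ref_count = c(0L, 2L, 1L, 3L),
    alt_count = c(3L, 0L, 2L, 0L)
  )
  g <- build_well_genotypes(snps, obs)
  expect_equal(nrow(g), 3L)            # w3 at pos 100 is bi-allelic: dropped
  expect_equal(g$g[g$well_id == "w1" & g$pos == 100], 1L)
  expect_equal(g$g[g$well_id == "w2"], -1L)
  expect_equal(g$g[g$well_id == "w1" & g$pos == 200], -1L)
})

test_that("profile round trip is lossless and invariants are enforced", {
  profile <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(0, 50e6, 0), end = c(50e6, 100e6, 60e6),
    n_A = c(1, 2, 2), n_B = c(1, 0, 1), clonality = c(1, 1, 0.5)
  )
  path <- withr::local_tempfile(fileext = ".bed")
  write_profile(profile, path, summary = list(purity = 0.8, ploidy = 2.1))
  back <- read_profile(path)
  expect_equal(as.data.frame(back), as.data.frame(profile), ignore_attr = TRUE)
  expect_equal(attr(back, "summary")$purity, 0.8)

  bad <- profile
  bad$n_B[2] <- 3
  expect_error(write_profile(bad, path), "canonical")
  overl <- profile
  overl$start[2] <- 40e6
  expect_error(write_profile(overl, path), "overlap")

  empty <- profile[0, ]
  write_profile(empty, path)
  expect_equal(nrow(read_profile(path)), 0L)
})

test_that("random valid profiles round-trip identically", {
  set.seed(42)
  for (rep in 1:10) {
    k <- sample(1:6, 1)
    bounds <- sort(sample(seq(0, 100e6, by = 1e6), k + 1))
    n_B <- sample(0:2, k, replace = TRUE)
    profile <- tibble::tibble(
      chrom = "chr1", start = bounds[-(k + 1)], end = bounds[-1],
      n_A = n_B + sample(0:3, k, replace = TRUE), n_B = n_B,
      clonality = sample(c(0.5, 1), k, replace = TRUE)
    )
    path <- withr::local_tempfile(fileext = ".bed")
    write_profile(profile, path)
    expect_equal(as.data.frame(read_profile(path)), as.data.frame(profile))
  }
})
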