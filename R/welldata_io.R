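# Readers and writers for the external formats: per-well aligned reads
# (BAM with the well in the read group, or a plain TSV dialect), candidate
# heterozygous SNPs (VCF with germline allele depths), per-well allele
# observations, germline window depths, and the copy-number profile BED.

#' Read per-well aligned read pairs
#'
#' Each record is the genomic span of one read pair in one well. For the
#' `"bam-rg"` dialect the two mates of a pair are merged into their union
#' span; pairs spanning more than `max_pair_span` are split into their two
#' mate intervals, since such a span cannot come from a single input
#' fragment. For the `"tsv"` dialect each row is already one interval:
#' whitespace-separated columns `well`, `chrom`, `start`, `end` (0-based
#' half-open), with an optional header line.
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"bam-rg"`.
#' @param genome Optional genome tibble; if given, intervals are checked to
#'   lie within their chromosome.
#' @param max_pair_span Mate pairs spanning more than this are split (bp).
#' @return A tibble `well_id`, `chrom`, `start`, `end`, sorted by
#'   (well, chrom, start).
#' @export
read_well_reads <- function(path, dialect = c("tsv", "bam-rg"), genome = NULL,
                            max_pair_span = 1e5) {
  dialect <- match.arg(dialect)
  check_that(file.exists(path), paste0("no such file: ", path))
  reads <- switch(dialect,
    "tsv" = read_well_reads_tsv(path),
    "bam-rg" = read_well_reads_bam(path, max_pair_span)
  )
  validate_well_reads(reads, genome)
  arrange(reads, .data$well_id, .data$chrom, .data$start)
}

read_well_reads_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    return(tibble(well_id = character(), chrom = character(),
                  start = numeric(), end = numeric()))
  }
  f1 <- strsplit(trimws(first), "\\s+")[[1L]]
  check_that(length(f1) >= 4L, "well-read TSV needs 4 columns: well chrom start end")
  has_header <- is.na(suppressWarnings(as.numeric(f1[3L])))
  tb <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  tb <- tb[, 1:4]
  names(tb) <- c("well_id", "chrom", "start", "end")
  tb$well_id <- as.character(tb$well_id)
  tb$chrom <- as.character(tb$chrom)
  as_tibble(tb)
}

read_well_reads_bam <- function(path, max_pair_span) {
  check_that(requireNamespace("Rsamtools", quietly = TRUE),
             "reading BAM requires the Rsamtools package")
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "qwidth"), tag = "RG",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  recs <- Rsamtools::scanBam(path, param = param)[[1L]]
  rg <- recs$tag$RG
  qname <- recs$qname
  if (length(qname) == 0L) {
    return(tibble(well_id = character(), chrom = character(),
                  start = numeric(), end = numeric()))
  }
  if (is.null(rg) || anyNA(rg)) {
    bad <- if (is.null(rg)) qname else qname[is.na(rg)]
    abort(paste0("reads without a well read group: ",
                 paste(utils::head(unique(bad), 5L), collapse = ", ")))
  }
  rec <- tibble(
    well_id = as.character(rg),
    qname = qname,
    chrom = as.character(recs$rname),
    start = as.numeric(recs$pos) - 1,          # BAM is 1-based
    end = as.numeric(recs$pos) - 1 + as.numeric(recs$qwidth)
  )
  pair <- rec |>
    group_by(.data$well_id, .data$qname, .data$chrom) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  wide <- pair$end - pair$start > max_pair_span
  if (any(wide)) {
    # keep the individual mate intervals for discordant pairs
    keys <- paste(pair$well_id, pair$qname, pair$chrom)[wide]
    rk <- paste(rec$well_id, rec$qname, rec$chrom)
    split_reads <- rec[rk %in% keys, c("well_id", "chrom", "start", "end")]
    pair <- bind_rows(pair[!wide, ], split_reads)
  }
  select(pair, "well_id", "chrom", "start", "end")
}

validate_well_reads <- function(reads, genome = NULL) {
  check_that(all(reads$start < reads$end), "well reads must have start < end")
  check_that(all(nzchar(reads$well_id)), "well_id must be non-empty")
  if (!is.null(genome) && nrow(reads) > 0L) {
    len <- genome$length[match(reads$chrom, genome$chrom)]
    check_that(!anyNA(len), "read on a chromosome absent from the genome")
    check_that(all(reads$start >= 0 & reads$end <= len),
               "read interval outside its chromosome")
  }
  invisible(reads)
}

#' Filter candidate SNPs to retained heterozygous sites
#'
#' Retains single-nucleotide bi-allelic sites with germline depth of at
#' least `min_depth` reads and a germline alternative-allele fraction inside
#' `af_range` (both bounds inclusive). The filter is idempotent and
#' order-independent; output is position-sorted within each chromosome.
#'
#' @param snps Tibble with `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `germline_depth`, `germline_af`.
#' @param min_depth Minimum germline read depth (default 20).
#' @param af_range Inclusive allele-fraction window (default 0.25--0.75).
#' @return The filtered, sorted tibble.
#' @export
filter_het_snps <- function(snps, min_depth = 20, af_range = c(0.25, 0.75)) {
  snps <- as_tibble(snps)
  keep <- nchar(snps$ref) == 1L & nchar(snps$alt) == 1L &
    snps$ref %in% c("A", "C", "G", "T") & snps$alt %in% c("A", "C", "G", "T") &
    snps$germline_depth >= min_depth &
    snps$germline_af >= af_range[1L] & snps$germline_af <= af_range[2L]
  out <- arrange(snps[keep & !is.na(keep), ], .data$chrom, .data$pos)
  distinct(out, .data$chrom, .data$pos, .keep_all = TRUE)
}

#' Read heterozygous SNP candidates from a VCF
#'
#' Germline allele depths are taken from the `AD` field of the first sample;
#' a VCF without allele depths is a fatal error. Sites are then passed
#' through [filter_het_snps()].
#'
#' @inheritParams filter_het_snps
#' @param path VCF file (plain or bgzipped).
#' @return Tibble of retained sites: `chrom`, `pos`, `ref`, `alt`,
#'   `germline_depth`, `germline_af`.
#' @export
read_het_snps <- function(path, min_depth = 20, af_range = c(0.25, 0.75)) {
  check_that(requireNamespace("vcfR", quietly = TRUE),
             "reading VCF requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- vcf@gt[, 1L]
  if (nrow(vcf@fix) == 0L) {
    return(filter_het_snps(tibble(chrom = character(), pos = numeric(),
                                  ref = character(), alt = character(),
                                  germline_depth = numeric(),
                                  germline_af = numeric()),
                           min_depth, af_range))
  }
  ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                 error = function(e) NULL)
  if (is.null(ad) || all(is.na(ad))) {
    abort("VCF has no AD (allele depth) field; germline allele depths are required")
  }
  ad1 <- ad[, 1L]
  parts <- strsplit(ad1, ",", fixed = TRUE)
  ref_d <- vapply(parts, function(p) suppressWarnings(as.numeric(p[1L])), 0)
  alt_d <- vapply(parts, function(p) {
    if (length(p) < 2L) return(NA_real_)
    suppressWarnings(as.numeric(p[2L]))
  }, 0)
  depth <- ref_d + alt_d
  snps <- tibble(
    chrom = vcf@fix[, "CHROM"],
    pos = as.numeric(vcf@fix[, "POS"]),
    ref = vcf@fix[, "REF"],
    alt = vcf@fix[, "ALT"],
    germline_depth = unname(depth),
    germline_af = unname(if_else(depth > 0, alt_d / depth, NA_real_))
  )
  # multi-allelic sites carry a comma in ALT and fail the single-base check
  filter_het_snps(snps, min_depth = min_depth, af_range = af_range)
}

#' Build the SNP-by-well genotype table from per-well allele observations
#'
#' Each retained SNP/well pair is scored `+1` if the well's reads support
#' only the alternative allele, `-1` if only the reference. Wells observing
#' both alleles at a SNP violate the mono-allelic assumption (evidence of
#' two input fragments colliding in one well) and are zeroed, i.e. dropped,
#' for that SNP. Wells with no coverage contribute no row.
#'
#' @param snps Retained SNP tibble (see [filter_het_snps()]).
#' @param allele_obs Tibble `chrom`, `pos`, `well_id`, `ref_count`,
#'   `alt_count` of per-well read support at candidate SNPs.
#' @return Long genotype tibble `snp_id`, `chrom`, `pos`, `well_id`, `g`
#'   with `g` in `{-1, +1}`; `snp_id` indexes rows of `snps`.
#' @export
build_well_genotypes <- function(snps, allele_obs) {
  snps <- mutate(as_tibble(snps), snp_id = row_number())
  obs <- inner_join(as_tibble(allele_obs), select(snps, "snp_id", "chrom", "pos"),
                    by = c("chrom", "pos"))
  obs <- obs |>
    group_by(.data$snp_id, .data$chrom, .data$pos, .data$well_id) |>
    summarise(ref_count = sum(.data$ref_count), alt_count = sum(.data$alt_count),
              .groups = "drop") |>
    filter(.data$ref_count + .data$alt_count > 0) |>
    filter(.data$ref_count == 0 | .data$alt_count == 0) |>   # mono-allelic only
    mutate(g = if_else(.data$alt_count > 0, 1L, -1L))
  arrange(select(obs, "snp_id", "chrom", "pos", "well_id", "g"),
          .data$snp_id, .data$well_id)
}

#' Write / read an allele-specific copy-number profile
#'
#' The profile is a BED-dialect TSV (`chrom`, `start`, `end`, `n_A`, `n_B`,
#' `clonality`; 0-based half-open intervals) with an optional JSON sidecar
#' (`<path>.summary.json`) holding purity, ploidy and the fit MSE.
#' The round trip is lossless. On read, overlapping segments or a segment
#' with `n_B > n_A` are fatal errors.
#'
#' @param profile Profile tibble.
#' @param path Output TSV path.
#' @param summary Optional named list (e.g. `purity`, `ploidy`, `mse`)
#'   written to the sidecar.
#' @return `write_profile` returns `path` invisibly; `read_profile` returns
#'   the profile tibble with the sidecar (if present) in
#'   `attr(, "summary")`.
#' @export
write_profile <- function(profile, path, summary = NULL) {
  profile <- validate_profile(profile)
  readr::write_tsv(profile, path)
  if (!is.null(summary)) {
    jsonlite::write_json(summary, paste0(path, ".summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(chrom = readr::col_character()))
  tb <- validate_profile(tb)
  sidecar <- paste0(path, ".summary.json")
  if (file.exists(sidecar)) {
    attr(tb, "summary") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  tb
}

validate_profile <- function(profile) {
  profile <- as_tibble(profile)
  need <- c("chrom", "start", "end", "n_A", "n_B", "clonality")
  check_that(all(need %in% names(profile)),
             paste0("profile needs columns: ", paste(need, collapse = ", ")))
  profile <- arrange(profile[, need], .data$chrom, .data$start)
  check_that(all(profile$end > profile$start), "profile segments must have start < end")
  check_that(all(profile$n_A >= profile$n_B),
             "profile violates canonical order n_A >= n_B")
  by_chr <- split(profile, profile$chrom)
  for (p in by_chr) {
    if (nrow(p) > 1L) {
      check_that(all(p$start[-1L] >= p$end[-nrow(p)]),
                 "profile has overlapping segments")
    }
  }
  profile
}

#' Read germline read counts per window
#'
#' Germline depths are supplied precomputed: a TSV with columns `chrom`,
#' `start`, `end`, `reads` on the same tiling as `windows`.
#'
#' @param path TSV path.
#' @param windows Window tibble from [tile_windows()].
#' @return `windows` with a `germline_reads` column.
#' @export
read_germline_depths <- function(path, windows) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  check_that(all(c("chrom", "start", "end", "reads") %in% names(tb)),
             "germline depth TSV needs columns chrom, start, end, reads")
  idx <- match(paste(windows$chrom, windows$start), paste(tb$chrom, tb$start))
  check_that(!anyNA(idx), "germline depths do not cover all windows")
  mutate(windows, germline_reads = as.numeric(tb$reads[idx]))
}
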