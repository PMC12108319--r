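# Genotype container, PLINK binary I/O, allele frequencies and SNP QC.

MISSING_DOSAGE <- NA_real_

#' Construct a genotype panel
#'
#' A `genotype_panel` holds a dosage matrix (individuals x SNPs, entries
#' 0/1/2 counting copies of allele A1, `NA` = missing) together with
#' individual and SNP metadata. Allele frequencies are attached by
#' [compute_freqs()].
#'
#' @param dosages numeric matrix, individuals in rows, SNPs in columns;
#'   entries in `{0, 1, 2, NA}` (fractional dosages are allowed until
#'   [round_dosages()] is applied).
#' @param fam data frame with columns `fid`, `iid` (one row per individual).
#' @param snps data frame with columns `chrom`, `snp_id`, `pos`, `a1`, `a2`.
#' @param validate check invariants (unique SNP ids, dimensions, codes).
#'
#' @return An object of class `genotype_panel` with elements `dosages`,
#'   `fam`, `snps`, and (after [compute_freqs()]) `freq_a` and `maf`.
#' @export
genotype_panel <- function(dosages, fam, snps, validate = TRUE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  fam <- as.data.frame(fam, stringsAsFactors = FALSE)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (validate) {
    if (nrow(fam) != nrow(dosages))
      stop("fam has ", nrow(fam), " rows but dosage matrix has ",
           nrow(dosages), " rows")
    if (nrow(snps) != ncol(dosages))
      stop("snps has ", nrow(snps), " rows but dosage matrix has ",
           ncol(dosages), " columns")
    if (anyDuplicated(snps$snp_id))
      stop("snp_id must be unique within a panel")
    if (any(snps$pos < 0))
      stop("SNP positions must be non-negative")
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2)
      stop("dosages must lie in [0, 2] or be NA")
  }
  structure(
    list(dosages = dosages, fam = fam, snps = snps,
         freq_a = NULL, maf = NULL),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "SNPs\n")
  n_miss <- sum(is.na(x$dosages))
  cat("  missing calls:", n_miss,
      sprintf("(%.3f%%)", 100 * n_miss / length(x$dosages)), "\n")
  if (!is.null(x$maf))
    cat("  MAF range:", sprintf("%.4f - %.4f",
        min(x$maf, na.rm = TRUE), max(x$maf, na.rm = TRUE)), "\n")
  invisible(x)
}

#' Number of individuals / SNPs in a panel
#' @param panel a [genotype_panel()].
#' @return integer count.
#' @export
n_individuals <- function(panel) nrow(panel$dosages)

#' @rdname n_individuals
#' @export
n_snps <- function(panel) ncol(panel$dosages)

#' Subset a genotype panel
#'
#' @param panel a [genotype_panel()].
#' @param individuals optional integer/logical index of individuals to keep.
#' @param snps optional integer/logical index of SNPs to keep.
#' @return a `genotype_panel` with frequencies carried over (per-SNP
#'   quantities are subset, not recomputed, so a reference allele-frequency
#'   set can be reused across individual subsets).
#' @export
panel_subset <- function(panel, individuals = NULL, snps = NULL) {
  if (is.null(individuals)) individuals <- seq_len(n_individuals(panel))
  if (is.null(snps)) snps <- seq_len(n_snps(panel))
  out <- genotype_panel(
    panel$dosages[individuals, snps, drop = FALSE],
    panel$fam[individuals, , drop = FALSE],
    panel$snps[snps, , drop = FALSE],
    validate = FALSE
  )
  if (!is.null(panel$freq_a)) {
    out$freq_a <- panel$freq_a[snps]
    out$maf <- panel$maf[snps]
  }
  out
}

# 2-bit PLINK codes (within-byte, low bits first):
# 00 = hom A1 (dosage 2), 01 = missing, 10 = het, 11 = hom A2 (dosage 0)
.plink_decode_lut <- local({
  code2dose <- c(2, NA, 1, 0)
  lut <- matrix(NA_real_, nrow = 256, ncol = 4)
  for (b in 0:255)
    for (k in 0:3)
      lut[b + 1, k + 1] <- code2dose[bitwAnd(bitwShiftR(b, 2L * k), 3L) + 1]
  lut
})

#' Read a PLINK binary genotype trio
#'
#' Reads `prefix.bed` / `prefix.bim` / `prefix.fam` (PLINK 1 binary format,
#' SNP-major). The counted allele is A1 of the `.bim` file, so a dosage of
#' 2 means homozygous A1. Individual and SNP order are preserved.
#'
#' @param prefix path stem of the trio (without extension).
#' @return a [genotype_panel()] (frequencies not yet computed).
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("missing PLINK file: ", f)

  fam_df <- read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                       colClasses = "character")
  if (ncol(fam_df) < 2) stop("malformed .fam file: ", fam)
  fam_df <- data.frame(fid = fam_df[[1]], iid = fam_df[[2]],
                       stringsAsFactors = FALSE)

  bim_df <- read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                       colClasses = c("character", "character", "numeric",
                                      "integer", "character", "character"))
  if (ncol(bim_df) != 6) stop("malformed .bim file: ", bim)
  snps <- data.frame(chrom = bim_df[[1]], snp_id = bim_df[[2]],
                     pos = bim_df[[4]], a1 = bim_df[[5]], a2 = bim_df[[6]],
                     stringsAsFactors = FALSE)

  n <- nrow(fam_df)
  m <- nrow(snps)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes): ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported: ", bed)
  bytes_per_snp <- ceiling(n / 4)
  expected <- 3L + bytes_per_snp * m
  if (length(raw) != expected)
    stop(".bed file length (", length(raw), ") inconsistent with ",
         n, " individuals x ", m, " SNPs (expected ", expected, " bytes)")

  body <- as.integer(raw[-(1:3)])
  # slot-major unravel: sample slots (4 per byte) vary fastest within a SNP
  slots <- t(.plink_decode_lut[body + 1L, , drop = FALSE])
  dos <- matrix(as.vector(slots), nrow = 4L * bytes_per_snp, ncol = m)
  dos <- dos[seq_len(n), , drop = FALSE]
  colnames(dos) <- snps$snp_id
  genotype_panel(dos, fam_df, snps, validate = FALSE)
}

#' Write a genotype panel as a PLINK binary trio
#'
#' Inverse of [read_plink()]. Dosages must be integer codes 0/1/2 or `NA`.
#'
#' @param panel a [genotype_panel()].
#' @param prefix output path stem.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  d <- panel$dosages
  if (any(!is.na(d) & d != round(d)))
    stop("write_plink requires integer dosage codes; see round_dosages()")
  n <- nrow(d)
  m <- ncol(d)
  fam <- panel$fam
  write.table(
    data.frame(fam$fid, fam$iid, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = " "
  )
  s <- panel$snps
  write.table(
    data.frame(s$chrom, s$snp_id, 0, s$pos, s$a1, s$a2),
    paste0(prefix, ".bim"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  # dosage -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
  code <- matrix(3L, nrow = n, ncol = m)
  code[!is.na(d) & d == 2] <- 0L
  code[!is.na(d) & d == 1] <- 2L
  code[is.na(d)] <- 1L
  bytes_per_snp <- ceiling(n / 4)
  padded <- matrix(0L, nrow = 4L * bytes_per_snp, ncol = m)
  padded[seq_len(n), ] <- code
  k <- rep(seq_len(bytes_per_snp), each = 4L)
  shifts <- rep(c(0L, 2L, 4L, 6L), times = bytes_per_snp)
  shifted <- padded * as.integer(2L^shifts)
  bytes <- rowsum(shifted, group = k, reorder = TRUE)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' Round fractional dosages to integer genotype codes
#'
#' Imputed genotypes are often fractional; downstream modelling uses
#' integer codes. Each non-missing entry is replaced by the nearest
#' integer in `{0, 1, 2}`; ties at .5 round half away from zero
#' (0.5 -> 1, 1.5 -> 2), a deterministic rule independent of the
#' banker's rounding used by [round()].
#'
#' @param panel a [genotype_panel()] whose entries lie in `[0, 2]` or `NA`.
#' @return the panel with integer dosage codes.
#' @export
round_dosages <- function(panel) {
  d <- panel$dosages
  rng <- range(d, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages outside [0, 2] cannot be rounded to genotype codes")
  panel$dosages[] <- floor(d + 0.5)
  panel
}

#' Compute allele frequencies and MAF
#'
#' The counted-allele frequency is estimated from the observed (non-missing)
#' calls: `freq_a = sum(dosages) / (2 * n_called)`. MAF is the folded
#' frequency `min(freq_a, 1 - freq_a)`. SNPs with no observed calls get
#' `NA` frequencies and are flagged with a warning.
#'
#' @param panel a [genotype_panel()].
#' @return the panel with `freq_a` and `maf` filled in.
#' @export
compute_freqs <- function(panel) {
  d <- panel$dosages
  n_called <- colSums(!is.na(d))
  freq <- colSums(d, na.rm = TRUE) / (2 * n_called)
  freq[n_called == 0] <- NA_real_
  if (any(n_called == 0))
    warning(sum(n_called == 0), " SNP(s) have no observed calls; ",
            "frequency undefined")
  panel$freq_a <- unname(freq)
  panel$maf <- pmin(panel$freq_a, 1 - panel$freq_a)
  panel
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test of Hardy-Weinberg proportions (the SNP-HWE test
#' used by PLINK): conditional on the observed allele counts, heterozygote
#' counts are enumerated and the p-value is the total probability of
#' configurations no more probable than the observed one (mid-p off).
#'
#' @param n_hom1 count of individuals homozygous for the first allele.
#' @param n_het count of heterozygotes.
#' @param n_hom2 count of individuals homozygous for the second allele.
#' @return the exact p-value; monomorphic sites return 1.
#' @export
hwe_test <- function(n_hom1, n_het, n_hom2) {
  counts <- c(n_hom1, n_het, n_hom2)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("total genotype count must be positive")
  n_a <- 2 * n_hom1 + n_het
  n_b <- 2 * n_hom2 + n_het
  n_rare <- min(n_a, n_b)
  if (n_rare == 0) return(1)

  h <- seq.int(n_rare %% 2, n_rare, by = 2)
  # P(het = h | allele counts), multinomial over genotypes conditional on
  # the margin: 2^h * n! / (n_AA! h! n_aa!) * n_a! n_b! / (2n)!
  logp <- h * log(2) + lfactorial(n) -
    lfactorial((n_rare - h) / 2) - lfactorial(h) -
    lfactorial(n - (n_rare + h) / 2) +
    lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  p_all <- exp(logp - max(logp))
  p_all <- p_all / sum(p_all)
  p_obs <- p_all[match(n_het, h)]
  if (is.na(p_obs))
    stop("heterozygote count incompatible with allele-count parity")
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-12)]))
}

#' SNP quality control
#'
#' Filters SNPs sequentially in three passes, attributing each removed SNP
#' to the first filter it fails: (1) missing call rate above
#' `max_missing_rate`; (2) exact Hardy-Weinberg test p-value below
#' `hwe_p_threshold`; (3) MAF below `min_maf`.
#'
#' @param panel a [genotype_panel()] with frequencies computed
#'   (see [compute_freqs()]).
#' @param max_missing_rate maximum per-SNP missing call rate (default 0.05).
#' @param hwe_p_threshold HWE exact-test p-value below which a SNP is
#'   removed (default `1e-5`).
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @return a list with `panel` (the filtered panel, frequencies carried
#'   over) and `report` (a `qc_report` with per-filter removal counts).
#' @export
apply_qc <- function(panel, max_missing_rate = 0.05,
                     hwe_p_threshold = 1e-5, min_maf = 0.01) {
  stopifnot(max_missing_rate > 0, max_missing_rate < 1,
            hwe_p_threshold > 0, hwe_p_threshold < 1,
            min_maf > 0, min_maf < 1)
  if (is.null(panel$freq_a))
    panel <- compute_freqs(panel)
  d <- panel$dosages
  m <- ncol(d)

  miss_rate <- colMeans(is.na(d))
  fail_miss <- miss_rate > max_missing_rate

  fail_hwe <- rep(FALSE, m)
  candidates <- which(!fail_miss)
  for (j in candidates) {
    x <- d[, j]
    n2 <- sum(x == 2, na.rm = TRUE)
    n1 <- sum(x == 1, na.rm = TRUE)
    n0 <- sum(x == 0, na.rm = TRUE)
    if (n2 + n1 + n0 == 0) next
    fail_hwe[j] <- hwe_test(n2, n1, n0) < hwe_p_threshold
  }

  fail_maf <- !fail_miss & !fail_hwe &
    (is.na(panel$maf) | panel$maf < min_maf)

  keep <- !(fail_miss | fail_hwe | fail_maf)
  if (!any(keep))
    stop("no SNPs passed quality control")

  report <- structure(
    list(n_input = m,
         n_removed_missing = sum(fail_miss),
         n_removed_hwe = sum(fail_hwe & !fail_miss),
         n_removed_maf = sum(fail_maf),
         n_retained = sum(keep),
         params = list(max_missing_rate = max_missing_rate,
                       hwe_p_threshold = hwe_p_threshold,
                       min_maf = min_maf)),
    class = "qc_report"
  )
  list(panel = panel_subset(panel, snps = which(keep)), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP quality control:\n")
  cat("  input SNPs:          ", x$n_input, "\n")
  cat("  removed, missingness:", x$n_removed_missing,
      sprintf("(rate > %g)", x$params$max_missing_rate), "\n")
  cat("  removed, HWE:        ", x$n_removed_hwe,
      sprintf("(p < %g)", x$params$hwe_p_threshold), "\n")
  cat("  removed, MAF:        ", x$n_removed_maf,
      sprintf("(MAF < %g)", x$params$min_maf), "\n")
  cat("  retained:            ", x$n_retained, "\n")
  invisible(x)
}

#' Read a whitespace-delimited phenotype file
#'
#' Expected columns: family ID, individual ID, value. A header line is
#' detected (third field non-numeric) and skipped. Missing values are
#' coded `NA`.
#'
#' @param path file path.
#' @return data frame with columns `fid`, `iid`, `value`.
#' @export
read_phenotypes <- function(path) {
  first <- scan(path, what = character(), nlines = 1, quiet = TRUE)
  if (length(first) < 3)
    stop("phenotype file must have at least 3 columns: FID IID VALUE")
  has_header <- is.na(suppressWarnings(as.numeric(first[3]))) &&
    first[3] != "NA"
  df <- read.table(path, header = has_header, stringsAsFactors = FALSE,
                   na.strings = "NA",
                   colClasses = c("character", "character", "numeric",
                                  rep("NULL", length(first) - 3)))
  names(df) <- c("fid", "iid", "value")
  df
}

#' Write phenotypes in FID IID VALUE form
#' @param df data frame with columns `fid`, `iid`, `value`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(df, path) {
  write.table(df[, c("fid", "iid", "value")], path, quote = FALSE,
              row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(path)
}
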