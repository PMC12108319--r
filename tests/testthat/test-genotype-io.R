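# PLINK I/O, dosage rounding, allele frequencies, HWE and QC.

test_that("PLINK trio round-trips dosages, IDs and order exactly", {
  set.seed(42)
  for (n in c(2, 3, 13)) {  # exercise all byte-padding remainders
    m <- 7
    d <- matrix(sample(c(0, 1, 2, NA), n * m, replace = TRUE,
                       prob = c(.3, .3, .3, .1)), n, m)
    pan <- suppressWarnings(toy_panel(d))  # all-NA columns may occur
    prefix <- file.path(withr::local_tempdir(), "trio")
    write_plink(pan, prefix)
    back <- read_plink(prefix)
    expect_identical(unname(back$dosages), unname(pan$dosages))
    expect_identical(back$fam$iid, pan$fam$iid)
    expect_identical(back$snps$snp_id, pan$snps$snp_id)
  }
})

test_that("bed decoding matches an independent bit-level decoder", {
  set.seed(7)
  d <- matrix(sample(c(0, 1, 2, NA), 3 * 5, replace = TRUE), 3, 5)
  pan <- toy_panel(d)
  prefix <- file.path(withr::local_tempdir(), "trio")
  write_plink(pan, prefix)
  oracle <- oracle_read_bed(paste0(prefix, ".bed"), 3, 5)
  got <- read_plink(prefix)$dosages
  expect_identical(unname(got), oracle)
})

test_that("malformed .bed files are rejected", {
  dir <- withr::local_tempdir()
  pan <- toy_panel(matrix(c(0, 1, 2, 1), 2, 2))
  prefix <- file.path(dir, "trio")
  write_plink(pan, prefix)

  bad <- file.path(dir, "bad")
  file.copy(paste0(prefix, ".bim"), paste0(bad, ".bim"))
  file.copy(paste0(prefix, ".fam"), paste0(bad, ".fam"))
  raw <- readBin(paste0(prefix, ".bed"), "raw", 100)
  raw[1] <- as.raw(0x00)
  writeBin(raw, paste0(bad, ".bed"))
  expect_error(read_plink(bad), "magic")

  trunc <- file.path(dir, "trunc")
  file.copy(paste0(prefix, ".bim"), paste0(trunc, ".bim"))
  file.copy(paste0(prefix, ".fam"), paste0(trunc, ".fam"))
  raw <- readBin(paste0(prefix, ".bed"), "raw", 100)
  writeBin(raw[-length(raw)], paste0(trunc, ".bed"))
  expect_error(read_plink(trunc), "inconsistent")
})

test_that("dosage rounding uses nearest integer, ties away from zero", {
  pan <- toy_panel(matrix(c(0.4, 1.6, 0.5, 1.5, 2, NA), 2, 3))
  out <- round_dosages(pan)
  expect_identical(unname(out$dosages),
                   matrix(c(0, 2, 1, 2, 2, NA), 2, 3))

  set.seed(1)
  frac <- matrix(runif(200, 0, 2), 10, 20)
  rounded <- round_dosages(toy_panel(frac))$dosages
  expect_true(all(rounded %in% c(0, 1, 2)))
  expect_lte(max(abs(rounded - frac)), 0.5)

  expect_error(round_dosages(toy_panel(matrix(c(2.2, 1), 2, 1))),
               "outside")
})

test_that("allele frequencies use observed calls only", {
  pan <- compute_freqs(toy_panel(matrix(c(0, 1, 2), 3, 1)))
  expect_equal(pan$freq_a, 0.5)
  expect_equal(pan$maf, 0.5)

  pan <- compute_freqs(toy_panel(matrix(c(2, 2, 2), 3, 1)))
  expect_equal(pan$maf, 0)

  pan <- compute_freqs(toy_panel(matrix(c(0, 0, 1, NA), 4, 1)))
  expect_equal(pan$freq_a, 1 / 6)
  expect_equal(pan$maf, 1 / 6)

  pan_na <- suppressWarnings(toy_panel(matrix(NA_real_, 3, 1)))
  expect_warning(compute_freqs(pan_na), "no observed calls")
})

test_that("exact HWE test matches enumeration and handles edge cases", {
  # modal heterozygote configuration: every configuration is <= it
  expect_equal(hwe_test(25, 50, 25), 1.0)
  # complete heterozygote deficit is extreme
  expect_lt(hwe_test(50, 0, 50), 1e-5)
  # monomorphic
  expect_equal(hwe_test(10, 0, 0), 1)

  set.seed(11)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    n1 <- sample(0:n, 1)
    n2 <- sample(0:(n - n1), 1)
    counts <- c(n1, n2, n - n1 - n2)
    expect_equal(do.call(hwe_test, as.list(counts)),
                 do.call(oracle_hwe, as.list(counts)),
                 tolerance = 1e-10,
                 info = paste(counts, collapse = ","))
  }
})

test_that("QC filters sequentially and attributes each SNP once", {
  n <- 60
  set.seed(3)
  clean1 <- rbinom(n, 2, 0.3)
  clean2 <- rbinom(n, 2, 0.4)
  high_missing <- c(rep(NA_real_, 6), rbinom(n - 6, 2, 0.3))  # 10% missing
  hwe_violation <- rep(1, n)                 # all heterozygous
  rare <- c(1, rep(0, n - 1))                # MAF 1/120 < 0.01
  pan <- compute_freqs(toy_panel(cbind(high_missing, hwe_violation,
                                       rare, clean1, clean2)))
  res <- apply_qc(pan)
  expect_equal(res$report$n_input, 5)
  expect_equal(res$report$n_removed_missing, 1)
  expect_equal(res$report$n_removed_hwe, 1)
  expect_equal(res$report$n_removed_maf, 1)
  expect_equal(res$report$n_retained, 2)
  expect_equal(res$panel$snps$snp_id, c("s4", "s5"))
  expect_equal(
    res$report$n_retained,
    res$report$n_input - res$report$n_removed_missing -
      res$report$n_removed_hwe - res$report$n_removed_maf)

  # clean panel passes unchanged; QC is idempotent
  again <- apply_qc(res$panel)
  expect_equal(again$report$n_retained, 2)
  expect_equal(again$report$n_removed_missing +
                 again$report$n_removed_hwe +
                 again$report$n_removed_maf, 0)
  expect_identical(again$panel$dosages, res$panel$dosages)

  # retained SNPs respect the MAF bound
  expect_true(all(res$panel$maf >= 0.01 & res$panel$maf <= 0.5))

  expect_error(apply_qc(compute_freqs(toy_panel(matrix(rep(1, 40), 20, 2)))),
               "no SNPs passed")
})

test_that("phenotype files round-trip with and without header", {
  dir <- withr::local_tempdir()
  df <- data.frame(fid = c("F1", "F2"), iid = c("I1", "I2"),
                   value = c(1.25, -0.5))
  p <- file.path(dir, "ph.txt")
  write_phenotypes(df, p)
  back <- read_phenotypes(p)
  expect_equal(back$value, df$value)
  expect_equal(back$iid, df$iid)

  writeLines(c("FID IID VALUE", "F1 I1 1.25", "F2 I2 NA"),
             file.path(dir, "ph2.txt"))
  back2 <- read_phenotypes(file.path(dir, "ph2.txt"))
  expect_equal(back2$value, c(1.25, NA))
})
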