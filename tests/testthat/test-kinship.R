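# Selection-adjusted GRM construction, MAF binning, serialization.

test_that("single-SNP GRM is independent of S (algebraic cancellation)", {
  pan <- toy_panel(matrix(c(0, 1), 2, 1), freq = 0.25)
  expected <- matrix(c(2, -2, -2, 2) / 3, 2, 2)
  for (s in c(-2, -1.5, -1, -0.5, 0, 0.5, 1)) {
    g <- build_grm(pan, s)
    expect_equal(g$values, expected, tolerance = 1e-12,
                 info = paste("S =", s))
  }
})

test_that("GRM equals the triple-loop oracle on random panels", {
  set.seed(5)
  for (rep in 1:4) {
    pan <- generate_panel(10, 20, seed = rep)
    for (s in c(-2, -1, -0.5, 0, 1)) {
      g <- build_grm(pan, s)
      o <- oracle_grm(pan$dosages, pan$freq_a, s)
      expect_lt(max(abs(g$values - o)), 1e-12)
    }
  }
  # with missing calls mean-imputed
  pan <- generate_panel(8, 15, seed = 9)
  pan$dosages[cbind(c(1, 3, 5), c(2, 7, 11))] <- NA
  g <- build_grm(pan, -1)
  expect_lt(max(abs(g$values - oracle_grm(pan$dosages, pan$freq_a, -1))),
            1e-12)
})

test_that("S=0 reproduces VanRaden and S=-1 the GCTA construction", {
  pan <- generate_panel(12, 30, seed = 2)
  g0 <- build_grm(pan, 0)
  expect_lt(max(abs(g0$values -
                      oracle_vanraden_grm(pan$dosages, pan$freq_a))),
            1e-12)
  expect_equal(g0$denominator, sum(2 * pan$freq_a * (1 - pan$freq_a)))

  pan2 <- toy_panel(matrix(c(0, 1, 2, 2, 1, 0), 3, 2))
  gm1 <- build_grm(pan2, -1)
  expect_lt(max(abs(gm1$values -
                      oracle_gcta_grm(pan2$dosages, pan2$freq_a))),
            1e-12)
})

test_that("GRM is invariant to allele-label swaps", {
  pan <- generate_panel(15, 40, seed = 4)
  swapped <- pan
  flip <- c(3, 10, 22)
  swapped$dosages[, flip] <- 2 - swapped$dosages[, flip]
  swapped$freq_a[flip] <- 1 - swapped$freq_a[flip]
  for (s in c(-1.5, 0, 1)) {
    expect_lt(max(abs(build_grm(pan, s)$values -
                        build_grm(swapped, s)$values)), 1e-10)
  }
})

test_that("GRM rejects degenerate inputs", {
  pan <- toy_panel(matrix(c(0, 1, 2, 2, 2, 2), 3, 2))
  expect_error(build_grm(pan, -1), "polymorphic")
  expect_error(build_grm(pan, 0, snp_subset = integer(0)), "empty")
  pan_nofreq <- toy_panel(matrix(c(0, 1), 2, 1))
  pan_nofreq$freq_a <- NULL
  expect_error(build_grm(pan_nofreq, 0), "frequencies")
})

test_that("mean diagonal of the S=-1 GRM approaches 1 on HWE genotypes", {
  pan <- generate_panel(200, 3000, seed = 8)
  g <- build_grm(pan, -1)
  expect_lt(abs(mean(diag(g$values)) - 1), 0.05)
})

test_that("MAF bins follow the right-closed convention", {
  pan <- toy_panel(matrix(0, 2, 5),
                   freq = c(0.05, 0.35, 0.5, 0.1, 0.2))
  # dosages irrelevant for binning; set maf directly through freq
  b <- assign_bins(pan)
  expect_equal(b$assignment, c(1L, 4L, 5L, 1L, 2L))

  bad <- toy_panel(matrix(0, 2, 1), freq = 0.005)
  expect_error(assign_bins(bad), "outside")
})

test_that("uniform-MAF panels fill bins near their expected shares", {
  pan <- generate_panel(300, 4000, seed = 12)
  b <- assign_bins(pan)
  # maf_law uniform on [0.01, 0.5]: realized-MAF bin shares approximate
  # the interval widths (.09/.49, .1/.49 x4) up to frequency-estimation
  # spill at the edges
  shares <- b$counts / sum(b$counts)
  widths <- diff(maf_bin_edges()) / diff(range(maf_bin_edges()))
  expect_true(all(abs(shares - widths) < 0.05))
})

test_that("stratified GRMs reconstruct the whole-panel GRM", {
  pan <- generate_panel(50, 500, seed = 6)
  for (s in c(-1.5, 0)) {
    full <- build_grm(pan, s)
    parts <- build_stratified_grms(pan, s)
    rec <- Reduce(`+`, lapply(parts, function(k)
      k$values * k$denominator)) / full$denominator
    expect_lt(max(abs(rec - full$values)), 1e-10)
    # each component is a Gram matrix: PSD up to numerical tolerance
    for (k in parts) {
      ev <- eigen(k$values, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-8 * max(ev))
      expect_lt(max(abs(k$values - t(k$values))), 1e-10)
    }
  }
})

test_that("empty MAF bins are dropped with a warning", {
  set.seed(10)
  pan <- compute_freqs(toy_panel(cbind(
    rbinom(400, 2, 0.05), rbinom(400, 2, 0.06),
    rbinom(400, 2, 0.45), rbinom(400, 2, 0.48))))
  b <- assign_bins(pan)
  expect_setequal(unique(b$assignment), c(1L, 5L))
  warns <- testthat::capture_warnings(
    grms <- build_stratified_grms(pan, 0, binning = b))
  expect_length(warns, 3)
  expect_named(grms, c("bin1", "bin5"))
})

test_that("GRM serialization round-trips through the GCTA text format", {
  pan <- generate_panel(10, 60, seed = 3)
  km <- build_grm(pan, -0.5)
  prefix <- file.path(withr::local_tempdir(), "test")
  write_grm(km, prefix)
  back <- read_grm(prefix)
  expect_lt(max(abs(back$values - km$values)), 1e-9)
  expect_equal(back$individuals$iid, km$individuals$iid)
  expect_equal(back$s_value, km$s_value)
  expect_equal(back$denominator, km$denominator, tolerance = 1e-12)
  expect_equal(back$snp_ids, km$snp_ids)

  # truncated matrix file is rejected
  lines <- readLines(gzfile(paste0(prefix, ".grm.gz")))
  con <- gzfile(paste0(prefix, ".grm.gz"), "w")
  writeLines(lines[-length(lines)], con)
  close(con)
  expect_error(read_grm(prefix), "truncated|expected")
})

test_that("files from an independent minimal writer read identically", {
  pan <- generate_panel(6, 25, seed = 13)
  km <- build_grm(pan, 0)
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "ext")
  # minimal writer: plain loops, full precision
  con <- gzfile(paste0(prefix, ".grm.gz"), "w")
  for (i in seq_len(6))
    for (j in seq_len(i))
      cat(sprintf("%d\t%d\t%d\t%.15g\n", i, j, 25, km$values[i, j]),
          file = con)
  close(con)
  writeLines(paste(km$individuals$fid, km$individuals$iid, sep = "\t"),
             paste0(prefix, ".grm.id"))
  back <- read_grm(prefix)
  expect_lt(max(abs(back$values - km$values)), 1e-12)
  expect_equal(back$individuals$fid, km$individuals$fid)
})
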