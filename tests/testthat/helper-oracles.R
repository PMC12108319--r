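# Shared fixtures and independent oracles used across the test files.

# Small deterministic panel with known dosages and frequencies.
toy_panel <- function(dosages, freq = NULL) {
  dosages <- as.matrix(dosages)
  n <- nrow(dosages)
  m <- ncol(dosages)
  pan <- genotype_panel(
    dosages,
    fam = data.frame(fid = sprintf("F%d", seq_len(n)),
                     iid = sprintf("I%d", seq_len(n)),
                     stringsAsFactors = FALSE),
    snps = data.frame(chrom = "1", snp_id = sprintf("s%d", seq_len(m)),
                      pos = seq_len(m), a1 = "A", a2 = "B",
                      stringsAsFactors = FALSE),
    validate = FALSE
  )
  if (is.null(freq)) {
    pan <- compute_freqs(pan)
  } else {
    pan$freq_a <- freq
    pan$maf <- pmin(freq, 1 - freq)
  }
  pan
}

# Independent byte-level PLINK .bed decoder built on rawToBits(), a
# different code path from the package's lookup-table decoder.
oracle_read_bed <- function(path, n_ind, n_snp) {
  raw <- readBin(path, "raw", n = file.size(path))
  stopifnot(raw[1] == as.raw(0x6c), raw[2] == as.raw(0x1b),
            raw[3] == as.raw(0x01))
  body <- raw[-(1:3)]
  bps <- ceiling(n_ind / 4)
  out <- matrix(NA_real_, n_ind, n_snp)
  for (j in seq_len(n_snp)) {
    bytes <- body[((j - 1) * bps + 1):(j * bps)]
    bits <- as.integer(rawToBits(bytes))  # little-endian bit order
    for (s in seq_len(n_ind)) {
      b0 <- bits[2 * s - 1]
      b1 <- bits[2 * s]
      code <- b0 + 2L * b1
      out[s, j] <- c(2, NA, 1, 0)[code + 1L]
    }
  }
  out
}

# Brute-force triple-loop GRM: no matrix algebra.
oracle_grm <- function(dosages, p, s) {
  n <- nrow(dosages)
  m <- ncol(dosages)
  het <- 2 * p * (1 - p)
  denom <- sum(het^(s + 1))
  g <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_len(m)) {
        xi <- dosages[i, k]
        xj <- dosages[j, k]
        if (is.na(xi)) xi <- 2 * p[k]
        if (is.na(xj)) xj <- 2 * p[k]
        acc <- acc + (xi - 2 * p[k]) * (xj - 2 * p[k]) * het[k]^s
      }
      g[i, j] <- acc / denom
    }
  g
}

# Per-SNP standardized-products GRM (the GCTA construction): average over
# SNPs of outer products of (x - 2p)/sqrt(2p(1-p)).
oracle_gcta_grm <- function(dosages, p) {
  n <- nrow(dosages)
  m <- ncol(dosages)
  g <- matrix(0, n, n)
  for (k in seq_len(m)) {
    z <- (dosages[, k] - 2 * p[k]) / sqrt(2 * p[k] * (1 - p[k]))
    g <- g + tcrossprod(z)
  }
  g / m
}

# VanRaden GRM: raw centered dosages, denominator sum(2p(1-p)).
oracle_vanraden_grm <- function(dosages, p) {
  w <- sweep(dosages, 2L, 2 * p)
  tcrossprod(w) / sum(2 * p * (1 - p))
}

# Dense-algebra restricted log-likelihood for y ~ N(1*mu, s2*(h2 G +
# (1-h2) I)), with the scale profiled out. Independent of the package's
# eigendecomposition path.
oracle_reml_ll <- function(y, g, h2) {
  n <- length(y)
  x <- matrix(1, n, 1)
  k <- h2 * g + (1 - h2) * diag(n)
  ki <- solve(k)
  xkx <- drop(t(x) %*% ki %*% x)
  p <- ki - ki %*% x %*% t(x) %*% ki / xkx
  ypy <- drop(t(y) %*% p %*% y)
  s2 <- ypy / (n - 1)
  -0.5 * ((n - 1) * log(s2) + as.numeric(determinant(k)$modulus) +
            log(xkx) + (n - 1) + (n - 1) * log(2 * pi))
}

# Exact HWE p-value by direct enumeration on the probability scale
# (factorials, no log-space), valid for small totals.
oracle_hwe <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  n_a <- 2 * n_hom1 + n_het
  n_b <- 2 * n_hom2 + n_het
  nr <- min(n_a, n_b)
  if (nr == 0) return(1)
  hs <- seq(nr %% 2, nr, by = 2)
  pr <- vapply(hs, function(h) {
    2^h * factorial(n) /
      (factorial((nr - h) / 2) * factorial(h) *
         factorial(n - (nr + h) / 2))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Henderson mixed-model-equations solve for one genetic component over
# train+candidate individuals; returns candidate genetic values.
oracle_mme_gebv <- function(g, y_train, train, cand, sigma_a2, sigma_e2) {
  n <- nrow(g)
  nt <- length(train)
  z <- matrix(0, nt, n)
  z[cbind(seq_len(nt), train)] <- 1
  x <- matrix(1, nt, 1)
  gi <- solve(g)
  lambda <- sigma_e2 / sigma_a2
  lhs <- rbind(
    cbind(crossprod(x), t(x) %*% z),
    cbind(t(z) %*% x, crossprod(z) + lambda * gi)
  )
  rhs <- c(crossprod(x, y_train), crossprod(z, y_train))
  sol <- solve(lhs, rhs)
  sol[1 + cand]
}
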