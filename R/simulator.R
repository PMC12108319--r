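# Synthetic genotype panels and quantitative traits simulated under a
# chosen selection signature: causal-variant effect variances scale with
# allele frequency as [2p(1-p)]^S at a fixed target heritability.

#' Derive reproducible child seeds from one master seed
#'
#' Stages of a pipeline (panel generation, causal-variant sampling,
#' effect draws, fold splits, ...) each get their own child seed so that a
#' stage can be re-run in isolation. The derivation is deterministic:
#' child seeds are drawn by `sample.int()` under the master seed.
#'
#' @param master_seed integer master seed.
#' @param n number of child seeds.
#' @return integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a synthetic genotype panel
#'
#' Allele frequencies are drawn from `maf_law` (default uniform on
#' `[0.01, 0.5]`) and genotypes per SNP as the sum of two independent
#' Bernoulli(p) allele draws, i.e. Hardy-Weinberg proportions with
#' linkage equilibrium between SNPs. The panel stands in for a
#' QC-filtered genotype set, so SNPs whose realized sample MAF falls
#' below 0.01 (including monomorphic draws) are resampled until every
#' column would pass the MAF filter.
#' An optional block structure correlates allele draws within blocks of
#' `ld_block_size` adjacent SNPs through a Gaussian copula with
#' correlation `ld_rho` (off by default; the models here ignore LD).
#'
#' @param n_individuals number of individuals.
#' @param n_snps number of SNPs.
#' @param maf_law function taking a count and returning that many allele
#'   frequencies in (0, 1); default `function(m) runif(m, 0.01, 0.5)`.
#' @param seed integer seed; the same seed reproduces the same panel.
#' @param ld_block_size optional block length for correlated SNPs;
#'   `NULL` (default) gives linkage equilibrium.
#' @param ld_rho within-block copula correlation (used only when
#'   `ld_block_size` is set).
#' @return a [genotype_panel()] with frequencies computed from the
#'   realized genotypes.
#' @export
generate_panel <- function(n_individuals, n_snps,
                           maf_law = function(m) runif(m, 0.01, 0.5),
                           seed = 1L, ld_block_size = NULL, ld_rho = 0.6) {
  stopifnot(n_individuals > 0, n_snps > 0)
  set.seed(as.integer(seed))
  p <- maf_law(n_snps)
  if (any(p <= 0) || any(p >= 1))
    stop("maf_law must return frequencies strictly inside (0, 1)")

  draw_alleles <- function(p_vec) {
    m <- length(p_vec)
    if (is.null(ld_block_size)) {
      a1 <- matrix(runif(n_individuals * m), n_individuals, m)
      a2 <- matrix(runif(n_individuals * m), n_individuals, m)
    } else {
      a1 <- .block_copula_uniform(n_individuals, m, ld_block_size, ld_rho)
      a2 <- .block_copula_uniform(n_individuals, m, ld_block_size, ld_rho)
    }
    pm <- matrix(p_vec, n_individuals, m, byrow = TRUE)
    (a1 < pm) + (a2 < pm)
  }

  d <- draw_alleles(p)
  # resample SNPs whose realized MAF would fail the 0.01 QC floor
  for (iter in 1:200) {
    f <- colMeans(d) / 2
    low <- which(pmin(f, 1 - f) < 0.01)
    if (length(low) == 0) break
    p[low] <- maf_law(length(low))
    d[, low] <- draw_alleles(p[low])
  }
  if (length(low <- which(pmin(colMeans(d) / 2,
                               1 - colMeans(d) / 2) < 0.01)))
    stop("could not generate ", length(low),
         " SNP(s) with realized MAF >= 0.01; check maf_law")

  fam <- data.frame(fid = sprintf("F%04d", seq_len(n_individuals)),
                    iid = sprintf("I%04d", seq_len(n_individuals)),
                    stringsAsFactors = FALSE)
  snps <- data.frame(chrom = "1",
                     snp_id = sprintf("snp%05d", seq_len(n_snps)),
                     pos = seq_len(n_snps) * 1000L,
                     a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  compute_freqs(genotype_panel(d, fam, snps, validate = FALSE))
}

# correlated uniforms in blocks: equicorrelated Gaussians -> probit copula
.block_copula_uniform <- function(n, m, block, rho) {
  u <- matrix(0, n, m)
  start <- 1L
  while (start <= m) {
    end <- min(start + block - 1L, m)
    k <- end - start + 1L
    shared <- rnorm(n)
    z <- sqrt(rho) * matrix(shared, n, k) +
      sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
    u[, start:end] <- pnorm(z)
    start <- end + 1L
  }
  u
}

#' Simulate a quantitative trait under a selection signature
#'
#' Draws `n_cv` causal variants (CVs) uniformly without replacement from
#' the polymorphic SNPs of the panel. Effects are
#' `g_i = [2 p_i (1 - p_i)]^(S/2) * g_i*` with `g_i* ~ N(0, 1)`, so the
#' per-CV effect variance is `[2p(1-p)]^S`: negative `S` gives rare
#' variants larger effects. True breeding values are `tbv = X_cv g`; the
#' genetic variance `sigma_a2` is the empirical variance of `tbv`, and
#' residuals are drawn `N(0, sigma_a2 (1 - h2) / h2)` so the realized
#' heritability `var(tbv)/var(y)` concentrates near `h2`.
#'
#' @param panel a [genotype_panel()] with frequencies computed.
#' @param n_cv number of causal variants.
#' @param s_true the true selection exponent S.
#' @param h2 target heritability in (0, 1).
#' @param seed integer seed.
#' @return a `simulated_trait`: list with `cv_indices`, `effects`, `tbv`,
#'   `residuals`, `phenotypes`, `sigma_a2`, `s_true`, `h2`, `seed`.
#' @export
simulate_trait <- function(panel, n_cv = 1000, s_true = 0, h2 = 0.1,
                           seed = 1L) {
  if (h2 <= 0 || h2 >= 1) stop("h2 must lie strictly between 0 and 1")
  if (is.null(panel$freq_a))
    stop("allele frequencies not computed; call compute_freqs() first")
  poly <- which(!is.na(panel$freq_a) &
                  panel$freq_a > 0 & panel$freq_a < 1)
  if (n_cv > length(poly))
    stop("n_cv (", n_cv, ") exceeds the number of polymorphic SNPs (",
         length(poly), ")")
  seeds <- derive_seeds(seed, 3L)

  set.seed(seeds[1])
  cv <- sort(sample(poly, n_cv))

  p <- panel$freq_a[cv]
  het <- 2 * p * (1 - p)
  set.seed(seeds[2])
  g_star <- rnorm(n_cv)
  effects <- exp((s_true / 2) * log(het)) * g_star

  x <- panel$dosages[, cv, drop = FALSE]
  if (anyNA(x)) {
    fill <- matrix(2 * p, nrow = nrow(x), ncol = n_cv, byrow = TRUE)
    x[is.na(x)] <- fill[is.na(x)]
  }
  tbv <- drop(x %*% effects)
  sigma_a2 <- var(tbv)

  set.seed(seeds[3])
  residuals <- rnorm(length(tbv), sd = sqrt(sigma_a2 * (1 - h2) / h2))
  structure(
    list(cv_indices = cv, effects = effects, tbv = tbv,
         residuals = residuals, phenotypes = tbv + residuals,
         sigma_a2 = sigma_a2, s_true = s_true, h2 = h2, seed = seed),
    class = "simulated_trait"
  )
}

#' @export
print.simulated_trait <- function(x, ...) {
  cat("simulated_trait:", length(x$tbv), "individuals,",
      length(x$cv_indices), "causal variants\n")
  cat(sprintf("  true S = %g, target h2 = %g, realized h2 = %.4f\n",
              x$s_true, x$h2,
              var(x$tbv) / var(x$phenotypes)))
  invisible(x)
}

#' Heritability explained by each causal variant
#'
#' The realized (single-draw) heritability contribution of CV `i` is
#' `h_i^2 = 2 p_i (1 - p_i) g_i^2`. Under simulation with exponent `S`
#' its expectation is proportional to `[2p(1-p)]^(S+1)`, so at `S = -1`
#' the per-CV contribution is flat in MAF, decreasing for `S < -1` and
#' increasing for `S > -1`.
#'
#' @param trait a [simulate_trait()] result.
#' @param panel the panel the trait was simulated on.
#' @return numeric vector, one value per CV (same order as
#'   `trait$cv_indices`).
#' @export
per_cv_heritability <- function(trait, panel) {
  p <- panel$freq_a[trait$cv_indices]
  2 * p * (1 - p) * trait$effects^2
}

#' Mean per-CV heritability by MAF bin
#'
#' Convenience summary of [per_cv_heritability()] over the five standard
#' MAF bins; useful for inspecting the simulated genetic architecture.
#'
#' @inheritParams per_cv_heritability
#' @return data frame with columns `bin`, `maf_mid`, `n_cv`, `mean_h2`.
#' @export
binned_cv_heritability <- function(trait, panel) {
  h <- per_cv_heritability(trait, panel)
  maf <- panel$maf[trait$cv_indices]
  edges <- maf_bin_edges()
  bin <- as.integer(cut(pmax(maf, edges[1]), breaks = edges,
                        include.lowest = TRUE, right = TRUE))
  data.frame(
    bin = seq_len(length(edges) - 1L),
    maf_mid = (utils::head(edges, -1) + edges[-1]) / 2,
    n_cv = tabulate(bin, nbins = length(edges) - 1L),
    mean_h2 = vapply(seq_len(length(edges) - 1L), function(t) {
      v <- h[bin == t]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
  )
}
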