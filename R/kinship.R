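# Selection-adjusted genomic relationship matrices (GRMs).
#
# The GRM with selection exponent S has elements
#   G = M M' / sum_i [2 p_i (1 - p_i)]^(S+1),
#   m_ij = (x_ij - 2 p_i) * [2 p_i (1 - p_i)]^(S/2),
# where p_i is the counted-allele frequency of SNP i. S = 0 recovers the
# VanRaden GRM; S = -1 the GCTA average of per-SNP standardized products.

#' Build a selection-adjusted genomic relationship matrix
#'
#' Centers each SNP by twice its counted-allele frequency, scales it by
#' `[2p(1-p)]^(S/2)` and normalizes the cross-product by
#' `sum([2p(1-p)]^(S+1))`. Missing genotypes are mean-imputed (replaced by
#' `2p`) at construction time, so they contribute exactly zero to the
#' centered matrix; the panel itself is not modified.
#'
#' @param panel a [genotype_panel()] with frequencies computed. Frequencies
#'   are taken from the panel as stored, so a reference frequency set can
#'   be reused for candidate individuals.
#' @param s_value the selection exponent S. Negative values up-weight rare
#'   alleles (negative selection), 0 is the neutral VanRaden scaling, and
#'   positive values up-weight common alleles.
#' @param snp_subset optional integer index of SNPs to use (default all).
#' @return a `kinship_matrix`: list with `values` (symmetric n x n matrix),
#'   `individuals` (data frame `fid`, `iid`), `s_value`, `snp_ids`, and
#'   `denominator` (the scaling sum).
#' @export
build_grm <- function(panel, s_value, snp_subset = NULL) {
  if (is.null(panel$freq_a))
    stop("allele frequencies not computed; call compute_freqs() first")
  if (is.null(snp_subset)) snp_subset <- seq_len(n_snps(panel))
  if (length(snp_subset) == 0)
    stop("empty SNP subset")
  p <- panel$freq_a[snp_subset]
  if (any(is.na(p)) || any(p <= 0) || any(p >= 1))
    stop("all SNPs in the subset must be polymorphic (0 < p < 1); ",
         "zero-variance scaling is undefined")
  x <- panel$dosages[, snp_subset, drop = FALSE]

  het <- 2 * p * (1 - p)
  # log-space exponentiation: stable for strongly negative S at p near 0.01
  w <- exp((s_value / 2) * log(het))
  denom <- sum(exp((s_value + 1) * log(het)))

  center <- matrix(2 * p, nrow = nrow(x), ncol = length(p), byrow = TRUE)
  m <- x - center
  m[is.na(m)] <- 0  # mean-imputed entries vanish after centering
  m <- sweep(m, 2L, w, `*`)
  g <- tcrossprod(m) / denom
  g <- (g + t(g)) / 2

  structure(
    list(values = g,
         individuals = panel$fam,
         s_value = s_value,
         snp_ids = panel$snps$snp_id[snp_subset],
         denominator = denom),
    class = "kinship_matrix"
  )
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("kinship_matrix:", nrow(x$values), "individuals,",
      length(x$snp_ids), "SNPs, S =", x$s_value, "\n")
  cat("  mean diagonal:", sprintf("%.4f", mean(diag(x$values))), "\n")
  invisible(x)
}

#' Subset a kinship matrix to a set of individuals
#' @param km a `kinship_matrix`.
#' @param idx integer index of individuals to keep.
#' @return a `kinship_matrix` over the selected individuals.
#' @export
kinship_subset <- function(km, idx) {
  km$values <- km$values[idx, idx, drop = FALSE]
  km$individuals <- km$individuals[idx, , drop = FALSE]
  km
}

#' The five MAF bins used for stratified GRMs
#'
#' Bin edges 0.01-0.1, 0.1-0.2, 0.2-0.3, 0.3-0.4, 0.4-0.5. Intervals are
#' right-closed, with the first bin closed on both ends, so a SNP with MAF
#' exactly 0.1 falls in bin 1.
#'
#' @return numeric vector of the six bin edges.
#' @export
maf_bin_edges <- function() c(0.01, 0.1, 0.2, 0.3, 0.4, 0.5)

#' Assign QC-passing SNPs to MAF bins
#'
#' @param panel a [genotype_panel()] with frequencies computed; every SNP
#'   must have MAF in `[0.01, 0.5]` (i.e. have passed QC).
#' @return a `maf_binning`: list with `edges`, `assignment` (per-SNP bin
#'   index 1..5) and `counts`.
#' @export
assign_bins <- function(panel) {
  if (is.null(panel$maf))
    stop("allele frequencies not computed; call compute_freqs() first")
  maf <- panel$maf
  edges <- maf_bin_edges()
  if (any(is.na(maf)) || any(maf < edges[1] - 1e-12) ||
      any(maf > edges[length(edges)] + 1e-12))
    stop("MAF outside [0.01, 0.5]; apply QC before binning")
  bin <- as.integer(cut(maf, breaks = edges, include.lowest = TRUE,
                        right = TRUE))
  structure(
    list(edges = edges, assignment = bin,
         counts = tabulate(bin, nbins = length(edges) - 1L)),
    class = "maf_binning"
  )
}

#' @export
print.maf_binning <- function(x, ...) {
  lab <- paste0(utils::head(x$edges, -1), "-", x$edges[-1])
  cat("MAF binning:\n")
  for (t in seq_along(x$counts))
    cat(sprintf("  bin %d (%s): %d SNPs\n", t, lab[t], x$counts[t]))
  invisible(x)
}

#' Build five MAF-stratified selection-adjusted GRMs
#'
#' One GRM per MAF bin, each built by [build_grm()] from the SNPs in that
#' bin with its own normalizing denominator. Empty bins are dropped with a
#' warning. The denominator-weighted sum of the per-bin matrices
#' reconstructs the whole-panel GRM:
#' `G_full = sum_t (d_t / d_full) G_t`.
#'
#' @inheritParams build_grm
#' @param binning optional [assign_bins()] result (computed if omitted).
#' @return named list of `kinship_matrix` objects (`bin1` ... `bin5`,
#'   non-empty bins only).
#' @export
build_stratified_grms <- function(panel, s_value, binning = NULL) {
  if (is.null(binning)) binning <- assign_bins(panel)
  n_bins <- length(binning$edges) - 1L
  out <- list()
  for (t in seq_len(n_bins)) {
    idx <- which(binning$assignment == t)
    if (length(idx) == 0) {
      warning("MAF bin ", t, " is empty; component dropped")
      next
    }
    out[[paste0("bin", t)]] <- build_grm(panel, s_value, snp_subset = idx)
  }
  if (length(out) == 0)
    stop("all MAF bins are empty")
  out
}

#' Write / read a kinship matrix in GCTA text format
#'
#' `write_grm()` writes `prefix.grm.gz` (gzipped text, one line per
#' lower-triangle element: `i j n_snps value`), `prefix.grm.id`
#' (`FID IID`) and a JSON sidecar `prefix.grm.json` holding `s_value`,
#' `denominator` and the contributing SNP ids. `read_grm()` reverses this.
#'
#' @param km a `kinship_matrix`.
#' @param prefix output path stem.
#' @return `write_grm()`: `prefix`, invisibly. `read_grm()`: a
#'   `kinship_matrix`.
#' @export
write_grm <- function(km, prefix) {
  n <- nrow(km$values)
  i <- rep(seq_len(n), times = seq_len(n))
  j <- sequence(seq_len(n))
  vals <- km$values[cbind(i, j)]
  con <- gzfile(paste0(prefix, ".grm.gz"), "w")
  writeLines(sprintf("%d\t%d\t%d\t%.12g", i, j, length(km$snp_ids), vals),
             con)
  close(con)
  write.table(km$individuals[, c("fid", "iid")],
              paste0(prefix, ".grm.id"), quote = FALSE,
              row.names = FALSE, col.names = FALSE, sep = "\t")
  jsonlite::write_json(
    list(s_value = km$s_value, denominator = km$denominator,
         snp_ids = km$snp_ids),
    paste0(prefix, ".grm.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix) {
  id_path <- paste0(prefix, ".grm.id")
  grm_path <- paste0(prefix, ".grm.gz")
  ids <- read.table(id_path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  names(ids) <- c("fid", "iid")
  n <- nrow(ids)
  tab <- read.table(gzfile(grm_path), header = FALSE)
  if (nrow(tab) != n * (n + 1) / 2)
    stop("GRM file has ", nrow(tab), " rows; expected ", n * (n + 1) / 2,
         " for ", n, " individuals (truncated file?)")
  if (max(tab[[1]]) != n || any(tab[[2]] > tab[[1]]))
    stop("GRM indices inconsistent with the .grm.id companion file")
  g <- matrix(0, n, n)
  g[cbind(tab[[1]], tab[[2]])] <- tab[[4]]
  g[cbind(tab[[2]], tab[[1]])] <- tab[[4]]
  meta_path <- paste0(prefix, ".grm.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  else
    list(s_value = NA_real_, denominator = NA_real_, snp_ids = character())
  structure(
    list(values = g, individuals = ids, s_value = meta$s_value,
         snp_ids = meta$snp_ids, denominator = meta$denominator),
    class = "kinship_matrix"
  )
}
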