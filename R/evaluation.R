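# Cross-validation, prediction accuracy, heritability enrichment across
# MAF bins, and the chi-square uniformity diagnostic used to choose the
# selection exponent S.

#' Make cross-validation folds
#'
#' Two schemes: `"holdout91"` splits reference and candidate individuals
#' 9:1 (one candidate fold of ~10%); `"kfold10"` assigns every individual
#' to one of `k` folds of near-equal size (difference at most 1). Both are
#' uniform at random and deterministic under `seed`.
#'
#' @param ids character vector (or count) of individuals.
#' @param mode `"holdout91"` or `"kfold10"`.
#' @param k number of folds for `"kfold10"` (default 10).
#' @param seed integer seed.
#' @return a `cv_scheme`: list with `mode`, `fold` (per-individual fold
#'   index; in holdout mode 1 = candidate, 0 = reference), `n_folds`,
#'   `seed`.
#' @export
make_folds <- function(ids, mode = c("kfold10", "holdout91"), k = 10,
                       seed = 1L) {
  mode <- match.arg(mode)
  n <- if (length(ids) == 1 && is.numeric(ids)) as.integer(ids)
       else length(ids)
  if (n < 20) stop("at least 20 individuals are required for ",
                   "cross-validation")
  set.seed(as.integer(seed))
  if (mode == "holdout91") {
    n_cand <- round(n / 10)
    fold <- integer(n)
    fold[sample.int(n, n_cand)] <- 1L
    n_folds <- 1L
  } else {
    fold <- sample(rep(seq_len(k), length.out = n))
    n_folds <- as.integer(k)
  }
  structure(list(mode = mode, fold = fold, n_folds = n_folds,
                 seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Prediction accuracy
#'
#' Sample Pearson correlation between reference values (true breeding
#' values in simulations, phenotypes for real data) and predicted GEBVs.
#'
#' @param truth numeric vector.
#' @param gebv numeric vector of the same length (>= 3).
#' @return the correlation.
#' @export
accuracy <- function(truth, gebv) {
  if (length(truth) != length(gebv))
    stop("truth and gebv lengths differ")
  if (length(truth) < 3)
    stop("at least 3 pairs are required")
  if (sd(truth) == 0 || sd(gebv) == 0)
    stop("accuracy undefined: zero variance in input")
  cor(truth, gebv)
}

#' Expected heritability share of each MAF bin
#'
#' Under selection exponent `S`, SNP `j` is expected to contribute
#' variance proportional to `[2 p_j (1 - p_j)]^(S+1)`, so the expected
#' heritability share of bin `i` is the bin's share of
#' `sum_j [2p_j(1-p_j)]^(S+1)`. At `S = -1` every SNP contributes equally
#' and the shares reduce to bin SNP-count fractions.
#'
#' @param panel a [genotype_panel()] with frequencies computed.
#' @param binning an [assign_bins()] result for the panel.
#' @param s_value the selection exponent of the model under evaluation.
#' @return numeric vector of per-bin proportions (sums to 1).
#' @export
expected_bin_props <- function(panel, binning, s_value) {
  if (n_snps(panel) == 0) stop("empty panel")
  p <- panel$freq_a
  contrib <- exp((s_value + 1) * log(2 * p * (1 - p)))
  n_bins <- length(binning$edges) - 1L
  tot <- vapply(seq_len(n_bins), function(t)
    sum(contrib[binning$assignment == t]), numeric(1))
  tot / sum(tot)
}

#' Heritability enrichment across MAF bins
#'
#' Compares the observed heritability share of each MAF bin (from a
#' five-component stratified REML fit) with its expected share under the
#' model's `S` ([expected_bin_props()]). Enrichment is the
#' observed/expected ratio; proportions close to 1:1:1:1:1 indicate a
#' well-calibrated `S`. The chi-square uniformity statistic is attached.
#'
#' @param fit a [fit_reml()] result whose components align with the bins
#'   of `expected_prop`.
#' @param expected_prop per-bin expected proportions (summing to 1).
#' @param s_value the model S (provenance; optional).
#' @return an `enrichment_result`: list with `observed_h2`,
#'   `observed_prop`, `expected_prop`, `enrichment`, `chi_square`,
#'   `s_value`.
#' @export
enrichment <- function(fit, expected_prop, s_value = NA_real_) {
  stopifnot(inherits(fit, "reml_fit"))
  if (fit$n_components != length(expected_prop))
    stop("fit has ", fit$n_components, " components but expected_prop has ",
         length(expected_prop))
  if (abs(sum(expected_prop) - 1) > 1e-8)
    stop("expected_prop must sum to 1")
  obs_h2 <- fit$h2_per_component
  if (sum(obs_h2) <= 0)
    stop("total estimated heritability is zero; enrichment undefined")
  obs_prop <- obs_h2 / sum(obs_h2)
  enr <- obs_prop / expected_prop
  if (any(expected_prop == 0 & obs_prop > 0)) {
    warning("bin with zero expected share but positive observed share: ",
            "infinite enrichment")
  }
  res <- structure(
    list(observed_h2 = obs_h2,
         observed_prop = obs_prop,
         expected_prop = expected_prop,
         enrichment = enr,
         chi_square = NA_real_,
         s_value = s_value),
    class = "enrichment_result"
  )
  res$chi_square <- chi_square_uniformity(res)
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result (model S =", x$s_value, "):\n")
  for (t in seq_along(x$enrichment))
    cat(sprintf("  bin %d: observed %.4f, expected %.4f, enrichment %.3f\n",
                t, x$observed_prop[t], x$expected_prop[t], x$enrichment[t]))
  cat(sprintf("  chi-square = %.4f\n", x$chi_square))
  invisible(x)
}

#' Chi-square uniformity statistic for heritability enrichment
#'
#' `sum_i (O_i - E_i)^2 / E_i` over the MAF bins, where `O_i` and `E_i`
#' are the observed and expected heritability proportions (each summing
#' to 1). Small values indicate that the assumed `S` reproduces the
#' observed distribution of heritability across the MAF spectrum; the
#' statistic's minimum over an S grid identifies the best-calibrated S.
#'
#' @param result an `enrichment_result`, or the observed-proportion
#'   vector (in which case `expected` must be given).
#' @param expected per-bin expected proportions when `result` is a plain
#'   vector.
#' @param df degrees of freedom for the optional p-value (bins - 1).
#' @param p_value also return the chi-square tail probability.
#' @return the statistic, or a list `(statistic, p_value)` when
#'   `p_value = TRUE`.
#' @export
chi_square_uniformity <- function(result, expected = NULL, df = NULL,
                                  p_value = FALSE) {
  if (inherits(result, "enrichment_result")) {
    obs <- result$observed_prop
    exp_p <- result$expected_prop
  } else {
    obs <- result
    exp_p <- expected
    if (is.null(exp_p)) stop("expected proportions required")
  }
  if (any(exp_p == 0)) stop("expected proportion of zero in some bin")
  stat <- sum((obs - exp_p)^2 / exp_p)
  if (!p_value) return(stat)
  if (is.null(df)) df <- length(obs) - 1
  list(statistic = stat,
       p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

# Fit + predict one model (gblup-s or gblup-sms) for one S on one panel,
# over the folds of `scheme`. Heritability/LRT/enrichment come from the
# full-data fit; folds are used for prediction accuracy only.
.eval_one_s <- function(panel, y, s_value, model, scheme, truth,
                        binning = NULL) {
  n <- n_individuals(panel)
  if (model == "gblup-s") {
    grms <- list(build_grm(panel, s_value))
  } else {
    grms <- unname(build_stratified_grms(panel, s_value,
                                         binning = binning))
  }
  g_mats <- lapply(grms, function(k) k$values)

  full_fit <- fit_reml(y, g_mats)
  null_fit <- fit_reml(y, list())
  lrt_stat <- lrt(full_fit, null_fit)

  enr <- NULL
  if (model == "gblup-sms" && length(g_mats) == 5) {
    exp_prop <- expected_bin_props(panel, binning, s_value)
    enr <- tryCatch(enrichment(full_fit, exp_prop, s_value = s_value),
                    error = function(e) NULL)
  }

  folds <- if (scheme$mode == "holdout91") 1L else seq_len(scheme$n_folds)
  acc <- numeric(length(folds))
  fold_sizes <- integer(length(folds))
  for (f in seq_along(folds)) {
    cand <- which(scheme$fold == folds[f])
    train <- setdiff(seq_len(n), cand)
    fit_tr <- fit_reml(y[train], lapply(g_mats, function(g)
      g[train, train, drop = FALSE]))
    pred <- predict_gebv(fit_tr, g_mats, y[train], train, cand)
    # a boundary fit (all genetic variance zero) yields constant GEBVs;
    # record NA rather than aborting the whole grid
    acc[f] <- tryCatch(accuracy(truth[cand], pred$gebv),
                       error = function(e) NA_real_)
    fold_sizes[f] <- length(cand)
  }

  data.frame(
    model = model, s = s_value, fold = folds,
    fold_size = fold_sizes,
    accuracy = acc,
    h2 = full_fit$h2_total,
    loglik = full_fit$loglik,
    lrt = lrt_stat,
    converged = full_fit$converged,
    chi_square = if (!is.null(enr)) enr$chi_square else NA_real_,
    t(if (!is.null(enr)) matrix(enr$enrichment, 5, length(folds),
                                dimnames = list(paste0("enrich_bin", 1:5)))
      else matrix(NA_real_, 5, length(folds),
                  dimnames = list(paste0("enrich_bin", 1:5)))),
    stringsAsFactors = FALSE
  )
}

#' Evaluate GBLUP-S / GBLUP-SMS across a grid of selection exponents
#'
#' For each `S` in `s_grid`, builds the model's GRM(s), fits REML on the
#' full data (heritability, restricted log-likelihood, LRT against the
#' no-genetics null, and for GBLUP-SMS the heritability enrichment and
#' chi-square), then scores prediction accuracy on the folds of `scheme`
#' (variance components re-estimated within each training set).
#'
#' @param panel a QC'd [genotype_panel()] with frequencies computed.
#' @param phenotype numeric phenotype vector aligned with the panel.
#' @param s_grid numeric vector of model S values
#'   (default `c(-2, -1.5, -1, -0.5, 0, 0.5, 1)`).
#' @param model `"gblup-s"` (single GRM) or `"gblup-sms"` (five MAF-bin
#'   GRMs), or both.
#' @param scheme a [make_folds()] scheme over the panel's individuals.
#' @param truth reference vector for accuracy (true breeding values in
#'   simulations); defaults to `phenotype`.
#' @return data frame with one row per (model, S, fold): `accuracy`,
#'   `h2`, `loglik`, `lrt`, `chi_square`, `enrich_bin1..5`.
#' @export
run_s_grid <- function(panel, phenotype,
                       s_grid = c(-2, -1.5, -1, -0.5, 0, 0.5, 1),
                       model = c("gblup-s", "gblup-sms"),
                       scheme = NULL, truth = NULL) {
  model <- match.arg(model, several.ok = TRUE)
  if (is.null(truth)) truth <- phenotype
  if (length(phenotype) != n_individuals(panel))
    stop("phenotype length does not match panel")
  if (is.null(scheme))
    scheme <- make_folds(n_individuals(panel), "holdout91", seed = 1L)
  binning <- if ("gblup-sms" %in% model) assign_bins(panel) else NULL
  out <- list()
  for (mo in model)
    for (s in s_grid)
      out[[length(out) + 1L]] <-
        .eval_one_s(panel, phenotype, s, mo, scheme, truth,
                    binning = binning)
  do.call(rbind, out)
}

#' Fold-size-weighted mean accuracy
#'
#' Aggregates per-fold accuracies from [run_s_grid()] output, weighting
#' each fold by its candidate count.
#'
#' @param results a [run_s_grid()] result (or compatible data frame).
#' @return data frame with one row per (model, S): `accuracy`, `h2`,
#'   `lrt`, `chi_square`.
#' @export
aggregate_s_grid <- function(results) {
  key <- interaction(results$model, results$s, drop = TRUE)
  rows <- lapply(split(results, key), function(d) {
    ok <- !is.na(d$accuracy)
    data.frame(model = d$model[1], s = d$s[1],
               accuracy = if (any(ok))
                 sum(d$accuracy[ok] * d$fold_size[ok]) /
                   sum(d$fold_size[ok])
               else NA_real_,
               h2 = d$h2[1], lrt = d$lrt[1],
               chi_square = d$chi_square[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$model, out$s), , drop = FALSE]
}
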