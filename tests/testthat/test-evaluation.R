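# Cross-validation folds, accuracy, enrichment and the chi-square
# uniformity diagnostic.

test_that("fold assignment partitions individuals deterministically", {
  s1 <- make_folds(100, "kfold10", seed = 4)
  s2 <- make_folds(100, "kfold10", seed = 4)
  expect_identical(s1$fold, s2$fold)
  expect_equal(as.vector(table(s1$fold)), rep(10, 10))

  s3 <- make_folds(103, "kfold10", seed = 4)
  sizes <- as.vector(table(s3$fold))
  expect_lte(diff(range(sizes)), 1)
  expect_equal(sum(sizes), 103)

  hold <- make_folds(5024, "holdout91", seed = 9)
  expect_true(sum(hold$fold == 1) %in% c(502, 503))
  expect_true(all(hold$fold %in% c(0L, 1L)))

  expect_error(make_folds(10, "kfold10"), "at least 20")
})

test_that("accuracy is the sample Pearson correlation", {
  x <- c(1.2, -0.4, 2.2, 0.1, 1.0)
  expect_equal(accuracy(x, x), 1)
  expect_equal(accuracy(x, -x), -1)

  truth <- c(1, 2, 3, 4, 5)
  gebv <- c(2.0, 1.5, 3.5, 3.0, 6.0)
  # textbook formula, written out
  num <- sum((truth - mean(truth)) * (gebv - mean(gebv)))
  den <- sqrt(sum((truth - mean(truth))^2) * sum((gebv - mean(gebv))^2))
  expect_equal(accuracy(truth, gebv), num / den, tolerance = 1e-12)

  expect_error(accuracy(truth, gebv[1:4]), "lengths differ")
  expect_error(accuracy(rep(1, 5), gebv), "zero variance")
})

test_that("expected bin shares follow the [2p(1-p)]^(S+1) weighting", {
  pan <- toy_panel(matrix(0, 2, 2), freq = c(0.1, 0.4))
  binning <- assign_bins(pan)
  props <- expected_bin_props(pan, binning, 0)
  expect_equal(props[1], 0.18 / 0.66, tolerance = 1e-12)
  expect_equal(props[4], 0.48 / 0.66, tolerance = 1e-12)
  expect_equal(sum(props), 1, tolerance = 1e-12)

  # S = -1: every SNP weighted equally -> SNP-count shares
  pan2 <- generate_panel(80, 600, seed = 25)
  b2 <- assign_bins(pan2)
  props2 <- expected_bin_props(pan2, b2, -1)
  expect_equal(props2, b2$counts / sum(b2$counts), tolerance = 1e-12)

  for (s in c(-2, -0.5, 1))
    expect_equal(sum(expected_bin_props(pan2, b2, s)), 1,
                 tolerance = 1e-12)
})

test_that("enrichment ratios and the chi-square follow the definitions", {
  mkfit <- function(shares) {
    tot <- 0.6
    structure(list(sigma_a2 = shares * tot, sigma_e2 = 1 - tot,
                   h2_per_component = shares * tot, h2_total = tot,
                   n_components = 5L, n = 100, loglik = 0,
                   converged = TRUE, y = numeric(100)),
              class = "reml_fit")
  }
  uniform <- rep(0.2, 5)
  fit <- mkfit(uniform)
  er <- enrichment(fit, uniform)
  expect_equal(er$enrichment, rep(1, 5))
  expect_equal(er$chi_square, 0)

  obs <- c(0.4, 0.15, 0.15, 0.15, 0.15)
  er2 <- enrichment(mkfit(obs), uniform)
  expect_equal(er2$enrichment, c(2, 0.75, 0.75, 0.75, 0.75))
  expect_equal(er2$chi_square, 0.25)
  expect_equal(sum(er2$observed_prop), 1, tolerance = 1e-10)

  expect_error(enrichment(mkfit(uniform), rep(0.25, 4)), "components")
  expect_error(chi_square_uniformity(obs, c(0, 0.4, 0.2, 0.2, 0.2)),
               "zero")
})

test_that("chi-square grows monotonically away from the expectation", {
  e <- c(0.3, 0.25, 0.2, 0.15, 0.1)
  dir <- c(0.2, -0.05, -0.05, -0.05, -0.05)
  stats <- vapply(seq(0, 1, by = 0.25), function(a)
    chi_square_uniformity(e + a * dir, e), numeric(1))
  expect_true(all(diff(stats) > 0))

  pv <- chi_square_uniformity(e + 0.5 * dir, e, p_value = TRUE)
  expect_equal(pv$p_value,
               pchisq(pv$statistic, df = 4, lower.tail = FALSE))
})

test_that("a one-point S grid reproduces a direct fit and predict", {
  pan <- generate_panel(120, 500, seed = 61)
  tr <- simulate_trait(pan, n_cv = 100, s_true = 0, h2 = 0.5, seed = 23)
  scheme <- make_folds(120, "holdout91", seed = 5)
  res <- run_s_grid(pan, tr$phenotypes, s_grid = 0, model = "gblup-s",
                    scheme = scheme, truth = tr$tbv)
  expect_equal(nrow(res), 1)

  g <- build_grm(pan, 0)
  cand <- which(scheme$fold == 1)
  train <- setdiff(1:120, cand)
  fit_tr <- fit_reml(tr$phenotypes[train],
                     g$values[train, train, drop = FALSE])
  pred <- predict_gebv(fit_tr, g, tr$phenotypes[train], train, cand)
  expect_equal(res$accuracy, accuracy(tr$tbv[cand], pred$gebv),
               tolerance = 1e-10)

  full <- fit_reml(tr$phenotypes, g)
  expect_equal(res$h2, full$h2_total, tolerance = 1e-10)
  expect_equal(res$lrt, lrt(full, fit_reml(tr$phenotypes, list())),
               tolerance = 1e-8)
})

test_that("the S grid has the full shape contract for both models", {
  pan <- generate_panel(100, 600, seed = 67)
  tr <- simulate_trait(pan, n_cv = 100, s_true = -1, h2 = 0.5, seed = 29)
  scheme <- make_folds(100, "holdout91", seed = 7)
  res <- run_s_grid(pan, tr$phenotypes,
                    s_grid = c(-2, -1.5, -1, -0.5, 0, 0.5, 1),
                    model = c("gblup-s", "gblup-sms"), scheme = scheme,
                    truth = tr$tbv)
  expect_equal(nrow(res), 14)
  expect_equal(sum(res$model == "gblup-s"), 7)
  expect_true(all(res$converged))
  expect_true(all(is.na(res$chi_square[res$model == "gblup-s"])))
  expect_true(all(is.finite(res$chi_square[res$model == "gblup-sms"])))
  expect_true(all(is.finite(res$lrt)))

  agg <- aggregate_s_grid(res)
  expect_equal(nrow(agg), 14)

  # k-fold aggregation is a fold-size-weighted mean
  sch10 <- make_folds(100, "kfold10", seed = 11)
  res10 <- run_s_grid(pan, tr$phenotypes, s_grid = 0, model = "gblup-s",
                      scheme = sch10, truth = tr$tbv)
  expect_equal(nrow(res10), 10)
  expect_equal(sort(unique(res10$fold)), 1:10)
  agg10 <- aggregate_s_grid(res10)
  expect_equal(agg10$accuracy,
               sum(res10$accuracy * res10$fold_size) /
                 sum(res10$fold_size))
})
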