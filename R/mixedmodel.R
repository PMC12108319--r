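# REML variance-component estimation and BLUP prediction for models
#   y = 1*mu + sum_t a_t + e,  a_t ~ N(0, G_t sigma2_t),  e ~ N(0, I sigma2_e).
# One genomic component gives the GBLUP-S model; five MAF-bin components
# give GBLUP-SMS. The single-component case is solved exactly by
# eigendecomposition plus one-dimensional optimization of the heritability;
# the multi-component case by average-information (AI) REML with
# expectation-maximization fallback steps and non-negativity constraints.

.as_grm_list <- function(grms) {
  if (inherits(grms, "kinship_matrix")) grms <- list(grms)
  if (is.matrix(grms)) grms <- list(grms)
  lapply(grms, function(g) {
    v <- if (inherits(g, "kinship_matrix")) g$values else as.matrix(g)
    if (!isTRUE(all.equal(v, t(v), tolerance = 1e-8)))
      stop("GRM is not symmetric")
    v
  })
}

.check_psd <- function(g) {
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6 * max(abs(ev), 1))
    stop("GRM is not positive semi-definite within tolerance ",
         "(smallest eigenvalue ", format(min(ev)), ")")
  invisible(ev)
}

# Restricted log-likelihood of y ~ N(X b, V), X = intercept, V given.
# Returns list(loglik, P y, beta_hat). V_inv passed in.
.reml_ll_from_vinv <- function(y, v_inv, logdet_v) {
  n <- length(y)
  vx <- rowSums(v_inv)           # V^{-1} X for X = 1
  xvx <- sum(vx)
  vy <- drop(v_inv %*% y)
  beta <- sum(vx * y) / xvx
  py <- vy - vx * (sum(vx * y) / xvx)
  ypy <- sum(y * py)
  ll <- -0.5 * (logdet_v + log(xvx) + ypy + (n - 1) * log(2 * pi))
  list(loglik = ll, py = py, ypy = ypy, beta = beta, vx = vx, xvx = xvx)
}

# Null (residual-only) REML fit with intercept: closed form.
.fit_null <- function(y) {
  n <- length(y)
  ss <- sum((y - mean(y))^2)
  s2 <- ss / (n - 1)
  ll <- -0.5 * ((n - 1) * log(s2) + log(n) + (n - 1) +
                  (n - 1) * log(2 * pi))
  list(sigma_e2 = s2, loglik = ll)
}

# Single-GRM REML by eigendecomposition of G and profiling of the scale.
# Restricted likelihood in h2 with K = h2 G + (1 - h2) I:
#   l(h2) = -0.5[(n-1) log(sighat2) + log|K| + log(x'K^-1 x) + (n-1)(1+log 2pi)]
# with sighat2 = y' P_K y / (n - 1).
.fit_single_eigen <- function(y, g, eigen_g = NULL, n_grid = 101) {
  n <- length(y)
  if (is.null(eigen_g)) eigen_g <- eigen(g, symmetric = TRUE)
  d <- eigen_g$values
  u <- eigen_g$vectors
  yt <- drop(crossprod(u, y))
  xt <- drop(crossprod(u, rep(1, n)))

  profile <- function(h2) {
    w <- h2 * d + (1 - h2)
    if (min(w) <= 0) return(list(ll = -Inf))
    xkx <- sum(xt^2 / w)
    yky <- sum(yt^2 / w)
    ykx <- sum(yt * xt / w)
    ypy <- yky - ykx^2 / xkx
    s2 <- ypy / (n - 1)
    ll <- -0.5 * ((n - 1) * log(s2) + sum(log(w)) + log(xkx) +
                    (n - 1) + (n - 1) * log(2 * pi))
    list(ll = ll, s2 = s2)
  }

  hi <- 1 - 1e-8
  grid <- seq(0, hi, length.out = n_grid)
  ll_grid <- vapply(grid, function(h) profile(h)$ll, numeric(1))
  k <- which.max(ll_grid)
  lo_b <- grid[max(1, k - 1)]
  hi_b <- grid[min(n_grid, k + 1)]
  opt <- optimize(function(h) profile(h)$ll, lower = lo_b, upper = hi_b,
                  maximum = TRUE, tol = 1e-10)
  cand_h2 <- c(opt$maximum, 0, hi)
  cand_ll <- c(opt$objective, ll_grid[1], ll_grid[n_grid])
  best <- which.max(cand_ll)
  h2 <- cand_h2[best]
  pr <- profile(h2)
  sigma_p2 <- pr$s2
  list(sigma_a2 = h2 * sigma_p2, sigma_e2 = (1 - h2) * sigma_p2,
       h2 = h2, loglik = pr$ll, n_iter = n_grid, converged = TRUE)
}

# Multi-component AI-REML: average-information steps with step-halving
# against the restricted likelihood, EM fallback, and projection onto the
# non-negative boundary.
.fit_ai_reml <- function(y, g_list, max_iter = 200, tol_loglik = 1e-6,
                         tol_param = 1e-4, verbose = FALSE) {
  n <- length(y)
  k <- length(g_list)
  vp <- var(y)
  floor_v <- 1e-8 * vp
  theta <- rep(vp / (k + 1), k + 1)  # components 1..k genetic, k+1 residual
  one <- rep(1, n)

  # restricted loglik only (cholesky + two solves); used to vet a step
  ll_only <- function(th) {
    v <- diag(th[k + 1], n)
    for (i in seq_len(k)) v <- v + th[i] * g_list[[i]]
    ch <- tryCatch(chol(v), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    logdet_v <- 2 * sum(log(diag(ch)))
    vy <- backsolve(ch, forwardsolve(t(ch), y))
    vx <- backsolve(ch, forwardsolve(t(ch), one))
    xvx <- sum(vx)
    ypy <- sum(y * vy) - sum(vx * y)^2 / xvx
    -0.5 * (logdet_v + log(xvx) + ypy + (n - 1) * log(2 * pi))
  }

  # full state: loglik, Py, traces tr(P G_i), quadratics y'P G_i P y, AI
  state_at <- function(th) {
    v <- diag(th[k + 1], n)
    for (i in seq_len(k)) v <- v + th[i] * g_list[[i]]
    ch <- tryCatch(chol(v), error = function(e) NULL)
    if (is.null(ch))
      stop("covariance matrix not positive definite during REML; ",
           "check the GRMs")
    logdet_v <- 2 * sum(log(diag(ch)))
    v_inv <- chol2inv(ch)
    st <- .reml_ll_from_vinv(y, v_inv, logdet_v)
    p_full <- v_inv - tcrossprod(st$vx) / st$xvx
    py <- st$py
    gpy <- vector("list", k + 1)
    trpg <- numeric(k + 1)
    q <- numeric(k + 1)
    for (i in seq_len(k + 1)) {
      if (i <= k) {
        gpy[[i]] <- drop(g_list[[i]] %*% py)
        trpg[i] <- sum(p_full * g_list[[i]])
      } else {
        gpy[[i]] <- py
        trpg[i] <- sum(diag(p_full))
      }
      q[i] <- sum(py * gpy[[i]])
    }
    ai <- matrix(0, k + 1, k + 1)
    pu <- lapply(gpy, function(u) drop(p_full %*% u))
    for (i in seq_len(k + 1))
      for (j in i:(k + 1)) {
        ai[i, j] <- 0.5 * sum(gpy[[i]] * pu[[j]])
        ai[j, i] <- ai[i, j]
      }
    list(ll = st$loglik, trpg = trpg, q = q, ai = ai,
         grad = -0.5 * (trpg - q))
  }

  st <- state_at(theta)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    em_theta <- pmax(theta + theta^2 * (st$q - st$trpg) / n, floor_v)

    theta_new <- NULL
    if (iter > 1) {  # first step is EM, as is conventional
      # active set: components pinned at the zero boundary with a
      # negative gradient are held there and dropped from the AI system
      free <- !(theta <= floor_v * (1 + 1e-6) & st$grad < 0)
      free[k + 1] <- TRUE  # residual variance always free
      delta <- rep(0, k + 1)
      sol <- tryCatch(solve(st$ai[free, free, drop = FALSE],
                            st$grad[free]),
                      error = function(e) NULL)
      if (!is.null(sol) && all(is.finite(sol))) {
        delta[free] <- sol
        for (h in 0:6) {  # step halving against the restricted likelihood
          cand <- pmax(theta + delta / 2^h, floor_v)
          if (ll_only(cand) >= st$ll - 1e-10) {
            theta_new <- cand
            break
          }
        }
      }
    }
    if (is.null(theta_new)) theta_new <- em_theta

    st_new <- state_at(theta_new)
    max_rel_change <- max(abs(theta_new - theta) / pmax(theta, floor_v))
    dll <- st_new$ll - st$ll
    if (verbose)
      message(sprintf("iter %d: loglik = %.6f (change %.2e), theta = %s",
                      iter, st_new$ll, dll,
                      paste(sprintf("%.4g", theta_new), collapse = ", ")))
    theta <- theta_new
    st <- st_new
    if (abs(dll) < tol_loglik && max_rel_change < tol_param) {
      converged <- TRUE
      break
    }
  }
  list(sigma_a2 = theta[seq_len(k)], sigma_e2 = theta[k + 1],
       loglik = st$ll, n_iter = iter, converged = converged)
}

#' REML variance-component estimation for genomic mixed models
#'
#' Fits `y = mu + sum_t a_t + e` with `a_t ~ N(0, G_t sigma2_t)` by
#' restricted maximum likelihood. The fixed part is an intercept only
#' (phenotypes are assumed pre-adjusted for other fixed effects; the
#' intercept is still projected out for robustness). Variances are
#' constrained non-negative. With a single GRM the restricted likelihood
#' is profiled on the heritability after one eigendecomposition of `G`;
#' with several GRMs average-information updates are used, with
#' expectation-maximization fallback whenever an AI step would leave the
#' parameter space, until the restricted log-likelihood changes by less
#' than `tol_loglik` and parameters by less than `tol_param` (relative).
#'
#' @param y numeric phenotype vector (pre-adjusted; need not be exactly
#'   mean-zero).
#' @param grms a `kinship_matrix`, a plain symmetric matrix, or a list of
#'   these (one element per variance component). An empty list fits the
#'   residual-only null model.
#' @param eigen_g optional precomputed `eigen()` of the single GRM
#'   (symmetric = TRUE); ignored for multi-component fits. Useful when
#'   many traits are fitted against the same GRM.
#' @param max_iter iteration cap for the multi-component fit.
#' @param tol_loglik absolute convergence tolerance on the restricted
#'   log-likelihood.
#' @param tol_param relative convergence tolerance on the parameters.
#' @param check_psd verify positive semi-definiteness of each GRM first
#'   (an O(n^3) eigendecomposition per matrix; disable for speed).
#' @param verbose print per-iteration progress.
#' @return a `reml_fit`: list with `sigma_a2` (per-component vector),
#'   `sigma_e2`, `h2_total`, `h2_per_component`, `loglik`, `converged`,
#'   `n_iter`, `n`, and the phenotype vector `y` (used by [lrt()] to
#'   verify that two fits share data).
#' @export
fit_reml <- function(y, grms, eigen_g = NULL, max_iter = 200,
                     tol_loglik = 1e-6, tol_param = 1e-4,
                     check_psd = FALSE, verbose = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 10) stop("at least 10 phenotyped individuals are required")
  if (anyNA(y)) stop("phenotypes contain NA; subset before fitting")
  g_list <- if (is.null(grms) || (is.list(grms) && length(grms) == 0 &&
                                    !inherits(grms, "kinship_matrix")))
    list()
  else
    .as_grm_list(grms)
  for (g in g_list) {
    if (nrow(g) != n)
      stop("GRM dimension (", nrow(g), ") does not match phenotype length (",
           n, ")")
    if (check_psd) .check_psd(g)
  }

  k <- length(g_list)
  if (k == 0) {
    nf <- .fit_null(y)
    fit <- list(sigma_a2 = numeric(0), sigma_e2 = nf$sigma_e2,
                loglik = nf$loglik, n_iter = 0L, converged = TRUE)
  } else if (k == 1) {
    fit <- .fit_single_eigen(y, g_list[[1]], eigen_g = eigen_g)
    fit <- list(sigma_a2 = fit$sigma_a2, sigma_e2 = fit$sigma_e2,
                loglik = fit$loglik, n_iter = fit$n_iter,
                converged = fit$converged)
  } else {
    fit <- .fit_ai_reml(y, g_list, max_iter = max_iter,
                        tol_loglik = tol_loglik, tol_param = tol_param,
                        verbose = verbose)
  }

  total <- sum(fit$sigma_a2) + fit$sigma_e2
  structure(
    list(sigma_a2 = fit$sigma_a2,
         sigma_e2 = fit$sigma_e2,
         h2_total = if (k > 0) sum(fit$sigma_a2) / total else 0,
         h2_per_component = if (k > 0) fit$sigma_a2 / total else numeric(0),
         loglik = fit$loglik,
         converged = fit$converged,
         n_iter = fit$n_iter,
         n = n,
         n_components = k,
         y = y),
    class = "reml_fit"
  )
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("reml_fit:", x$n, "individuals,", x$n_components,
      "genetic component(s)\n")
  if (x$n_components > 0)
    for (t in seq_along(x$sigma_a2))
      cat(sprintf("  sigma_a2[%d] = %.6g (share %.4f)\n", t,
                  x$sigma_a2[t], x$h2_per_component[t]))
  cat(sprintf("  sigma_e2    = %.6g\n", x$sigma_e2))
  cat(sprintf("  h2 total    = %.4f\n", x$h2_total))
  cat(sprintf("  restricted loglik = %.4f (%s, %d iterations)\n",
              x$loglik, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  invisible(x)
}

#' Log-likelihood ratio statistic against the no-genetics null
#'
#' `2 * (loglik_full - loglik_null)`, floored at zero (the genetic
#' variances are boundary parameters, so sampling noise can make the raw
#' difference slightly negative). Both fits must be on the same phenotype
#' vector.
#'
#' @param full a [fit_reml()] result with genetic components.
#' @param null the residual-only fit of the same phenotypes
#'   (`fit_reml(y, list())`).
#' @return the LRT statistic (non-negative).
#' @export
lrt <- function(full, null) {
  stopifnot(inherits(full, "reml_fit"), inherits(null, "reml_fit"))
  if (full$n != null$n ||
      !isTRUE(all.equal(full$y, null$y, tolerance = 1e-12)))
    stop("full and null fits are not on the same phenotype vector")
  max(0, 2 * (full$loglik - null$loglik))
}

#' Boundary-corrected p-value for a single-component LRT
#'
#' Under the null the genetic variance sits on the boundary of the
#' parameter space, so the LRT is asymptotically a 50:50 mixture of a
#' point mass at zero and a 1-df chi-square. Only meaningful for
#' single-component models.
#'
#' @param stat an [lrt()] statistic.
#' @return the mixture p-value.
#' @export
lrt_pvalue <- function(stat) {
  if (stat < 0) stop("LRT statistic must be non-negative")
  if (stat == 0) return(1)
  0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
}

#' BLUP prediction of genomic breeding values for candidates
#'
#' Given variance components estimated on a training set and GRMs built
#' over the union of training and candidate individuals, predicts each
#' candidate's genetic value per component as
#' `a_t(cand) = sigma2_t G_t[cand, train] V^-1 (y - mu_hat)` with
#' `V = sum_t G_t[train, train] sigma2_t + I sigma2_e`, and the GEBV as
#' the sum over components. This is the conditional expectation of the
#' candidate genetic values and coincides with the mixed-model-equations
#' solution extended by the genomic covariance.
#'
#' @param fit a [fit_reml()] result from the training individuals.
#' @param grms_full a `kinship_matrix` or list of them over the union of
#'   training and candidate individuals.
#' @param y_train phenotypes of the training individuals (order matching
#'   `train_idx`).
#' @param train_idx integer index of training individuals within the GRM
#'   ordering.
#' @param cand_idx integer index of candidate individuals within the GRM
#'   ordering.
#' @return a `prediction_result`: list with `gebv` (per candidate),
#'   `individuals` (candidate IDs when available), and `model` provenance.
#' @export
predict_gebv <- function(fit, grms_full, y_train, train_idx, cand_idx) {
  stopifnot(inherits(fit, "reml_fit"))
  ids <- if (inherits(grms_full, "kinship_matrix"))
    grms_full$individuals
  else if (is.list(grms_full) && length(grms_full) &&
             inherits(grms_full[[1]], "kinship_matrix"))
    grms_full[[1]]$individuals
  else NULL
  g_list <- .as_grm_list(grms_full)
  k <- length(g_list)
  if (k != fit$n_components)
    stop("number of GRMs (", k, ") does not match fitted components (",
         fit$n_components, ")")
  if (length(y_train) != length(train_idx))
    stop("y_train and train_idx lengths differ")
  if (sum(fit$sigma_a2) + fit$sigma_e2 <= 0)
    stop("all variance components are zero; V is singular")

  nt <- length(train_idx)
  v <- diag(fit$sigma_e2, nt)
  for (t in seq_len(k))
    v <- v + fit$sigma_a2[t] * g_list[[t]][train_idx, train_idx]
  ch <- chol(v)
  v_inv <- chol2inv(ch)
  one <- rep(1, nt)
  vx <- drop(v_inv %*% one)
  mu <- sum(vx * y_train) / sum(vx)
  w <- drop(v_inv %*% (y_train - mu))

  gebv <- numeric(length(cand_idx))
  for (t in seq_len(k))
    gebv <- gebv +
      fit$sigma_a2[t] * drop(g_list[[t]][cand_idx, train_idx] %*% w)

  structure(
    list(gebv = gebv,
         individuals = if (!is.null(ids))
           ids[cand_idx, , drop = FALSE] else NULL,
         model = list(n_components = k, sigma_a2 = fit$sigma_a2,
                      sigma_e2 = fit$sigma_e2, mu = mu)),
    class = "prediction_result"
  )
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("prediction_result:", length(x$gebv), "candidates,",
      x$model$n_components, "component(s)\n")
  cat(sprintf("  GEBV range: %.4g .. %.4g\n", min(x$gebv), max(x$gebv)))
  invisible(x)
}
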