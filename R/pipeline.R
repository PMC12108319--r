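# Configuration handling and the end-to-end drivers behind the command
# line interface. A run configuration is a flat JSON object; CLI flags
# override file values. Every run writes its resolved configuration and
# seed next to its outputs so it can be re-executed exactly.

.default_config <- function() {
  list(
    subcommand = NA_character_,
    bfile = NA_character_,
    pheno = NA_character_,
    out = "selblup_out",
    master_seed = 1L,
    log_level = "info",
    # qc
    geno = 0.05, hwe = 1e-5, maf = 0.01,
    # grm
    s_value = 0, maf_stratify = FALSE,
    # simulate / synthetic panel
    synthetic_n = NA_integer_, synthetic_m = NA_integer_,
    n_cv = 1000, s_true = 0, h2 = 0.1, reps = 10,
    # fit / evaluate
    grm = NA_character_, model = "gblup-s",
    s_grid = c(-2, -1.5, -1, -0.5, 0, 0.5, 1),
    cv = "holdout91",
    # predict
    fit = NA_character_, train_ids = NA_character_,
    cand_ids = NA_character_
  )
}

#' Load, merge and validate a run configuration
#'
#' Reads a flat JSON configuration file (if given), overlays `overrides`
#' (typically parsed CLI flags; flags take precedence over file values),
#' and validates against the known schema. Unknown keys are an error
#' naming the offending field.
#'
#' @param path optional path to a JSON configuration file.
#' @param overrides named list of values overriding the file.
#' @return a validated `run_config` list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    file_cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    bad <- setdiff(names(file_cfg), names(cfg))
    if (length(bad))
      stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
    cfg[names(file_cfg)] <- file_cfg
  }
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  cfg[names(overrides)] <- overrides
  cfg$master_seed <- as.integer(cfg$master_seed)
  if (is.na(cfg$master_seed)) stop("configuration field master_seed: ",
                                   "integer required")
  structure(cfg, class = "run_config")
}

.log_msg <- function(cfg, stage, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"),
                  stage, paste0(...)))
}

.write_provenance <- function(cfg, out_dir) {
  resolved <- unclass(cfg)
  resolved$r_version <- as.character(getRversion())
  resolved$package_version <-
    as.character(utils::packageVersion("selblup"))
  jsonlite::write_json(resolved, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
}

.load_panel_for <- function(cfg, stage) {
  if (!is.na(cfg$bfile)) {
    .log_msg(cfg, stage, "reading PLINK trio ", cfg$bfile)
    compute_freqs(read_plink(cfg$bfile))
  } else if (!is.na(cfg$synthetic_n) && !is.na(cfg$synthetic_m)) {
    .log_msg(cfg, stage, "generating synthetic panel ",
             cfg$synthetic_n, " x ", cfg$synthetic_m)
    generate_panel(cfg$synthetic_n, cfg$synthetic_m,
                   seed = derive_seeds(cfg$master_seed, 1L))
  } else {
    stop("configuration field bfile (or synthetic_n/synthetic_m): ",
         "a genotype source is required for '", stage, "'")
  }
}

.pheno_for <- function(cfg, panel, stage) {
  if (is.na(cfg$pheno))
    stop("configuration field pheno: a phenotype file is required for '",
         stage, "'")
  ph <- read_phenotypes(cfg$pheno)
  key <- paste(panel$fam$fid, panel$fam$iid)
  idx <- match(key, paste(ph$fid, ph$iid))
  if (anyNA(idx))
    stop(sum(is.na(idx)), " genotyped individual(s) missing from the ",
         "phenotype file")
  ph$value[idx]
}

#' Run a pipeline stage from a configuration
#'
#' Dispatches on `config$subcommand`: `qc`, `grm`, `simulate`, `fit`,
#' `predict`, `evaluate` or `reproduce-sim`. Outputs are written under
#' `config$out` together with the resolved configuration
#' (`run_config.json`), so any run can be re-executed exactly.
#'
#' @param config a [load_config()] result (or a named list of the same
#'   shape).
#' @return invisibly, the path of the output directory.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    config <- load_config(overrides = config)
  sub <- config$subcommand
  known <- c("qc", "grm", "simulate", "fit", "predict", "evaluate",
             "reproduce-sim")
  if (is.na(sub) || !sub %in% known)
    stop("configuration field subcommand: must be one of ",
         paste(known, collapse = ", "))
  out_dir <- config$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  switch(sub,
    "qc" = .stage_qc(config, out_dir),
    "grm" = .stage_grm(config, out_dir),
    "simulate" = .stage_simulate(config, out_dir),
    "fit" = .stage_fit(config, out_dir),
    "predict" = .stage_predict(config, out_dir),
    "evaluate" = .stage_evaluate(config, out_dir),
    "reproduce-sim" = .stage_reproduce_sim(config, out_dir)
  )
  .write_provenance(config, out_dir)
  .log_msg(config, sub, "done; outputs in ", out_dir)
  invisible(out_dir)
}

.stage_qc <- function(cfg, out_dir) {
  panel <- .load_panel_for(cfg, "qc")
  res <- apply_qc(panel, max_missing_rate = cfg$geno,
                  hwe_p_threshold = cfg$hwe, min_maf = cfg$maf)
  prefix <- file.path(out_dir, "qc")
  write_plink(round_dosages(res$panel), prefix)
  rep_txt <- utils::capture.output(print(res$report))
  writeLines(rep_txt, file.path(out_dir, "qc_report.txt"))
  .log_msg(cfg, "qc", res$report$n_retained, " of ",
           res$report$n_input, " SNPs retained")
}

.stage_grm <- function(cfg, out_dir) {
  panel <- .load_panel_for(cfg, "grm")
  if (isTRUE(cfg$maf_stratify)) {
    grms <- build_stratified_grms(panel, cfg$s_value)
    for (nm in names(grms))
      write_grm(grms[[nm]], file.path(out_dir, paste0("grm_", nm)))
  } else {
    write_grm(build_grm(panel, cfg$s_value), file.path(out_dir, "grm"))
  }
}

.stage_simulate <- function(cfg, out_dir) {
  panel <- .load_panel_for(cfg, "simulate")
  seeds <- derive_seeds(cfg$master_seed, cfg$reps + 1L)[-1L]
  cv_rows <- list()
  for (r in seq_len(cfg$reps)) {
    tr <- simulate_trait(panel, n_cv = cfg$n_cv, s_true = cfg$s_true,
                         h2 = cfg$h2, seed = seeds[r])
    write_phenotypes(
      data.frame(fid = panel$fam$fid, iid = panel$fam$iid,
                 value = tr$phenotypes),
      file.path(out_dir, sprintf("pheno_rep%02d.txt", r)))
    write_phenotypes(
      data.frame(fid = panel$fam$fid, iid = panel$fam$iid,
                 value = tr$tbv),
      file.path(out_dir, sprintf("tbv_rep%02d.txt", r)))
    cv_rows[[r]] <- data.frame(
      replicate = r, snp_id = panel$snps$snp_id[tr$cv_indices],
      p = panel$freq_a[tr$cv_indices], effect = tr$effects)
  }
  write.table(do.call(rbind, cv_rows),
              file.path(out_dir, "causal_variants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

.stage_fit <- function(cfg, out_dir) {
  if (is.na(cfg$grm)) stop("configuration field grm: required for 'fit'")
  prefixes <- strsplit(cfg$grm, ",", fixed = TRUE)[[1]]
  grms <- lapply(prefixes, read_grm)
  ids <- grms[[1]]$individuals
  ph <- read_phenotypes(cfg$pheno)
  idx <- match(paste(ids$fid, ids$iid), paste(ph$fid, ph$iid))
  if (anyNA(idx)) stop("phenotypes missing for some GRM individuals")
  y <- ph$value[idx]
  fit <- fit_reml(y, grms)
  null <- fit_reml(y, list())
  stat <- lrt(fit, null)
  tab <- data.frame(
    component = c(seq_along(fit$sigma_a2), "residual"),
    variance = c(fit$sigma_a2, fit$sigma_e2),
    share = c(fit$h2_per_component, 1 - fit$h2_total),
    loglik = fit$loglik, lrt = stat, iterations = fit$n_iter,
    converged = fit$converged)
  write.table(tab, file.path(out_dir, "fit.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  saveRDS_path <- file.path(out_dir, "fit.json")
  jsonlite::write_json(
    list(sigma_a2 = fit$sigma_a2, sigma_e2 = fit$sigma_e2,
         h2_total = fit$h2_total, loglik = fit$loglik, lrt = stat,
         grm_prefixes = prefixes),
    saveRDS_path, auto_unbox = TRUE, digits = NA)
}

.stage_predict <- function(cfg, out_dir) {
  if (is.na(cfg$fit) || is.na(cfg$grm) || is.na(cfg$train_ids) ||
      is.na(cfg$cand_ids))
    stop("configuration fields fit, grm, train_ids, cand_ids: ",
         "all required for 'predict'")
  meta <- jsonlite::read_json(cfg$fit, simplifyVector = TRUE)
  prefixes <- strsplit(cfg$grm, ",", fixed = TRUE)[[1]]
  grms <- lapply(prefixes, read_grm)
  ids <- grms[[1]]$individuals
  key <- paste(ids$fid, ids$iid)
  read_ids <- function(p) {
    d <- read.table(p, header = FALSE, colClasses = "character")
    paste(d[[1]], d[[2]])
  }
  train <- match(read_ids(cfg$train_ids), key)
  cand <- match(read_ids(cfg$cand_ids), key)
  if (anyNA(train) || anyNA(cand))
    stop("train/candidate IDs not all present in the GRM")
  ph <- read_phenotypes(cfg$pheno)
  y_train <- ph$value[match(key[train], paste(ph$fid, ph$iid))]
  fit <- structure(
    list(sigma_a2 = meta$sigma_a2, sigma_e2 = meta$sigma_e2,
         n_components = length(meta$sigma_a2), n = length(train),
         y = y_train),
    class = "reml_fit")
  pred <- predict_gebv(fit, grms, y_train, train, cand)
  write.table(
    data.frame(ids[cand, ], gebv = pred$gebv),
    file.path(out_dir, "gebv.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
}

.stage_evaluate <- function(cfg, out_dir) {
  panel <- .load_panel_for(cfg, "evaluate")
  y <- .pheno_for(cfg, panel, "evaluate")
  mode <- if (identical(cfg$cv, "kfold10")) "kfold10" else "holdout91"
  scheme <- make_folds(n_individuals(panel), mode,
                       seed = derive_seeds(cfg$master_seed, 2L)[2])
  res <- run_s_grid(panel, y, s_grid = cfg$s_grid, model = cfg$model,
                    scheme = scheme)
  write.table(res, file.path(out_dir, "evaluate.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(aggregate_s_grid(res),
              file.path(out_dir, "evaluate_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

.stage_reproduce_sim <- function(cfg, out_dir) {
  res <- reproduce_simulation_study(
    n_individuals = if (is.na(cfg$synthetic_n)) 500L else cfg$synthetic_n,
    n_snps = if (is.na(cfg$synthetic_m)) 2000L else cfg$synthetic_m,
    n_cv = min(cfg$n_cv, 200L), h2 = cfg$h2,
    s_true_grid = cfg$s_grid, s_model_grid = cfg$s_grid,
    n_replicates = cfg$reps, master_seed = cfg$master_seed)
  write.table(res, file.path(out_dir, "simulation_study.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Reduced-scale reproduction of the simulation study
#'
#' Simulates traits at each true S on a synthetic panel, evaluates both
#' GBLUP-S and GBLUP-SMS across the model-S grid with a 9:1
#' reference/candidate split per replicate, and returns the tidy results
#' (accuracy, heritability, LRT, chi-square) for the boxplot-style
#' summaries of the study design.
#'
#' @param n_individuals,n_snps synthetic panel size.
#' @param n_cv causal variants per trait.
#' @param h2 simulated heritability.
#' @param s_true_grid true selection exponents to simulate.
#' @param s_model_grid model exponents to evaluate.
#' @param n_replicates replicates per true S.
#' @param master_seed master seed (panel, traits and folds derive from it).
#' @param models which models to evaluate.
#' @return data frame: one row per (true S, replicate, model, model S).
#' @export
reproduce_simulation_study <- function(n_individuals = 500,
                                       n_snps = 2000,
                                       n_cv = 200,
                                       h2 = 0.1,
                                       s_true_grid = c(-2, -1, 0, 1),
                                       s_model_grid =
                                         c(-2, -1.5, -1, -0.5, 0, 0.5, 1),
                                       n_replicates = 10,
                                       master_seed = 1L,
                                       models = c("gblup-s", "gblup-sms")) {
  seeds <- derive_seeds(master_seed,
                        1L + 2L * length(s_true_grid) * n_replicates)
  panel <- generate_panel(n_individuals, n_snps, seed = seeds[1])
  out <- list()
  si <- 1L
  for (s_true in s_true_grid) {
    for (r in seq_len(n_replicates)) {
      si <- si + 1L
      trait <- simulate_trait(panel, n_cv = n_cv, s_true = s_true,
                              h2 = h2, seed = seeds[si])
      si <- si + 1L
      scheme <- make_folds(n_individuals, "holdout91", seed = seeds[si])
      res <- run_s_grid(panel, trait$phenotypes, s_grid = s_model_grid,
                        model = models, scheme = scheme,
                        truth = trait$tbv)
      res$s_true <- s_true
      res$replicate <- r
      out[[length(out) + 1L]] <- res
    }
  }
  do.call(rbind, out)
}
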