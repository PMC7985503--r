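#' Configure an end-to-end pipeline run
#'
#' Bundles the generator settings and every analysis parameter for
#' [run_pipeline()].  Defaults follow the pipeline's standard analysis
#' settings: robust HC0 interaction inference with covariate
#' interactions, clumping at `r2 < 0.2` within 250 kb, the
#' `.001/.05/.1/.../1` threshold grid, and the genome-wide base alpha
#' `5e-8` corrected across environments.
#'
#' @param sim a [sim_config()]; its `holdout_n` defines the prediction
#'   split and its `seed` drives every stage.
#' @param covariates covariate columns used in the scans (default: all
#'   generated covariates).
#' @param envs environments to scan (default: all configured).
#' @param robust,hc interaction-test inference settings (see
#'   [design_spec()]).
#' @param clump_r2,clump_kb clumping parameters.
#' @param grid PRS p-value threshold grid.
#' @param base_alpha per-SNP base significance level (default 5e-8).
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim, covariates = NULL, envs = NULL, robust = TRUE,
                       hc = "HC0", clump_r2 = 0.2, clump_kb = 250,
                       grid = c(0.001, 0.05, seq(0.1, 1, 0.1)),
                       base_alpha = 5e-8) {
  stopifnot(inherits(sim, "sim_config"))
  envs <- envs %||% names(sim$environments)
  structure(list(sim = sim, covariates = covariates, envs = envs,
                 robust = robust, hc = hc, clump_r2 = clump_r2,
                 clump_kb = clump_kb, grid = grid,
                 base_alpha = base_alpha),
            class = "run_config")
}

#' Run the full pipeline
#'
#' simulate -> write PLINK/cohort -> QC -> per-environment interaction
#' scans and a main-effect GWAS on the training split -> clumping ->
#' score grids -> hold-out evaluation -> report.  Every output lands in
#' `out_dir` together with a manifest (seed, config fingerprint, package
#' version, per-stage counts); re-running with the same config reproduces
#' all outputs exactly.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the output directory; the `"results"` attribute
#'   holds the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline halted at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  counts <- list()

  sim <- stage("simulate", simulate_cohort(config$sim))
  stage("write", {
    write_plink(sim$genotypes, file.path(out_dir, "genotypes"))
    write_cohort(sim$cohort, file.path(out_dir, "cohort.tsv"))
  })
  counts$simulated_snps <- nrow(sim$genotypes$snps)
  counts$samples <- length(sim$genotypes$sample_ids)

  geno <- stage("qc", qc_filter(sim$genotypes))
  counts$snps_post_qc <- nrow(geno$snps)

  covars <- config$covariates %||% attr(sim$cohort, "schema")$covariates
  hold_mask <- sim$cohort$holdout
  train <- sim$cohort[!hold_mask, , drop = FALSE]
  attr(train, "schema") <- sim$schema
  class(train) <- class(sim$cohort)
  holdout <- sim$cohort[hold_mask, , drop = FALSE]
  attr(holdout, "schema") <- sim$schema
  class(holdout) <- class(sim$cohort)
  geno_train <- subset_genotypes(geno, samples = !hold_mask)
  geno_hold <- subset_genotypes(geno, samples = hold_mask)

  gweis <- list()
  for (env in config$envs) {
    spec <- design_spec(env, covars, robust = config$robust,
                        hc = config$hc)
    ss <- stage(paste0("gweis:", env), run_gweis(geno_train, train, spec))
    write_summary_stats(ss, file.path(out_dir,
                                      paste0("gweis_", env, ".tsv")))
    gweis[[env]] <- ss
  }
  counts$gweis_rows <- vapply(gweis, nrow, integer(1))

  gwas <- stage("gwas", run_gwas(geno_train, train, covars))
  write_summary_stats(gwas, file.path(out_dir, "gwas.tsv"))
  counts$gwas_rows <- nrow(gwas)

  evals <- list()
  if (nrow(holdout) > 0) {
    prs_models <- stage("prs", build_threshold_grid(
      gwas, geno_train, kind = "PRS", grid = config$grid,
      r2_threshold = config$clump_r2, window_kb = config$clump_kb))
    prs_eval <- stage("evaluate", evaluate_grid(
      prs_models, geno_hold, holdout, covariates = covars))
    evals[["PRS"]] <- prs_eval
    best_prs_row <- if (nrow(prs_eval)) select_best_threshold(prs_eval)
                    else NULL
    best_prs_score <- if (!is.null(best_prs_row)) {
      score_prs(geno_hold,
                prs_models[[as.character(best_prs_row$threshold)]])
    } else NULL

    for (env in config$envs) {
      im <- stage(paste0("iprs:", env), build_threshold_grid(
        gweis[[env]], geno_train, kind = "iPRS_GxE", grid = config$grid,
        r2_threshold = config$clump_r2, window_kb = config$clump_kb))
      if (!is.null(best_prs_score)) {
        evals[[paste0("iPRS_GxE:", env)]] <- stage(
          paste0("evaluate:", env),
          evaluate_grid(im, geno_hold, holdout, covariates = covars,
                        env = env, prs_grid = best_prs_score))
        gm <- build_threshold_grid(
          gwas, geno_train, kind = "iPRS_G", grid = config$grid,
          r2_threshold = config$clump_r2, window_kb = config$clump_kb)
        evals[[paste0("iPRS_G:", env)]] <- stage(
          paste0("evaluate:", env),
          evaluate_grid(gm, geno_hold, holdout, covariates = covars,
                        env = env, prs_grid = best_prs_score))
      }
    }
    for (nm in names(evals)) {
      utils::write.table(evals[[nm]],
                         file.path(out_dir, paste0(
                           "prs_eval_", gsub("[^A-Za-z0-9_]", "_", nm),
                           ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- list(
    seed = config$sim$seed,
    config_fingerprint = config_fingerprint(config),
    package_version = as.character(utils::packageVersion("gweisr")),
    counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  results <- list(sim = sim, geno = geno, gweis = gweis, gwas = gwas,
                  evals = evals, counts = counts)
  out <- out_dir
  attr(out, "results") <- results
  invisible(out)
}

# FNV-1a over the serialised config; a stable fingerprint for manifests
config_fingerprint <- function(config) {
  bytes <- serialize(unclass(config), NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Summarise a pipeline run
#'
#' Reads the summary statistics and score evaluations in a run directory
#' and builds the per-environment significance tables (at the
#' per-analysis and cross-environment thresholds), the genomic inflation
#' factors, and the best score-threshold rows.  Regeneration is
#' idempotent: the report is a pure function of the run directory.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @param base_alpha per-SNP base alpha (default 5e-8).
#' @param n_environments environments analysed (default: the number of
#'   interaction-scan files found).
#' @return A list of class `gweis_report`: `significant` (data.frame),
#'   `lambda` (per-scan), `prs` (best rows per score family),
#'   `thresholds`.
#' @export
report <- function(run_dir, base_alpha = 5e-8, n_environments = NULL) {
  gweis_files <- list.files(run_dir, "^gweis_.*\\.tsv$", full.names = TRUE)
  n_env <- n_environments %||% max(length(gweis_files), 1L)
  thr1 <- bonferroni_threshold(base_alpha, "per-analysis", n_tests = 1)
  thr2 <- bonferroni_threshold(base_alpha, "cross-environment",
                               n_tests = 1, n_environments = n_env)

  sig <- list(); lam <- c()
  for (f in gweis_files) {
    ss <- read_summary_stats(f)
    env <- if (nrow(ss)) ss$ENV[1] else sub("^gweis_(.*)\\.tsv$", "\\1",
                                            basename(f))
    lam[env] <- genomic_lambda(ss$P_GXE)
    hit <- ss[!is.na(ss$P_GXE) & ss$P_GXE < thr1, , drop = FALSE]
    if (nrow(hit)) {
      hit$cross_env_significant <- hit$P_GXE < thr2
      sig[[env]] <- hit
    }
  }
  gwas_path <- file.path(run_dir, "gwas.tsv")
  if (file.exists(gwas_path)) {
    gw <- read_summary_stats(gwas_path)
    lam["GWAS"] <- genomic_lambda(gw$P_G)
  }

  eval_files <- list.files(run_dir, "^prs_eval_.*\\.tsv$",
                           full.names = TRUE)
  prs_best <- list()
  for (f in eval_files) {
    ev <- utils::read.table(f, header = TRUE, sep = "\t")
    if (nrow(ev)) {
      prs_best[[sub("^prs_eval_(.*)\\.tsv$", "\\1", basename(f))]] <-
        select_best_threshold(ev)
    }
  }

  structure(list(
    significant = if (length(sig)) do.call(rbind, sig) else
      empty_sumstats("gweis"),
    lambda = lam,
    prs = prs_best,
    thresholds = c(per_analysis = thr1, cross_environment = thr2,
                   iprs = bonferroni_threshold(0.05, "iprs",
                                               n_environments = n_env))),
    class = "gweis_report")
}

#' @export
print.gweis_report <- function(x, ...) {
  cat("<gweis_report>\n")
  cat(sprintf("  thresholds: per-analysis %.3g, cross-environment %.3g, score %.3g\n",
              x$thresholds["per_analysis"], x$thresholds["cross_environment"],
              x$thresholds["iprs"]))
  cat(sprintf("  significant interaction SNPs (per-analysis): %d\n",
              nrow(x$significant)))
  if (length(x$lambda)) {
    cat("  genomic inflation:\n")
    for (nm in names(x$lambda)) {
      cat(sprintf("    %s: %.3f\n", nm, x$lambda[nm]))
    }
  }
  for (nm in names(x$prs)) {
    b <- x$prs[[nm]]
    cat(sprintf("  %s: best threshold %.3g, delta adj-R2 %.4g (p = %.3g)\n",
                nm, b$threshold, b$delta_adj_r2, b$p))
  }
  invisible(x)
}
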