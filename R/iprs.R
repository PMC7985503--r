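#' Construct a polygenic score model
#'
#' A score model is a weighted SNP set of one of four kinds:
#' * `PRS` -- main-effect score, weights are GWAS main-effect betas;
#' * `iPRS_G` -- the main-effect score multiplied by the environment;
#' * `iPRS_GxE` -- weights are interaction betas, the weighted allele
#'   count is multiplied by the environment;
#' * `iPRS_G_plus_GxE` -- as `iPRS_GxE` plus the (unmultiplied)
#'   main-effect term from the same interaction scan.
#'
#' Models remember the training sample ids their weights came from so
#' that evaluation can refuse hold-out samples that overlap the training
#' split (leakage guard).
#'
#' @param kind score kind (see above).
#' @param weights data.frame with columns `snp`, `effect_allele`, `beta`
#'   (and `beta_g` for `iPRS_G_plus_GxE`); optionally `eaf`, the training
#'   effect-allele frequency used to impute missing dosages.
#' @param p_threshold the p-value threshold the SNP set was selected at.
#' @param source free-text provenance (e.g. `"GWAS"` or
#'   `"GWEIS(env1)"`).
#' @param training_ids sample ids of the split the weights derive from.
#' @return A list of class `prs_model`.
#' @export
prs_model <- function(kind = c("PRS", "iPRS_G", "iPRS_GxE",
                               "iPRS_G_plus_GxE"),
                      weights, p_threshold = 1, source = "",
                      training_ids = character()) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(weights),
            all(c("snp", "effect_allele", "beta") %in% names(weights)))
  if (anyDuplicated(weights$snp)) stop("duplicate SNP ids in weights")
  if (any(!is.finite(weights$beta))) stop("non-finite beta in weights")
  if (kind == "iPRS_G_plus_GxE" && is.null(weights$beta_g)) {
    stop("iPRS_G_plus_GxE weights need a beta_g column")
  }
  structure(list(kind = kind, weights = weights,
                 p_threshold = p_threshold, source = source,
                 training_ids = as.character(training_ids)),
            class = "prs_model")
}

# align model weights to the genotype matrix: returns dosage matrix
# (samples x model SNPs) counting the model's effect allele, with missing
# entries imputed as 2 * effect-allele frequency (training eaf when the
# model carries one, otherwise the scoring-sample frequency)
aligned_dosages <- function(geno, model) {
  w <- model$weights
  pos <- match(w$snp, geno$snps$id)
  if (anyNA(pos)) {
    stop("model SNP(s) absent from genotypes: ",
         paste(utils::head(w$snp[is.na(pos)], 5), collapse = ", "))
  }
  D <- geno$dosages[, pos, drop = FALSE]
  same <- geno$snps$effect_allele[pos] == w$effect_allele
  flipped <- geno$snps$other_allele[pos] == w$effect_allele
  if (any(!same & !flipped)) {
    stop("unresolvable allele mismatch for SNP(s): ",
         paste(utils::head(w$snp[!same & !flipped], 5), collapse = ", "))
  }
  if (any(flipped & !same)) {
    fl <- which(flipped & !same)
    D[, fl] <- 2 - D[, fl, drop = FALSE]
  }
  if (anyNA(D)) {
    fill <- if (!is.null(w$eaf)) 2 * w$eaf else colMeans(D, na.rm = TRUE)
    for (j in which(colSums(is.na(D)) > 0)) {
      D[is.na(D[, j]), j] <- fill[j]
    }
  }
  D
}

#' Compute a main-effect polygenic score
#'
#' The weighted effect-allele count `PRS_i = sum_j G_ij beta_j` over the
#' model's SNPs.  Alleles are aligned to the model's effect allele
#' (dosages flipped where the genotype file counts the other allele);
#' missing dosages contribute their mean-imputed value.
#'
#' @param geno a [genotype_matrix()] containing every model SNP.
#' @param model a [prs_model()].
#' @return Named numeric vector of per-sample scores, carrying the
#'   model's training ids as attribute `"training_ids"`.
#' @export
score_prs <- function(geno, model) {
  stopifnot(inherits(model, "prs_model"))
  D <- aligned_dosages(geno, model)
  s <- drop(D %*% model$weights$beta)
  names(s) <- geno$sample_ids
  attr(s, "training_ids") <- model$training_ids
  s
}

#' Compute an interaction-based polygenic score
#'
#' * `iPRS_G`: the main-effect score times the sample's environment,
#'   `PRS_i * E_i`.
#' * `iPRS_GxE`: the interaction-weighted allele count times the
#'   environment, `E_i * sum_j G_ij beta_j^GxE`.
#' * `iPRS_G_plus_GxE`: adds the main-effect term,
#'   `E_i * sum_j G_ij beta_j^GxE + sum_j G_ij beta_j^G`.
#'
#' @param geno a [genotype_matrix()].
#' @param E per-sample environment vector aligned with `geno`.
#' @param model a [prs_model()] of an interaction kind.
#' @return Named numeric score vector with a `"training_ids"` attribute.
#' @export
score_iprs <- function(geno, E, model) {
  stopifnot(inherits(model, "prs_model"))
  if (length(E) != length(geno$sample_ids)) {
    stop("environment vector length must match sample count")
  }
  s <- switch(model$kind,
    iPRS_G = unclass(score_prs(geno, model)) * E,
    iPRS_GxE = {
      D <- aligned_dosages(geno, model)
      E * drop(D %*% model$weights$beta)
    },
    iPRS_G_plus_GxE = {
      D <- aligned_dosages(geno, model)
      E * drop(D %*% model$weights$beta) + drop(D %*% model$weights$beta_g)
    },
    stop("score_iprs needs an interaction-kind model, got ", model$kind))
  names(s) <- geno$sample_ids
  attr(s, "training_ids") <- model$training_ids
  s
}

#' Build score models across a p-value threshold grid
#'
#' Clumps the training summary statistics (defaults `r2 < 0.2`, 250 kb)
#' and builds one [prs_model()] per grid threshold containing the index
#' SNPs with `p <= threshold`.  Models are nested along the grid.
#'
#' @param stats training summary statistics (main-effect dialect for
#'   `PRS`/`iPRS_G`, interaction dialect for the `iPRS_GxE` kinds).
#' @param geno training-split [genotype_matrix()] (LD reference and
#'   allele-frequency source).
#' @param kind score kind; decides which beta column is used as weight.
#' @param grid p-value thresholds (default `.001, .05, .1, .2, ..., 1`).
#' @param r2_threshold,window_kb clumping parameters.
#' @return Named list of [prs_model()]s (possibly with zero SNPs at
#'   strict thresholds), names = grid values.
#' @export
build_threshold_grid <- function(stats, geno,
                                 kind = c("PRS", "iPRS_G", "iPRS_GxE",
                                          "iPRS_G_plus_GxE"),
                                 grid = c(0.001, 0.05, seq(0.1, 1, 0.1)),
                                 r2_threshold = 0.2, window_kb = 250) {
  kind <- match.arg(kind)
  pcol <- if ("P_GXE" %in% names(stats)) "P_GXE" else "P_G"
  wanted <- if (kind %in% c("PRS", "iPRS_G")) "BETA_G" else "BETA_GXE"
  if (!wanted %in% names(stats)) {
    stop(kind, " models need the ", wanted, " column (wrong dialect?)")
  }
  idx <- clump(stats, geno, r2_threshold = r2_threshold,
               window_kb = window_kb, p_threshold = max(grid))
  keep <- match(idx$snp, stats$SNP)
  eaf <- snp_summaries(geno$dosages)$eaf[match(stats$SNP[keep],
                                               geno$snps$id)]
  base <- data.frame(snp = stats$SNP[keep],
                     effect_allele = stats$A1[keep],
                     beta = stats[[wanted]][keep],
                     eaf = eaf, p = stats[[pcol]][keep],
                     stringsAsFactors = FALSE)
  if (kind == "iPRS_G_plus_GxE") base$beta_g <- stats$BETA_G[keep]
  src <- if (pcol == "P_G") "GWAS" else
    paste0("GWEIS(", stats$ENV[1] %||% "", ")")
  models <- lapply(grid, function(th) {
    w <- base[base$p <= th, setdiff(names(base), "p"), drop = FALSE]
    prs_model(kind, w, p_threshold = th, source = src,
              training_ids = geno$sample_ids)
  })
  names(models) <- as.character(grid)
  models
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - R2) (n - 1) / (n - p - 1)` for `p` predictors beside the
#' intercept; preferred over the raw R-squared when comparing models with
#' many predictors, since it estimates the population explained variance
#' without the mechanical increase from added regressors.  May be
#' negative.
#'
#' @param r2 raw R-squared.
#' @param n sample size.
#' @param p_predictors number of predictors excluding the intercept.
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, p_predictors) {
  stopifnot(n > p_predictors + 1)
  1 - (1 - r2) * (n - 1) / (n - p_predictors - 1)
}

#' Evaluate a polygenic score in the hold-out sample
#'
#' Fits the covariate-only and the full (score-added) linear models and
#' reports the increment in adjusted R-squared plus the nested-model
#' F-test.  For the plain `PRS` the covariate-only model is the base
#' covariates alone.  For interaction scores the covariate-only model
#' additionally contains the main-effect PRS, the environment, and their
#' interactions with every base covariate -- mirroring the scan's own
#' confounder control -- so the interaction score is only credited with
#' variance beyond all main effects.
#'
#' @param holdout hold-out `cohort_table`.
#' @param score per-sample score (named by sample id, as returned by
#'   [score_prs()]/[score_iprs()]).
#' @param kind score kind.
#' @param env environment column name (interaction kinds only).
#' @param covariates base covariate column names.
#' @param prs main-effect PRS vector named by sample id (interaction
#'   kinds only).
#' @return A list of class `prs_evaluation`: `kind`, `env`,
#'   `p_threshold`, `delta_adj_r2`, `F`, `p`, `n`, `n_snps`.
#' @export
evaluate_prs <- function(holdout, score, kind = "PRS", env = NULL,
                         covariates = character(), prs = NULL) {
  sc <- attr(holdout, "schema")
  if (is.null(sc)) stop("holdout must carry a schema (see as_cohort_table)")
  ids <- holdout[[sc$id]]
  train_ids <- attr(score, "training_ids")
  if (!is.null(train_ids) && length(intersect(ids, train_ids))) {
    stop("hold-out sample overlaps the training split the score weights ",
         "were estimated in; refusing to evaluate (leakage guard)")
  }
  s <- unclass(score)[ids]
  if (anyNA(match(ids, names(score)))) {
    stop("score is missing value(s) for hold-out sample(s)")
  }
  y <- holdout[[sc$phenotype]]
  C <- if (length(covariates)) {
    as.matrix(holdout[, covariates, drop = FALSE])
  } else matrix(numeric(0), length(y), 0)

  if (kind == "PRS") {
    X0 <- cbind(`(Intercept)` = 1, C)
  } else {
    if (is.null(env) || is.null(prs)) {
      stop("interaction-score evaluation needs env and the main-effect prs")
    }
    e <- holdout[[env]]
    pr <- unclass(prs)[ids]
    X0 <- cbind(`(Intercept)` = 1, C, PRS = pr, E = e)
    if (ncol(C) > 0) {
      PxC <- C * pr; colnames(PxC) <- paste0(colnames(C), ":PRS")
      ExC <- C * e; colnames(ExC) <- paste0(colnames(C), ":E")
      X0 <- cbind(X0, PxC, ExC)
    }
  }
  X1 <- cbind(X0, score = s)
  mask <- !is.na(y) & stats::complete.cases(X1)
  y <- y[mask]; X0 <- X0[mask, , drop = FALSE]; X1 <- X1[mask, , drop = FALSE]
  n <- length(y)

  fit0 <- ols_fit(X0, y)
  fit1 <- tryCatch(ols_fit(X1, y), gweisr_rank_error = function(cnd) {
    stop("full evaluation model is rank deficient (score collinear with ",
         "covariates): ", conditionMessage(cnd))
  })
  tss <- sum((y - mean(y))^2)
  rss0 <- sum(fit0$residuals^2)
  rss1 <- sum(fit1$residuals^2)
  r2_0 <- 1 - rss0 / tss
  r2_1 <- 1 - rss1 / tss
  d_adj <- adjusted_r2(r2_1, n, ncol(X1) - 1) -
    adjusted_r2(r2_0, n, ncol(X0) - 1)
  df2 <- n - ncol(X1)
  Fstat <- (rss0 - rss1) / (rss1 / df2)
  pval <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  structure(list(kind = kind, env = env,
                 p_threshold = attr(score, "p_threshold"),
                 delta_adj_r2 = d_adj, F = Fstat, p = pval, n = n,
                 n_snps = attr(score, "n_snps")),
            class = "prs_evaluation")
}

#' Evaluate a model grid and pick the best threshold
#'
#' Scores each grid model in the hold-out sample, evaluates it, and
#' returns the per-threshold table.  Empty models (no SNP passes the
#' threshold) are skipped with a note.
#'
#' @param models named list from [build_threshold_grid()].
#' @param geno_holdout hold-out [genotype_matrix()].
#' @param holdout hold-out `cohort_table`.
#' @param covariates base covariate names.
#' @param env environment column (interaction kinds).
#' @param prs_grid for interaction kinds, the main-effect PRS to use as
#'   covariate (single vector applied at every threshold).
#' @return data.frame with one row per evaluated threshold
#'   (`threshold`, `n_snps`, `delta_adj_r2`, `F`, `p`, `n`).
#' @export
evaluate_grid <- function(models, geno_holdout, holdout,
                          covariates = character(), env = NULL,
                          prs_grid = NULL) {
  rows <- list()
  for (nm in names(models)) {
    mod <- models[[nm]]
    if (nrow(mod$weights) == 0) next
    s <- if (mod$kind == "PRS") {
      score_prs(geno_holdout, mod)
    } else {
      score_iprs(geno_holdout, holdout[[env]][
        match(geno_holdout$sample_ids, holdout[[attr(holdout, "schema")$id]])],
        mod)
    }
    attr(s, "p_threshold") <- mod$p_threshold
    attr(s, "n_snps") <- nrow(mod$weights)
    ev <- evaluate_prs(holdout, s, kind = mod$kind, env = env,
                       covariates = covariates, prs = prs_grid)
    rows[[nm]] <- data.frame(threshold = as.numeric(nm),
                             n_snps = nrow(mod$weights),
                             delta_adj_r2 = ev$delta_adj_r2,
                             F = ev$F, p = ev$p, n = ev$n)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(threshold = numeric(), n_snps = integer(),
               delta_adj_r2 = numeric(), F = numeric(), p = numeric(),
               n = integer())
  rownames(out) <- NULL
  out
}

#' Select the best-predicting threshold
#'
#' Maximises the adjusted-R-squared increment over the evaluated grid;
#' exact ties go to the smallest (most parsimonious) threshold.
#'
#' @param evaluations data.frame from [evaluate_grid()].
#' @return The winning row.
#' @export
select_best_threshold <- function(evaluations) {
  if (nrow(evaluations) == 0) stop("no evaluations to select from")
  ord <- order(-evaluations$delta_adj_r2, evaluations$threshold)
  evaluations[ord[1], , drop = FALSE]
}
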