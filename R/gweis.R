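#' Specify the per-SNP interaction design
#'
#' Describes one scan: which environment column interacts with each SNP,
#' which covariates enter, and how inference is done.  With covariate
#' interactions enabled (the default, and the recommended setting) the
#' design has `4 + 3k` columns for `k` covariates -- intercept, SNP,
#' environment, SNP-by-environment, covariate main effects, and
#' covariate-by-SNP plus covariate-by-environment interactions.  Covariate
#' main effects alone do not control confounding of the interaction term:
#' a covariate that both moderates the SNP effect and correlates with the
#' environment leaks into the SNP-by-environment coefficient unless its
#' own interactions are modelled.
#'
#' @param env environment column name.
#' @param covariates covariate column names.
#' @param covariate_interactions include covariate-by-SNP and
#'   covariate-by-environment terms (default `TRUE`).
#' @param robust use heteroscedasticity-robust (sandwich) standard errors
#'   (default `TRUE`); `FALSE` gives classical model-based errors.
#' @param hc sandwich variant: `"HC0"` (raw squared residuals, default)
#'   or `"HC1"` (scaled by `n/(n-p)`).
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(env, covariates = character(),
                        covariate_interactions = TRUE, robust = TRUE,
                        hc = c("HC0", "HC1")) {
  hc <- match.arg(hc)
  structure(list(env = env, covariates = covariates,
                 covariate_interactions = covariate_interactions,
                 robust = robust, hc = hc),
            class = "design_spec")
}

#' Build the per-SNP design matrix
#'
#' Assembles columns in the fixed order
#' `[1, G, E, GxE, C..., CxG..., CxE...]` and drops rows with any missing
#' value in the outcome, dosage, environment or covariates (listwise,
#' per SNP -- complete-case n may therefore differ across SNPs).
#'
#' @param g dosage vector for one SNP.
#' @param e environment vector.
#' @param C covariate matrix (or `NULL`).
#' @param y outcome vector.
#' @param covariate_interactions include the `CxG`/`CxE` blocks.
#' @return `list(X, y, mask)` where `mask` marks the retained rows.
#' @export
build_design <- function(g, e, C = NULL, y,
                         covariate_interactions = TRUE) {
  n <- length(y)
  if (length(g) != n || length(e) != n) stop("column length mismatch")
  C <- if (is.null(C)) matrix(numeric(0), n, 0) else as.matrix(C)
  if (nrow(C) != n) stop("column length mismatch")
  mask <- !(is.na(y) | is.na(g) | is.na(e))
  if (ncol(C) > 0) mask <- mask & stats::complete.cases(C)

  gs <- g[mask]; es <- e[mask]; Cs <- C[mask, , drop = FALSE]
  X <- cbind(1, gs, es, gs * es)
  colnames(X) <- c("(Intercept)", "G", "E", "GxE")
  if (ncol(Cs) > 0) {
    cn <- colnames(Cs) %||% paste0("C", seq_len(ncol(Cs)))
    colnames(Cs) <- cn
    X <- cbind(X, Cs)
    if (covariate_interactions) {
      CxG <- Cs * gs; colnames(CxG) <- paste0(cn, ":G")
      CxE <- Cs * es; colnames(CxE) <- paste0(cn, ":E")
      X <- cbind(X, CxG, CxE)
    }
  }
  if (sum(mask) < ncol(X) + 1) {
    stop(errorCondition(
      sprintf("under-determined design: %d complete cases for %d columns",
              sum(mask), ncol(X)),
      class = c("gweisr_underdetermined", "gweisr_rank_error")))
  }
  list(X = X, y = y[mask], mask = mask)
}

#' Ordinary least squares fit with rank checking
#'
#' QR-based least squares; a rank-deficient design (monomorphic SNP,
#' constant environment, collinear covariates) raises a condition of
#' class `gweisr_rank_error` so genome-wide scans can skip the SNP with a
#' logged reason instead of aborting.
#'
#' @param X design matrix.
#' @param y outcome vector.
#' @return `list(coefficients, residuals, fitted, qr, n, p)`.
#' @export
ols_fit <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop(errorCondition(
      sprintf("rank-deficient design (rank %d < %d columns)",
              qx$rank, ncol(X)),
      class = "gweisr_rank_error"))
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  list(coefficients = beta, residuals = y - fitted, fitted = fitted,
       qr = qx, n = nrow(X), p = ncol(X))
}

#' Huber-White sandwich covariance of OLS coefficients
#'
#' Classical model-based standard errors assume a single residual
#' variance for all observations; the sandwich estimator instead allows a
#' unique residual variance per observation, approximated by the squared
#' residual:
#' \deqn{(X'X)^{-1} X' \mathrm{diag}(e_i^2) X (X'X)^{-1}}
#' `"HC0"` uses the raw squared residuals; `"HC1"` applies the
#' finite-sample scale `n/(n-p)`.
#'
#' @param X design matrix.
#' @param residuals OLS residuals for this design.
#' @param type `"HC0"` (default) or `"HC1"`.
#' @return Symmetric positive semi-definite covariance matrix of the
#'   coefficients.
#' @export
sandwich_cov <- function(X, residuals, type = c("HC0", "HC1")) {
  type <- match.arg(type)
  X <- as.matrix(X)
  R <- qr.R(qr(X))
  xtx_inv <- chol2inv(R)
  meat <- crossprod(X * residuals)
  V <- xtx_inv %*% meat %*% xtx_inv
  if (type == "HC1") {
    n <- nrow(X); p <- ncol(X)
    V <- V * n / (n - p)
  }
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

# model-based covariance sigma^2 (X'X)^-1
model_cov <- function(X, residuals) {
  R <- qr.R(qr(X))
  xtx_inv <- chol2inv(R)
  n <- nrow(X); p <- ncol(X)
  s2 <- sum(residuals^2) / (n - p)
  V <- s2 * xtx_inv
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' Test one coefficient with a t reference
#'
#' Two-sided t-test of a fitted coefficient using either the sandwich or
#' the model-based covariance, with `df = n - p`.  The t rather than the
#' normal reference is negligible at biobank sample sizes but correct at
#' the small n of simulation fixtures.
#'
#' @param fit an [ols_fit()] result.
#' @param X the design matrix the fit came from.
#' @param coef name (or index) of the tested coefficient; default
#'   `"GxE"`, the interaction term of interest.
#' @param robust sandwich (`TRUE`) or model-based (`FALSE`) covariance.
#' @param hc sandwich variant.
#' @return `list(estimate, se, statistic, p, df)`.
#' @export
test_coefficient <- function(fit, X, coef = "GxE", robust = TRUE,
                             hc = "HC0") {
  V <- if (robust) sandwich_cov(X, fit$residuals, hc)
       else model_cov(X, fit$residuals)
  j <- if (is.character(coef)) match(coef, colnames(X)) else coef
  if (is.na(j)) stop("coefficient not in design: ", coef)
  est <- unname(fit$coefficients[j])
  se <- sqrt(V[j, j])
  df <- fit$n - fit$p
  tstat <- if (est == 0) 0 else est / se
  p <- 2 * stats::pt(-abs(tstat), df = df)
  list(estimate = est, se = se, statistic = tstat, p = p, df = df)
}

#' Genome-wide SNP-by-environment interaction scan
#'
#' Fits the full interaction model for every SNP against one environment
#' and tests the SNP-by-environment coefficient with
#' heteroscedasticity-robust standard errors (per `spec`).  SNPs whose
#' design is rank deficient (monomorphic dosage, constant environment
#' after listwise deletion, ...) are skipped and logged, not fatal.
#'
#' @param geno a [genotype_matrix()] (QC'd; see [qc_filter()]).
#' @param cohort a `cohort_table` whose schema declares the phenotype and
#'   the environment/covariate columns named in `spec`.
#' @param spec a [design_spec()].
#' @return Summary statistics (interaction dialect, one row per analysed
#'   SNP; see [write_summary_stats()]).  Skipped SNPs are recorded in the
#'   `"skipped"` attribute as a data.frame of (id, reason).
#' @export
run_gweis <- function(geno, cohort, spec) {
  stopifnot(inherits(geno, "genotype_matrix"),
            inherits(spec, "design_spec"))
  sc <- attr(cohort, "schema")
  if (is.null(sc)) stop("cohort must carry a schema (see as_cohort_table)")
  if (!spec$env %in% names(cohort)) {
    stop("environment column absent from cohort: ", spec$env)
  }
  aligned <- align_cohort(geno, cohort, sc)
  y <- aligned$cohort[[sc$phenotype]]
  e <- aligned$cohort[[spec$env]]
  C <- if (length(spec$covariates)) {
    as.matrix(aligned$cohort[, spec$covariates, drop = FALSE])
  } else NULL

  m <- nrow(geno$snps)
  rows <- vector("list", m)
  skipped <- list()
  for (j in seq_len(m)) {
    g <- aligned$dosages[, j]
    res <- tryCatch({
      d <- build_design(g, e, C, y, spec$covariate_interactions)
      fit <- ols_fit(d$X, d$y)
      V <- if (spec$robust) sandwich_cov(d$X, fit$residuals, spec$hc)
           else model_cov(d$X, fit$residuals)
      est <- unname(fit$coefficients[4])
      se <- sqrt(V[4, 4])
      tstat <- if (est == 0) 0 else est / se
      pval <- 2 * stats::pt(-abs(tstat), df = fit$n - fit$p)
      tst <- list(estimate = est, se = se, statistic = tstat, p = pval)
      se_g <- sqrt(V[2, 2])
      data.frame(SNP = geno$snps$id[j], CHR = geno$snps$chr[j],
                 BP = geno$snps$bp[j],
                 A1 = geno$snps$effect_allele[j],
                 A2 = geno$snps$other_allele[j],
                 ENV = spec$env, N = fit$n,
                 BETA_G = unname(fit$coefficients[2]), SE_G = se_g,
                 BETA_E = unname(fit$coefficients[3]),
                 BETA_GXE = tst$estimate, SE_GXE = tst$se,
                 STAT_GXE = tst$statistic, P_GXE = tst$p,
                 stringsAsFactors = FALSE)
    }, gweisr_rank_error = function(cnd) {
      skipped[[length(skipped) + 1L]] <<-
        data.frame(id = geno$snps$id[j], reason = conditionMessage(cnd))
      NULL
    })
    rows[[j]] <- res
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_sumstats("gweis")
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                          else data.frame(id = character(), reason = character())
  out
}

#' Genome-wide main-effect scan (GWAS mode)
#'
#' Per-SNP model `Y ~ 1 + G + C` with classical model-based standard
#' errors by default (the convention of standard GWAS software; sandwich
#' errors available via `robust`).
#'
#' @param geno a [genotype_matrix()].
#' @param cohort a `cohort_table`.
#' @param covariates covariate column names.
#' @param robust use sandwich standard errors (default `FALSE`).
#' @param hc sandwich variant when `robust`.
#' @return Summary statistics in the main-effect dialect.
#' @export
run_gwas <- function(geno, cohort, covariates = character(),
                     robust = FALSE, hc = "HC0") {
  stopifnot(inherits(geno, "genotype_matrix"))
  sc <- attr(cohort, "schema")
  if (is.null(sc)) stop("cohort must carry a schema (see as_cohort_table)")
  aligned <- align_cohort(geno, cohort, sc)
  y <- aligned$cohort[[sc$phenotype]]
  C <- if (length(covariates)) {
    as.matrix(aligned$cohort[, covariates, drop = FALSE])
  } else NULL

  m <- nrow(geno$snps)
  rows <- vector("list", m)
  skipped <- list()
  for (j in seq_len(m)) {
    g <- aligned$dosages[, j]
    res <- tryCatch({
      mask <- !(is.na(y) | is.na(g))
      if (!is.null(C)) mask <- mask & stats::complete.cases(C)
      X <- cbind(`(Intercept)` = 1, G = g[mask])
      if (!is.null(C)) X <- cbind(X, C[mask, , drop = FALSE])
      if (sum(mask) < ncol(X) + 1) {
        stop(errorCondition("under-determined design",
                            class = "gweisr_rank_error"))
      }
      fit <- ols_fit(X, y[mask])
      tst <- test_coefficient(fit, X, "G", robust, hc)
      data.frame(SNP = geno$snps$id[j], CHR = geno$snps$chr[j],
                 BP = geno$snps$bp[j],
                 A1 = geno$snps$effect_allele[j],
                 A2 = geno$snps$other_allele[j], N = fit$n,
                 BETA_G = tst$estimate, SE_G = tst$se,
                 STAT_G = tst$statistic, P_G = tst$p,
                 stringsAsFactors = FALSE)
    }, gweisr_rank_error = function(cnd) {
      skipped[[length(skipped) + 1L]] <<-
        data.frame(id = geno$snps$id[j], reason = conditionMessage(cnd))
      NULL
    })
    rows[[j]] <- res
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_sumstats("gwas")
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                          else data.frame(id = character(), reason = character())
  out
}

# match cohort rows to genotype sample order (inner join on sample id)
align_cohort <- function(geno, cohort, sc) {
  ids <- cohort[[sc$id]]
  pos <- match(geno$sample_ids, ids)
  keep <- !is.na(pos)
  list(dosages = geno$dosages[keep, , drop = FALSE],
       cohort = cohort[pos[keep], , drop = FALSE])
}

empty_sumstats <- function(dialect) {
  cols <- sumstats_columns(dialect)
  out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  for (nm in intersect(cols, c("SNP", "CHR", "A1", "A2", "ENV"))) {
    out[[nm]] <- character(0)
  }
  out$BP <- integer(0); out$N <- integer(0)
  out[, cols]
}
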