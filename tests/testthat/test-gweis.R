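make_design_inputs <- function(n, seed = 1) {
  set.seed(seed)
  list(g = rbinom(n, 2, 0.3), e = rnorm(n),
       C = matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("age", "pc1"))),
       y = rnorm(n))
}

test_that("the design has 4 + 3k columns in the documented order", {
  inp <- make_design_inputs(50)
  d <- build_design(inp$g, inp$e, inp$C, inp$y)
  expect_equal(ncol(d$X), 10)  # k = 2 covariates
  expect_equal(colnames(d$X),
               c("(Intercept)", "G", "E", "GxE", "age", "pc1",
                 "age:G", "pc1:G", "age:E", "pc1:E"))
  expect_true(all(d$mask))
  expect_equal(d$X[, "GxE"], d$X[, "G"] * d$X[, "E"])
  # no covariate interactions: 4 + k columns
  d2 <- build_design(inp$g, inp$e, inp$C, inp$y,
                     covariate_interactions = FALSE)
  expect_equal(ncol(d2$X), 6)
})

test_that("listwise deletion drops exactly the incomplete rows", {
  inp <- make_design_inputs(40)
  e <- inp$e; e[7] <- NA
  d <- build_design(inp$g, e, inp$C, inp$y)
  expect_equal(sum(d$mask), 39)
  expect_false(d$mask[7])
  g <- inp$g; g[c(2, 9)] <- NA
  d2 <- build_design(g, e, inp$C, inp$y)
  expect_equal(sum(d2$mask), 37)
  expect_error(build_design(rbinom(4, 2, .5), rnorm(4), NULL, rnorm(4)),
               class = "gweisr_underdetermined")
})

test_that("OLS matches the normal-equations oracle and flags rank loss", {
  set.seed(4)
  X <- cbind(1, matrix(rnorm(48), 12, 4))
  y <- rnorm(12)
  fit <- ols_fit(X, y)
  expect_equal(unname(fit$coefficients), drop(oracle_ols(X, y)),
               tolerance = 1e-8)
  expect_lt(max(abs(crossprod(X, fit$residuals))), 1e-10)

  # exact linear y: zero residuals
  y2 <- drop(X %*% c(1, -2, 0.5, 3, 0))
  expect_lt(max(abs(ols_fit(X, y2)$residuals)), 1e-10)

  # monomorphic SNP makes the design rank deficient
  inp <- make_design_inputs(30)
  d <- build_design(rep(0, 30), inp$e, inp$C, inp$y)
  expect_error(ols_fit(d$X, d$y), class = "gweisr_rank_error")
})

test_that("the sandwich estimator matches closed forms and a dense oracle", {
  set.seed(7)
  # intercept-only: Var(mean) = sum(e^2) / n^2
  n <- 25
  y <- rnorm(n)
  X <- matrix(1, n, 1)
  e <- y - mean(y)
  expect_equal(drop(sandwich_cov(X, e)), sum(e^2) / n^2, tolerance = 1e-12)

  # zero residuals give the zero matrix
  expect_equal(max(abs(sandwich_cov(X, rep(0, n)))), 0)

  # random instance vs element-wise brute-force triple product
  X2 <- cbind(1, matrix(rnorm(45), 15, 3))
  y2 <- rnorm(15)
  f <- ols_fit(X2, y2)
  V <- sandwich_cov(X2, f$residuals)
  expect_equal(unname(V), unname(oracle_hc0(X2, f$residuals)),
               tolerance = 1e-10)
  expect_true(isSymmetric(V))
  expect_true(all(eigen(V, only.values = TRUE)$values > -1e-12))
  # HC1 is the n/(n-p) rescaling
  expect_equal(sandwich_cov(X2, f$residuals, "HC1"),
               V * 15 / (15 - 4), tolerance = 1e-12)
})

test_that("the sandwich agrees with an established reference implementation", {
  skip_if_not_installed("sandwich")
  set.seed(21)
  df <- data.frame(g = rbinom(60, 2, 0.4), e = rnorm(60), y = rnorm(60))
  lmfit <- lm(y ~ g * e, data = df)
  X <- model.matrix(lmfit)
  V0 <- sandwich_cov(X, residuals(lmfit), "HC0")
  expect_equal(unname(V0), unname(sandwich::vcovHC(lmfit, type = "HC0")),
               tolerance = 1e-10)
  V1 <- sandwich_cov(X, residuals(lmfit), "HC1")
  expect_equal(unname(V1), unname(sandwich::vcovHC(lmfit, type = "HC1")),
               tolerance = 1e-10)
})

test_that("a zero interaction coefficient gives p = 1", {
  set.seed(2)
  inp <- make_design_inputs(40)
  d <- build_design(inp$g, inp$e, inp$C, inp$y)
  fit <- ols_fit(d$X, d$y)
  fit$coefficients[["GxE"]] <- 0
  tst <- test_coefficient(fit, d$X, "GxE")
  expect_equal(tst$statistic, 0)
  expect_equal(tst$p, 1)
})

test_that("the interaction |t| is invariant to allele flips", {
  set.seed(31)
  inp <- make_design_inputs(200)
  y <- inp$y + 0.3 * inp$g * inp$e
  t_of <- function(g) {
    d <- build_design(g, inp$e, inp$C, y)
    fit <- ols_fit(d$X, d$y)
    test_coefficient(fit, d$X, "GxE")$statistic
  }
  t1 <- t_of(inp$g)
  t2 <- t_of(2 - inp$g)
  expect_equal(abs(t1), abs(t2), tolerance = 1e-8)
  expect_equal(t1, -t2, tolerance = 1e-8)
})

test_that("robust and model-based inference coincide under homoscedasticity", {
  set.seed(41)
  n <- 20000
  inp <- make_design_inputs(n, seed = 41)
  y <- 0.05 * inp$g + rnorm(n)  # no interaction: p moderate, not extreme
  d <- build_design(inp$g, inp$e, inp$C, y)
  fit <- ols_fit(d$X, d$y)
  rob <- test_coefficient(fit, d$X, "GxE", robust = TRUE)
  mod <- test_coefficient(fit, d$X, "GxE", robust = FALSE)
  expect_lt(abs(rob$p - mod$p) / mod$p, 0.1)
  expect_lt(abs(rob$se / mod$se - 1), 0.05)
})

test_that("results are invariant to affine rescaling of covariates", {
  set.seed(51)
  inp <- make_design_inputs(500, seed = 51)
  y <- inp$y + 0.2 * inp$g * inp$e + 0.3 * inp$C[, 1] * inp$g
  t_of <- function(C) {
    d <- build_design(inp$g, inp$e, C, y)
    fit <- ols_fit(d$X, d$y)
    test_coefficient(fit, d$X, "GxE")$statistic
  }
  C2 <- sweep(sweep(inp$C, 2, c(10, 0.2), `*`), 2, c(-3, 100), `+`)
  expect_equal(abs(t_of(inp$C)), abs(t_of(C2)), tolerance = 1e-6)
})

test_that("the genome-wide scan is calibrated, order-invariant and logs skips", {
  cfg <- sim_config(n_samples = 800, n_snps = 100, n_pcs = 1,
                    n_centres = 2, seed = 61)
  sim <- simulate_cohort(cfg)
  covars <- attr(sim$cohort, "schema")$covariates
  spec <- design_spec("env1", covars)
  ss <- run_gweis(sim$genotypes, sim$cohort, spec)
  expect_equal(nrow(ss), 100)
  # null calibration: ~5 of 100 below 0.05 (binomial 99.9% envelope)
  n_sig <- sum(ss$P_GXE < 0.05)
  expect_gte(n_sig, qbinom(0.0005, 100, 0.05))
  expect_lte(n_sig, qbinom(0.9995, 100, 0.05))

  # permuting the cohort rows leaves every statistic unchanged
  perm <- sample(nrow(sim$cohort))
  cohort2 <- sim$cohort[perm, , drop = FALSE]
  attr(cohort2, "schema") <- sim$schema
  class(cohort2) <- class(sim$cohort)
  ss2 <- run_gweis(sim$genotypes, cohort2, spec)
  expect_equal(ss2, ss, ignore_attr = TRUE)

  # a monomorphic SNP is skipped with a logged reason, not fatal
  g2 <- sim$genotypes
  g2$dosages[, 3] <- 2
  ss3 <- run_gweis(g2, sim$cohort, spec)
  expect_equal(nrow(ss3), 99)
  skipped <- attr(ss3, "skipped")
  expect_equal(skipped$id, "snp0003")
  expect_match(skipped$reason, "rank")

  expect_error(run_gweis(sim$genotypes, sim$cohort,
                         design_spec("nope", covars)), "absent")
})

test_that("the main-effect scan detects a causal SNP and respects allele coding", {
  cfg <- sim_config(n_samples = 20000, n_snps = 30, n_pcs = 1,
                    n_centres = 2,
                    effects = list(beta_g = 0.12, causal_snp = 7),
                    seed = 71)
  sim <- simulate_cohort(cfg)
  covars <- attr(sim$cohort, "schema")$covariates
  ss <- run_gwas(sim$genotypes, sim$cohort, covars)
  expect_lt(ss$P_G[7], 5e-8)
  # null SNPs stay unremarkable
  expect_gt(min(ss$P_G[-7]), 1e-5)

  # allele flip: beta changes sign, p unchanged
  g2 <- sim$genotypes
  g2$dosages <- 2 - g2$dosages
  tmp <- g2$snps$effect_allele
  g2$snps$effect_allele <- g2$snps$other_allele
  g2$snps$other_allele <- tmp
  ss2 <- run_gwas(g2, sim$cohort, covars)
  expect_equal(ss2$BETA_G, -ss$BETA_G, tolerance = 1e-8)
  expect_equal(ss2$P_G, ss$P_G, tolerance = 1e-8)
})

test_that("null interaction p-values are uniform under the robust test", {
  cfg <- sim_config(n_samples = 1000, n_snps = 2000, n_pcs = 1,
                    n_centres = 1, seed = 81)
  sim <- simulate_cohort(cfg)
  spec <- design_spec("env1", attr(sim$cohort, "schema")$covariates)
  ss <- run_gweis(sim$genotypes, sim$cohort, spec)
  ks <- suppressWarnings(ks.test(ss$P_GXE, "punif"))
  expect_gt(ks$p.value, 0.01)
})
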