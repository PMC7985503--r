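fixture_model <- function(kind = "PRS", beta = c(0.2, -0.1, 0.4, 0, 0.3),
                          with_g = FALSE) {
  w <- data.frame(snp = sprintf("rs%03d", 1:5), effect_allele = "A",
                  beta = beta, stringsAsFactors = FALSE)
  if (with_g) w$beta_g <- c(0.1, 0.2, -0.3, 0.05, 0)
  prs_model(kind, w, p_threshold = 1, training_ids = "trainer")
}

test_that("main-effect scoring is the weighted effect-allele count", {
  g <- random_genotype_matrix(4, 5, seed = 14)
  m <- fixture_model()
  s <- score_prs(g, m)
  # hand-computed dot product, sample by sample
  want <- sapply(1:4, function(i) sum(g$dosages[i, ] * m$weights$beta))
  expect_equal(as.vector(s), want)

  zero <- fixture_model(beta = rep(0, 5))
  expect_equal(as.vector(score_prs(g, zero)), rep(0, 4))

  single <- prs_model("PRS", data.frame(snp = "rs002", effect_allele = "A",
                                        beta = 1))
  expect_equal(as.vector(score_prs(g, single)),
               unname(g$dosages[, 2]))
})

test_that("scoring aligns alleles and rejects unresolvable mismatches", {
  g <- random_genotype_matrix(6, 5, seed = 15)
  m <- fixture_model()
  base <- unclass(score_prs(g, m))
  # the genotype file counts the other allele at SNP 3: dosage flips
  g2 <- g
  g2$dosages[, 3] <- 2 - g2$dosages[, 3]
  g2$snps$effect_allele[3] <- "G"
  g2$snps$other_allele[3] <- "A"
  s2 <- unclass(score_prs(g2, m))
  expect_equal(s2, base, tolerance = 1e-12)

  g3 <- g
  g3$snps$effect_allele[2] <- "T"
  g3$snps$other_allele[2] <- "C"
  expect_error(score_prs(g3, m), "unresolvable allele mismatch")
})

test_that("missing dosages contribute their training-frequency imputation", {
  g <- random_genotype_matrix(10, 5, seed = 16)
  g$dosages[4, 1] <- NA
  m <- fixture_model()
  m$weights$eaf <- c(0.25, 0.3, 0.4, 0.2, 0.1)
  s <- unclass(score_prs(g, m))
  manual <- sum(c(2 * 0.25, g$dosages[4, 2:5]) * m$weights$beta)
  expect_equal(s[[4]], manual)
})

test_that("interaction scores follow their defining formulas", {
  g <- random_genotype_matrix(8, 5, seed = 17)
  set.seed(18)
  E <- rnorm(8)
  m_gxe <- fixture_model("iPRS_GxE")
  s <- unclass(score_iprs(g, E, m_gxe))
  want <- E * drop(g$dosages %*% m_gxe$weights$beta)
  expect_equal(s, want, ignore_attr = TRUE)

  # E = 0 zeroes the score; E = 1 reduces to the weighted allele count
  expect_equal(unclass(score_iprs(g, rep(0, 8), m_gxe)), rep(0, 8),
               ignore_attr = TRUE)
  prs_weights <- fixture_model("PRS")
  expect_equal(unclass(score_iprs(g, rep(1, 8), m_gxe)),
               unclass(score_prs(g, prs_weights)), ignore_attr = TRUE)

  m_g <- fixture_model("iPRS_G")
  expect_equal(unclass(score_iprs(g, E, m_g)),
               unclass(score_prs(g, m_g)) * E, ignore_attr = TRUE)

  m_both <- fixture_model("iPRS_G_plus_GxE", with_g = TRUE)
  s_both <- unclass(score_iprs(g, E, m_both))
  want_both <- E * drop(g$dosages %*% m_both$weights$beta) +
    drop(g$dosages %*% m_both$weights$beta_g)
  expect_equal(s_both, want_both, ignore_attr = TRUE)
  expect_error(score_iprs(g, E, fixture_model("PRS")), "interaction-kind")
})

test_that("threshold-grid models are nested and clumped", {
  cfg <- sim_config(n_samples = 500, n_snps = 20,
                    ld_blocks = list(list(size = 2, rho = 1, maf = 0.3)),
                    seed = 19)
  g <- simulate_genotypes(cfg)
  set.seed(20)
  stats <- data.frame(SNP = g$snps$id, CHR = g$snps$chr, BP = g$snps$bp,
                      A1 = "A", A2 = "G", N = 500L,
                      BETA_G = rnorm(20), SE_G = 0.1, STAT_G = 1,
                      P_G = runif(20))
  models <- build_threshold_grid(stats, g, kind = "PRS")
  # threshold 1 holds every index SNP; the duplicated pair collapsed
  expect_equal(nrow(models[["1"]]$weights), 19)
  # nesting along the grid
  grid <- as.numeric(names(models))
  for (i in seq_len(length(grid) - 1)) {
    expect_true(all(models[[i]]$weights$snp %in%
                      models[[i + 1]]$weights$snp))
  }
  # below the minimum p: empty model
  stats$P_G <- pmax(stats$P_G, 0.01)
  m2 <- build_threshold_grid(stats, g, kind = "PRS", grid = c(1e-4, 1))
  expect_equal(nrow(m2[["1e-04"]]$weights), 0)
  expect_identical(models[["1"]]$training_ids, g$sample_ids)
})

test_that("adjusted R-squared matches its closed form", {
  expect_equal(adjusted_r2(1, 50, 3), 1)
  expect_equal(adjusted_r2(0.5, 101, 10), 1 - 0.5 * 100 / 90)
  expect_equal(adjusted_r2(0.3, 40, 0), 0.3)  # intercept-only baseline
})

test_that("the evaluation refuses training/hold-out leakage and collinearity", {
  set.seed(22)
  ct <- toy_cohort(50)
  score <- structure(rnorm(50), names = ct$IID,
                     training_ids = c("s001", "zzz"))
  expect_error(evaluate_prs(ct, score, "PRS",
                            covariates = c("age", "sexi")),
               "leakage")
  # a score duplicating a covariate is rank deficient, not silently dropped
  dup <- structure(ct$age, names = ct$IID, training_ids = "elsewhere")
  expect_error(evaluate_prs(ct, dup, "PRS", covariates = c("age", "sexi")),
               "rank deficient")
})

test_that("the adjusted-R2 increment matches the partial-correlation identity", {
  set.seed(23)
  ct <- toy_cohort(300)
  ct$phenotype <- 0.3 * ct$age / 8 + rnorm(300)
  s <- structure(0.4 * ct$phenotype + rnorm(300), names = ct$IID,
                 training_ids = "elsewhere")
  ev <- evaluate_prs(ct, s, "PRS", covariates = c("age", "sexi"))

  X0 <- cbind(1, ct$age, ct$sexi)
  ry <- residuals(lm.fit(X0, ct$phenotype))
  rs <- residuals(lm.fit(X0, unclass(s)))
  pr2 <- cor(ry, rs)^2
  r2_0 <- summary(lm(ct$phenotype ~ ct$age + ct$sexi))$r.squared
  r2_1 <- r2_0 + (1 - r2_0) * pr2
  n <- 300
  want <- adjusted_r2(r2_1, n, 3) - adjusted_r2(r2_0, n, 2)
  expect_equal(ev$delta_adj_r2, want, tolerance = 1e-10)
  # F-test agrees with the stock nested-model comparison
  lm0 <- lm(ct$phenotype ~ ct$age + ct$sexi)
  lm1 <- lm(ct$phenotype ~ ct$age + ct$sexi + unclass(s))
  an <- anova(lm0, lm1)
  expect_equal(ev$F, an$F[2], tolerance = 1e-10)
  expect_equal(ev$p, an$`Pr(>F)`[2], tolerance = 1e-10)
})

test_that("best-threshold selection is an argmax with smallest-threshold ties", {
  ev <- data.frame(threshold = c(0.001, 0.05, 0.1, 0.5),
                   n_snps = c(1, 4, 9, 20),
                   delta_adj_r2 = c(0.01, 0.03, 0.02, 0.03),
                   F = 1, p = 0.5, n = 100)
  best <- select_best_threshold(ev)
  expect_equal(best$threshold, 0.05)  # tie with 0.5 broken downward
  expect_equal(select_best_threshold(ev[1, ])$threshold, 0.001)
  set.seed(24)
  for (i in 1:10) {
    ev$delta_adj_r2 <- rnorm(4)
    expect_equal(select_best_threshold(ev)$delta_adj_r2,
                 max(ev$delta_adj_r2))
  }
})
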