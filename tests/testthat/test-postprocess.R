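test_that("QC filtering applies the MAF, missingness and info rules", {
  set.seed(5)
  n <- 400
  dos <- cbind(rbinom(n, 2, 0.3),    # fine
               rbinom(n, 2, 0.005),  # rare
               rbinom(n, 2, 0.4),    # will get missingness
               rbinom(n, 2, 0.2))    # low info
  dos[seq_len(0.06 * n), 3] <- NA
  snps <- data.frame(id = paste0("v", 1:4), chr = "1", bp = 1:4 * 1000L,
                     effect_allele = "A", other_allele = "G",
                     info = c(0.99, 0.95, 0.99, 0.5))
  g <- genotype_matrix(dos, snps, sample_ids = paste0("s", 1:n))
  out <- qc_filter(g)
  expect_equal(out$snps$id, "v1")
  rep <- attr(out, "qc_report")
  expect_equal(rep$fail_maf, 1)
  expect_equal(rep$fail_missingness, 1)
  expect_equal(rep$fail_info, 1)

  # all-pass input is unchanged; the filter is idempotent
  g2 <- random_genotype_matrix(200, 5, seed = 2)
  f1 <- qc_filter(g2)
  expect_equal(f1$snps$id, g2$snps$id)
  f2 <- qc_filter(f1)
  expect_identical(f2$dosages, f1$dosages)
})

test_that("LD r2 is correlation-based, affine-invariant and flags degenerate input", {
  set.seed(8)
  x <- rbinom(5000, 2, 0.3)
  expect_equal(ld_r2(x, x), 1)
  expect_equal(ld_r2(x, 2 - x), 1)  # allele flip
  y <- rbinom(10000, 2, 0.3)
  x2 <- rbinom(10000, 2, 0.3)
  expect_lt(ld_r2(x2, y), 0.01)
  expect_true(is.na(ld_r2(rep(1, 100), y[1:100])))
})

test_that("clumping matches a brute-force greedy oracle on random fixtures", {
  for (seed in 1:5) {
    cfg <- sim_config(n_samples = 400, n_snps = 10,
                      ld_blocks = list(list(size = 3, rho = 0.95, maf = 0.3),
                                       list(size = 3, rho = 0.9, maf = 0.2)),
                      seed = seed)
    g <- simulate_genotypes(cfg)
    set.seed(seed + 100)
    stats <- data.frame(SNP = g$snps$id, CHR = g$snps$chr, BP = g$snps$bp,
                        P_GXE = runif(10))
    got <- clump(stats, g, r2_threshold = 0.2, window_kb = 20,
                 p_threshold = 0.9)
    dos <- g$dosages
    want <- oracle_clump(
      data.frame(snp = stats$SNP, chr = stats$CHR, bp = stats$BP,
                 p = stats$P_GXE),
      dos, r2 = 0.2, kb = 20, p1 = 0.9)
    expect_equal(got$snp, want)
  }
})

test_that("clumping postconditions hold and ties break deterministically", {
  cfg <- sim_config(n_samples = 500, n_snps = 12,
                    ld_blocks = list(list(size = 4, rho = 0.97, maf = 0.25)),
                    seed = 9)
  g <- simulate_genotypes(cfg)
  set.seed(99)
  stats <- data.frame(SNP = g$snps$id, CHR = g$snps$chr, BP = g$snps$bp,
                      P_GXE = runif(12))
  res <- clump(stats, g, r2_threshold = 0.2, window_kb = 30)
  # every clumped SNP is within the window and correlated with its index
  for (i in seq_len(nrow(res))) {
    members <- strsplit(res$clumped[i], ";")[[1]]
    members <- members[nzchar(members)]
    for (msnp in members) {
      mrow <- stats[stats$SNP == msnp, ]
      expect_lte(abs(mrow$BP - res$bp[i]), 30000)
      expect_gte(ld_r2(g$dosages[, res$snp[i]], g$dosages[, msnp]), 0.2)
    }
  }
  # index SNPs are mutually below the r2 threshold within the window
  for (i in seq_len(nrow(res))) for (j in seq_len(nrow(res))) {
    if (i < j && abs(res$bp[i] - res$bp[j]) <= 30000) {
      expect_lt(ld_r2(g$dosages[, res$snp[i]], g$dosages[, res$snp[j]]),
                0.2)
    }
  }
  # input row order does not matter
  res2 <- clump(stats[sample(12), ], g, r2_threshold = 0.2, window_kb = 30)
  expect_equal(res2, res)
  # equal p-values: lower position wins the index role
  stats$P_GXE <- 0.5
  res3 <- clump(stats, g, r2_threshold = 0.2, window_kb = 30)
  expect_equal(res3$snp[1], "snp0001")
})

test_that("perfectly correlated pairs clump to the lower p-value", {
  cfg <- sim_config(n_samples = 300, n_snps = 2,
                    ld_blocks = list(list(size = 2, rho = 1, maf = 0.3)),
                    seed = 3)
  g <- simulate_genotypes(cfg)
  stats <- data.frame(SNP = g$snps$id, CHR = g$snps$chr, BP = g$snps$bp,
                      P_GXE = c(0.01, 0.002))
  res <- clump(stats, g, r2_threshold = 0.2, window_kb = 250)
  expect_equal(res$snp, "snp0002")
  expect_equal(res$clumped, "snp0001")
  # uncorrelated SNPs: every sub-threshold SNP is its own index
  g2 <- random_genotype_matrix(2000, 4, seed = 4)
  stats2 <- data.frame(SNP = g2$snps$id, CHR = g2$snps$chr,
                       BP = g2$snps$bp, P_GXE = c(0.2, 0.01, 0.6, 0.03))
  res2 <- clump(stats2, g2, r2_threshold = 0.2, window_kb = 250,
                p_threshold = 0.05)
  expect_setequal(res2$snp, c("rs002", "rs004"))
})

test_that("the genomic inflation factor behaves at its closed forms", {
  set.seed(12)
  expect_lt(abs(genomic_lambda(runif(10000)) - 1), 0.03)
  expect_equal(genomic_lambda(rep(0.5, 10)), 1)
  expect_equal(genomic_lambda(rep(0.2, 10)),
               qchisq(0.2, 1, lower.tail = FALSE) / qchisq(0.5, 1))
  expect_gt(genomic_lambda(runif(5000) * 0.05), 1)
  qt <- qq_table(runif(100))
  expect_equal(nrow(qt), 100)
  expect_false(is.unsorted(rev(qt$expected)))  # decreasing -log10 p
})

test_that("Bonferroni layers divide the alpha as declared", {
  expect_equal(bonferroni_threshold(0.05, "per-analysis", n_tests = 100),
               5e-4)
  expect_equal(bonferroni_threshold(0.05, "cross-environment",
                                    n_tests = 100, n_environments = 10),
               5e-5)
  expect_equal(bonferroni_threshold(0.05, "iprs", n_environments = 10,
                                    n_models = 2), 0.0025)
})
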