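# fixture builders shared across test files; everything generated in code

random_genotype_matrix <- function(n, m, miss_rate = 0, seed = 1) {
  set.seed(seed)
  maf <- runif(m, 0.05, 0.5)
  dos <- sapply(maf, function(f) rbinom(n, 2, f))
  dos <- matrix(as.numeric(dos), n, m)
  if (miss_rate > 0) dos[runif(n * m) < miss_rate] <- NA
  snps <- data.frame(id = sprintf("rs%03d", seq_len(m)), chr = "1",
                     bp = 1000L * seq_len(m),
                     effect_allele = "A", other_allele = "G",
                     stringsAsFactors = FALSE)
  genotype_matrix(dos, snps, sample_ids = sprintf("s%03d", seq_len(n)))
}

toy_cohort <- function(n, seed = 1, env_name = "env1") {
  set.seed(seed)
  df <- data.frame(IID = sprintf("s%03d", seq_len(n)),
                   phenotype = rnorm(n),
                   age = rnorm(n, 57, 8), sexi = rbinom(n, 1, 0.5),
                   stringsAsFactors = FALSE)
  df[[env_name]] <- rnorm(n)
  schema <- cohort_schema(phenotype = "phenotype",
                          environments = setNames(list("continuous"),
                                                  env_name),
                          covariates = c("age", "sexi"), id = "IID")
  as_cohort_table(df, schema)
}

# independent dense-matrix oracles used to cross-check the engine
oracle_ols <- function(X, y) solve(t(X) %*% X) %*% t(X) %*% y

oracle_hc0 <- function(X, e) {
  B <- solve(t(X) %*% X)
  B %*% (t(X) %*% diag(as.numeric(e)^2) %*% X) %*% B
}

# brute-force greedy clumping, written independently of gweisr::clump
oracle_clump <- function(df, dosages, r2, kb, p1) {
  df <- df[df$p <= p1, ]
  df <- df[order(df$p, df$bp, df$snp), ]
  index <- character(0)
  while (nrow(df) > 0) {
    top <- df[1, ]
    index <- c(index, top$snp)
    keep <- rep(TRUE, nrow(df))
    for (i in seq_len(nrow(df))) {
      if (df$snp[i] == top$snp) { keep[i] <- FALSE; next }
      if (df$chr[i] == top$chr && abs(df$bp[i] - top$bp) <= kb * 1000) {
        r <- suppressWarnings(
          cor(dosages[, top$snp], dosages[, df$snp[i]],
              use = "pairwise.complete.obs"))
        if (!is.na(r) && r^2 >= r2) keep[i] <- FALSE
      }
    }
    df <- df[keep, , drop = FALSE]
  }
  index
}
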