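#' Specify a synthetic environment
#'
#' Declares one environmental exposure for the cohort generator.  The
#' latent exposure is Gaussian; ordinal and count types are produced by
#' quantile-binning the latent value into the declared number of levels,
#' mirroring questionnaire exposures that are recorded as graded responses
#' or endorsement counts but analysed as continuous.  An exposure can be
#' partly heritable (a fraction `h2` of its variance contributed by a set
#' of causal SNPs) and partly driven by a measured confounder
#' (`confounder_share`), which is how gene-by-covariate confounding
#' scenarios are constructed.
#'
#' @param type `"continuous"`, `"ordinal"` or `"count"`.
#' @param levels number of ordinal levels (codes `0..levels-1`).
#' @param max maximum for count type (codes `0..max`).
#' @param h2 fraction of latent variance from causal SNPs, in `[0, 1)`.
#' @param causal_snps SNP column indices contributing heritable variance.
#' @param confounder name of a covariate column (or `NULL`) that loads on
#'   the exposure.
#' @param confounder_share fraction of latent variance from the
#'   confounder.
#' @return A list of class `env_spec`.
#' @export
env_spec <- function(type = c("continuous", "ordinal", "count"),
                     levels = NULL, max = NULL, h2 = 0,
                     causal_snps = integer(), confounder = NULL,
                     confounder_share = 0) {
  type <- match.arg(type)
  if (type == "ordinal" && (is.null(levels) || levels < 2)) {
    stop("ordinal environments need levels >= 2")
  }
  if (type == "count" && (is.null(max) || max < 1)) {
    stop("count environments need max >= 1")
  }
  if (h2 < 0 || h2 >= 1) stop("h2 must be in [0, 1)")
  if (h2 > 0 && length(causal_snps) == 0) {
    stop("heritable environment (h2 > 0) needs a non-empty causal SNP set")
  }
  if (h2 + confounder_share >= 1) {
    stop("h2 + confounder_share must be < 1")
  }
  structure(list(type = type, levels = levels, max = max, h2 = h2,
                 causal_snps = as.integer(causal_snps),
                 confounder = confounder,
                 confounder_share = confounder_share),
            class = "env_spec")
}

#' Configure the synthetic cohort generator
#'
#' Collects every knob of the generative model in one validated object.
#' The phenotype is built from the full interaction regression model
#' \deqn{Y = \beta_0 + G\beta_G + E\beta_E + GE\beta_{GxE} + C'\beta_C +
#'   C'G\beta_{CxG} + C'E\beta_{CxE} + \epsilon}
#' with noise either homoscedastic (`theta = 0`) or heteroscedastic with
#' variance \eqn{\sigma^2 e^{\theta E_i}}.  Genotypes are drawn in
#' Hardy-Weinberg equilibrium with optional block LD; covariates comprise
#' an age analogue, a sex indicator, standard-normal PC-like columns and
#' assessment-centre indicators.
#'
#' @param n_samples,n_snps cohort dimensions.
#' @param maf_range per-SNP minor allele frequencies are drawn uniformly
#'   from this range (default 0.01-0.5, the post-QC spectrum).
#' @param ld_blocks optional list of `list(size =, rho =, maf =)` blocks
#'   of consecutive SNPs sharing within-block haplotype correlation `rho`
#'   (and, if given, a common `maf`); SNPs not covered are independent.
#' @param missing_rate genotype missingness injected completely at random.
#' @param n_pcs number of PC-like standard-normal covariates.
#' @param n_centres number of assessment centres (one-hot indicators,
#'   first centre as reference).
#' @param environments named list of [env_spec()]s.
#' @param effects list of generative coefficients: `intercept`, `beta_g`,
#'   `beta_e`, `beta_gxe` (scalars), `beta_c`, `beta_cxg`, `beta_cxe`
#'   (vectors over covariate columns, recycled; default 0), `causal_snp`
#'   (index of the SNP carrying `beta_g`/`beta_gxe`) and `env` (which
#'   environment interacts; default the first).
#' @param sigma residual standard deviation at `E = 0`.
#' @param theta heteroscedasticity parameter: residual variance is
#'   `sigma^2 * exp(theta * E)`.
#' @param phenotype `"linear"` (the model's continuous outcome) or
#'   `"likert12"` (rank-binned into the 13 equal-frequency integer levels
#'   of a 0-12 questionnaire sum score).
#' @param holdout_n samples reserved for the prediction hold-out split.
#' @param bp_spacing base-pair distance between consecutive simulated
#'   SNPs (all on chromosome 1).
#' @param seed master seed; every stream downstream is derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 2000, n_snps = 500,
                       maf_range = c(0.01, 0.5), ld_blocks = NULL,
                       missing_rate = 0, n_pcs = 2, n_centres = 3,
                       environments = list(env1 = env_spec("continuous")),
                       effects = list(), sigma = 1, theta = 0,
                       phenotype = c("linear", "likert12"),
                       holdout_n = 0, bp_spacing = 5000L, seed = 1L) {
  phenotype <- match.arg(phenotype)
  stopifnot(n_samples >= 1, n_snps >= 0, sigma > 0,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            missing_rate >= 0, missing_rate < 1,
            holdout_n >= 0, holdout_n <= n_samples)
  defaults <- list(intercept = 0, beta_g = 0, beta_e = 0, beta_gxe = 0,
                   beta_c = 0, beta_cxg = 0, beta_cxe = 0,
                   causal_snp = 1L, env = names(environments)[1] %||% NULL)
  effects <- utils::modifyList(defaults, effects)
  if (n_snps > 0 && (effects$causal_snp < 1 || effects$causal_snp > n_snps)) {
    stop("causal_snp index out of range")
  }
  for (e in environments) {
    if (length(e$causal_snps) && any(e$causal_snps > n_snps)) {
      stop("environment causal SNP index exceeds n_snps")
    }
  }
  if (!is.null(ld_blocks)) {
    if (sum(vapply(ld_blocks, function(b) b$size, numeric(1))) > n_snps) {
      stop("LD blocks cover more SNPs than n_snps")
    }
  }
  structure(list(n_samples = n_samples, n_snps = n_snps,
                 maf_range = maf_range, ld_blocks = ld_blocks,
                 missing_rate = missing_rate, n_pcs = n_pcs,
                 n_centres = n_centres, environments = environments,
                 effects = effects, sigma = sigma, theta = theta,
                 phenotype = phenotype, holdout_n = holdout_n,
                 bp_spacing = as.integer(bp_spacing),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate genotypes in Hardy-Weinberg equilibrium with block LD
#'
#' Each sample carries two haplotypes per SNP.  Within an LD block the
#' haplotype alleles derive from a shared latent Gaussian factor with
#' correlation `rho`, thresholded at the allele-frequency quantile, which
#' yields tunable pairwise r2 without coalescent machinery; across blocks
#' haplotypes are independent.  The dosage is the haplotype sum, so
#' unlinked SNPs are binomial(2, maf) and in HWE by construction.
#'
#' @param config a [sim_config()].
#' @return A [genotype_matrix()]; SNPs are placed on chromosome 1 at
#'   `bp_spacing` intervals with alleles A (effect) / G.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genotypes"))
  n <- config$n_samples
  m <- config$n_snps

  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  rho <- rep(0, m)
  block_id <- seq_len(m)  # singleton blocks by default
  if (!is.null(config$ld_blocks)) {
    at <- 1L
    for (b in seq_along(config$ld_blocks)) {
      blk <- config$ld_blocks[[b]]
      idx <- seq.int(at, length.out = blk$size)
      rho[idx] <- blk$rho
      block_id[idx] <- -b
      if (!is.null(blk$maf)) maf[idx] <- blk$maf
      at <- at + blk$size
    }
  }

  dos <- matrix(0, n, m)
  for (blk in unique(block_id)) {
    idx <- which(block_id == blk)
    r <- rho[idx[1]]
    # two haplotypes; shared factor per haplotype within the block
    for (h in 1:2) {
      u <- stats::rnorm(n)
      z <- sqrt(r) * u +
        sqrt(1 - r) * matrix(stats::rnorm(n * length(idx)), n)
      alleles <- sweep(z, 2, stats::qnorm(maf[idx]), `<`)
      dos[, idx] <- dos[, idx] + alleles
    }
  }
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
    dos[drop] <- NA
  }

  snps <- data.frame(id = sprintf("snp%04d", seq_len(m)), chr = "1",
                     bp = config$bp_spacing * seq_len(m),
                     effect_allele = "A", other_allele = "G",
                     stringsAsFactors = FALSE)
  genotype_matrix(dos, snps,
                  sample_ids = sprintf("id%05d", seq_len(n)))
}

#' Simulate one environment column
#'
#' Builds the latent Gaussian exposure as a variance-weighted sum of a
#' genetic component (over the spec's causal SNPs), a confounder
#' component, and independent noise, then applies the type transform
#' (identity, or equal-frequency quantile binning into ordinal/count
#' codes).
#'
#' @param spec an [env_spec()].
#' @param G dosage matrix (needed when `h2 > 0`).
#' @param confounder numeric vector (needed when `confounder_share > 0`).
#' @param n number of samples (taken from `G`/`confounder` when present).
#' @param seed integer seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_environment <- function(spec, G = NULL, confounder = NULL,
                                 n = NULL, seed = 1L) {
  stopifnot(inherits(spec, "env_spec"))
  n <- n %||% (if (!is.null(G)) nrow(G) else length(confounder))
  if (is.null(n)) stop("cannot infer sample size")
  set.seed(as.integer(seed))

  e_noise <- stats::rnorm(n)
  lat <- sqrt(1 - spec$h2 - spec$confounder_share) * e_noise
  if (spec$h2 > 0) {
    if (is.null(G)) stop("heritable environment requires genotypes")
    gam <- stats::rnorm(length(spec$causal_snps))
    gpart <- G[, spec$causal_snps, drop = FALSE] %*% gam
    gpart[is.na(gpart)] <- 0
    s <- stats::sd(gpart)
    if (s == 0) stop("genetic component of environment is constant")
    lat <- lat + sqrt(spec$h2) * scale(gpart)[, 1]
  }
  if (spec$confounder_share > 0) {
    if (is.null(confounder)) stop("confounded environment requires the confounder column")
    lat <- lat + sqrt(spec$confounder_share) * scale(confounder)[, 1]
  }

  switch(spec$type,
         continuous = lat,
         ordinal = quantile_bin(lat, spec$levels),
         count = quantile_bin(lat, spec$max + 1L))
}

# equal-frequency binning into integer codes 0..(k-1)
quantile_bin <- function(x, k) {
  r <- rank(x, ties.method = "first")
  as.numeric(ceiling(r * k / length(x)) - 1L)
}

#' Simulate the phenotype from the interaction model
#'
#' Evaluates the generative regression (intercept, SNP, environment,
#' SNP-by-environment, covariate main effects and covariate-by-SNP /
#' covariate-by-environment interactions) for the configured causal SNP
#' and environment, then adds Gaussian noise with variance
#' `sigma^2 * exp(theta * E)`.  With `phenotype = "likert12"` the linear
#' outcome is rank-binned into 13 equal-frequency integer levels 0-12.
#'
#' @param config a [sim_config()].
#' @param G dosage matrix (missing dosages enter as the SNP mean).
#' @param E named environment matrix or vector.
#' @param C covariate matrix.
#' @return Numeric phenotype vector.
#' @export
simulate_phenotype <- function(config, G, E, C) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "phenotype"))
  ef <- config$effects
  n <- nrow(C) %||% length(E)
  if (is.matrix(E) || is.data.frame(E)) {
    E <- as.matrix(E)[, ef$env %||% 1]
  }
  g <- if (config$n_snps > 0) G[, ef$causal_snp] else rep(0, n)
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  C <- as.matrix(C)
  k <- ncol(C)
  bc <- rep_len(ef$beta_c, k)
  bcg <- rep_len(ef$beta_cxg, k)
  bce <- rep_len(ef$beta_cxe, k)

  mu <- ef$intercept + g * ef$beta_g + E * ef$beta_e +
    g * E * ef$beta_gxe + drop(C %*% bc) +
    drop((C * g) %*% bcg) + drop((C * E) %*% bce)
  sd_i <- config$sigma * exp(config$theta * E / 2)
  y <- mu + stats::rnorm(length(mu), sd = sd_i)
  if (config$phenotype == "likert12") y <- quantile_bin(y, 13L)
  y
}

#' Simulate a full cohort
#'
#' Runs the generator end to end: genotypes, covariates (age analogue,
#' sex indicator, PC-like columns, centre indicators), every configured
#' environment, and the phenotype.  All randomness derives from the
#' config's master seed via fixed per-stage streams, so the same config
#' always reproduces the same cohort.
#'
#' @param config a [sim_config()].
#' @return A list with elements `genotypes` (a [genotype_matrix()]),
#'   `cohort` (a `cohort_table` including a `holdout` flag column) and
#'   `schema` (the matching [cohort_schema()]).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  geno <- simulate_genotypes(config)
  n <- config$n_samples

  set.seed(derive_seed(config$seed, "missingness"))
  covs <- data.frame(age = stats::rnorm(n, 57, 8),
                     sex = stats::rbinom(n, 1, 0.5))
  if (config$n_pcs > 0) {
    for (j in seq_len(config$n_pcs)) {
      covs[[paste0("PC", j)]] <- stats::rnorm(n)
    }
  }
  if (config$n_centres > 1) {
    centre <- sample.int(config$n_centres, n, replace = TRUE)
    for (j in 2:config$n_centres) {
      covs[[paste0("centre", j)]] <- as.numeric(centre == j)
    }
  }

  envs <- list()
  for (i in seq_along(config$environments)) {
    nm <- names(config$environments)[i]
    sp <- config$environments[[i]]
    conf_col <- if (!is.null(sp$confounder)) covs[[sp$confounder]] else NULL
    envs[[nm]] <- simulate_environment(
      sp, G = geno$dosages, confounder = conf_col, n = n,
      seed = derive_seed(config$seed, "environment") + i)
  }
  E <- do.call(cbind, envs)
  colnames(E) <- names(envs)

  y <- simulate_phenotype(config, geno$dosages, E, as.matrix(covs))

  df <- data.frame(IID = geno$sample_ids, phenotype = y,
                   as.data.frame(E), covs,
                   stringsAsFactors = FALSE, check.names = FALSE)
  split <- split_holdout(df$IID, config$holdout_n,
                         seed = derive_seed(config$seed, "holdout"))
  df$holdout <- df$IID %in% split$holdout

  env_decl <- lapply(config$environments, function(sp) {
    switch(sp$type,
           continuous = "continuous",
           ordinal = list(type = "ordinal", levels = sp$levels),
           count = list(type = "count", max = sp$max))
  })
  schema <- cohort_schema(phenotype = "phenotype", environments = env_decl,
                          covariates = names(covs), id = "IID",
                          holdout = "holdout")
  list(genotypes = geno, cohort = as_cohort_table(df, schema),
       schema = schema)
}

#' Split sample ids into training and hold-out sets
#'
#' Reproducible disjoint, exhaustive split used to keep score weights
#' (estimated on the training set) independent of the prediction sample.
#'
#' @param ids sample ids (or a `cohort_table`, whose id column is used).
#' @param holdout_n hold-out size.
#' @param seed integer seed.
#' @return `list(train =, holdout =)` of id vectors.
#' @export
split_holdout <- function(ids, holdout_n, seed = 1L) {
  if (inherits(ids, "cohort_table")) {
    ids <- ids[[attr(ids, "schema")$id]]
  }
  stopifnot(holdout_n >= 0, holdout_n <= length(ids))
  set.seed(as.integer(seed))
  hold <- if (holdout_n > 0) sort(sample(ids, holdout_n)) else character(0)
  list(train = setdiff(ids, hold), holdout = hold)
}
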