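#' Quality-control filter on genotype data
#'
#' Retains SNPs passing all three standard post-imputation filters:
#' minor allele frequency at least `maf_min`, missingness at most
#' `miss_max`, and imputation info score at least `info_min`.  SNPs
#' without an info score (e.g. simulated hard calls) pass the info filter
#' trivially; the filter report notes this.  The operation is idempotent.
#'
#' @param geno a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param miss_max maximum per-SNP missingness (default 0.05).
#' @param info_min minimum imputation info score (default 0.9).
#' @return Filtered [genotype_matrix()]; the `"qc_report"` attribute
#'   counts removals per criterion.
#' @export
qc_filter <- function(geno, maf_min = 0.01, miss_max = 0.05,
                      info_min = 0.9) {
  stopifnot(inherits(geno, "genotype_matrix"))
  s <- geno$snps
  maf_ok <- !is.na(s$maf) & s$maf >= maf_min
  miss_ok <- s$missingness <= miss_max
  info_ok <- is.na(s$info) | s$info >= info_min
  keep <- maf_ok & miss_ok & info_ok
  out <- subset_genotypes(geno, snps = which(keep))
  attr(out, "qc_report") <- list(
    n_in = nrow(s), n_out = sum(keep),
    fail_maf = sum(!maf_ok), fail_missingness = sum(!miss_ok),
    fail_info = sum(!info_ok), info_absent = sum(is.na(s$info)))
  out
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of two dosage vectors over
#' pairwise-complete samples -- the genotype-correlation measure standard
#' clumping uses.  A constant column has no defined correlation and
#' returns `NA`.
#'
#' @param x,y dosage vectors.
#' @return r-squared in `[0, 1]`, or `NA` for degenerate input.
#' @export
ld_r2 <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

#' Greedy LD clumping of summary statistics
#'
#' PLINK-style clumping: repeatedly take the most significant unassigned
#' SNP below `p_threshold` as an index SNP and assign to it every
#' unassigned SNP on the same chromosome within `window_kb` whose
#' r-squared with the index reaches `r2_threshold`.  Index SNPs therefore
#' mutually satisfy `r2 < r2_threshold` within the window.  Ties on the
#' p-value are broken by (chromosome, position), then SNP id, so the
#' result does not depend on input row order.
#'
#' @param stats summary statistics (either dialect); the p-value column
#'   is `P_GXE` or `P_G`.
#' @param geno a [genotype_matrix()] providing dosages for LD; must
#'   contain every SNP in `stats`.
#' @param r2_threshold clumping r-squared (default 0.2, the score-
#'   construction setting; 0.8 is the looser "independent signal"
#'   reporting convention).
#' @param window_kb half-window in kb around the index SNP (default 250).
#' @param p_threshold only SNPs at or below this p enter clumping
#'   (default 1: all).
#' @return data.frame of index SNPs (id, chr, bp, p, n_clumped,
#'   clumped ids semicolon-joined), ordered by p.
#' @export
clump <- function(stats, geno, r2_threshold = 0.2, window_kb = 250,
                  p_threshold = 1) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1, window_kb > 0)
  pcol <- if ("P_GXE" %in% names(stats)) "P_GXE" else "P_G"
  pos <- match(stats$SNP, geno$snps$id)
  if (anyNA(pos)) {
    stop("SNP(s) in summary statistics absent from genotypes: ",
         paste(utils::head(stats$SNP[is.na(pos)], 5), collapse = ", "))
  }
  cand <- data.frame(snp = stats$SNP, chr = stats$CHR, bp = stats$BP,
                     p = stats[[pcol]], col = pos,
                     stringsAsFactors = FALSE)
  cand <- cand[!is.na(cand$p) & cand$p <= p_threshold, , drop = FALSE]
  ord <- order(cand$p, chr_key(cand$chr), cand$bp, cand$snp)
  cand <- cand[ord, , drop = FALSE]

  assigned <- rep(FALSE, nrow(cand))
  out <- list()
  for (i in seq_len(nrow(cand))) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    idx <- cand[i, ]
    near <- which(!assigned &
                    cand$chr == idx$chr &
                    abs(cand$bp - idx$bp) <= window_kb * 1000)
    members <- character(0)
    if (length(near)) {
      g0 <- geno$dosages[, idx$col]
      r2 <- vapply(near, function(k) ld_r2(g0, geno$dosages[, cand$col[k]]),
                   numeric(1))
      take <- near[!is.na(r2) & r2 >= r2_threshold]
      assigned[take] <- TRUE
      members <- cand$snp[take]
    }
    out[[length(out) + 1L]] <- data.frame(
      snp = idx$snp, chr = idx$chr, bp = idx$bp, p = idx$p,
      n_clumped = length(members),
      clumped = paste(members, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(snp = character(), chr = character(), bp = integer(),
               p = numeric(), n_clumped = integer(), clumped = character())
  rownames(res) <- NULL
  res
}

#' Genomic inflation factor
#'
#' Median of the chi-squared(1) statistics implied by the p-values,
#' divided by the null median of chi-squared(1) (about 0.4549).  Values
#' near 1 indicate a calibrated test; values above 1 indicate inflation,
#' e.g. the spurious inflation a model-based interaction test shows under
#' heteroscedastic residuals.
#'
#' @param p p-value vector (NAs dropped).
#' @return lambda, a positive scalar.
#' @export
genomic_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' QQ table of observed vs expected -log10 p
#'
#' @param p p-value vector.
#' @return data.frame with `expected` and `observed` -log10 p columns,
#'   sorted for plotting, plus the inflation factor as attribute
#'   `"lambda"`.
#' @export
qq_table <- function(p) {
  p <- sort(p[!is.na(p)])
  n <- length(p)
  out <- data.frame(expected = -log10(stats::ppoints(n)),
                    observed = -log10(p))
  attr(out, "lambda") <- genomic_lambda(p)
  out
}

#' Layered Bonferroni significance thresholds
#'
#' A multi-environment interaction study corrects at several layers:
#' within one scan (`base_alpha / n_tests`), across the analysed
#' environments (the per-analysis threshold further divided by
#' `n_environments`), and for the polygenic-score comparison across both
#' environments and the two interaction-score families
#' (`base_alpha / n_environments / n_models`).
#'
#' @param base_alpha nominal level (e.g. 0.05, or 5e-8 for the
#'   genome-wide SNP convention).
#' @param layer `"per-analysis"`, `"cross-environment"` or `"iprs"`.
#' @param n_tests tests within one scan (for `"per-analysis"` and
#'   `"cross-environment"`).
#' @param n_environments number of environments (default 25).
#' @param n_models number of score families (default 2).
#' @return The significance threshold.
#' @examples
#' bonferroni_threshold(5e-8, "cross-environment", n_tests = 1)   # 2e-9
#' bonferroni_threshold(0.05, "per-analysis", n_tests = 19831)
#' bonferroni_threshold(0.05, "iprs")                             # 1e-3
#' @export
bonferroni_threshold <- function(base_alpha,
                                 layer = c("per-analysis",
                                           "cross-environment", "iprs"),
                                 n_tests = 1, n_environments = 25,
                                 n_models = 2) {
  layer <- match.arg(layer)
  stopifnot(base_alpha > 0, n_tests >= 1, n_environments >= 1,
            n_models >= 1)
  switch(layer,
         "per-analysis" = base_alpha / n_tests,
         "cross-environment" = base_alpha / n_tests / n_environments,
         "iprs" = base_alpha / n_environments / n_models)
}
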