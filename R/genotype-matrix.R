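#' Construct a genotype matrix container
#'
#' Bundles a samples-by-SNPs additive dosage matrix with per-SNP metadata
#' and per-sample sex.  Dosages count copies of each SNP's effect allele:
#' autosomal values are 0, 1 or 2; on the X chromosome male dosages are 0
#' or 2 (single allele copies counted twice, the convention used by
#' genome-wide scans that include haploid male X genotypes).  Missing
#' genotypes are `NA` -- never a numeric sentinel.
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns; values
#'   in \{0, 1, 2, NA\}.
#' @param snps data.frame with one row per SNP and columns `id`, `chr`
#'   (1-22, "X" or "23"), `bp` (1-based), `effect_allele`, `other_allele`,
#'   and optionally `info` (imputation quality in \[0, 1\]).  `maf` and
#'   `missingness` are recomputed from the dosages.
#' @param sample_ids character vector of unique sample identifiers.
#' @param sex per-sample sex, one of `"male"`, `"female"`, `"unknown"`.
#'   Defaults to `"unknown"`; required to be informative only when X
#'   chromosome SNPs are present.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `snps`, `sample_ids`, `sex`.
#' @examples
#' g <- genotype_matrix(
#'   matrix(c(0, 1, 2, 1), 2, 2),
#'   data.frame(id = c("rs1", "rs2"), chr = "1", bp = c(100L, 200L),
#'              effect_allele = "A", other_allele = "G"),
#'   sample_ids = c("s1", "s2"))
#' g$snps$maf
#' @export
genotype_matrix <- function(dosages, snps, sample_ids = rownames(dosages),
                            sex = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  m <- ncol(dosages)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) stop("sample_ids length must match nrow(dosages)")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (!is.data.frame(snps) || nrow(snps) != m) {
    stop("snps must be a data.frame with one row per dosage column")
  }
  required <- c("id", "chr", "bp", "effect_allele", "other_allele")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols)) {
    stop("snps is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  snps$id <- as.character(snps$id)
  snps$chr <- as.character(snps$chr)
  snps$bp <- as.integer(snps$bp)
  chr_key(snps$chr)  # validates labels
  if (is.null(sex)) sex <- rep("unknown", n)
  sex <- as.character(sex)
  if (length(sex)) {
    sex <- match.arg(sex, c("male", "female", "unknown"),
                     several.ok = TRUE)
  }
  if (length(sex) == 1L) sex <- rep(sex, n)
  if (length(sex) != n) stop("sex must have one entry per sample")

  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (m > 0 && any(is_x_chr(snps$chr))) {
    xcols <- which(is_x_chr(snps$chr))
    male_x <- dosages[sex == "male", xcols, drop = FALSE]
    if (any(male_x == 1, na.rm = TRUE)) {
      stop("male X-chromosome dosages must be 0 or 2")
    }
  }

  stats <- snp_summaries(dosages)
  snps$maf <- stats$maf
  snps$missingness <- stats$missingness
  if (is.null(snps$info)) snps$info <- rep(NA_real_, nrow(snps))
  rownames(snps) <- NULL
  dimnames(dosages) <- list(sample_ids, snps$id)

  structure(list(dosages = dosages, snps = snps,
                 sample_ids = sample_ids, sex = sex),
            class = "genotype_matrix")
}

# per-SNP effect-allele frequency (folded to MAF), and missingness
snp_summaries <- function(dosages) {
  n_obs <- colSums(!is.na(dosages))
  freq <- colMeans(dosages, na.rm = TRUE) / 2
  freq[n_obs == 0] <- NA_real_
  maf <- pmin(freq, 1 - freq)
  miss <- 1 - n_obs / nrow(dosages)
  if (nrow(dosages) == 0) miss <- rep(NA_real_, ncol(dosages))
  list(eaf = freq, maf = maf, missingness = miss)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs\n",
              length(x$sample_ids), nrow(x$snps)))
  if (nrow(x$snps)) {
    cat(sprintf("  chromosomes: %s\n",
                paste(unique(x$snps$chr), collapse = ", ")))
    cat(sprintf("  MAF range: %.4g-%.4g; mean missingness: %.3g\n",
                min(x$snps$maf, na.rm = TRUE), max(x$snps$maf, na.rm = TRUE),
                mean(x$snps$missingness)))
  }
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param samples sample indices, logical mask or ids to keep.
#' @param snps SNP indices, logical mask or ids to keep.
#' @return A new `genotype_matrix` (MAF and missingness recomputed).
#' @export
subset_genotypes <- function(x, samples = NULL, snps = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  si <- resolve_index(samples, x$sample_ids)
  vi <- resolve_index(snps, x$snps$id)
  genotype_matrix(x$dosages[si, vi, drop = FALSE],
                  x$snps[vi, setdiff(names(x$snps), c("maf", "missingness")),
                         drop = FALSE],
                  sample_ids = x$sample_ids[si], sex = x$sex[si])
}

resolve_index <- function(idx, ids) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) stop("unknown id(s): ", paste(idx[is.na(pos)], collapse = ", "))
    return(pos)
  }
  if (is.logical(idx)) return(which(idx))
  as.integer(idx)
}
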