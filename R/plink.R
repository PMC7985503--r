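#' Read PLINK binary genotype files
#'
#' Decodes a SNP-major PLINK .bed file (magic bytes `0x6C 0x1B`, mode byte
#' `0x01`) together with its .bim and .fam companions into a
#' [genotype_matrix()].  The 2-bit genotype codes are `00` = homozygous A1,
#' `01` = missing, `10` = heterozygous, `11` = homozygous A2.  The returned
#' dosage counts copies of the *effect* allele, which defaults to the bim
#' A1 allele; the counted allele is always recorded in the SNP table
#' (`effect_allele`) so that coefficient signs downstream are unambiguous.
#'
#' @param prefix path prefix; `<prefix>.bed/.bim/.fam` are read.  Ignored
#'   when the three explicit paths are given.
#' @param bed,bim,fam explicit file paths (all three or none).
#' @param effect which bim allele the dosage counts: `"A1"` (default) or
#'   `"A2"`.
#' @return A [genotype_matrix()].
#' @seealso [write_plink()]
#' @export
read_plink <- function(prefix = NULL, bed = NULL, bim = NULL, fam = NULL,
                       effect = c("A1", "A2")) {
  effect <- match.arg(effect)
  if (!is.null(prefix)) {
    bed <- bed %||% paste0(prefix, ".bed")
    bim <- bim %||% paste0(prefix, ".bim")
    fam <- fam %||% paste0(prefix, ".fam")
  }
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }

  bim_df <- if (file.size(bim) > 0) {
    utils::read.table(bim, header = FALSE, sep = "\t",
                      colClasses = c("character", "character", "numeric",
                                     "integer", "character", "character"))
  } else {
    data.frame(V1 = character(), V2 = character(), V3 = numeric(),
               V4 = integer(), V5 = character(), V6 = character())
  }
  names(bim_df) <- c("chr", "id", "cm", "bp", "a1", "a2")
  fam_df <- utils::read.table(fam, header = FALSE,
                              colClasses = c("character", "character",
                                             "character", "character",
                                             "integer", "character"))
  names(fam_df) <- c("fid", "iid", "pat", "mat", "sex_code", "pheno")

  n <- nrow(fam_df)
  m <- nrow(bim_df)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6C) || raw[2] != as.raw(0x1B)) {
    stop("not a PLINK .bed file (bad magic bytes): ", bed)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("unsupported .bed mode byte (only SNP-major 0x01 is supported): ", bed)
  }
  bytes_per_snp <- ceiling(n / 4)
  expected <- 3L + bytes_per_snp * m
  if (length(raw) != expected) {
    stop(sprintf(".bed file truncated or oversized: %d bytes, expected %d",
                 length(raw), expected))
  }

  body <- as.integer(raw[-(1:3)])
  # lookup: for each byte value 0..255 the four 2-bit codes' A1 allele counts
  lut <- plink_decode_lut()
  if (m > 0 && n > 0) {
    codes <- lut[body + 1L, , drop = FALSE]          # (bytes) x 4
    codes <- t(matrix(t(codes), nrow = 4L * bytes_per_snp, ncol = m))
    a1_count <- codes[, seq_len(n), drop = FALSE]    # drop pad slots
    a1_count <- t(a1_count)                          # samples x SNPs
  } else {
    a1_count <- matrix(numeric(0), nrow = n, ncol = m)
  }
  dos <- if (effect == "A1") a1_count else 2 - a1_count

  snps <- data.frame(id = bim_df$id, chr = bim_df$chr, bp = bim_df$bp,
                     effect_allele = if (effect == "A1") bim_df$a1 else bim_df$a2,
                     other_allele = if (effect == "A1") bim_df$a2 else bim_df$a1,
                     stringsAsFactors = FALSE)
  sex <- c("unknown", "male", "female")[match(fam_df$sex_code, c(0L, 1L, 2L),
                                              nomatch = 1L)]
  genotype_matrix(dos, snps, sample_ids = fam_df$iid, sex = sex)
}

# A1-copy count for each (byte value, slot); slot 1 = lowest 2 bits
plink_decode_lut <- function() {
  codes <- c(2, NA, 1, 0)  # 00, 01, 10, 11 -> A1 copies
  b <- 0:255
  sapply(0:3, function(k) codes[bitwAnd(bitwShiftR(b, 2L * k), 3L) + 1L])
}

#' Write PLINK binary genotype files
#'
#' Inverse of [read_plink()]: encodes a [genotype_matrix()] as a SNP-major
#' .bed plus .bim/.fam text companions.  The effect allele is written as
#' bim A1, so `read_plink(write_plink(x))` reproduces the dosage matrix,
#' sample ids and SNP metadata exactly (missing values included).
#'
#' @param x a [genotype_matrix()].
#' @param prefix output path prefix (`<prefix>.bed/.bim/.fam`).
#' @return Invisibly, the three file paths.
#' @export
write_plink <- function(x, prefix) {
  stopifnot(inherits(x, "genotype_matrix"))
  n <- length(x$sample_ids)
  m <- nrow(x$snps)

  bim <- data.frame(chr = x$snps$chr, id = x$snps$id,
                    cm = rep(0, m), bp = x$snps$bp,
                    a1 = x$snps$effect_allele, a2 = x$snps$other_allele)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  sex_code <- match(x$sex, c("male", "female"), nomatch = 0L) # unknown -> 0
  fam <- data.frame(fid = x$sample_ids, iid = x$sample_ids, pat = 0, mat = 0,
                    sex = sex_code, pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  bed_path <- paste0(prefix, ".bed")
  con <- file(bed_path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6C, 0x1B, 0x01)), con)
  if (m > 0) {
    bytes_per_snp <- ceiling(n / 4)
    # effect-allele count -> 2-bit code: 2 -> 00, NA -> 01, 1 -> 10, 0 -> 11
    code_of <- function(d) {
      out <- integer(length(d))
      out[is.na(d)] <- 1L
      out[!is.na(d) & d == 2] <- 0L
      out[!is.na(d) & d == 1] <- 2L
      out[!is.na(d) & d == 0] <- 3L
      out
    }
    pad <- 4L * bytes_per_snp - n
    for (j in seq_len(m)) {
      codes <- c(code_of(x$dosages[, j]), rep(0L, pad))
      slots <- matrix(codes, nrow = 4L)
      bytes <- slots[1, ] + bitwShiftL(slots[2, ], 2L) +
        bitwShiftL(slots[3, ], 4L) + bitwShiftL(slots[4, ], 6L)
      writeBin(as.raw(bytes), con)
    }
  }
  invisible(c(bed = bed_path, bim = paste0(prefix, ".bim"),
              fam = paste0(prefix, ".fam")))
}
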