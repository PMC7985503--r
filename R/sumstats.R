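#' Write per-SNP summary statistics to TSV
#'
#' The interaction-scan dialect has the fixed column order
#' `SNP CHR BP A1 A2 ENV N BETA_G SE_G BETA_E BETA_GXE SE_GXE STAT_GXE
#' P_GXE`; the main-effect (GWAS) dialect drops `ENV` and the interaction
#' columns and carries the main-effect test instead
#' (`SNP CHR BP A1 A2 N BETA_G SE_G STAT_G P_G`).  `A1` is the counted
#' effect allele.  Numbers are written with full double precision
#' (p-values in scientific notation below 1e-4), so `read_summary_stats()`
#' recovers the table exactly.
#'
#' @param results data.frame as produced by [run_gweis()] or [run_gwas()].
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_summary_stats <- function(results, path) {
  dialect <- if ("P_GXE" %in% names(results)) "gweis" else "gwas"
  cols <- sumstats_columns(dialect)
  absent <- setdiff(cols, names(results))
  if (length(absent)) {
    stop("summary statistics missing column(s): ", paste(absent, collapse = ", "))
  }
  out <- results[, cols, drop = FALSE]
  pcol <- if (dialect == "gweis") "P_GXE" else "P_G"
  for (nm in cols) {
    if (is.numeric(out[[nm]]) && nm != "N" && nm != "BP") {
      v <- out[[nm]]
      s <- formatC(v, format = "g", digits = 17)
      if (nm == pcol) {
        sci <- !is.na(v) & v < 1e-4 & v > 0
        s[sci] <- formatC(v[sci], format = "e", digits = 16)
      }
      s[is.na(v)] <- "NA"
      out[[nm]] <- trimws(s)
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read per-SNP summary statistics from TSV
#'
#' Detects the interaction-scan vs main-effect dialect from the header.
#'
#' @param path TSV path written by [write_summary_stats()] (or compatible).
#' @return data.frame with typed columns.
#' @export
read_summary_stats <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  dialect <- if ("P_GXE" %in% names(df)) "gweis" else "gwas"
  cols <- sumstats_columns(dialect)
  absent <- setdiff(cols, names(df))
  if (length(absent)) {
    stop("not a recognised summary-statistics file; missing: ",
         paste(absent, collapse = ", "))
  }
  df$CHR <- as.character(df$CHR)
  df$BP <- as.integer(df$BP)
  df$N <- as.integer(df$N)
  for (nm in setdiff(cols, c("SNP", "CHR", "BP", "A1", "A2", "ENV", "N"))) {
    df[[nm]] <- as.numeric(df[[nm]])
  }
  df[, cols, drop = FALSE]
}

sumstats_columns <- function(dialect = c("gweis", "gwas")) {
  dialect <- match.arg(dialect)
  if (dialect == "gweis") {
    c("SNP", "CHR", "BP", "A1", "A2", "ENV", "N",
      "BETA_G", "SE_G", "BETA_E", "BETA_GXE", "SE_GXE", "STAT_GXE", "P_GXE")
  } else {
    c("SNP", "CHR", "BP", "A1", "A2", "N", "BETA_G", "SE_G", "STAT_G", "P_G")
  }
}
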