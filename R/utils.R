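# internal helpers shared across modules

# Chromosome labels are kept as character; "23" and "X" both denote the X
# chromosome.  This maps them onto an integer sort key.
chr_key <- function(chr) {
  chr <- toupper(as.character(chr))
  chr[chr == "X"] <- "23"
  key <- suppressWarnings(as.integer(chr))
  if (anyNA(key)) {
    stop("unrecognised chromosome label(s): ",
         paste(unique(chr[is.na(key)]), collapse = ", "))
  }
  key
}

is_x_chr <- function(chr) chr_key(chr) == 23L

# Deterministic per-stage seeds derived from one master seed, so pipeline
# stages can be re-run independently.  Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(genotypes = 11L, environment = 23L, phenotype = 37L,
               missingness = 41L, holdout = 53L, pipeline = 67L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 2654435761 + off) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# significance formatting used by the summary-statistics writer: >= 3
# significant digits, scientific below 1e-4
format_pval <- function(p) {
  out <- character(length(p))
  out[is.na(p)] <- "NA"
  ok <- !is.na(p)
  sci <- ok & p < 1e-4 & p > 0
  out[sci] <- formatC(p[sci], format = "e", digits = 3)
  plain <- ok & !sci
  out[plain] <- formatC(p[plain], format = "g", digits = 6)
  out
}
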