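#' Declare the column layout of a cohort table
#'
#' A cohort schema names the phenotype column, the typed environment
#' columns, the numeric covariate columns and (optionally) a hold-out flag
#' column.  Environment types follow the questionnaire conventions of
#' biobank-style exposures: `"continuous"`, `"ordinal"` (integer codes
#' `0 .. levels-1`; analysed as continuous downstream) and `"count"`
#' (integer `0 .. max`).
#'
#' @param phenotype name of the numeric phenotype column.
#' @param environments named list; each element is `"continuous"`, or a
#'   list `list(type = "ordinal", levels = k)` /
#'   `list(type = "count", max = m)`.
#' @param covariates character vector of numeric covariate column names.
#' @param id name of the sample-id column (default `"IID"`).
#' @param holdout optional name of a logical hold-out flag column.
#' @return A list of class `cohort_schema`.
#' @export
cohort_schema <- function(phenotype, environments = list(),
                          covariates = character(), id = "IID",
                          holdout = NULL) {
  environments <- lapply(environments, function(e) {
    if (is.character(e) && length(e) == 1L) e <- list(type = e)
    if (!is.list(e) || is.null(e$type)) {
      stop("each environment spec must be a type string or list(type = ...)")
    }
    if (!e$type %in% c("continuous", "ordinal", "count")) {
      stop("undeclared environment type: ", e$type)
    }
    if (e$type == "ordinal" && is.null(e$levels)) {
      stop("ordinal environments need a 'levels' count")
    }
    if (e$type == "count" && is.null(e$max)) {
      stop("count environments need a 'max'")
    }
    e
  })
  structure(list(phenotype = phenotype, environments = environments,
                 covariates = covariates, id = id, holdout = holdout),
            class = "cohort_schema")
}

#' Read a cohort table from TSV
#'
#' Reads a tab-separated cohort file (header row, `.` decimal, blank cells
#' meaning missing) and validates it against a [cohort_schema()]: ordinal
#' environment codes must be integers inside their declared level range,
#' counts inside `0..max`.
#'
#' @param path TSV file path.
#' @param schema a [cohort_schema()].
#' @return A data.frame of class `cohort_table` carrying the schema as an
#'   attribute; the hold-out column (if any) is coerced to logical.
#' @export
read_cohort <- function(path, schema) {
  stopifnot(inherits(schema, "cohort_schema"))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          na.strings = c("", "NA"), stringsAsFactors = FALSE,
                          check.names = FALSE)
  as_cohort_table(df, schema)
}

#' Validate a data.frame as a cohort table
#'
#' @param df data.frame with the columns named by `schema`.
#' @param schema a [cohort_schema()].
#' @return The validated `cohort_table`.
#' @export
as_cohort_table <- function(df, schema) {
  stopifnot(inherits(schema, "cohort_schema"))
  needed <- c(schema$id, schema$phenotype, names(schema$environments),
              schema$covariates, schema$holdout)
  absent <- setdiff(needed, names(df))
  if (length(absent)) {
    stop("cohort table is missing column(s): ", paste(absent, collapse = ", "))
  }
  df[[schema$id]] <- as.character(df[[schema$id]])
  if (anyDuplicated(df[[schema$id]])) stop("duplicate sample ids in cohort")
  df[[schema$phenotype]] <- as.numeric(df[[schema$phenotype]])
  for (nm in names(schema$environments)) {
    e <- schema$environments[[nm]]
    v <- as.numeric(df[[nm]])
    obs <- v[!is.na(v)]
    if (e$type %in% c("ordinal", "count")) {
      if (any(obs != round(obs))) {
        stop(sprintf("non-integer code in %s environment '%s'", e$type, nm))
      }
      hi <- if (e$type == "ordinal") e$levels - 1 else e$max
      if (any(obs < 0 | obs > hi)) {
        stop(sprintf("environment '%s' has codes outside 0..%d", nm, hi))
      }
    }
    df[[nm]] <- v
  }
  for (nm in schema$covariates) df[[nm]] <- as.numeric(df[[nm]])
  if (!is.null(schema$holdout)) {
    h <- df[[schema$holdout]]
    if (is.character(h)) h <- toupper(h) %in% c("TRUE", "T", "1")
    df[[schema$holdout]] <- as.logical(h)
  }
  structure(df, schema = schema, class = c("cohort_table", "data.frame"))
}

#' Write a cohort table to TSV
#'
#' @param x a `cohort_table` (or plain data.frame).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  sc <- attr(x, "schema")
  cat(sprintf("<cohort_table> %d samples; phenotype '%s'; %d environment(s); %d covariate(s)\n",
              nrow(x), sc$phenotype, length(sc$environments),
              length(sc$covariates)))
  NextMethod()
}
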