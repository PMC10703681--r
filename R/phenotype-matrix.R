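#' Masked phenotype matrix
#'
#' The central container: an N x P numeric value matrix with missing entries
#' stored as `NA`, the matching N x P observedness mask (1 = observed,
#' 0 = missing), sample identifiers and a [pheno_schema()]. Every stage of the
#' pipeline consumes and produces this object; no operation outside the
#' masking module ever alters the mask.
#'
#' @param values numeric matrix, `NA` at missing cells. Column order must
#'   match the schema (continuous block first).
#' @param ids character vector of unique sample identifiers, one per row.
#' @param schema a [pheno_schema()].
#' @param mask optional integer/logical matrix; defaults to `!is.na(values)`.
#' @return An object of class `pheno_matrix`: list with elements `values`
#'   (NA at masked cells), `mask` (integer 0/1), `ids`, `schema`.
#' @export
pheno_matrix <- function(values, ids, schema, mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- !is.na(values)
  mask <- matrix(as.integer(mask), nrow(values), ncol(values))
  if (!identical(dim(values), dim(mask))) {
    stop_pc("values and mask dimensions differ")
  }
  if (ncol(values) != nrow(schema)) {
    stop_pc("schema declares ", nrow(schema), " phenotypes but matrix has ",
            ncol(values), " columns")
  }
  if (length(ids) != nrow(values)) stop_pc("one id required per row")
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop_pc("duplicate sample ids: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  # the sentinel is NA and is never read as data
  values[mask == 0L] <- NA_real_
  if (any(is.na(values) & mask == 1L)) {
    stop_pc("cell marked observed but value is missing")
  }
  bin <- which(schema_is_binary(schema))
  for (j in bin) {
    v <- values[mask[, j] == 1L, j]
    if (length(v) && !all(v %in% c(0, 1))) {
      stop_pc("binary phenotype '", schema$name[j],
              "' contains values outside {0,1}")
    }
  }
  dimnames(values) <- list(ids, schema$name)
  dimnames(mask) <- dimnames(values)
  structure(list(values = values, mask = mask, ids = ids, schema = schema),
            class = "pheno_matrix")
}

#' @export
print.pheno_matrix <- function(x, ...) {
  n_obs <- sum(x$mask)
  cat(sprintf(
    "Masked phenotype matrix: %d individuals x %d phenotypes (%.1f%% observed)\n",
    nrow(x$values), ncol(x$values),
    if (length(x$mask)) 100 * n_obs / length(x$mask) else NA_real_))
  cat(sprintf("  %d continuous-like, %d binary phenotypes\n",
              schema_C(x$schema), nrow(x$schema) - schema_C(x$schema)))
  invisible(x)
}

#' @export
dim.pheno_matrix <- function(x) dim(x$values)

subset_rows <- function(data, idx) {
  pheno_matrix(data$values[idx, , drop = FALSE], data$ids[idx], data$schema,
               data$mask[idx, , drop = FALSE])
}

#' Missingness summary per phenotype
#'
#' @param data a [pheno_matrix()].
#' @return data frame with per-phenotype observed counts and missingness rate.
#' @export
missingness_summary <- function(data) {
  obs <- colSums(data$mask)
  data.frame(phenotype = data$schema$name, kind = data$schema$kind,
             n_observed = obs, n_missing = nrow(data$values) - obs,
             missing_rate = 1 - obs / max(1L, nrow(data$values)),
             row.names = NULL, stringsAsFactors = FALSE)
}
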