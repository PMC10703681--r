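#' Read a phenotype table
#'
#' Reads a delimited samples-by-phenotypes table (TSV by default, CSV for
#' `.csv` files) with a header row and a leading `IID` column, validates it
#' against a schema, and returns a [pheno_matrix()]. Empty fields, `NA` and
#' `NaN` (case-insensitive) are treated as missing; columns are reordered so
#' continuous/ordinal phenotypes precede binary ones, matching the
#' index-partition convention the model uses. The original file order is kept
#' in the schema for round-trip writing.
#'
#' @param path file path.
#' @param schema a [pheno_schema()] or path to a JSON schema file.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return A [pheno_matrix()].
#' @seealso [write_phenotype_table()]
#' @export
read_phenotype_table <- function(path, schema, sep = NULL) {
  if (is.character(schema) && length(schema) == 1L) schema <- read_schema(schema)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = NULL,
                           quote = "", comment.char = "")
  if (!ncol(raw)) stop_pc("no columns found in ", path)
  id_col <- names(raw)[1]
  pheno_cols <- names(raw)[-1]
  unknown <- setdiff(pheno_cols, schema$name)
  if (length(unknown)) {
    stop_pc("column(s) in file but not in schema: ",
            paste(unknown, collapse = ", "))
  }
  absent <- setdiff(schema$name, pheno_cols)
  if (length(absent)) {
    stop_pc("schema phenotype(s) missing from file: ",
            paste(absent, collapse = ", "))
  }
  ids <- raw[[id_col]]
  P <- nrow(schema)
  values <- matrix(NA_real_, nrow(raw), P)
  for (j in seq_len(P)) {
    nm <- schema$name[j]
    tok <- trimws(raw[[nm]])
    miss <- tok == "" | tolower(tok) %in% c("na", "nan")
    num <- suppressWarnings(as.numeric(tok))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      stop_pc("non-numeric value '", tok[which(bad)[1]], "' in phenotype '",
              nm, "' (row ", which(bad)[1], ")")
    }
    num[miss] <- NA_real_
    values[, j] <- num
  }
  pheno_matrix(values, ids, schema)
}

#' Write a phenotype table
#'
#' Writes a [pheno_matrix()] back to delimited text with missing cells as
#' `NA`, restoring the original column order recorded in the schema.
#'
#' @param data a [pheno_matrix()] (or completed matrix from [predict.phenocomplete()]).
#' @param path output file path; `.csv` extension selects comma separation.
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(data, path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  ord <- attr(data$schema, "original_order") %||% data$schema$name
  vals <- data$values[, match(ord, data$schema$name), drop = FALSE]
  df <- data.frame(IID = data$ids, as.data.frame(vals), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("IID", ord)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Split individuals into train / validation / test sets
#'
#' Randomly assigns rows to three disjoint sets. Following the benchmark
#' protocol, `test_fraction = 0.5` reserves half the individuals for testing
#' and `validation_fraction = 0.2` then splits the remainder 80-20 into
#' training and validation.
#'
#' @param data a [pheno_matrix()].
#' @param test_fraction proportion of all rows withheld for testing, in `[0,1)`.
#' @param validation_fraction proportion of the non-test rows used for
#'   validation, in `[0,1)`.
#' @param seed integer seed; identical seeds give identical splits.
#' @return A list with elements `train`, `validation`, `test`
#'   (each a [pheno_matrix()]) and `index` (the row assignment).
#' @export
split_individuals <- function(data, test_fraction = 0.5,
                              validation_fraction = 0.2, seed = 1) {
  if (test_fraction < 0 || test_fraction >= 1) {
    stop_pc("test_fraction must be in [0, 1)")
  }
  if (validation_fraction < 0 || validation_fraction >= 1) {
    stop_pc("validation_fraction must be in [0, 1)")
  }
  N <- nrow(data$values)
  perm <- with_seed(derive_seed(seed, 1L), sample.int(N))
  n_test <- round(N * test_fraction)
  n_val <- round((N - n_test) * validation_fraction)
  if (N > 0 && test_fraction > 0 && n_test == 0 ||
      N > 0 && validation_fraction > 0 && (N - n_test) > 0 && n_val == 0) {
    stop_pc("N = ", N, " too small for the requested non-empty split")
  }
  test_idx <- sort(perm[seq_len(n_test)])
  val_idx <- sort(perm[n_test + seq_len(n_val)])
  train_idx <- sort(perm[-seq_len(n_test + n_val)])
  assignment <- rep("train", N)
  assignment[test_idx] <- "test"
  assignment[val_idx] <- "validation"
  list(train = subset_rows(data, train_idx),
       validation = subset_rows(data, val_idx),
       test = subset_rows(data, test_idx),
       index = assignment)
}

#' Fit normalization statistics on a training split
#'
#' Continuous (and ordinal) phenotypes are standardized to zero mean, unit
#' variance using statistics of the observed training entries only; the
#' population (divide-by-N) standard deviation is used. Binary phenotypes are
#' not rescaled here: they keep their 0/1 coding in the data container and are
#' recoded to -0.5/+0.5 at the encoder input (recorded in the returned object).
#' Test data must be normalized with training statistics to avoid leakage.
#'
#' @param train a [pheno_matrix()] of training rows.
#' @return An object of class `pheno_normalization` with per-column `center`,
#'   `scale` (NA for binary columns) and the binary recoding convention.
#' @export
fit_normalization <- function(train) {
  schema <- train$schema
  P <- nrow(schema)
  center <- rep(NA_real_, P)
  scale <- rep(NA_real_, P)
  for (j in seq_len(P)) {
    if (schema_is_binary(schema)[j]) next
    v <- train$values[train$mask[, j] == 1L, j]
    if (length(v) == 0L) {
      stop_pc("phenotype '", schema$name[j], "' has no observed training values")
    }
    if (length(v) < 2L) {
      stop_pc("phenotype '", schema$name[j],
              "' has fewer than 2 observed training values")
    }
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))  # population SD
    if (s <= 0) {
      stop_pc("phenotype '", schema$name[j],
              "' is constant in the training split (zero variance)")
    }
    center[j] <- m
    scale[j] <- s
  }
  structure(list(center = center, scale = scale,
                 names = schema$name, kinds = schema$kind,
                 binary_recoding = c(`0` = -0.5, `1` = 0.5),
                 sd_estimator = "population"),
            class = "pheno_normalization")
}

#' Apply or invert normalization
#'
#' Transforms only observed cells; the mask is untouched and missing cells
#' stay missing. `forward` followed by `inverse` is the identity on observed
#' values.
#'
#' @param data a [pheno_matrix()].
#' @param stats a `pheno_normalization` from [fit_normalization()].
#' @param direction `"forward"` (raw to standardized) or `"inverse"`.
#' @return A [pheno_matrix()] with transformed continuous columns.
#' @export
apply_normalization <- function(data, stats,
                                direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  if (!identical(stats$names, data$schema$name) ||
      !identical(stats$kinds, data$schema$kind)) {
    stop_pc("normalization statistics do not match the data schema")
  }
  vals <- data$values
  for (j in seq_len(ncol(vals))) {
    if (is.na(stats$scale[j])) next  # binary column
    obs <- data$mask[, j] == 1L
    if (direction == "forward") {
      vals[obs, j] <- (vals[obs, j] - stats$center[j]) / stats$scale[j]
    } else {
      vals[obs, j] <- vals[obs, j] * stats$scale[j] + stats$center[j]
    }
  }
  pheno_matrix(vals, data$ids, data$schema, data$mask)
}
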