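#' Phenotype schema
#'
#' Declares, for every phenotype column, whether it is continuous, binary, or
#' ordinal. Ordinal phenotypes are modelled identically to continuous ones but
#' keep their label so reports can flag them. Columns are stored with all
#' continuous/ordinal phenotypes first, followed by the binary block; the
#' number of columns treated as continuous is the index partition `C` used by
#' the model and the loss.
#'
#' @param names character vector of phenotype identifiers (unique, non-empty).
#' @param kinds character vector, one of `"continuous"`, `"binary"`,
#'   `"ordinal"` per phenotype.
#' @return An object of class `pheno_schema`: a data frame with columns
#'   `name` and `kind`, attribute `C` (count of continuous+ordinal columns)
#'   and attribute `original_order` (the order in which names were supplied,
#'   used when writing tables back out).
#' @examples
#' sch <- pheno_schema(c("bmi", "smoker", "sbp"),
#'                     c("continuous", "binary", "continuous"))
#' attr(sch, "C")  # 2 continuous columns, ordered first
#' @export
pheno_schema <- function(names, kinds) {
  if (length(names) != length(kinds)) {
    stop_pc("`names` and `kinds` must have equal length")
  }
  if (anyDuplicated(names)) {
    stop_pc("duplicate phenotype names: ",
            paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  bad <- setdiff(unique(kinds), c("continuous", "binary", "ordinal"))
  if (length(bad)) {
    stop_pc("unknown phenotype kind(s): ", paste(bad, collapse = ", "))
  }
  original <- names
  cont <- kinds %in% c("continuous", "ordinal")
  ord <- c(which(cont), which(!cont))
  out <- data.frame(name = names[ord], kind = kinds[ord],
                    stringsAsFactors = FALSE)
  attr(out, "C") <- sum(cont)
  attr(out, "original_order") <- original
  class(out) <- c("pheno_schema", "data.frame")
  out
}

#' @export
print.pheno_schema <- function(x, ...) {
  cat(sprintf("Phenotype schema: %d phenotypes (%d continuous-like, %d binary)\n",
              nrow(x), attr(x, "C"), nrow(x) - attr(x, "C")))
  print.data.frame(x, ...)
  invisible(x)
}

schema_C <- function(schema) attr(schema, "C")

schema_is_binary <- function(schema) schema$kind == "binary"

#' Read or write a schema file
#'
#' The on-disk format is a JSON object mapping each phenotype name to
#' `{"kind": "continuous"|"binary"|"ordinal"}`.
#'
#' @param path file path.
#' @return `read_schema` returns a [pheno_schema()]; `write_schema` returns
#'   `path` invisibly.
#' @export
read_schema <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!length(obj)) stop_pc("schema file is empty: ", path)
  kinds <- vapply(obj, function(e) {
    if (is.list(e)) as.character(e$kind) else as.character(e)
  }, character(1))
  pheno_schema(names(obj), unname(kinds))
}

#' @rdname read_schema
#' @param schema a [pheno_schema()].
#' @export
write_schema <- function(schema, path) {
  ord <- attr(schema, "original_order")
  kinds <- schema$kind[match(ord, schema$name)]
  obj <- lapply(seq_along(ord), function(i) list(kind = kinds[i]))
  names(obj) <- ord
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

schema_compatible <- function(a, b) {
  identical(a$name, b$name) && identical(a$kind, b$kind)
}
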