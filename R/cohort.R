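#' Construct a cohort from a feature table
#'
#' A `cohort` couples a rectangular feature table (one row per patient) with
#' the [feature_schema()] it conforms to. Validation is strict: missing
#' values are rejected outright (the analysis assumes a complete-case
#' cohort), and every discrete value must be one of the schema's levels.
#'
#' @param table A data.frame whose columns match the schema feature names.
#'   May carry a `patient_id` column; otherwise `ids` must be given or row
#'   numbers are used.
#' @param schema A `feature_schema`.
#' @param ids Optional character vector of unique patient identifiers.
#' @return A `cohort` object with elements `ids`, `table`, `schema`, `m`.
#' @export
cohort <- function(table, schema, ids = NULL) {
  if (!is.data.frame(table)) ps_validation_error("cohort table must be a data.frame")
  if (is.null(ids)) {
    if ("patient_id" %in% names(table)) {
      ids <- as.character(table[["patient_id"]])
      table <- table[setdiff(names(table), "patient_id")]
    } else {
      ids <- as.character(seq_len(nrow(table)))
    }
  }
  ids <- as.character(ids)
  if (length(ids) != nrow(table)) ps_validation_error("ids length must equal row count")
  if (anyDuplicated(ids)) ps_validation_error("patient ids must be unique")
  nms <- schema_names(schema)
  missing_cols <- setdiff(nms, names(table))
  if (length(missing_cols))
    ps_validation_error(paste0("table is missing schema features: ",
                               paste(missing_cols, collapse = ", ")))
  table <- table[nms]

  for (f in schema) {
    col <- table[[f$name]]
    if (f$dtype == "numeric") {
      col <- suppressWarnings(as.numeric(as.character(col)))
      bad <- which(is.na(col))
      if (length(bad))
        ps_validation_error(sprintf("missing or non-numeric value in feature '%s', row %d",
                                    f$name, bad[1L]))
      table[[f$name]] <- col
    } else {
      col <- as.character(col)
      bad <- which(is.na(col) | !nzchar(col))
      if (length(bad))
        ps_validation_error(sprintf("missing value in feature '%s', row %d", f$name, bad[1L]))
      unknown <- which(!(col %in% f$levels))
      if (length(unknown))
        ps_validation_error(sprintf(
          "value '%s' in feature '%s' (row %d) is not a schema level",
          col[unknown[1L]], f$name, unknown[1L]))
      table[[f$name]] <- factor(col, levels = f$levels,
                                ordered = f$dtype == "ordinal")
    }
  }
  rownames(table) <- NULL
  structure(list(ids = ids, table = table, schema = schema, m = nrow(table)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients x %d features\n", x$m, ncol(x$table)))
  invisible(x)
}

#' Number of patients in a cohort
#' @param x A `cohort`.
#' @export
n_patients <- function(x) x$m

#' Subset a cohort by row index
#' @param x A `cohort`.
#' @param i Integer or logical index over patients.
#' @param ... Ignored.
#' @export
`[.cohort` <- function(x, i, ...) {
  out <- cohort(x$table[i, , drop = FALSE], x$schema, ids = x$ids[i])
  lab <- attr(x, "latent_cluster")
  if (!is.null(lab)) attr(out, "latent_cluster") <- lab[i]
  out
}

#' Read and write cohort tables as CSV
#'
#' The on-disk format is UTF-8 CSV with a header row, a leading `patient_id`
#' column and one column per schema feature; discrete features are stored as
#' their level strings (never 0/1 codes). Reading validates against the
#' schema: any empty cell or out-of-schema level is an error naming the
#' offending row and column.
#'
#' @param path CSV file path.
#' @param schema A `feature_schema`.
#' @return `read_cohort` returns a `cohort`.
#' @export
read_cohort <- function(path, schema) {
  tab <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = c("NA", ""))
  if (!"patient_id" %in% names(tab))
    ps_validation_error("cohort CSV must have a patient_id column")
  cohort(tab, schema)
}

#' @rdname read_cohort
#' @param x A `cohort`.
#' @export
write_cohort <- function(x, path) {
  tab <- x$table
  for (j in seq_along(tab)) if (is.factor(tab[[j]])) tab[[j]] <- as.character(tab[[j]])
  out <- cbind(data.frame(patient_id = x$ids, stringsAsFactors = FALSE), tab)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a cohort into training and test sets
#'
#' Patients are assigned at random (seeded) so that the training set holds
#' `round(fraction * m)` patients. The default fraction reproduces a
#' 22899 / 7568 partition of a 30467-patient cohort. All downstream fitted
#' transforms use the training set only and are then applied to the test set.
#'
#' @param x A `cohort`.
#' @param fraction Training proportion in (0, 1).
#' @param seed Integer seed; the same seed always yields the same partition.
#' @return A `split_cohort` with elements `train`, `test`, `fraction`, `seed`.
#' @export
split_train_test <- function(x, fraction = 0.7516, seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 || fraction >= 1)
    ps_param_error("fraction must lie strictly between 0 and 1")
  if (x$m < 2L) ps_param_error("cohort must have at least 2 patients to split")
  n_train <- round(fraction * x$m)
  n_train <- max(1L, min(x$m - 1L, n_train))
  idx <- local({
    set.seed(as.integer(seed))
    sample.int(x$m, n_train)
  })
  idx <- sort(idx)
  structure(list(train = x[idx], test = x[-idx],
                 fraction = fraction, seed = as.integer(seed)),
            class = "split_cohort")
}

#' @export
print.split_cohort <- function(x, ...) {
  cat(sprintf("<split_cohort> train %d / test %d (fraction %.4f, seed %d)\n",
              x$train$m, x$test$m, x$fraction, x$seed))
  invisible(x)
}
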