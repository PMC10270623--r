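#' Define a single feature of a cohort schema
#'
#' @param name Feature name (unique within a schema).
#' @param dtype One of `"numeric"`, `"ordinal"`, `"binary"`, `"categorical"`.
#' @param levels For ordinal features, the ordered level list (>= 2 levels);
#'   for binary exactly 2 levels; for categorical >= 2 levels. The *first*
#'   level of a binary feature is the one whose prevalence is parameterized
#'   by [cohort_spec()].
#' @param units Free-text units (numeric features), or `NULL`.
#' @return A `schema_feature` list.
#' @export
schema_feature <- function(name, dtype = c("numeric", "ordinal", "binary", "categorical"),
                           levels = NULL, units = NULL) {
  dtype <- match.arg(dtype)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    ps_validation_error("feature name must be a non-empty string")
  if (dtype == "numeric") {
    if (!is.null(levels)) ps_validation_error(sprintf("numeric feature '%s' cannot have levels", name))
  } else {
    if (is.null(levels) || length(levels) < 2L)
      ps_validation_error(sprintf("feature '%s' (%s) needs >= 2 levels", name, dtype))
    if (dtype == "binary" && length(levels) != 2L)
      ps_validation_error(sprintf("binary feature '%s' must have exactly 2 levels", name))
    if (anyDuplicated(levels))
      ps_validation_error(sprintf("feature '%s' has duplicated levels", name))
    levels <- as.character(levels)
  }
  structure(list(name = name, dtype = dtype, levels = levels, units = units),
            class = "schema_feature")
}

#' Assemble a typed feature schema
#'
#' A `feature_schema` is the contract every cohort table must satisfy: which
#' features exist, their kind (numeric / ordinal / binary / categorical) and,
#' for discrete features, the admissible levels in their canonical order.
#'
#' @param ... `schema_feature` objects, or a single list of them.
#' @return A `feature_schema` object.
#' @export
feature_schema <- function(...) {
  feats <- list(...)
  if (length(feats) == 1L && !inherits(feats[[1L]], "schema_feature")) feats <- feats[[1L]]
  if (!length(feats)) ps_validation_error("schema must contain at least one feature")
  ok <- vapply(feats, inherits, logical(1), "schema_feature")
  if (!all(ok)) ps_validation_error("all schema entries must be schema_feature objects")
  nms <- vapply(feats, `[[`, character(1), "name")
  if (anyDuplicated(nms)) ps_validation_error("feature names must be unique")
  names(feats) <- nms
  structure(feats, class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf("<feature_schema> %d features\n", length(x)))
  for (f in x) {
    lv <- if (is.null(f$levels)) "" else paste0(" [", paste(f$levels, collapse = " < "), "]")
    cat(sprintf("  %-16s %-12s%s\n", f$name, f$dtype, lv))
  }
  invisible(x)
}

schema_names <- function(schema) vapply(schema, `[[`, character(1), "name")
schema_dtypes <- function(schema) vapply(schema, `[[`, character(1), "dtype")

#' Features of a given kind
#' @param schema A `feature_schema`.
#' @param dtypes Character vector of kinds to keep.
#' @return Character vector of feature names.
#' @export
schema_features_of <- function(schema, dtypes) {
  schema_names(schema)[schema_dtypes(schema) %in% dtypes]
}

#' The default COPD cohort schema
#'
#' Sixteen features routinely available for a primary-care COPD cohort:
#' four numeric (age at index, BMI, FEV1 % predicted, eosinophil % of white
#' blood cells), one ordinal (inhaled-therapy line: none < mono < dual <
#' triple, from combinations of ICS/LABA/LAMA prescriptions), and eleven
#' binary features (sex, current-vs-ex smoking, and nine diagnosis flags).
#'
#' @return A `feature_schema` with 16 features.
#' @export
copd_schema <- function() {
  yn <- c("yes", "no")
  feature_schema(
    schema_feature("age", "numeric", units = "years"),
    schema_feature("bmi", "numeric", units = "kg/m^2"),
    schema_feature("fev1_pct_pred", "numeric", units = "% predicted"),
    schema_feature("eosinophil_pct", "numeric", units = "% of WBC"),
    schema_feature("therapy", "ordinal", levels = c("none", "mono", "dual", "triple")),
    schema_feature("sex", "binary", levels = c("male", "female")),
    schema_feature("smoking", "binary", levels = c("current", "ex")),
    schema_feature("anxiety", "binary", levels = yn),
    schema_feature("depression", "binary", levels = yn),
    schema_feature("atopy", "binary", levels = yn),
    schema_feature("crs", "binary", levels = yn),
    schema_feature("diabetes", "binary", levels = yn),
    schema_feature("hypertension", "binary", levels = yn),
    schema_feature("heart_failure", "binary", levels = yn),
    schema_feature("ihd", "binary", levels = yn),
    schema_feature("gerd", "binary", levels = yn)
  )
}

#' Read / write a schema as YAML
#'
#' The on-disk format is a YAML list with one entry per feature carrying
#' `name`, `dtype` and optionally `levels` and `units`.
#'
#' @param path File path.
#' @return `read_schema` returns a `feature_schema`.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  feats <- lapply(raw, function(f) {
    schema_feature(f$name, f$dtype, levels = f$levels, units = f$units)
  })
  feature_schema(feats)
}

#' @rdname read_schema
#' @param schema A `feature_schema`.
#' @export
write_schema <- function(schema, path) {
  raw <- lapply(unclass(schema), function(f) {
    out <- list(name = f$name, dtype = f$dtype)
    if (!is.null(f$levels)) out$levels <- as.list(f$levels)
    if (!is.null(f$units)) out$units <- f$units
    out
  })
  names(raw) <- NULL
  yaml::write_yaml(raw, path)
  invisible(path)
}
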