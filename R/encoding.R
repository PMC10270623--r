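#' Derive GOLD airflow-obstruction stage from FEV1 % predicted
#'
#' Stage 1: FEV1 % predicted at or above 80; stage 2: 50 up to but not
#' including 80; stage 3: 30 up to 50; stage 4: below 30. Total and
#' deterministic on the positive axis, monotone non-increasing in FEV1 %
#' predicted.
#'
#' @param fev1_pct_pred Numeric vector of FEV1 % predicted values (> 0).
#' @return Ordered factor with levels `"1" < "2" < "3" < "4"`.
#' @export
derive_gold_stage <- function(fev1_pct_pred) {
  x <- as.numeric(fev1_pct_pred)
  if (any(!is.finite(x)) || any(x <= 0))
    ps_stop("FEV1 % predicted must be positive and finite", "patsim_domain_error")
  stage <- ifelse(x >= 80, 1L, ifelse(x >= 50, 2L, ifelse(x >= 30, 3L, 4L)))
  factor(stage, levels = 1:4, ordered = TRUE)
}

#' Classify COPD inhaled-therapy line from prescribed drug classes
#'
#' From combinations of ICS (inhaled corticosteroid), LABA and LAMA
#' (long-acting bronchodilators): `none` = neither LABA nor LAMA prescribed
#' (ICS alone is still `none`); `mono` = exactly one of LABA/LAMA and no
#' ICS; `dual` = LABA&LAMA, LABA&ICS or LAMA&ICS; `triple` = all three.
#'
#' @param prescribed A list of character vectors, each a subset of
#'   `c("ICS", "LABA", "LAMA")`; a single character vector is treated as one
#'   patient.
#' @return Ordered factor with levels `none < mono < dual < triple`.
#' @export
derive_therapy_class <- function(prescribed) {
  if (is.character(prescribed) || (is.null(prescribed))) prescribed <- list(prescribed)
  if (!is.list(prescribed)) ps_validation_error("prescribed must be a list of character vectors")
  out <- vapply(prescribed, function(drugs) {
    drugs <- unique(as.character(drugs))
    bad <- setdiff(drugs, c("ICS", "LABA", "LAMA"))
    if (length(bad))
      ps_validation_error(paste0("unknown drug token(s): ", paste(bad, collapse = ", ")))
    bronch <- sum(c("LABA", "LAMA") %in% drugs)
    ics <- "ICS" %in% drugs
    if (bronch == 0L) "none"
    else if (bronch == 1L && !ics) "mono"
    else if (bronch == 2L && ics) "triple"
    else "dual"
  }, character(1))
  factor(out, levels = c("none", "mono", "dual", "triple"), ordered = TRUE)
}

#' Define a numeric-to-ordinal binning rule
#'
#' Bins are left-closed right-open, with the last bin right-closed. Under
#' the `"edges"` strategy the cut points are given explicitly (e.g. clinical
#' GOLD thresholds); values falling outside the outermost edges are assigned
#' to the nearest terminal bin with a warning. Under the `"quantile"`
#' strategy the edges are the training-split quantiles (fit with
#' [fit_binning_rule()] before applying to held-out data).
#'
#' @param feature Name of the feature the rule applies to.
#' @param strategy `"edges"` or `"quantile"`.
#' @param edges For `"edges"`: strictly increasing interior cut points.
#' @param n_bins For `"quantile"`: number of bins (>= 2).
#' @param labels Optional ordered bin labels (default `"b1"`, `"b2"`, ...).
#' @param domain Optional length-2 vector; values outside it are still
#'   assigned to the terminal bins but trigger a warning.
#' @return A `binning_rule`.
#' @export
binning_rule <- function(feature, strategy = c("edges", "quantile"),
                         edges = NULL, n_bins = NULL, labels = NULL,
                         domain = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "edges") {
    if (is.null(edges) || length(edges) < 1L || is.unsorted(edges, strictly = TRUE))
      ps_param_error("edges must be a strictly increasing numeric vector")
    n_bins <- length(edges) + 1L
  } else {
    if (is.null(n_bins) || n_bins < 2L) ps_param_error("quantile strategy needs n_bins >= 2")
    n_bins <- as.integer(n_bins)
  }
  if (is.null(labels)) labels <- paste0("b", seq_len(n_bins))
  if (length(labels) != n_bins) ps_param_error("labels must have one entry per bin")
  structure(list(feature = feature, strategy = strategy, edges = edges,
                 n_bins = n_bins, labels = as.character(labels), domain = domain,
                 fitted = strategy == "edges"),
            class = "binning_rule")
}

#' Fit a quantile binning rule on training values
#'
#' @param rule A `binning_rule`.
#' @param values Training-split numeric values.
#' @return The rule with interior edges filled in.
#' @export
fit_binning_rule <- function(rule, values) {
  if (rule$strategy == "edges") return(rule)
  probs <- seq_len(rule$n_bins - 1L) / rule$n_bins
  edges <- unname(stats::quantile(values, probs, type = 7))
  if (anyDuplicated(edges) || length(unique(values)) < rule$n_bins)
    ps_stop(sprintf("degenerate quantile edges for feature '%s'", rule$feature),
            "patsim_degenerate_error")
  rule$edges <- edges
  rule$fitted <- TRUE
  rule
}

#' Apply a binning rule to numeric values
#'
#' @param values Numeric vector.
#' @param rule A fitted `binning_rule`.
#' @return Ordered factor over the rule's labels.
#' @export
bin_numeric <- function(values, rule) {
  if (!isTRUE(rule$fitted)) ps_param_error("binning rule must be fitted before use")
  x <- as.numeric(values)
  # interior edges define half-open bins [e_{i-1}, e_i); values beyond the
  # terminal bins are absorbed by them (warned, never dropped)
  idx <- findInterval(x, rule$edges, left.open = FALSE) + 1L
  if (!is.null(rule$domain)) {
    n_out <- sum(x < rule$domain[1L] | x > rule$domain[2L])
    if (n_out > 0L)
      warning(sprintf("%d value(s) of '%s' outside [%g, %g]; assigned to terminal bins",
                      n_out, rule$feature, rule$domain[1L], rule$domain[2L]))
  }
  factor(rule$labels[idx], levels = rule$labels, ordered = TRUE)
}

#' One-hot encode discrete cohort features
#'
#' Produces the indicator ("dummy variable") matrix: one column per schema
#' level of each requested feature, level order taken from the schema. Every
#' per-feature block of a row sums to exactly 1.
#'
#' @param x A `cohort`, or a data.frame of factors.
#' @param features Names of discrete features to encode (default: all
#'   ordinal/binary/categorical features in the schema).
#' @return An `encoded_matrix`: list with `values` (m x p numeric matrix)
#'   and `column_meta` (data.frame with `source`, `level`, `kind`).
#' @export
one_hot_encode <- function(x, features = NULL) {
  if (inherits(x, "cohort")) {
    if (is.null(features)) features <- schema_features_of(x$schema, c("ordinal", "binary", "categorical"))
    bad <- setdiff(features, schema_features_of(x$schema, c("ordinal", "binary", "categorical")))
    if (length(bad))
      ps_validation_error(paste0("not discrete schema features: ", paste(bad, collapse = ", ")))
    tab <- x$table[features]
    m <- x$m
  } else {
    tab <- as.data.frame(x)
    if (is.null(features)) features <- names(tab)
    tab <- tab[features]
    m <- nrow(tab)
  }
  if (!length(features)) {
    return(structure(list(values = matrix(numeric(0), nrow = m, ncol = 0),
                          column_meta = data.frame(source = character(0),
                                                   level = character(0),
                                                   kind = character(0))),
                     class = "encoded_matrix"))
  }
  blocks <- lapply(features, function(nm) {
    col <- tab[[nm]]
    if (!is.factor(col)) col <- factor(col)
    if (anyNA(col)) ps_validation_error(sprintf("level not in schema for feature '%s'", nm))
    lv <- levels(col)
    ind <- matrix(0, nrow = m, ncol = length(lv),
                  dimnames = list(NULL, paste(nm, lv, sep = "=")))
    ind[cbind(seq_len(m), as.integer(col))] <- 1
    ind
  })
  values <- do.call(cbind, blocks)
  meta <- do.call(rbind, lapply(features, function(nm) {
    col <- tab[[nm]]
    lv <- if (is.factor(col)) levels(col) else sort(unique(as.character(col)))
    data.frame(source = nm, level = lv, kind = "indicator", stringsAsFactors = FALSE)
  }))
  structure(list(values = values, column_meta = meta), class = "encoded_matrix")
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat(sprintf("<encoded_matrix> %d x %d (%d source features)\n",
              nrow(x$values), ncol(x$values), length(unique(x$column_meta$source))))
  invisible(x)
}

#' Fit a numeric feature scaler on training data
#'
#' `minmax` maps the training minimum to 0 and maximum to 1; `standardize`
#' maps to zero mean and unit SD on the training split. Held-out data
#' transformed with training statistics may fall outside \[0,1\].
#'
#' @param x Numeric matrix (training rows).
#' @param mode `"minmax"` or `"standardize"`.
#' @return A `scaler` holding per-column statistics.
#' @export
fit_scaler <- function(x, mode = c("minmax", "standardize")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (mode == "minmax") {
    lo <- apply(x, 2, min)
    hi <- apply(x, 2, max)
    bad <- which(hi - lo <= 0)
    if (length(bad))
      ps_stop(sprintf("zero-range column '%s' cannot be min-max scaled",
                      colnames(x)[bad[1L]] %||% bad[1L]), "patsim_degenerate_error")
    st <- list(center = lo, scale = hi - lo)
  } else {
    mu <- colMeans(x)
    s <- apply(x, 2, stats::sd)
    bad <- which(s <= 0)
    if (length(bad))
      ps_stop(sprintf("zero-variance column '%s' cannot be standardized",
                      colnames(x)[bad[1L]] %||% bad[1L]), "patsim_degenerate_error")
    st <- list(center = mu, scale = s)
  }
  structure(list(mode = mode, center = st$center, scale = st$scale,
                 columns = colnames(x)), class = "scaler")
}

#' Apply a fitted scaler
#' @param scaler A `scaler` from [fit_scaler()].
#' @param x Numeric matrix with the same columns as the training data.
#' @return Scaled matrix.
#' @export
apply_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(scaler$center))
    ps_validation_error("column count does not match fitted scaler")
  sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Serialize / restore fitted transform parameters as JSON
#'
#' Binning rules and scalers round-trip through JSON so a fitted transform
#' can be re-applied to unseen data bit-identically.
#'
#' @param x A `binning_rule` or `scaler`.
#' @param path JSON file path.
#' @export
write_transform <- function(x, path) {
  obj <- c(list(.class = class(x)[1L]), unclass(x))
  # digits = I(17): doubles survive the text round trip bit-identically
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  obj$.class <- NULL
  structure(obj, class = cls)
}
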