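#' Principal component analysis of a numeric block
#'
#' Columns are centered (and by default standardized — the numeric features
#' mix years, kg/m^2 and percentages, so raw variances would impose an
#' arbitrary weighting) and decomposed by SVD. Scores are uncorrelated;
#' explained fractions are the eigenvalues of the (scaled) covariance over
#' their total. Component signs are fixed by forcing the largest-magnitude
#' loading of each component positive, so results are reproducible across
#' linear-algebra backends.
#'
#' @param x Numeric matrix, m >= 2 rows.
#' @param standardize Scale columns to unit variance (default `TRUE`).
#' @return An `embedding` with `coordinates`, `explained`, `method = "pca"`
#'   and the transform state needed by [project()].
#' @export
fit_pca <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) ps_param_error("PCA needs at least 2 rows")
  center <- colMeans(x)
  if (standardize) {
    scl <- apply(x, 2, stats::sd)
    bad <- which(scl <= 0)
    if (length(bad))
      ps_stop(sprintf("constant column %s cannot be standardized",
                      colnames(x)[bad[1L]] %||% bad[1L]), "patsim_degenerate_error")
  } else {
    scl <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2, center, "-"), 2, scl, "/")
  sv <- svd(xs)
  rotation <- fix_signs(sv$v)
  scores <- xs %*% rotation
  ev <- sv$d^2 / (nrow(x) - 1)          # eigenvalues of the covariance
  explained <- ev / sum(ev)
  new_embedding(
    coordinates = scores, explained = explained, method = "pca",
    state = list(center = center, scale = scl, rotation = rotation,
                 columns = colnames(x))
  )
}

# flip each column so its largest-|.| entry is positive
fix_signs <- function(v) {
  signs <- apply(v, 2, function(col) {
    s <- sign(col[which.max(abs(col))])
    if (s == 0) 1 else s
  })
  sweep(v, 2, signs, "*")
}

#' Multiple correspondence analysis of an indicator matrix
#'
#' Correspondence analysis of the one-hot indicator matrix of Q discrete
#' features with J total levels: the standardized residual matrix
#' `S = D_r^{-1/2} (P - r c') D_c^{-1/2}` is decomposed by SVD; scores are
#' row principal coordinates and the principal inertias are the squared
#' singular values, with total inertia `J/Q - 1`. By default the explained
#' fractions are these raw inertias over the total; the Benzecri adjustment
#' (which re-expresses inertias above the 1/Q threshold and typically
#' concentrates "explained" mass in far fewer components) is available via
#' `correction = "benzecri"`.
#'
#' @param indicator An `encoded_matrix` from [one_hot_encode()] (every
#'   per-feature block must sum to 1 in each row, each level observed at
#'   least once), or a plain 0/1 matrix together with `n_features`.
#' @param n_features Number of source features Q (only needed for a plain
#'   matrix input).
#' @param correction `"none"` (default) or `"benzecri"`.
#' @return An `embedding` with `method = "mca"`, principal `inertias`, and
#'   `total_inertia = J/Q - 1`.
#' @export
fit_mca <- function(indicator, n_features = NULL, correction = c("none", "benzecri")) {
  correction <- match.arg(correction)
  if (inherits(indicator, "encoded_matrix")) {
    z <- indicator$values
    n_features <- length(unique(indicator$column_meta$source))
  } else {
    z <- as.matrix(indicator)
    if (is.null(n_features)) ps_param_error("n_features (Q) required for plain matrix input")
  }
  Q <- n_features
  J <- ncol(z)
  if (any(abs(rowSums(z) - Q) > 1e-9))
    ps_validation_error("indicator rows must sum to the number of features Q")
  empty <- which(colSums(z) == 0)
  if (length(empty))
    ps_validation_error(paste0("unobserved level column(s): ",
                               paste(colnames(z)[empty] %||% empty, collapse = ", ")))
  n <- sum(z)
  P <- z / n
  r <- rowSums(P)                       # all equal to 1/m
  cm <- colSums(P)                      # column masses
  S <- (P - tcrossprod(r, cm)) / sqrt(tcrossprod(r, cm))
  sv <- svd(S)
  keep <- which(sv$d > 1e-10)
  d <- sv$d[keep]
  V <- fix_signs(sv$v[, keep, drop = FALSE])
  # row principal coordinates: profile deviations projected on V, scaled
  profiles <- z / rowSums(z)
  scores <- sweep(profiles, 2, cm, "-") %*% (V / sqrt(cm))
  inertias <- d^2
  total <- J / Q - 1
  explained <- switch(correction,
    none = inertias / total,
    benzecri = {
      adj <- ifelse(inertias > 1 / Q, (Q / (Q - 1) * (inertias - 1 / Q))^2, 0)
      if (sum(adj) == 0) inertias / total else adj / sum(adj)
    })
  new_embedding(
    coordinates = scores, explained = explained, method = "mca",
    state = list(col_mass = cm, V = V, Q = Q, columns = colnames(z)),
    inertias = inertias, total_inertia = total
  )
}

new_embedding <- function(coordinates, explained, method, state, ...) {
  stopifnot(all(diff(explained) <= 1e-10), all(explained >= -1e-12))
  structure(list(coordinates = coordinates, explained = as.numeric(explained),
                 method = method, state = state, ...),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding:%s> %d x %d, leading explained fractions: %s\n",
              x$method, nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.3f", utils::head(x$explained, 5)), collapse = " ")))
  invisible(x)
}

#' Retain leading components at a cumulative explained-variance threshold
#'
#' Keeps the smallest leading c components whose cumulative explained
#' fraction reaches the threshold; never fewer than one. Monotone: a higher
#' threshold never keeps fewer components.
#'
#' @param embedding An `embedding`.
#' @param threshold Fraction in (0, 1\].
#' @return The embedding truncated to c components (`retained = c`).
#' @export
retain_components <- function(embedding, threshold = 0.75) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    ps_param_error("threshold must lie in (0, 1]")
  cum <- cumsum(embedding$explained)
  c_keep <- which(cum >= threshold - 1e-12)[1L]
  if (is.na(c_keep)) c_keep <- length(embedding$explained)
  c_keep <- max(1L, c_keep)
  embedding$coordinates <- embedding$coordinates[, seq_len(c_keep), drop = FALSE]
  embedding$explained <- embedding$explained[seq_len(c_keep)]
  if (embedding$method == "pca") {
    embedding$state$rotation <- embedding$state$rotation[, seq_len(c_keep), drop = FALSE]
  } else if (embedding$method == "mca") {
    embedding$state$V <- embedding$state$V[, seq_len(c_keep), drop = FALSE]
  }
  embedding$retained <- c_keep
  embedding
}

#' Project new rows with a fitted embedding
#'
#' Applies the train-fitted transform state: re-projecting the training rows
#' reproduces the stored coordinates to numerical tolerance, and held-out
#' rows are mapped without refitting anything.
#'
#' @param embedding A fitted `embedding`.
#' @param newdata Numeric matrix (PCA) or indicator matrix /
#'   `encoded_matrix` (MCA) with the fitted column structure.
#' @return Coordinate matrix with `ncol(embedding$coordinates)` columns.
#' @export
project <- function(embedding, newdata) {
  if (!inherits(embedding, "embedding")) ps_validation_error("not an embedding")
  if (embedding$method == "pca") {
    x <- as.matrix(newdata)
    st <- embedding$state
    if (ncol(x) != length(st$center))
      ps_validation_error("newdata columns do not match the fitted PCA")
    if (nrow(x) == 0L)
      return(matrix(numeric(0), 0L, ncol(st$rotation)))
    sweep(sweep(x, 2, st$center, "-"), 2, st$scale, "/") %*% st$rotation
  } else if (embedding$method == "mca") {
    z <- if (inherits(newdata, "encoded_matrix")) newdata$values else as.matrix(newdata)
    st <- embedding$state
    if (ncol(z) != length(st$col_mass))
      ps_validation_error("newdata columns do not match the fitted MCA")
    if (nrow(z) == 0L)
      return(matrix(numeric(0), 0L, ncol(st$V)))
    profiles <- z / rowSums(z)
    sweep(profiles, 2, st$col_mass, "-") %*% (st$V / sqrt(st$col_mass))
  } else {
    ps_validation_error(sprintf("unknown embedding method '%s'", embedding$method))
  }
}
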