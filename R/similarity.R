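#' Pairwise Euclidean distance matrix
#'
#' @param coords Numeric coordinate matrix (rows = patients); row names, if
#'   present, become the id index.
#' @return Symmetric m x m matrix with zero diagonal.
#' @export
pairwise_distances <- function(coords) {
  coords <- as.matrix(coords)
  if (any(!is.finite(coords))) ps_validation_error("coordinates must be finite")
  d <- as.matrix(stats::dist(coords, method = "euclidean"))
  ids <- rownames(coords)
  if (!is.null(ids)) dimnames(d) <- list(ids, ids)
  d
}

#' N closest neighbors of every patient
#'
#' Per patient, the N smallest off-diagonal distances; ties are broken by
#' ascending patient index. Self is always excluded.
#'
#' @param dist Symmetric distance matrix (e.g. from [pairwise_distances()]).
#' @param N Neighbor count, 1 <= N <= m - 1.
#' @return A `neighbor_set`: list with `index` and `distance` (both m x N
#'   matrices, rows ordered as `dist`), `ids`, and `N`.
#' @export
nearest_neighbors <- function(dist, N) {
  dist <- as.matrix(dist)
  m <- nrow(dist)
  if (!is.numeric(N) || N < 1 || N > m - 1)
    ps_param_error("N must satisfy 1 <= N <= m - 1")
  N <- as.integer(N)
  idx <- matrix(0L, m, N)
  dd <- matrix(0, m, N)
  for (i in seq_len(m)) {
    row <- dist[i, ]
    row[i] <- Inf
    ord <- order(row, seq_len(m))[seq_len(N)]   # distance, then index
    idx[i, ] <- ord
    dd[i, ] <- row[ord]
  }
  structure(list(index = idx, distance = dd,
                 ids = rownames(dist) %||% as.character(seq_len(m)), N = N),
            class = "neighbor_set")
}

#' @export
print.neighbor_set <- function(x, ...) {
  cat(sprintf("<neighbor_set> %d patients, N = %d\n", nrow(x$index), x$N))
  invisible(x)
}

#' Closest non-identical patient to a reference
#'
#' Walks the reference's neighbors in distance order and returns the first
#' whose *raw feature vector* (all schema features, not coordinates) differs
#' on at least one feature. Exact duplicates of the reference — however
#' close in the representation — are skipped.
#'
#' @param dist Distance matrix whose row order matches `x`.
#' @param x The `cohort` the distances were computed over.
#' @param ref_id Patient id of the reference.
#' @return The matched patient's id.
#' @export
best_match_nonidentical <- function(dist, x, ref_id) {
  dist <- as.matrix(dist)
  ids <- rownames(dist) %||% x$ids
  i <- match(ref_id, ids)
  if (is.na(i)) ps_validation_error(sprintf("reference id '%s' not found", ref_id))
  row <- dist[i, ]
  row[i] <- Inf
  ord <- order(row, seq_along(row))
  ri <- match(ref_id, x$ids)
  same_features <- function(a, b) {
    all(vapply(seq_along(x$table), function(k) {
      col <- x$table[[k]]
      col[a] == col[b]
    }, logical(1)))
  }
  for (j in ord) {
    if (!is.finite(row[j])) break
    cj <- match(ids[j], x$ids)
    if (!same_features(ri, cj)) return(ids[j])
  }
  ps_stop(sprintf("all patients are identical to reference '%s'", ref_id),
          "patsim_degenerate_error")
}

#' Export pairwise distances in long format
#'
#' One row per unordered pair (i < j): `id_i, id_j, distance`.
#'
#' @param dist Distance matrix.
#' @param path CSV path.
#' @export
write_distances <- function(dist, path) {
  dist <- as.matrix(dist)
  ids <- rownames(dist) %||% as.character(seq_len(nrow(dist)))
  pr <- which(upper.tri(dist), arr.ind = TRUE)
  out <- data.frame(id_i = ids[pr[, 1L]], id_j = ids[pr[, 2L]],
                    distance = dist[pr])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
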