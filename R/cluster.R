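#' Hopkins cluster-tendency index
#'
#' Per repeat, `m_h` data points are sampled without replacement and `m_h`
#' points are drawn uniformly in the axis-aligned bounding box of the data.
#' With `u_i` the distance from each uniform point to its nearest data point
#' and `w_i` the distance from each sampled data point to its nearest
#' *other* data point, the statistic is
#' `H = sum(u_i^d) / (sum(u_i^d) + sum(w_i^d))` with `d` the coordinate
#' dimension; the returned value is the mean over repeats. H is close to
#' 0.5 for spatially random data, approaches 1 for clustered data and 0 for
#' regularly spaced data.
#'
#' @param coords Finite numeric coordinate matrix.
#' @param m_h Sample size per repeat (< number of rows).
#' @param repeats Number of repeats averaged.
#' @param seed Integer seed.
#' @return A `hopkins_result`: `H`, `per_repeat`, `m_h`, `repeats`, `seed`.
#' @export
hopkins_index <- function(coords, m_h = 100L, repeats = 20L, seed = 1L) {
  coords <- as.matrix(coords)
  if (any(!is.finite(coords))) ps_validation_error("coordinates must be finite")
  m <- nrow(coords)
  d <- ncol(coords)
  if (m_h >= m) ps_param_error("m_h must be smaller than the number of points")
  lo <- apply(coords, 2, min)
  hi <- apply(coords, 2, max)
  sq <- function(a, b) {
    # squared cross-distances between rows of a and rows of b
    outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  }
  set.seed(as.integer(seed))
  per_repeat <- vapply(seq_len(repeats), function(r) {
    si <- sample.int(m, m_h)
    u_pts <- matrix(stats::runif(m_h * d, rep(lo, each = m_h), rep(hi, each = m_h)),
                    nrow = m_h)
    du <- sq(u_pts, coords)
    u <- sqrt(pmax(apply(du, 1, min), 0))
    dw <- sq(coords[si, , drop = FALSE], coords)
    dw[cbind(seq_len(m_h), si)] <- Inf        # exclude self
    w <- sqrt(pmax(apply(dw, 1, min), 0))
    sum(u^d) / (sum(u^d) + sum(w^d))
  }, numeric(1))
  structure(list(H = mean(per_repeat), per_repeat = per_repeat,
                 m_h = as.integer(m_h), repeats = as.integer(repeats),
                 seed = as.integer(seed)),
            class = "hopkins_result")
}

#' @export
print.hopkins_result <- function(x, ...) {
  cat(sprintf("<hopkins_result> H = %.3f (m_h = %d, %d repeats)\n",
              x$H, x$m_h, x$repeats))
  invisible(x)
}

#' Seeded k-means partition (Lloyd iteration)
#'
#' Initial centroids are `k` distinct patient indices drawn by the seeded
#' generator, so the same seed yields the same initial index sets across
#' pipelines run on the same patients ("identical random initialisations").
#' Several seeded restarts are run and the solution with minimal
#' within-cluster sum of squares kept; an emptied cluster is re-seeded with
#' the point currently farthest from its centroid.
#'
#' @param coords Numeric coordinate matrix.
#' @param k Cluster count, 2 <= k <= m.
#' @param seed Integer seed.
#' @param restarts Number of seeded initializations (best inertia wins).
#' @param max_iter Lloyd iteration cap.
#' @param tol Convergence threshold on the maximum centroid shift.
#' @return A `clustering_result`: `k`, `labels` (in 1..k, one per row),
#'   `inertia`, `seed`.
#' @export
kmeans_partition <- function(coords, k, seed = 1L, restarts = 25L,
                             max_iter = 300L, tol = 1e-6) {
  coords <- as.matrix(coords)
  m <- nrow(coords)
  if (k > m) ps_param_error("k cannot exceed the number of points")
  if (k < 1) ps_param_error("k must be at least 1")
  set.seed(as.integer(seed))
  inits <- lapply(seq_len(restarts), function(r) sample.int(m, k))
  best <- NULL
  xs <- rowSums(coords^2)
  for (init in inits) {
    cen <- coords[init, , drop = FALSE]
    labels <- integer(m)
    for (it in seq_len(max_iter)) {
      d2 <- outer(xs, rowSums(cen^2), "+") - 2 * tcrossprod(coords, cen)
      labels <- max.col(-d2, ties.method = "first")
      new_cen <- cen
      for (j in seq_len(k)) {
        idx <- which(labels == j)
        if (length(idx)) {
          new_cen[j, ] <- colMeans(coords[idx, , drop = FALSE])
        } else {
          # deterministically re-seed with the worst-fitted point
          far <- which.max(d2[cbind(seq_len(m), labels)])
          new_cen[j, ] <- coords[far, ]
        }
      }
      shift <- max(abs(new_cen - cen))
      cen <- new_cen
      if (shift < tol) break
    }
    d2 <- outer(xs, rowSums(cen^2), "+") - 2 * tcrossprod(coords, cen)
    labels <- max.col(-d2, ties.method = "first")
    inertia <- sum(pmax(d2[cbind(seq_len(m), labels)], 0))
    if (is.null(best) || inertia < best$inertia)
      best <- list(labels = labels, inertia = inertia)
  }
  structure(list(k = as.integer(k), labels = best$labels,
                 inertia = best$inertia, seed = as.integer(seed)),
            class = "clustering_result")
}

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms(n - 1L)) for (pos in seq_len(n))
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

#' Cluster co-assignment congruity between two labelings
#'
#' Builds the k x k contingency table of the two labelings, finds the
#' cluster matching that maximizes the total overlap (exhaustive over label
#' permutations; the labelings come from different pipelines so no natural
#' correspondence exists), and returns 100 x matched overlap / m. Invariant
#' to relabeling of either side and symmetric in its arguments.
#'
#' @param labels_a,labels_b Cluster labels over the same patients.
#' @return Percentage in \[0, 100\].
#' @export
congruity <- function(labels_a, labels_b) {
  if (inherits(labels_a, "clustering_result")) labels_a <- labels_a$labels
  if (inherits(labels_b, "clustering_result")) labels_b <- labels_b$labels
  if (length(labels_a) != length(labels_b))
    ps_validation_error("labelings must cover the same patients")
  a <- as.integer(factor(labels_a))
  b <- as.integer(factor(labels_b))
  k <- max(max(a), max(b))
  if (k > 8L) ps_param_error("congruity matching supports up to 8 clusters")
  tab <- matrix(0, k, k)
  for (i in seq_along(a)) tab[a[i], b[i]] <- tab[a[i], b[i]] + 1
  best <- 0
  for (p in perms(k)) {
    s <- sum(tab[cbind(seq_len(k), p)])
    if (s > best) best <- s
  }
  100 * best / length(a)
}

#' Bootstrap pair-stability of a clustering
#'
#' Per repeat, a subsample of `floor(fraction * m)` patients is drawn and
#' re-clustered. For every patient pair appearing together in at least two
#' repeats, the co-membership status (same vs different cluster) is compared
#' across all pairs of those repeats; the returned value is the mean
#' agreement fraction over such pairs, times 100.
#'
#' @param coords Coordinate matrix.
#' @param k Cluster count.
#' @param fraction Subsample fraction in (0, 1) (default 0.1).
#' @param repeats Number of subsample/re-cluster repeats (>= 2, default 20).
#' @param seed Integer seed.
#' @param restarts Passed to [kmeans_partition()].
#' @return Percentage in \[0, 100\].
#' @export
bootstrap_pair_stability <- function(coords, k, fraction = 0.1, repeats = 20L,
                                     seed = 1L, restarts = 25L) {
  coords <- as.matrix(coords)
  m <- nrow(coords)
  if (fraction <= 0 || fraction >= 1) ps_param_error("fraction must lie in (0, 1)")
  if (repeats < 2L) ps_param_error("need at least 2 repeats")
  n_s <- floor(fraction * m)
  if (n_s < k) ps_param_error("subsample smaller than k")
  set.seed(as.integer(seed))
  sub_idx <- lapply(seq_len(repeats), function(r) sample.int(m, n_s))
  same <- matrix(0L, m, m)
  tot <- matrix(0L, m, m)
  for (r in seq_len(repeats)) {
    idx <- sub_idx[[r]]
    cl <- kmeans_partition(coords[idx, , drop = FALSE], k,
                           seed = derive_seed(seed, r), restarts = restarts)
    co <- outer(cl$labels, cl$labels, "==")
    tot[idx, idx] <- tot[idx, idx] + 1L
    same[idx, idx] <- same[idx, idx] + co
  }
  ut <- upper.tri(tot)
  t_v <- tot[ut]
  s_v <- same[ut]
  keep <- t_v >= 2L
  if (!any(keep))
    ps_stop("no patient pair appeared in two or more repeats", "patsim_degenerate_error")
  t_v <- t_v[keep]
  s_v <- s_v[keep]
  agree <- (s_v * (s_v - 1) / 2 + (t_v - s_v) * (t_v - s_v - 1) / 2) / (t_v * (t_v - 1) / 2)
  100 * mean(agree)
}
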