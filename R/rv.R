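#' Per-feature variability over all cohort pairs
#'
#' The denominator of the relative-variability ratio. For a numeric feature
#' the statistic is the *median* absolute pairwise difference over all
#' m(m-1)/2 patient pairs; for an ordinal feature the *mean* absolute
#' pairwise rank difference (levels mapped to 0, 1, 2, ...); for a
#' binary/categorical feature the proportion of disagreeing pairs. Ordinal
#' and categorical statistics are computed exactly from level counts at any
#' m; the numeric median enumerates pairs exactly while m(m-1)/2 does not
#' exceed `max_pairs` and otherwise switches to a seeded uniform
#' pair-subsample of `n_subsample` pairs.
#'
#' A constant feature is recorded with variability 0 and `flagged = TRUE`
#' (its RV ratio is undefined downstream).
#'
#' @param x A `cohort` with m >= 2.
#' @param max_pairs Exact-enumeration ceiling on the number of pairs.
#' @param n_subsample Subsample size used above the ceiling.
#' @param seed Seed for the pair subsample.
#' @return Data frame: `feature`, `dtype`, `measure` (`"q"` or `"p"`),
#'   `value`, `flagged`.
#' @export
cohort_variability <- function(x, max_pairs = 2e6, n_subsample = 1e6, seed = 1L) {
  if (!inherits(x, "cohort")) ps_validation_error("x must be a cohort")
  m <- x$m
  if (m < 2L) ps_param_error("need at least 2 patients")
  n_pairs <- m * (m - 1) / 2
  rows <- lapply(x$schema, function(f) {
    col <- x$table[[f$name]]
    if (f$dtype == "numeric") {
      v <- as.numeric(col)
      if (max(v) == min(v)) return(vr(f, "q", 0, TRUE))
      if (n_pairs <= max_pairs) {
        # explicit |v_i - v_j| over all pairs: bit-identical to enumeration
        i_idx <- sequence(seq_len(m - 1L))
        j_idx <- rep(2:m, seq_len(m - 1L))
        q <- stats::median(abs(v[i_idx] - v[j_idx]))
      } else {
        set.seed(as.integer(seed))
        i <- sample.int(m, n_subsample, replace = TRUE)
        j <- sample.int(m - 1L, n_subsample, replace = TRUE)
        j <- ifelse(j >= i, j + 1L, j)     # uniform over ordered distinct pairs
        q <- stats::median(abs(v[i] - v[j]))
      }
      vr(f, "q", q, FALSE)
    } else if (f$dtype == "ordinal") {
      cnt <- tabulate(as.integer(col), nbins = length(f$levels))
      if (sum(cnt > 0) < 2L) return(vr(f, "q", 0, TRUE))
      if (n_pairs <= max_pairs) {
        r <- as.integer(col) - 1L
        i_idx <- sequence(seq_len(m - 1L))
        j_idx <- rep(2:m, seq_len(m - 1L))
        q <- mean(abs(r[i_idx] - r[j_idx]))
      } else {
        # exact from level counts at any scale
        r <- seq_along(cnt) - 1
        tot <- 0
        for (a in seq_along(cnt)) for (b in seq_along(cnt))
          if (b > a) tot <- tot + cnt[a] * cnt[b] * (r[b] - r[a])
        q <- tot / n_pairs
      }
      vr(f, "q", q, FALSE)
    } else {
      cnt <- tabulate(as.integer(col), nbins = length(f$levels))
      if (sum(cnt > 0) < 2L) return(vr(f, "p", 0, TRUE))
      if (n_pairs <= max_pairs) {
        g <- as.integer(col)
        i_idx <- sequence(seq_len(m - 1L))
        j_idx <- rep(2:m, seq_len(m - 1L))
        p <- mean(g[i_idx] != g[j_idx])
      } else {
        agree <- sum(cnt * (cnt - 1) / 2)
        p <- 1 - agree / n_pairs
      }
      vr(f, "p", p, FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

vr <- function(f, measure, value, flagged) {
  data.frame(feature = f$name, dtype = f$dtype, measure = measure,
             value = value, flagged = flagged, stringsAsFactors = FALSE)
}

#' Per-feature variability within representation neighborhoods
#'
#' The numerator of the relative-variability ratio: for every patient, the
#' same per-type statistic as [cohort_variability()] is computed over the N
#' (patient, neighbor) pairs given by a representation's neighbor structure
#' — numeric: median absolute difference (a `"mean"` mode is available);
#' ordinal: mean absolute rank difference; categorical: disagreement
#' proportion — and then averaged over all patients.
#'
#' @param x The `cohort`.
#' @param neighbors A `neighbor_set` built from the representation under
#'   evaluation (see [nearest_neighbors()]).
#' @param numeric_stat Per-patient summary of the N absolute differences for
#'   numeric features: `"median"` (default, mirroring the cohort-level
#'   median) or `"mean"`.
#' @return Data frame: `feature`, `dtype`, `measure`, `value`.
#' @export
neighborhood_variability <- function(x, neighbors, numeric_stat = c("median", "mean")) {
  numeric_stat <- match.arg(numeric_stat)
  if (!inherits(neighbors, "neighbor_set")) ps_validation_error("neighbors must be a neighbor_set")
  idx <- neighbors$index
  if (nrow(idx) != x$m) ps_validation_error("neighbor set does not match cohort size")
  stat_fun <- if (numeric_stat == "median") stats::median else mean
  rows <- lapply(x$schema, function(f) {
    col <- x$table[[f$name]]
    if (f$dtype == "numeric") {
      v <- as.numeric(col)
      diffs <- abs(v - matrix(v[idx], nrow = nrow(idx)))
      per_patient <- apply(diffs, 1, stat_fun)
      vr(f, "q", mean(per_patient), FALSE)[, 1:4]
    } else if (f$dtype == "ordinal") {
      r <- as.integer(col) - 1L
      diffs <- abs(r - matrix(r[idx], nrow = nrow(idx)))
      vr(f, "q", mean(rowMeans(diffs)), FALSE)[, 1:4]
    } else {
      g <- as.integer(col)
      dis <- g != matrix(g[idx], nrow = nrow(idx))
      vr(f, "p", mean(rowMeans(dis)), FALSE)[, 1:4]
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative-variability table
#'
#' RV = 100 x (neighborhood variability) / (cohort variability) per feature,
#' ranked ascending: rank 1 (lowest RV) marks the feature most strongly
#' driving similarity in the representation; values near 100 mean the
#' feature's spread among nearest neighbors matches its spread in the whole
#' cohort, i.e. it plays no role. Features flagged as constant in the cohort
#' are excluded with a warning (the ratio is undefined).
#'
#' @param cohort_var Output of [cohort_variability()].
#' @param neigh_var Output of [neighborhood_variability()].
#' @param N The neighbor count used (stored on the result).
#' @return An `rv_table` data frame: `rank`, `feature`, `dtype`, `rv`.
#' @export
relative_variability_table <- function(cohort_var, neigh_var, N = NULL) {
  if (!setequal(cohort_var$feature, neigh_var$feature))
    ps_validation_error("cohort and neighborhood variability cover different features")
  drop <- cohort_var$feature[cohort_var$flagged | cohort_var$value == 0]
  if (length(drop))
    warning(paste0("excluding zero-variability feature(s): ", paste(drop, collapse = ", ")))
  keep <- setdiff(cohort_var$feature, drop)
  cv <- cohort_var[match(keep, cohort_var$feature), ]
  nv <- neigh_var[match(keep, neigh_var$feature), ]
  rv <- 100 * nv$value / cv$value
  ord <- order(rv, seq_along(rv))
  out <- data.frame(rank = seq_along(keep), feature = keep[ord],
                    dtype = cv$dtype[ord], rv = rv[ord],
                    stringsAsFactors = FALSE)
  attr(out, "N") <- N
  class(out) <- c("rv_table", "data.frame")
  out
}

#' Compute an RV table directly from a cohort and coordinates
#'
#' Convenience wrapper: builds the Euclidean distance matrix and the
#' N-nearest-neighbor sets from `coords`, then the RV table.
#'
#' @param x A `cohort`.
#' @param coords Representation coordinates for the same patients, row order
#'   matching the cohort.
#' @param N Neighbor count (default 20).
#' @param ... Passed to [cohort_variability()] / [neighborhood_variability()].
#' @return An `rv_table`.
#' @export
relative_variability <- function(x, coords, N = 20L, ...) {
  nb <- nearest_neighbors(pairwise_distances(coords), N)
  relative_variability_table(cohort_variability(x),
                             neighborhood_variability(x, nb, ...), N = N)
}

#' Mean relative variability
#'
#' Arithmetic means of the per-feature RVs: over the numeric group, the
#' categorical group and overall. By default ordinal features are averaged
#' with the categorical group (matching how reference summary tables group a
#' therapy-line feature); `group_ordinal = "numeric"` follows the reading
#' that ordinal features belong with the numeric group.
#'
#' @param table An `rv_table`.
#' @param group_ordinal `"categorical"` (default) or `"numeric"`.
#' @return List with `mrv_numeric`, `mrv_categorical`, `mrv_overall`
#'   (an empty group yields `NA` for its summary).
#' @export
mrv_summary <- function(table, group_ordinal = c("categorical", "numeric")) {
  group_ordinal <- match.arg(group_ordinal)
  if (!nrow(table)) ps_validation_error("RV table is empty")
  num_types <- if (group_ordinal == "numeric") c("numeric", "ordinal") else "numeric"
  cat_types <- if (group_ordinal == "numeric") c("binary", "categorical") else
    c("binary", "categorical", "ordinal")
  grp_mean <- function(types) {
    v <- table$rv[table$dtype %in% types]
    if (length(v)) mean(v) else NA_real_
  }
  list(mrv_numeric = grp_mean(num_types),
       mrv_categorical = grp_mean(cat_types),
       mrv_overall = mean(table$rv))
}

#' RV robustness across neighborhood sizes
#'
#' Recomputes the RV table for each N and reports the Spearman rank
#' correlation of the feature ordering between consecutive Ns.
#'
#' @param x A `cohort`.
#' @param coords Representation coordinates.
#' @param Ns Vector of neighbor counts.
#' @param ... Passed to [relative_variability()].
#' @return List with `tables` (one `rv_table` per N, named) and
#'   `rank_correlation` (length `length(Ns) - 1`).
#' @export
rv_robustness <- function(x, coords, Ns, ...) {
  if (!length(Ns)) ps_param_error("Ns must be nonempty")
  tables <- lapply(Ns, function(N) relative_variability(x, coords, N = N, ...))
  names(tables) <- as.character(Ns)
  rc <- if (length(Ns) > 1L) {
    vapply(seq_len(length(Ns) - 1L), function(i) {
      a <- tables[[i]]; b <- tables[[i + 1L]]
      feats <- intersect(a$feature, b$feature)
      stats::cor(a$rank[match(feats, a$feature)],
                 b$rank[match(feats, b$feature)], method = "spearman")
    }, numeric(1))
  } else numeric(0)
  list(tables = tables, rank_correlation = rc)
}
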