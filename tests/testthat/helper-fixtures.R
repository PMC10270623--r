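# Shared fixtures and independent oracles used across test files.

toy_schema <- function() {
  feature_schema(
    schema_feature("x", "numeric", units = "au"),
    schema_feature("grade", "ordinal", levels = c("low", "mid", "high")),
    schema_feature("flag", "binary", levels = c("yes", "no"))
  )
}

toy_cohort <- function(x, grade, flag, ids = NULL) {
  cohort(data.frame(x = x, grade = grade, flag = flag,
                    stringsAsFactors = FALSE), toy_schema(), ids = ids)
}

# small random mixed cohort over the COPD schema
random_copd_cohort <- function(m, seed, ...) {
  generate_cohort(copd_cohort_spec(m = m, seed = seed, ...))
}

# --- independent oracles ----------------------------------------------------

# correspondence analysis of an indicator matrix, by explicit SVD of the
# standardized residual matrix, routed through U (the implementation goes
# through column profiles and V)
oracle_ca <- function(Z) {
  n <- sum(Z)
  P <- Z / n
  r <- rowSums(P)
  cm <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cm)) %*% diag(1 / sqrt(cm))
  sv <- svd(S)
  keep <- sv$d > 1e-10
  coords <- diag(1 / sqrt(r)) %*% sv$u[, keep, drop = FALSE] %*%
    diag(sv$d[keep], nrow = sum(keep))
  list(coords = coords, inertias = sv$d[keep]^2)
}

# PCA eigenvalues/scores by dense eigendecomposition of the covariance
oracle_pca <- function(X, standardize = TRUE) {
  Xs <- scale(X, center = TRUE, scale = standardize)
  ev <- eigen(stats::cov(Xs), symmetric = TRUE)
  keep <- ev$values > 1e-12
  list(values = ev$values[keep],
       scores = Xs %*% ev$vectors[, keep, drop = FALSE])
}

# exhaustive pair enumeration of per-feature cohort variability; explicit
# nested loops (colex order so float summation matches any enumeration that
# visits pairs in the same order)
oracle_cohort_variability <- function(co) {
  m <- co$m
  i_idx <- integer(0); j_idx <- integer(0)
  for (j in 2:m) { i_idx <- c(i_idx, 1:(j - 1)); j_idx <- c(j_idx, rep(j, j - 1)) }
  sapply(schema_names(co$schema), function(nm) {
    f <- co$schema[[nm]]
    col <- co$table[[nm]]
    if (f$dtype == "numeric") {
      v <- as.numeric(col)
      stats::median(abs(v[i_idx] - v[j_idx]))
    } else if (f$dtype == "ordinal") {
      r <- as.integer(col) - 1L
      mean(abs(r[i_idx] - r[j_idx]))
    } else {
      mean(col[i_idx] != col[j_idx])
    }
  })
}

# neighborhood variability by explicit per-patient loops
oracle_neighborhood_variability <- function(co, nb, numeric_stat = "median") {
  stat <- if (numeric_stat == "median") stats::median else mean
  sapply(schema_names(co$schema), function(nm) {
    f <- co$schema[[nm]]
    col <- co$table[[nm]]
    per <- sapply(seq_len(co$m), function(i) {
      js <- nb$index[i, ]
      if (f$dtype == "numeric") {
        stat(abs(as.numeric(col)[i] - as.numeric(col)[js]))
      } else if (f$dtype == "ordinal") {
        mean(abs((as.integer(col)[i] - 1L) - (as.integer(col)[js] - 1L)))
      } else {
        mean(col[i] != col[js])
      }
    })
    mean(per)
  })
}

# congruity by filtering all label assignments from a cartesian grid
oracle_congruity <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  k <- max(a, b)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  grid <- grid[apply(grid, 1, function(r) length(unique(r)) == k), , drop = FALSE]
  best <- 0
  for (gi in seq_len(nrow(grid))) {
    p <- grid[gi, ]
    best <- max(best, sum(b == p[a]))
  }
  100 * best / length(a)
}

# mean of a normal truncated to [lo, hi]
truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
}

# build a valid two-rater rating set carrying arbitrary ranks on pipeline
# "P"; filler pipelines "Q" (always rank 1) and "R" (always the worst rank)
# satisfy the 1-and-4-per-(case, rater) rule whatever P's ranks are
rating_fixture <- function(ranks_a, ranks_b, n_ranks = 4L) {
  n <- length(ranks_a)
  cid <- sprintf("c%02d", 1:n)
  block <- function(rater, pipeline, rank)
    data.frame(case_id = cid, rater_id = rater, pipeline = pipeline,
               rank = as.integer(rank))
  long <- rbind(
    block("r1", "P", ranks_a), block("r2", "P", ranks_b),
    block("r1", "Q", 1L), block("r2", "Q", 1L),
    block("r1", "R", n_ranks), block("r2", "R", n_ranks)
  )
  rating_set(long, n_ranks = n_ranks)
}
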