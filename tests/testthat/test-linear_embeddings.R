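test_that("PCA: rank-1 data, eigen oracle, uncorrelated scores", {
  x <- cbind(1:10, 2 * (1:10))
  emb <- fit_pca(x, standardize = FALSE)
  expect_equal(emb$explained[1], 1.0)

  x4 <- matrix(c(0, 0, 1, 1, 2, 0, 3, 1), ncol = 2, byrow = TRUE)
  emb4 <- fit_pca(x4, standardize = FALSE)
  orc <- oracle_pca(x4, standardize = FALSE)
  expect_equal(emb4$explained, orc$values / sum(orc$values), tolerance = 1e-10)
  for (j in seq_along(orc$values))
    expect_lt(min(sum((emb4$coordinates[, j] - orc$scores[, j])^2),
                  sum((emb4$coordinates[, j] + orc$scores[, j])^2)), 1e-10)

  set.seed(31)
  x <- matrix(rnorm(120), 20, 6)
  emb <- fit_pca(x)
  cv <- cov(emb$coordinates)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  expect_error(fit_pca(cbind(1:5, rep(2, 5)), standardize = TRUE),
               class = "patsim_degenerate_error")
})

test_that("MCA: total inertia J/Q - 1, oracle agreement, profile equality", {
  # closed-form total inertia for 2 features with 2 + 3 levels
  df <- data.frame(a = factor(c("x", "y", "x", "y", "x", "y")),
                   b = factor(c("p", "q", "r", "p", "q", "r")))
  emb <- fit_mca(one_hot_encode(df))
  expect_equal(emb$total_inertia, 5 / 2 - 1)
  expect_equal(sum(emb$inertias), 5 / 2 - 1, tolerance = 1e-10)

  # perfectly associated binary features: scores match the independent CA
  # oracle and the leading inertia is the maximum the design allows
  df2 <- data.frame(a = factor(c("x", "x", "x", "y", "y", "y")),
                    b = factor(c("p", "p", "p", "q", "q", "q")))
  enc2 <- one_hot_encode(df2)
  emb2 <- fit_mca(enc2)
  orc <- oracle_ca(enc2$values)
  expect_equal(emb2$inertias, orc$inertias, tolerance = 1e-8)
  expect_equal(max(emb2$inertias), 1, tolerance = 1e-10)  # 1 = max inertia per MCA axis
  for (j in seq_along(orc$inertias))
    expect_lt(min(sum((emb2$coordinates[, j] - orc$coords[, j])^2),
                  sum((emb2$coordinates[, j] + orc$coords[, j])^2)), 1e-8)

  # single balanced feature: same-level rows share coordinates
  df3 <- data.frame(a = factor(rep(c("u", "v", "w"), each = 2)))
  emb3 <- fit_mca(one_hot_encode(df3))
  expect_equal(emb3$coordinates[1, ], emb3$coordinates[2, ])
  expect_equal(emb3$coordinates[3, ], emb3$coordinates[4, ])

  expect_error(fit_mca(matrix(c(1, 1, 0, 0, 0, 0), 2, 3), n_features = 1),
               class = "patsim_validation_error")  # unobserved level column
})

test_that("MCA total inertia holds across random schemas (property)", {
  for (seed in 1:5) {
    set.seed(seed)
    Q <- sample(2:5, 1)
    df <- as.data.frame(lapply(seq_len(Q), function(q) {
      L <- sample(2:4, 1)
      factor(sample(letters[1:L], 30, replace = TRUE, prob = rep(1, L)))
    }))
    names(df) <- paste0("f", seq_len(Q))
    df <- df[, vapply(df, function(c) length(unique(c)) > 1, logical(1)), drop = FALSE]
    enc <- one_hot_encode(df)
    J <- ncol(enc$values); Qe <- ncol(df)
    emb <- fit_mca(enc)
    expect_equal(sum(emb$inertias), J / Qe - 1, tolerance = 1e-8)
  }
})

test_that("component retention respects the threshold and is monotone", {
  mk <- function(expl) structure(
    list(coordinates = matrix(0, 4, length(expl)), explained = expl,
         method = "pca",
         state = list(center = numeric(length(expl)), scale = rep(1, length(expl)),
                      rotation = diag(length(expl)))),
    class = "embedding")
  expect_equal(retain_components(mk(c(0.5, 0.3, 0.2)), 0.75)$retained, 2L)
  expect_equal(retain_components(mk(c(0.8, 0.2)), 0.75)$retained, 1L)
  expect_equal(retain_components(mk(c(0.5, 0.3, 0.2)), 1.0)$retained, 3L)
  for (t1 in c(0.2, 0.5, 0.75, 0.9)) for (t2 in c(0.95, 1)) {
    e <- mk(c(0.4, 0.3, 0.2, 0.1))
    expect_lte(retain_components(e, t1)$retained, retain_components(e, t2)$retained)
  }
  expect_error(retain_components(mk(c(1)), 0), class = "patsim_parameterization_error")
})

test_that("projection reproduces training coordinates and handles edge cases", {
  set.seed(7)
  x <- matrix(rnorm(60), 12, 5)
  emb <- retain_components(fit_pca(x), 0.9)
  expect_equal(project(emb, x), emb$coordinates, tolerance = 1e-8)
  expect_equal(project(emb, x[c(3, 3), ])[1, ], project(emb, x[c(3, 3), ])[2, ])
  expect_equal(dim(project(emb, x[0, , drop = FALSE])), c(0L, emb$retained))
  expect_error(project(emb, x[, 1:3]), class = "patsim_validation_error")

  co <- random_copd_cohort(400, seed = 5)
  enc <- one_hot_encode(co)
  memb <- fit_mca(enc)
  expect_equal(project(memb, enc), memb$coordinates, tolerance = 1e-8)
})

test_that("PCA and MCA agree with brute-force oracles on random inputs", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(8:20, 1); p <- sample(2:6, 1)
    x <- matrix(rnorm(n * p), n, p)
    emb <- fit_pca(x, standardize = TRUE)
    orc <- oracle_pca(x, standardize = TRUE)
    k <- length(orc$values)
    expect_equal(emb$explained[seq_len(k)] * sum(orc$values), orc$values,
                 tolerance = 1e-8)
    for (j in seq_len(k))
      expect_lt(min(sum((emb$coordinates[, j] - orc$scores[, j])^2),
                    sum((emb$coordinates[, j] + orc$scores[, j])^2)), 1e-8)

    Q <- sample(2:3, 1)
    df <- as.data.frame(lapply(seq_len(Q), function(q)
      factor(sample(letters[1:3], 15, replace = TRUE))))
    names(df) <- paste0("g", seq_len(Q))
    df <- df[, vapply(df, function(c) length(unique(c)) > 1, logical(1)), drop = FALSE]
    enc <- one_hot_encode(df)
    emb <- fit_mca(enc)
    orc <- oracle_ca(enc$values)
    expect_equal(emb$inertias, orc$inertias, tolerance = 1e-8)
    for (j in seq_along(orc$inertias))
      expect_lt(min(sum((emb$coordinates[, j] - orc$coords[, j])^2),
                    sum((emb$coordinates[, j] + orc$coords[, j])^2)), 1e-8)
  }
})
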