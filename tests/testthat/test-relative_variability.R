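test_that("cohort variability matches hand-enumerated pair statistics", {
  co <- toy_cohort(c(0, 1, 3), c("low", "mid", "high"), c("yes", "no", "yes"))
  cv <- cohort_variability(co)
  expect_equal(cv$value[cv$feature == "x"], 2)             # diffs {1, 3, 2}
  expect_equal(cv$value[cv$feature == "grade"], mean(c(1, 2, 1)))
  expect_equal(cv$value[cv$feature == "flag"], 2 / 3)

  co4 <- toy_cohort(c(1, 2, 3, 4), c("low", "low", "mid", "mid"),
                    c("yes", "yes", "no", "no"))
  cv4 <- cohort_variability(co4)
  expect_equal(cv4$value[cv4$feature == "flag"], 4 / 6)    # 2 of 4 positive

  const <- toy_cohort(c(5, 5, 5), rep("low", 3), rep("yes", 3))
  cvc <- cohort_variability(const)
  expect_true(all(cvc$flagged))
  expect_true(all(cvc$value == 0))
})

test_that("exact enumeration and the subsampled estimator agree in distribution", {
  co <- random_copd_cohort(300, seed = 21)
  exact <- cohort_variability(co)
  sub <- cohort_variability(co, max_pairs = 10, n_subsample = 2e5, seed = 9)
  num <- exact$dtype == "numeric"
  expect_equal(sub$value[num], exact$value[num], tolerance = 0.05)
  # discrete statistics are exact either way (count-based above the ceiling)
  expect_equal(sub$value[!num], exact$value[!num], tolerance = 1e-12)
})

test_that("neighborhood variability: homogeneous, hand enumeration, anchored analogue", {
  co <- toy_cohort(c(1, 1, 2, 2), c("low", "low", "mid", "mid"),
                   c("yes", "yes", "no", "no"))
  coords <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  nb <- nearest_neighbors(pairwise_distances(coords), 1)
  nv <- neighborhood_variability(co, nb)
  expect_true(all(nv$value == 0))    # every neighbor shares every value

  co5 <- toy_cohort(c(0, 1, 3, 6, 10), c("low", "mid", "high", "low", "mid"),
                    c("yes", "no", "yes", "no", "yes"))
  coords5 <- matrix(c(0, 1, 2, 3, 4), ncol = 1)
  nb5 <- nearest_neighbors(pairwise_distances(coords5), 2)
  nv5 <- neighborhood_variability(co5, nb5)
  orc5 <- oracle_neighborhood_variability(co5, nb5)
  expect_equal(nv5$value, unname(orc5[nv5$feature]))

  co6 <- random_copd_cohort(6, seed = 3)
  d6 <- pairwise_distances(matrix(rnorm(12), 6, 2))
  nb6 <- nearest_neighbors(d6, 5)    # N = m - 1: all other patients
  nv6 <- neighborhood_variability(co6, nb6)
  orc6 <- oracle_neighborhood_variability(co6, nb6)
  expect_equal(nv6$value, unname(orc6[nv6$feature]))
})

test_that("RV ratios, exclusion of flagged features, null and boundary cases", {
  co <- toy_cohort(c(1, 1, 2, 2), c("low", "low", "mid", "mid"),
                   c("yes", "yes", "no", "no"))
  cv <- cohort_variability(co)
  # neighborhoods that mirror cohort-level variability give RV = 100
  nv <- cv[, c("feature", "dtype", "measure", "value")]
  tab <- relative_variability_table(cv, nv, N = 2)
  expect_equal(tab$rv, rep(100, 3))
  # homogeneous neighborhoods give RV = 0
  nv0 <- nv; nv0$value <- 0
  expect_equal(relative_variability_table(cv, nv0, N = 2)$rv, rep(0, 3))
  # p_sample = 0.392 p_cohort -> RV = 39.2
  nvf <- nv; nvf$value <- nv$value * 0.392
  tabf <- relative_variability_table(cv, nvf, N = 2)
  expect_equal(tabf$rv, rep(39.2, 3), tolerance = 1e-10)

  const <- toy_cohort(c(1, 2, 3), rep("low", 3), c("yes", "no", "yes"))
  cvc <- cohort_variability(const)
  nvc <- cvc[, c("feature", "dtype", "measure", "value")]
  expect_warning(tc <- relative_variability_table(cvc, nvc, N = 1), "grade")
  expect_false("grade" %in% tc$feature)
  expect_equal(sort(tc$rank), seq_len(nrow(tc)))
})

test_that("production RV equals exhaustive enumeration for small cohorts", {
  for (seed in c(2, 5, 8)) {
    co <- random_copd_cohort(25, seed = seed)
    set.seed(seed)
    coords <- matrix(rnorm(50), 25, 2)
    nb <- nearest_neighbors(pairwise_distances(coords), 6)
    cv <- cohort_variability(co)
    expect_identical(cv$value, unname(oracle_cohort_variability(co)[cv$feature]))
    nv <- neighborhood_variability(co, nb)
    expect_identical(nv$value, unname(oracle_neighborhood_variability(co, nb)[nv$feature]))
  }
})

test_that("RV of a numeric feature is scale invariant", {
  co <- random_copd_cohort(80, seed = 17)
  set.seed(17)
  coords <- matrix(rnorm(160), 80, 2)
  base <- relative_variability(co, coords, N = 10)
  for (const in c(0.01, 3, 1000)) {
    co2 <- co
    co2$table$bmi <- co$table$bmi * const
    tab2 <- relative_variability(co2, coords, N = 10)
    expect_equal(tab2$rv[tab2$feature == "bmi"],
                 base$rv[base$feature == "bmi"], tolerance = 1e-10)
  }
})

test_that("MRV grouping follows the configured ordinal assignment", {
  tab <- structure(
    data.frame(rank = 1:4, feature = c("a", "t", "b", "x"),
               dtype = c("binary", "ordinal", "binary", "numeric"),
               rv = c(10, 20, 30, 60), stringsAsFactors = FALSE),
    class = c("rv_table", "data.frame"))
  m1 <- mrv_summary(tab)                      # ordinal with categorical
  expect_equal(m1$mrv_categorical, mean(c(10, 20, 30)))
  expect_equal(m1$mrv_numeric, 60)
  expect_equal(m1$mrv_overall, 30)
  m2 <- mrv_summary(tab, group_ordinal = "numeric")
  expect_equal(m2$mrv_numeric, 40)
  expect_equal(m2$mrv_categorical, 20)

  same <- tab; same$rv <- rep(55, 4)
  ms <- mrv_summary(same)
  expect_equal(unlist(ms), c(mrv_numeric = 55, mrv_categorical = 55, mrv_overall = 55))
})

test_that("rv_robustness produces one table per N and stable rankings on structure", {
  co <- generate_cohort(cohort_spec(
    toy_schema(), m = 200,
    numeric = list(x = list(mean = 0, sd = 1)),
    binary = c(flag = 0.5), ordinal = list(grade = rep(1, 3) / 3),
    k_planted = 2, numeric_shift = list(x = c(-3, 3)),
    prevalence_offset = list(flag = c(0.5, -0.5)), seed = 23))
  feats <- cbind(as.numeric(co$table$x), 3 * (co$table$flag == "yes"))
  rb <- rv_robustness(co, feats, Ns = c(5, 10, 20))
  expect_length(rb$tables, 3L)
  expect_length(rb$rank_correlation, 2L)
  expect_true(all(rb$rank_correlation > 0.8))
  single <- rv_robustness(co, feats, Ns = 10)
  expect_length(single$tables, 1L)
  expect_length(single$rank_correlation, 0L)
})
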