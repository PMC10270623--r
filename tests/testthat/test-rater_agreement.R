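test_that("vignette export: shape, blinding, determinism", {
  co <- random_copd_cohort(60, seed = 51)
  set.seed(51)
  coords <- list(MCA = matrix(rnorm(120), 60, 2),
                 AE = matrix(rnorm(180), 60, 3))
  ex <- export_vignettes(co, coords, sample_size = 10, seed = 4)
  expect_equal(nrow(ex$vignettes), 10L)
  expect_setequal(names(ex$blinding), c("A", "B"))
  expect_setequal(unname(ex$blinding), c("MCA", "AE"))
  # one feature block for the reference and one per blinded pipeline
  expect_equal(ncol(ex$vignettes), 1 + 16 + 2 * 17)
  expect_true(all(ex$vignettes$case_id %in% co$ids))
  for (lt in names(ex$blinding)) {
    mid <- ex$vignettes[[paste0("match_", lt, ".id")]]
    expect_true(all(mid %in% co$ids))
    expect_true(all(mid != ex$vignettes$case_id))
  }
  ex2 <- export_vignettes(co, coords, sample_size = 10, seed = 4)
  expect_identical(ex2$vignettes, ex$vignettes)
  expect_identical(ex2$blinding, ex$blinding)
  single <- export_vignettes(co, coords["MCA"], sample_size = 1, seed = 4)
  expect_equal(nrow(single$vignettes), 1L)
  expect_error(export_vignettes(co, coords, sample_size = 100),
               class = "patsim_parameterization_error")
})

test_that("rating validation enforces the 1-and-4 rule and rank range", {
  good <- rating_fixture(c(1, 2, 3, 4), c(1, 1, 4, 4))
  expect_s3_class(good, "rating_set")
  bad <- data.frame(case_id = "c1", rater_id = "r1",
                    pipeline = c("P", "Q"), rank = c(2L, 3L))
  expect_error(rating_set(bad), class = "patsim_validation_error")
  bad2 <- data.frame(case_id = "c1", rater_id = "r1",
                     pipeline = c("P", "Q"), rank = c(1L, 5L))
  expect_error(rating_set(bad2), class = "patsim_validation_error")
})

test_that("rating CSV round trip with unblinding", {
  path <- withr::local_tempfile(fileext = ".csv")
  wide <- data.frame(case_id = rep(c("c1", "c2"), each = 2),
                     rater_id = rep(c("r1", "r2"), 2),
                     rank_A = c(1, 1, 1, 4), rank_B = c(4, 4, 4, 1))
  write.csv(wide, path, row.names = FALSE)
  rs <- read_ratings(path, blinding = c(A = "MCA", B = "AE"), n_ranks = 4)
  expect_setequal(unique(rs$pipeline), c("MCA", "AE"))
  expect_equal(rs$rank[rs$pipeline == "MCA" & rs$case_id == "c1"], c(1L, 1L))
})

test_that("percent agreement across modes", {
  ranks_a <- c(1, 1, 2, 3, 4, 4, 2, 1, 3, 4)
  ranks_b <- c(1, 2, 2, 3, 4, 1, 3, 1, 3, 4)   # agree on 7 of 10
  rs <- rating_fixture(ranks_a, ranks_b)
  expect_equal(percent_agreement(rs, "P", "overall"), 0.7)
  expect_equal(percent_agreement(rs, "Q", "overall"), 1.0)
  expect_equal(percent_agreement(rs, "Q", "is_best"), 1.0)

  rs2 <- rating_fixture(rep(1, 6), rep(4, 6))
  expect_equal(percent_agreement(rs2, "P", "is_best"), 0)
  expect_equal(percent_agreement(rs2, "P", "is_worst"), 0)
  expect_error(percent_agreement(rating_set(rbind(
    data.frame(case_id = "c1", rater_id = c("r1", "r2", "r3"),
               pipeline = "P", rank = 1L),
    data.frame(case_id = "c1", rater_id = c("r1", "r2", "r3"),
               pipeline = "Q", rank = 4L)), 4), "P"),
    class = "patsim_design_error")
})

test_that("kappa closed forms and invariances", {
  # perfect agreement over >= 2 categories
  rs <- rating_fixture(c(1, 2, 3, 4, 1, 4), c(1, 2, 3, 4, 1, 4))
  expect_equal(cohen_kappa(rs, "P")$kappa, 1.0)

  # chance-level 2x2 table: observed agreement equals expected
  a <- rep(c(1L, 1L, 2L, 2L), 5)
  b <- rep(c(1L, 2L, 1L, 2L), 5)
  k0 <- patsim:::kappa_from_pair(a, b)
  expect_equal(k0$kappa, 0)

  # worked 2x2 example: diag 20, 15 of 50; off-diag 5, 10
  aw <- c(rep(1L, 25), rep(2L, 25))
  bw <- c(rep(1L, 20), rep(2L, 5), rep(1L, 10), rep(2L, 15))
  kw <- patsim:::kappa_from_pair(aw, bw)
  expect_equal(kw$p_o, 0.70)
  expect_equal(kw$p_e, 0.50)
  expect_equal(kw$kappa, 0.40)
  expect_true(kw$ci[1] <= kw$kappa && kw$kappa <= kw$ci[2])
  # category relabeling leaves kappa unchanged
  relab <- function(v) c(2L, 1L)[v]
  kr <- patsim:::kappa_from_pair(relab(aw), relab(bw))
  expect_equal(kr$kappa, kw$kappa)

  # both raters constant and identical: undefined, flagged
  ku <- patsim:::kappa_from_pair(rep(1L, 10), rep(1L, 10))
  expect_true(ku$undefined)
  expect_true(is.na(ku$kappa))

  # null-variance option gives a (different) finite CI
  kn <- patsim:::kappa_from_pair(aw, bw, variance = "null")
  expect_true(is.finite(kn$se) && kn$se > 0)
})

test_that("kappa <= 1 and centered at 0 for independent raters", {
  set.seed(52)
  kaps <- replicate(60, {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:4, 40, replace = TRUE)
    patsim:::kappa_from_pair(a, b)$kappa
  })
  expect_true(all(kaps <= 1))
  expect_lt(abs(mean(kaps)), 0.06)
})

test_that("summaries and binarization consistency", {
  ranks_a <- c(1, 1, 1, 2, 4)
  ranks_b <- c(1, 4, 1, 1, 4)
  rs <- rating_fixture(ranks_a, ranks_b)
  sm <- summarize_ratings(rs)
  expect_equal(sm$frac_best[sm$pipeline == "P" & sm$rater_id == "r1"], 0.6)
  expect_equal(sm$frac_best[sm$pipeline == "P" & sm$rater_id == "r2"], 0.6)
  expect_equal(sm$frac_best[sm$pipeline == "P" & sm$rater_id == "average"], 0.6)
  expect_equal(sm$frac_best[sm$pipeline == "Q" & sm$rater_id == "average"], 1.0)
  # the averaging contract: 50% and 62.8% average to 56.4%
  expect_equal(mean(c(0.50, 0.628)), 0.564)

  # binarized indicators reproduce the rank-1 / rank-4 sets exactly
  sub <- rs[rs$pipeline == "P" & rs$rater_id == "r1", ]
  expect_equal(which(sub$rank == 1L), which(ranks_a == 1))
  expect_equal(which(sub$rank == 4L), which(ranks_a == 4))

  expect_error(summarize_ratings(rs[0, ]), class = "patsim_validation_error")

  rep_tab <- agreement_report(rs)
  expect_equal(nrow(rep_tab), 3L)
  expect_true(all(c("agree_overall", "kappa_overall", "kappa_best") %in% names(rep_tab)))
})
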