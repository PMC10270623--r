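test_that("generator reproduces the configured marginals at scale", {
  co <- random_copd_cohort(m = 20000, seed = 42)
  expect_equal(co$m, 20000L)
  # reference-cohort anchor: age and sex marginals
  expect_lt(abs(mean(co$table$age) - 67.0), 0.2)
  expect_lt(abs(mean(co$table$sex == "male") - 0.545), 0.01)

  # all marginals within 3 standard errors of their generator targets;
  # numeric targets are the truncated-normal means (closed form oracle)
  spec <- copd_cohort_spec(m = 20000, seed = 42)
  for (nm in names(spec$numeric)) {
    sp <- spec$numeric[[nm]]
    target <- truncnorm_mean(sp$mean, sp$sd, sp$lower, sp$upper)
    se <- sd(co$table[[nm]]) / sqrt(co$m)
    expect_lt(abs(mean(co$table[[nm]]) - target), 3 * se)
  }
  for (nm in names(spec$binary)) {
    p <- spec$binary[[nm]]
    lv1 <- co$schema[[nm]]$levels[1L]
    se <- sqrt(p * (1 - p) / co$m)
    expect_lt(abs(mean(co$table[[nm]] == lv1) - p), 3 * se + 1e-12)
  }
  p_ther <- spec$ordinal$therapy
  obs <- as.numeric(table(co$table$therapy)) / co$m
  expect_true(all(abs(obs - p_ther) < 3 * sqrt(p_ther * (1 - p_ther) / co$m)))
})

test_that("degenerate prevalences and invalid specs behave by contract", {
  sch <- toy_schema()
  sp0 <- cohort_spec(sch, m = 50,
                     numeric = list(x = list(mean = 0, sd = 1)),
                     binary = c(flag = 0),
                     ordinal = list(grade = c(1, 0, 0)), seed = 3)
  co <- generate_cohort(sp0)
  expect_true(all(co$table$flag == "no"))
  expect_true(all(co$table$grade == "low"))

  expect_error(cohort_spec(sch, m = 10, binary = c(flag = 1.2)),
               class = "patsim_parameterization_error")
  expect_error(cohort_spec(sch, m = 10, ordinal = list(grade = c(0.5, 0.2, 0.2))),
               class = "patsim_parameterization_error")
  expect_error(cohort_spec(sch, m = 1), class = "patsim_size_error")
  expect_error(cohort_spec(sch, m = 10, k_planted = 2,
                           numeric_shift = list(zzz = c(0, 1))),
               class = "patsim_parameterization_error")
})

test_that("planted clusters shift features as specified and stay hidden", {
  sp <- cohort_spec(toy_schema(), m = 1000,
                    numeric = list(x = list(mean = 0, sd = 2)),
                    binary = c(flag = 0.5),
                    ordinal = list(grade = c(1, 1, 1) / 3),
                    k_planted = 2,
                    numeric_shift = list(x = c(0, 3)), seed = 11)
  co <- generate_cohort(sp)
  lab <- attr(co, "latent_cluster")
  expect_false(is.null(lab))
  gap_sd <- (mean(co$table$x[lab == 2]) - mean(co$table$x[lab == 1])) / 2
  expect_lt(abs(gap_sd - 3), 0.2)
  # labels ride along through subsetting but live outside the feature table
  expect_false("latent_cluster" %in% names(co$table))
  expect_identical(attr(co[1:10], "latent_cluster"), lab[1:10])
})

test_that("generation is deterministic in the spec", {
  a <- random_copd_cohort(500, seed = 9)
  b <- random_copd_cohort(500, seed = 9)
  expect_identical(a$table, b$table)
  expect_identical(a$ids, b$ids)
})

test_that("train/test split sizes, determinism and the partition property", {
  co <- random_copd_cohort(100, seed = 1)
  sp <- split_train_test(co, fraction = 0.75, seed = 5)
  expect_equal(sp$train$m, 75L)
  expect_equal(sp$test$m, 25L)
  # reference-cohort anchor: round(0.7516 * 30467) reproduces 22899 / 7568
  expect_equal(round(0.7516 * 30467), 22899)
  expect_identical(split_train_test(co, 0.75, seed = 5)$train$ids, sp$train$ids)

  for (frac in c(0.1, 0.5, 0.7516, 0.9)) {
    for (seed in c(1, 99)) {
      s <- split_train_test(co, frac, seed)
      expect_length(intersect(s$train$ids, s$test$ids), 0)
      expect_setequal(c(s$train$ids, s$test$ids), co$ids)
    }
  }
  expect_error(split_train_test(co, 1.2), class = "patsim_parameterization_error")
  expect_error(split_train_test(co, 0), class = "patsim_parameterization_error")
})

test_that("cohort CSV round trip is exact and schema violations are rejected", {
  co <- random_copd_cohort(10, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path, co$schema)
  expect_identical(back$ids, co$ids)
  expect_equal(back$table, co$table)

  lines <- readLines(path)
  broken <- withr::local_tempfile(fileext = ".csv")
  lines[3] <- sub("^([^,]*,)[^,]*", "\\1", lines[3])   # blank out age of row 2
  writeLines(lines, broken)
  expect_error(read_cohort(broken, co$schema), class = "patsim_validation_error")

  lines <- readLines(path)
  lines[2] <- sub("(none|mono|dual|triple)", "quad", lines[2])
  writeLines(lines, broken)
  expect_error(read_cohort(broken, co$schema), "quad",
               class = "patsim_validation_error")
})

test_that("schema YAML round trip preserves structure", {
  sch <- copd_schema()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_schema(sch, path)
  back <- read_schema(path)
  expect_identical(schema_names(back), schema_names(sch))
  expect_identical(schema_dtypes(back), schema_dtypes(sch))
  expect_identical(back$therapy$levels, sch$therapy$levels)
})
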