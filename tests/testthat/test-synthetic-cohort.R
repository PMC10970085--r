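test_that("generation is deterministic in (config, seed)", {
  cfg <- generator_config(n_strata = 4, psus_per_stratum = 2,
                          records_per_psu = 20, seed = 1L)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$truth$latent_probability, g2$truth$latent_probability)
  g3 <- generate_cohort(generator_config(n_strata = 4,
                                         psus_per_stratum = 2,
                                         records_per_psu = 20, seed = 2L))
  expect_false(identical(g1$cohort$sbp, g3$cohort$sbp))
})

test_that("design structure and weight total match the configuration", {
  cfg <- generator_config(n_strata = 5, psus_per_stratum = 3,
                          records_per_psu = 10,
                          population_total = 1234567, seed = 3L)
  g <- generate_cohort(cfg)
  expect_equal(nrow(g$cohort), 5 * 3 * 10)
  expect_equal(sum(g$cohort$weight), 1234567, tolerance = 1e-6)
  expect_true(all(g$cohort$weight > 0))
  expect_equal(nlevels(g$design$psu), 15)
  # every column the recoder and indices need is present
  expect_true(all(c("income_bracket", "education", "smoked_past_month",
                    "drinks_per_year", "physical_activity",
                    "occupation_current", "occupation_longest",
                    "sbp", "dbp", "tc", "hba1c", "bmi", "hdl", "tg",
                    "albumin", "clcr", "crp") %in% names(g$cohort)))
})

test_that("diagonal biomarker covariance yields uncorrelated markers", {
  p <- 10
  cfg <- generator_config(n_strata = 10, psus_per_stratum = 2,
                          records_per_psu = 500,
                          biomarker_cov = diag(c(14, 10, 40, 0.7, 6, 14,
                                                 90, 0.35, 40, 0.45)^2),
                          seed = 5L)
  g <- generate_cohort(cfg)
  markers <- as.matrix(g$cohort[, c("sbp", "dbp", "tc", "hba1c", "bmi",
                                    "hdl", "tg", "albumin", "clcr",
                                    "crp")])
  R <- cor(markers)
  offdiag <- R[upper.tri(R)]
  # MC tolerance 3/sqrt(n) at n = 10,000, avoiding floor-truncation pairs
  expect_lt(max(abs(offdiag)), 0.05)
})

test_that("default covariance delivers the negative HDL-TG correlation", {
  g <- generate_cohort(generator_config(n_strata = 10,
                                        psus_per_stratum = 2,
                                        records_per_psu = 100, seed = 6L))
  r <- cor(g$cohort$hdl, g$cohort$tg)
  expect_lt(r, -0.3)
  expect_gt(r, -0.5)
})

test_that("weighted marker means recover the configured means", {
  cfg <- generator_config(n_strata = 10, psus_per_stratum = 2,
                          records_per_psu = 300, seed = 7L)
  g <- generate_cohort(cfg)
  for (m in c("sbp", "tc", "bmi", "hdl")) {
    est <- weighted_mean_se(g$cohort[[m]], g$design)
    expect_lt(abs(est$estimate - cfg$biomarker_means[[m]]), 4 * est$se)
  }
})

test_that("non-PSD covariance is rejected naming the matrix", {
  bad <- diag(10)
  bad[1, 2] <- bad[2, 1] <- 2 # correlation > 1
  expect_error(generator_config(biomarker_cov = bad),
               "biomarker_cov.*positive semi-definite")
})

test_that("missingness injection hits target rates and spares design columns", {
  g <- generate_cohort(generator_config(n_strata = 10,
                                        psus_per_stratum = 2,
                                        records_per_psu = 250, seed = 8L))
  n <- nrow(g$cohort) # 5000

  # rate 0 leaves the table unchanged
  expect_identical(inject_missingness(g$cohort, c(sbp = 0), seed = 2),
                   g$cohort)
  # rate 1 blanks the column entirely
  all_gone <- inject_missingness(g$cohort, c(hdl = 1), seed = 2)
  expect_true(all(is.na(all_gone$hdl)))
  # rate 0.1 lands inside the binomial 99% interval at n = 5000
  m <- inject_missingness(g$cohort, c(tc = 0.1), seed = 3)
  frac <- mean(is.na(m$tc))
  expect_gte(frac, 0.082)
  expect_lte(frac, 0.118)

  expect_error(inject_missingness(g$cohort, c(sbp = 1.2)), "\\[0,1\\]")
  expect_error(inject_missingness(g$cohort, c(weight = 0.1)),
               "design/id columns")
})

test_that("cohort bundle round-trips through CSV/JSON/YAML files", {
  g <- generate_cohort(generator_config(n_strata = 3, psus_per_stratum = 2,
                                        records_per_psu = 10, seed = 9L))
  dir <- withr::local_tempdir()
  paths <- write_cohort(g, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths[["cohort"]], stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(g$cohort))
  expect_equal(back$sbp, g$cohort$sbp, tolerance = 1e-10)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$effect_sizes$beta_age, log(1.07), tolerance = 1e-8)
  cfg <- yaml::read_yaml(paths[["config"]])
  expect_equal(cfg$n_strata, 3)
})
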