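test_that("weighted quantile matches the integer-weight expansion oracle", {
  expect_equal(weighted_quantile(rep(7, 5), rep(1, 5), 0.3), 7)
  expect_equal(weighted_quantile(c(1, 2, 3, 4), rep(1, 4), 0.75),
               expansion_quantile(c(1, 2, 3, 4), rep(1, 4), 0.75))
  expect_equal(weighted_quantile(c(1, 2, 3, 4), c(1, 1, 1, 100), 0.5), 4)
  set.seed(21)
  for (i in 1:25) {
    v <- sample(-10:10, 8, replace = TRUE) + round(runif(8), 2)
    w <- sample(1:9, 8, replace = TRUE)
    q <- runif(1, 0.05, 0.95)
    expect_equal(weighted_quantile(v, w, q), expansion_quantile(v, w, q),
                 info = sprintf("case %d q=%.3f", i, q))
  }
  expect_error(weighted_quantile(numeric(0), numeric(0), 0.5),
               "no non-missing")
  expect_error(weighted_quantile(1:3, c(1, 0, 1), 0.5), "positive")
})

test_that("cutoffs respect direction, weighting and provenance", {
  g <- small_cohort(seed = 22, H = 6, m = 2, k = 50)
  cuts <- derive_cutoffs(g$cohort, al_spec(), g$design)
  expect_equal(nrow(cuts), 10)
  expect_equal(cuts$quantile[cuts$marker == "hdl"], 0.25)
  expect_equal(cuts$quantile[cuts$marker == "tg"], 0.75)
  expect_equal(cuts$cutoff[cuts$marker == "sbp"],
               weighted_quantile(g$cohort$sbp, rep(1, nrow(g$cohort)),
                                 0.75))
  expect_true(all(cuts$n_used == nrow(g$cohort)))

  # equal weights: weighted and unweighted cutoffs agree exactly
  d_eq <- svy_design(g$cohort$stratum, g$cohort$psu,
                     rep(2, nrow(g$cohort)))
  cw <- derive_cutoffs(g$cohort, al_spec(cutoff_weighting = "weighted"),
                       d_eq)
  expect_equal(cw$cutoff, cuts$cutoff)

  broke <- g$cohort
  broke$crp <- NA_real_
  expect_error(derive_cutoffs(broke, al_spec(), g$design), "crp")
})

test_that("scoring, summing and classifying follow the index contracts", {
  g <- small_cohort(seed = 23)
  spec <- csi_spec()
  cuts <- derive_cutoffs(g$cohort, spec, g$design)
  sc <- score_components(g$cohort, cuts, spec)
  score <- compute_index(sc$components)

  # score conservation on complete records
  expect_equal(score[sc$complete],
               as.integer(rowSums(sc$components[sc$complete, ])))
  expect_true(all(score[sc$complete] >= 0 & score[sc$complete] <= 10))
  expect_true(all(is.na(score[!sc$complete])))

  # hand-built extreme records
  rec <- g$cohort[1:2, ]
  rec$risk_education <- c(1L, 0L)
  rec$risk_poverty <- c(1L, 0L)
  rec$risk_alcohol <- c(1L, 0L)
  rec$risk_smoking <- c(1L, 0L)
  rec$risk_inactivity <- c(1L, 0L)
  for (m in c("sbp", "dbp", "tc", "hba1c", "bmi")) {
    rec[[m]] <- c(max(g$cohort[[m]]) + 1, min(g$cohort[[m]]) - 1)
  }
  sc2 <- score_components(rec, cuts, spec)
  expect_equal(unname(sc2$components[1, ]), rep(1L, 10))
  expect_equal(unname(sc2$components[2, ]), rep(0L, 10))

  rec$hba1c[1] <- NA
  sc3 <- score_components(rec, cuts, spec)
  expect_false(sc3$complete[1])
  expect_true(is.na(compute_index(sc3$components)[1]))

  # risk classification at the stated thresholds
  expect_equal(as.character(classify_risk(c(4L, 5L, 10L), csi_spec())),
               c("low", "high", "high"))
  expect_equal(as.character(classify_risk(c(2L, 3L), al_spec())),
               c("low", "high"))
  expect_equal(as.character(classify_risk(0L, csi_spec())), "low")
  expect_equal(as.character(classify_risk(0L, al_spec())), "low")
  expect_error(classify_risk(11L, csi_spec()), "\\[0,10\\]")
})

test_that("risk is monotone in components and in the threshold", {
  g <- small_cohort(seed = 24)
  spec <- al_spec()
  cuts <- derive_cutoffs(g$cohort, spec, g$design)
  sc <- score_components(g$cohort, cuts, spec)
  comp <- sc$components[sc$complete, ]
  score <- compute_index(comp)
  risk <- classify_risk(score, spec)
  # flipping any 0 component to 1 never lowers the risk class
  set.seed(24)
  for (i in sample(nrow(comp), 30)) {
    zeros <- which(comp[i, ] == 0L)
    if (!length(zeros)) next
    j <- sample(zeros, 1)
    flipped <- comp[i, ]
    flipped[j] <- 1L
    r2 <- classify_risk(compute_index(flipped), spec)
    expect_gte(as.integer(r2), as.integer(risk[i]))
  }
  # fraction high is nonincreasing in the threshold
  fr <- vapply(0:10, function(th) {
    mean(classify_risk(score, al_spec(risk_threshold = th)) == "high")
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("quartile components hit ~25% prevalence on iid markers", {
  g <- small_cohort(seed = 25, H = 10, m = 2, k = 100)
  spec <- al_spec()
  cuts <- derive_cutoffs(g$cohort, spec, g$design)
  sc <- score_components(g$cohort, cuts, spec)
  n <- nrow(g$cohort)
  tol <- 3 * sqrt(0.25 * 0.75 / n)
  prev <- colMeans(sc$components)
  expect_true(all(abs(prev - 0.25) < tol + 1 / n),
              info = paste(round(prev, 3), collapse = " "))
})

test_that("build_index_table performs complete-case scoring per index", {
  g <- small_cohort(seed = 26)
  g$cohort <- inject_missingness(g$cohort,
                                 c(hba1c = 0.15, hdl = 0.1,
                                   income_bracket = 0.1), seed = 5)
  g$cohort <- recode_all(g$cohort) # re-derive risk cols after missingness
  csi <- suppressMessages(build_index_table(g$cohort, csi_spec(),
                                            g$design))
  al <- suppressMessages(build_index_table(g$cohort, al_spec(), g$design))
  # the two indices lose different records (different component sets)
  expect_true(sum(csi$index$csi_complete) < nrow(g$cohort))
  expect_true(sum(al$index$al_complete) < nrow(g$cohort))
  expect_false(identical(csi$index$csi_complete, al$index$al_complete))
  # scores only on complete records
  expect_true(all(is.na(csi$index$csi_score[!csi$index$csi_complete])))
  expect_true(all(!is.na(csi$index$csi_score[csi$index$csi_complete])))
  # cutoffs derived before complete-case filtering: n_used is the
  # per-marker non-missing count, not the complete-case count
  expect_equal(al$cutoffs$n_used[al$cutoffs$marker == "hba1c"],
               sum(!is.na(g$cohort$hba1c)))
})
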