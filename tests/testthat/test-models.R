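test_that("survey logistic matches ordinary ML when weights are equal", {
  set.seed(51)
  n <- 400
  x <- rnorm(n)
  grp <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.4 + 0.8 * grp + 0.5 * x))
  dat <- data.frame(y = y, x = x, grp = grp)
  d <- iid_design(n, weight = 2)
  fit <- fit_survey_logistic(y ~ x + grp, dat, d)
  oracle <- glm(y ~ x + grp, family = binomial, data = dat)
  expect_equal(unname(fit$coefficients), unname(coef(oracle)),
               tolerance = 1e-6)
  # normalized-weight pseudo-AIC equals the classical AIC here
  expect_equal(fit$aic, AIC(oracle), tolerance = 1e-6)
  expect_lt(fit$convergence$score_norm, 1e-8)
})

test_that("a single binary predictor reproduces the 2x2 cross-product OR", {
  set.seed(52)
  n <- 500
  a <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + 1.1 * a))
  d <- iid_design(n)
  fit <- fit_survey_logistic(y ~ a, data.frame(y = y, a = a), d)
  tab <- table(a, y)
  or_oracle <- (tab["1", "1"] * tab["0", "0"]) /
    (tab["1", "0"] * tab["0", "1"])
  expect_equal(unname(fit$or[fit$terms == "a"]), or_oracle,
               tolerance = 1e-6)
})

test_that("OR, CI and p are internally consistent", {
  g <- small_cohort(seed = 53)
  fit <- fit_survey_logistic(latent_high ~ age + sex + smoker, g$cohort,
                             g$design)
  expect_equal(unname(fit$or), exp(unname(fit$coefficients)),
               tolerance = 1e-12)
  expect_true(all(fit$ci_low < fit$or & fit$or < fit$ci_high))
  expect_true(all(fit$or > 0))
  # p < 0.05 iff the 95% CI excludes OR = 1 (same t reference)
  sig <- unname(fit$p < 0.05)
  excl <- unname(fit$ci_low > 1 | fit$ci_high < 1)
  expect_equal(sig, excl)
})

test_that("degenerate model inputs are rejected with useful messages", {
  g <- small_cohort(seed = 54)
  g$cohort$constant <- 1
  expect_error(
    fit_survey_logistic(latent_high ~ age + constant, g$cohort, g$design),
    "constant")
  g$cohort$all_one <- 1L
  expect_error(
    fit_survey_logistic(all_one ~ age, g$cohort, g$design),
    "single level")
  # quasi-separated outcome reports separation, not a cryptic failure
  set.seed(54)
  n <- 200
  x <- rnorm(n)
  ysep <- as.integer(x > 0)
  expect_error(
    fit_survey_logistic(y ~ x, data.frame(y = ysep, x = x),
                        iid_design(n)),
    "separation|converge")
})

test_that("odds-ratio table lays out terms, references and the AIC footer", {
  g <- small_cohort(seed = 55)
  fit <- fit_survey_logistic(
    latent_high ~ age + sex + poverty_status + smoker + loa,
    g$cohort, g$design)
  ort <- odds_ratio_table(fit)
  expect_equal(ort$term[1], "age") # model order preserved
  expect_true("sex Female" %in% ort$term[ort$reference])
  expect_true("poverty_status At or Below" %in% ort$term[ort$reference])
  expect_true("loa High" %in% ort$term[ort$reference])
  expect_true(all(is.na(ort$p[ort$reference])))
  expect_equal(attr(ort, "aic"), fit$aic)
})

test_that("index comparison attributes candidates to the right test and index", {
  # candidate driven by CSI-only components (smoking + poverty) should
  # associate with CSI risk and not with AL risk (whose markers are
  # independent of behaviors here)
  hits_csi <- 0
  hits_al <- 0
  n_seeds <- 60
  for (s in seq_len(n_seeds)) {
    g <- small_cohort(seed = 500 + s, H = 8, m = 2, k = 40)
    csi <- suppressMessages(build_index_table(g$cohort, csi_spec(),
                                              g$design))
    al <- suppressMessages(build_index_table(g$cohort, al_spec(),
                                             g$design))
    g$cohort$csi_risk <- csi$index$csi_risk
    g$cohort$al_risk <- al$index$al_risk
    set.seed(900 + s)
    lp <- -1 + 2.5 * g$cohort$risk_smoking + 2.5 * g$cohort$risk_poverty
    g$cohort$candidate <- factor(ifelse(
      rbinom(nrow(g$cohort), 1, plogis(lp)) == 1, "yes", "no"))
    cm <- compare_indices(g$cohort, g$design, "candidate")
    hits_csi <- hits_csi +
      isTRUE(cm$significant[cm$index == "CSI"])
    hits_al <- hits_al + isTRUE(cm$significant[cm$index == "AL"])
  }
  expect_gte(hits_csi / n_seeds, 0.8)
  expect_lte(hits_al / n_seeds, 0.3)
})

test_that("null candidates are non-significant at about the nominal rate", {
  sig <- 0
  n_seeds <- 60
  for (s in seq_len(n_seeds)) {
    g <- small_cohort(seed = 700 + s, H = 8, m = 2, k = 40)
    csi <- suppressMessages(build_index_table(g$cohort, csi_spec(),
                                              g$design))
    al <- suppressMessages(build_index_table(g$cohort, al_spec(),
                                             g$design))
    g$cohort$csi_risk <- csi$index$csi_risk
    g$cohort$al_risk <- al$index$al_risk
    set.seed(1100 + s)
    g$cohort$noise <- rnorm(nrow(g$cohort))
    cm <- compare_indices(g$cohort, g$design, "noise")
    sig <- sig + sum(cm$significant)
  }
  # 2 cells per seed at alpha = 0.05: ~95% non-significant
  expect_lte(sig / (2 * n_seeds), 0.12)
})

test_that("comparison cells cover self-association and non-evaluable states", {
  g <- small_cohort(seed = 58)
  csi <- suppressMessages(build_index_table(g$cohort, csi_spec(),
                                            g$design))
  al <- suppressMessages(build_index_table(g$cohort, al_spec(), g$design))
  g$cohort$csi_risk <- csi$index$csi_risk
  g$cohort$al_risk <- al$index$al_risk
  g$cohort$csi_copy <- g$cohort$csi_risk
  g$cohort$unusable <- factor(rep("only", nrow(g$cohort)))
  cm <- compare_indices(g$cohort, g$design, c("csi_copy", "unusable"))
  expect_true(cm$significant[cm$index == "CSI" &
                               cm$candidate == "csi_copy"])
  expect_true(all(cm$status[cm$candidate == "unusable"] ==
                    "not evaluable"))
  # model-term candidates take their p from the supplied fit
  fit <- fit_survey_logistic(latent_high ~ age + sex, g$cohort, g$design)
  cm2 <- compare_indices(g$cohort, g$design, "age",
                         fits = list(al = fit, csi = fit))
  expect_equal(cm2$method, rep("logistic model term", 2))
  expect_equal(cm2$p, rep(unname(fit$p["age"]), 2))
})
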