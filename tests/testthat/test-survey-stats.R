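test_that("weighted mean reduces to the classical srs mean and SE", {
  set.seed(31)
  x <- rnorm(200, 5, 2)
  d <- iid_design(200, weight = 3.7)
  est <- weighted_mean_se(x, d)
  expect_equal(est$estimate, mean(x))
  # direct srs linearization oracle
  n <- length(x)
  expect_equal(est$se, sqrt(sum((x - mean(x))^2) * n / ((n - 1) * n^2)))
  expect_equal(est$df_design, n - 1)

  # all weight concentrated on one record pins the estimate to it
  w <- c(1e9, rep(1e-9, 9))
  d1 <- svy_design(rep(1, 10), 1:10, w)
  expect_equal(weighted_mean_se(1:10, d1)$estimate, 1, tolerance = 1e-6)
})

test_that("estimates, tests and fits are invariant to weight rescaling", {
  g <- small_cohort(seed = 32)
  d2 <- svy_design(g$cohort$stratum, g$cohort$psu,
                   g$cohort$weight * 137.5)
  e1 <- weighted_mean_se(g$cohort$bmi, g$design)
  e2 <- weighted_mean_se(g$cohort$bmi, d2)
  expect_equal(e1$estimate, e2$estimate)
  expect_equal(e1$se, e2$se)

  t1 <- rao_scott_chisq(g$cohort$sex, g$cohort$smoked_past_month, g$design)
  t2 <- rao_scott_chisq(g$cohort$sex, g$cohort$smoked_past_month, d2)
  expect_equal(t1$statistic, t2$statistic)
  expect_equal(t1$p, t2$p)

  r1 <- survey_ranksum(g$cohort$bmi, g$cohort$sex, g$design)
  r2 <- survey_ranksum(g$cohort$bmi, g$cohort$sex, d2)
  expect_equal(r1$statistic, r2$statistic)

  f1 <- fit_survey_logistic(latent_high ~ age + sex, g$cohort, g$design)
  f2 <- fit_survey_logistic(latent_high ~ age + sex, g$cohort, d2)
  expect_equal(f1$or, f2$or)
  expect_equal(f1$ci_low, f2$ci_low)
  expect_equal(f1$aic, f2$aic)
})

test_that("weighted proportions sum to one and match relative frequencies", {
  set.seed(33)
  x <- sample(c("a", "b", "c"), 150, replace = TRUE)
  d <- iid_design(150)
  pr <- weighted_proportions(x, d)
  expect_equal(sum(pr$proportion), 1, tolerance = 1e-12)
  expect_equal(pr$proportion, as.vector(prop.table(table(x))))
  # single level
  pr1 <- weighted_proportions(rep("only", 20), iid_design(20))
  expect_equal(pr1$proportion, 1)
  # unequal weights shift the proportions accordingly
  w <- c(rep(10, 50), rep(1, 100))
  dw <- svy_design(rep(1, 150), 1:150, w)
  prw <- weighted_proportions(rep(c("hi", "lo"), c(50, 100)), dw)
  expect_equal(prw$proportion[prw$level == "hi"], 500 / 600)
})

test_that("Rao-Scott test approximates the classical Pearson test when iid", {
  set.seed(34)
  diffs <- replicate(200, {
    n <- 300
    a <- sample(0:1, n, TRUE)
    b <- sample(1:3, n, TRUE)
    d <- iid_design(n)
    p_rs <- rao_scott_chisq(a, b, d)$p
    p_cl <- suppressWarnings(chisq.test(table(a, b), correct = FALSE))$p.value
    abs(p_rs - p_cl)
  })
  expect_lt(median(diffs), 0.02)
})

test_that("Rao-Scott test detects perfect dependence", {
  set.seed(35)
  x <- sample(c("u", "v"), 500, TRUE)
  d <- clustered_design(H = 10, m = 2, k = 25)
  expect_lt(rao_scott_chisq(x, x, d)$p, 0.001)
  expect_error(rao_scott_chisq(rep("u", 500), x, d), ">= 2 observed levels")
})

test_that("rank-sum test approximates the classical test when iid and has power", {
  set.seed(36)
  diffs <- replicate(200, {
    n <- 200
    y <- rnorm(n)
    grp <- sample(0:1, n, TRUE)
    d <- iid_design(n)
    p_s <- survey_ranksum(y, grp, d)$p
    p_c <- suppressWarnings(wilcox.test(y ~ grp, correct = FALSE))$p.value
    abs(p_s - p_c)
  })
  expect_lt(median(diffs), 0.02)

  # location shift of 2 SD at n = 500/group is detected overwhelmingly
  y <- c(rnorm(500), rnorm(500, 2))
  grp <- rep(0:1, each = 500)
  d <- clustered_design(H = 10, m = 4, k = 25)
  expect_lt(survey_ranksum(y, grp, d)$p, 0.001)
  expect_error(survey_ranksum(y, rep(0, 1000), d), "2 observed levels")
})

test_that("confidence intervals for the mean attain nominal coverage", {
  set.seed(37)
  hits <- replicate(1000, {
    d <- clustered_design(H = 10, m = 4, k = 50, wsd = 0.4)
    y <- rnorm(2000, 5, 2)
    e <- weighted_mean_se(y, d)
    ci <- e$estimate + c(-1, 1) * qt(0.975, e$df_design) * e$se
    ci[1] <= 5 && 5 <= ci[2]
  })
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("lonely PSUs error by default and can be certainty-handled", {
  d_bad <- svy_design(c(1, 1, 2), c(1, 2, 1), c(1, 1, 1))
  expect_error(weighted_mean_se(c(1, 2, 3), d_bad), "single PSU")
  expect_warning(
    est <- weighted_mean_se(c(1, 2, 3), d_bad, lonely_psu = "certainty"),
    "certainty")
  expect_true(est$se >= 0)
})

test_that("grouped summaries carry estimates, shares and the right tests", {
  g <- small_cohort(seed = 38)
  risk <- factor(ifelse(g$cohort$latent_high == 1, "high", "low"),
                 levels = c("low", "high"))
  gs <- grouped_summary(g$cohort, risk, c("age", "bmi", "sex", "smoker"),
                        g$design)
  expect_true(all(c("variable", "level", "type", "overall", "p", "n") %in%
                    names(gs)))
  # continuous rows: one per variable; categorical: one per level
  expect_equal(sum(gs$variable == "age"), 1)
  expect_equal(sum(gs$variable == "sex"), 2)
  # group shares for a level sum to 1 across the two groups
  sexrows <- gs[gs$variable == "sex", ]
  expect_equal(sexrows$low + sexrows$high, c(1, 1), tolerance = 1e-12)
  # categorical overall proportions sum to one within a variable
  expect_equal(sum(sexrows$overall), 1, tolerance = 1e-12)
  expect_error(grouped_summary(g$cohort, risk, "nope", g$design), "nope")
})
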