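#' Biomarkers generated by the synthetic cohort
#'
#' The ten continuous markers used by the CSI and AL indices, with their
#' generator column names.
#' @keywords internal
BIOMARKERS <- c("sbp", "dbp", "tc", "hba1c", "bmi",
                "hdl", "tg", "albumin", "clcr", "crp")

# Physiologic floors applied after multivariate-normal draws, so quartile
# cutoffs stay well-defined without implausible values.
.biomarker_floor <- c(sbp = 70, dbp = 40, tc = 80, hba1c = 3.5, bmi = 12,
                      hdl = 10, tg = 20, albumin = 1.5, clcr = 10,
                      crp = 0.01)

.default_biomarker_means <- c(sbp = 120, dbp = 72, tc = 200, hba1c = 5.4,
                              bmi = 28, hdl = 49.7, tg = 152.8,
                              albumin = 4.3, clcr = 144.2, crp = 0.39)

.default_biomarker_sds <- c(sbp = 14, dbp = 10, tc = 40, hba1c = 0.7,
                            bmi = 6, hdl = 14, tg = 90, albumin = 0.35,
                            clcr = 40, crp = 0.45)

# Default correlation structure: strong SBP-DBP coupling, the lipid panel
# relations (negative HDL-TG being the strongest pairwise relation), and
# adiposity/inflammation links.
.default_biomarker_cor <- function() {
  p <- length(BIOMARKERS)
  R <- diag(p)
  dimnames(R) <- list(BIOMARKERS, BIOMARKERS)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("sbp", "dbp", 0.60)
  set_r("sbp", "bmi", 0.20)
  set_r("dbp", "bmi", 0.20)
  set_r("tc", "tg", 0.30)
  set_r("tc", "hdl", 0.10)
  set_r("hdl", "tg", -0.40)
  set_r("bmi", "tg", 0.25)
  set_r("bmi", "hdl", -0.25)
  set_r("bmi", "crp", 0.30)
  set_r("tg", "crp", 0.15)
  set_r("hba1c", "bmi", 0.20)
  set_r("hba1c", "tg", 0.15)
  set_r("albumin", "crp", -0.15)
  set_r("clcr", "bmi", 0.20)
  R
}

#' Configuration for the synthetic survey cohort generator
#'
#' Describes a stratified two-stage sample (strata containing PSUs
#' containing records) with unequal lognormal weights rescaled to a target
#' population total, correlated continuous biomarkers, the categorical
#' income/education/occupation vocabularies used by the recoding rules, and
#' a latent-risk logistic model whose coefficients (`effect_sizes`) drive a
#' binary `latent_high` outcome used for parameter-recovery studies.
#'
#' Defaults describe a cohort of 15 strata x 2 PSUs x 140 records
#' (n = 4200) of adults aged 20-49 with a population total of 25 million —
#' the scale of a two-cycle national examination-survey extract for that
#' age band.
#'
#' @param n_strata,psus_per_stratum,records_per_psu positive integers
#'   giving the design dimensions.
#' @param population_total target for the sum of weights.
#' @param weight_dispersion lognormal sdlog of the raw weights before
#'   rescaling (0 = equal weights).
#' @param biomarker_means named numeric vector over the ten markers,
#'   clinical units.
#' @param biomarker_cov positive semi-definite covariance matrix over the
#'   ten markers (defaults to a clinically plausible correlation structure
#'   with a negative HDL-TG correlation).
#' @param effect_sizes named list/vector of log-odds effects on the latent
#'   high-risk outcome: `intercept`, `beta_age` (per year, age centred at
#'   35), `beta_male`, `beta_smoker`.
#' @param marker_loadings named numeric vector: shift of each biomarker per
#'   unit of the latent linear predictor (default all zero, so the realized
#'   biomarker covariance is exactly `biomarker_cov`).
#' @param coarse_income_frac fraction of respondents reporting only the
#'   coarse "More/Less than $20,000" income alternatives.
#' @param missing_rates named vector of MCAR missingness rates in \[0,1\]
#'   applied by [generate_cohort()] via [inject_missingness()].
#' @param seed integer RNG seed; `(config, seed)` fully determines the
#'   output.
#' @return a validated object of class `generator_config`.
#' @seealso [generate_cohort()]
#' @export
generator_config <- function(n_strata = 15L,
                             psus_per_stratum = 2L,
                             records_per_psu = 140L,
                             population_total = 25e6,
                             weight_dispersion = 0.5,
                             biomarker_means = .default_biomarker_means,
                             biomarker_cov = NULL,
                             effect_sizes = list(intercept = -0.25,
                                                 beta_age = log(1.07),
                                                 beta_male = log(2.0),
                                                 beta_smoker = log(1.5)),
                             marker_loadings = NULL,
                             coarse_income_frac = 0.05,
                             missing_rates = NULL,
                             seed = 1L) {
  if (is.null(biomarker_cov)) {
    R <- .default_biomarker_cor()
    s <- .default_biomarker_sds
    biomarker_cov <- R * tcrossprod(s)
  }
  if (is.null(dimnames(biomarker_cov))) {
    dimnames(biomarker_cov) <- list(BIOMARKERS, BIOMARKERS)
  }
  cfg <- list(
    n_strata = as.integer(n_strata),
    psus_per_stratum = as.integer(psus_per_stratum),
    records_per_psu = as.integer(records_per_psu),
    population_total = as.numeric(population_total),
    weight_dispersion = as.numeric(weight_dispersion),
    biomarker_means = biomarker_means,
    biomarker_cov = biomarker_cov,
    effect_sizes = as.list(effect_sizes),
    marker_loadings = marker_loadings %||%
      stats::setNames(numeric(length(BIOMARKERS)), BIOMARKERS),
    coarse_income_frac = as.numeric(coarse_income_frac),
    missing_rates = missing_rates,
    seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (n_strata < 1 || psus_per_stratum < 1 || records_per_psu < 1) {
      stop_named("design dimensions must be positive integers")
    }
    if (population_total <= 0) stop_named("population_total must be positive")
    if (weight_dispersion < 0) stop_named("weight_dispersion must be >= 0")
    if (!all(BIOMARKERS %in% names(biomarker_means))) {
      stop_named("biomarker_means must name all of: %s",
                 paste(BIOMARKERS, collapse = ", "))
    }
    check_psd(biomarker_cov, name = "biomarker_cov")
    if (!identical(colnames(biomarker_cov), BIOMARKERS) &&
        !is.null(colnames(biomarker_cov)) &&
        !all(BIOMARKERS %in% colnames(biomarker_cov))) {
      stop_named("biomarker_cov dimnames must cover the ten biomarkers")
    }
    if (coarse_income_frac < 0 || coarse_income_frac > 1) {
      stop_named("coarse_income_frac must lie in [0,1]")
    }
    if (!is.null(missing_rates) &&
        (any(missing_rates < 0) || any(missing_rates > 1))) {
      stop_named("missing_rates must lie in [0,1]")
    }
  })
  invisible(cfg)
}

# Income bracket vocabulary used by the generator (upper bounds in dollars;
# Inf = top-coded bracket).
.income_brackets <- data.frame(
  label = c("$0-$4,999", "$5,000-$9,999", "$10,000-$14,999",
            "$15,000-$19,999", "$20,000-$24,999", "$25,000-$34,999",
            "$35,000-$44,999", "$45,000-$54,999", "$55,000-$64,999",
            "$65,000-$74,999", "$75,000 and over"),
  lower = c(0, 5000, 10000, 15000, 20000, 25000, 35000, 45000, 55000,
            65000, 75000),
  upper = c(4999, 9999, 14999, 19999, 24999, 34999, 44999, 54999, 64999,
            74999, Inf),
  stringsAsFactors = FALSE)

.education_levels <- c(
  "Less than 9th grade",
  "9-11th grade (Includes 12th grade without diploma)",
  "High school graduate/GED or equivalent",
  "Some college or AA degree",
  "College graduate or above")

.race_levels <- c("NH White", "NH Black", "Mexican American",
                  "Other Hispanic", "Other and/or Multi-racial")

#' Generate a synthetic survey cohort
#'
#' Draws a stratified two-stage cohort under the configuration: design ids
#' and lognormal weights rescaled to the population total, demographics,
#' behaviors, occupation titles, ten correlated biomarkers (multivariate
#' normal, clipped to physiologic floors), and a binary latent high-risk
#' outcome drawn from the configured logistic model. Output is fully
#' reproducible from `(config, config$seed)`.
#'
#' @param config a [generator_config()].
#' @return a list with elements
#'   \describe{
#'     \item{cohort}{data.frame of participant records (one row per
#'       participant, keyed by `participant_id`), including design columns
#'       `stratum`, `psu`, `weight`.}
#'     \item{design}{the matching [svy_design()].}
#'     \item{truth}{the truth ledger: realized effect sizes, population
#'       quartiles per marker, per-record latent risk probability, and a
#'       config echo.}
#'   }
#' @examples
#' g <- generate_cohort(generator_config(n_strata = 4, records_per_psu = 25))
#' head(g$cohort)
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  n <- config$n_strata * config$psus_per_stratum * config$records_per_psu

  stratum <- rep(seq_len(config$n_strata),
                 each = config$psus_per_stratum * config$records_per_psu)
  psu <- rep(rep(seq_len(config$psus_per_stratum),
                 each = config$records_per_psu),
             times = config$n_strata)

  w_raw <- stats::rlnorm(n, meanlog = 0, sdlog = config$weight_dispersion)
  weight <- w_raw * config$population_total / sum(w_raw)

  age <- sample(20:49, n, replace = TRUE)
  sex <- factor(sample(c("Female", "Male"), n, replace = TRUE),
                levels = c("Female", "Male"))
  race <- factor(sample(.race_levels, n, replace = TRUE,
                        prob = c(0.68, 0.12, 0.10, 0.05, 0.05)),
                 levels = .race_levels)

  income_dollars <- stats::rlnorm(n, meanlog = log(40000), sdlog = 0.8)
  bi <- findInterval(income_dollars, c(.income_brackets$lower, Inf))
  income_bracket <- .income_brackets$label[pmin(bi, nrow(.income_brackets))]
  coarse <- stats::runif(n) < config$coarse_income_frac
  income_bracket[coarse] <- ifelse(income_dollars[coarse] < 20000,
                                   "Less than $20,000", "More than $20,000")

  education <- sample(.education_levels, n, replace = TRUE,
                      prob = c(0.05, 0.115, 0.28, 0.35, 0.205))

  smoked_past_month <- sample(c("Yes", "No"), n, replace = TRUE,
                              prob = c(0.30, 0.70))
  # drinks/year: point mass at low counts plus a lognormal drinking tail
  drinker <- stats::runif(n) < 0.72
  drinks_per_year <- ifelse(
    drinker, round(stats::rlnorm(n, meanlog = log(60), sdlog = 1)),
    sample(0:11, n, replace = TRUE))
  physical_activity <- sample(c("Yes", "No", "Unable to Do"), n,
                              replace = TRUE, prob = c(0.33, 0.66, 0.01))

  occ_map <- default_occupation_map()
  occupation_current <- sample(occ_map$occupation, n, replace = TRUE)
  occupation_longest <- ifelse(stats::runif(n) < 0.7, occupation_current,
                               sample(occ_map$occupation, n, replace = TRUE))

  # latent logistic risk model
  es <- config$effect_sizes
  eta <- (es$intercept %||% 0) +
    (es$beta_age %||% 0) * (age - 35) +
    (es$beta_male %||% 0) * (sex == "Male") +
    (es$beta_smoker %||% 0) * (smoked_past_month == "Yes")
  p_latent <- stats::plogis(eta)
  latent_high <- stats::rbinom(n, 1L, p_latent)

  mu <- config$biomarker_means[BIOMARKERS]
  markers <- MASS::mvrnorm(n, mu = mu,
                           Sigma = config$biomarker_cov[BIOMARKERS,
                                                        BIOMARKERS])
  load <- config$marker_loadings[BIOMARKERS]
  load[is.na(load)] <- 0
  markers <- markers + outer(eta - mean(eta), load)
  markers <- pmax(markers,
                  matrix(.biomarker_floor[BIOMARKERS], n,
                         length(BIOMARKERS), byrow = TRUE))
  colnames(markers) <- BIOMARKERS

  # self-reported health, worse with higher latent risk (candidate
  # variable for index-comparison analyses)
  hs_levels <- c("Excellent", "Very Good", "Good", "Fair", "Poor")
  hs_cut <- stats::qnorm(c(0.13, 0.51, 0.87, 0.98))
  hs_z <- stats::rnorm(n, mean = scale(eta)[, 1] * 0.6)
  health_status <- factor(hs_levels[findInterval(hs_z, hs_cut) + 1L],
                          levels = hs_levels)

  cohort <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    stratum = stratum, psu = psu, weight = weight,
    age = age, sex = sex, race_ethnicity = race,
    income_bracket = income_bracket, education = education,
    smoked_past_month = smoked_past_month,
    drinks_per_year = drinks_per_year,
    physical_activity = physical_activity,
    occupation_current = occupation_current,
    occupation_longest = occupation_longest,
    health_status = health_status,
    latent_high = latent_high,
    stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(markers))

  if (!is.null(config$missing_rates)) {
    cohort <- inject_missingness(cohort, config$missing_rates,
                                 seed = derive_seed(config$seed, "missing"))
  }

  design <- svy_design(cohort$stratum, cohort$psu, cohort$weight)

  truth <- list(
    effect_sizes = es,
    population_quartiles = lapply(
      stats::setNames(BIOMARKERS, BIOMARKERS),
      function(m) stats::quantile(cohort[[m]], c(0.25, 0.5, 0.75),
                                  na.rm = TRUE)),
    latent_probability = p_latent,
    config = config)

  list(cohort = cohort, design = design, truth = truth)
}

#' Inject missing-completely-at-random values
#'
#' Replaces values with `NA` independently per column at the given rates.
#' Design columns (`stratum`, `psu`, `weight`) and `participant_id` are
#' never made missing.
#'
#' @param table cohort data.frame.
#' @param missing_rates named numeric vector of per-column rates in \[0,1\].
#' @param seed RNG seed.
#' @return the table with missingness applied.
#' @export
inject_missingness <- function(table, missing_rates, seed = 1L) {
  if (any(missing_rates < 0) || any(missing_rates > 1)) {
    stop_named("missing_rates must lie in [0,1]")
  }
  protected <- c("stratum", "psu", "weight", "participant_id")
  bad <- intersect(names(missing_rates), protected)
  if (length(bad)) {
    stop_named("design/id columns may not be made missing: %s",
               paste(bad, collapse = ", "))
  }
  absent <- setdiff(names(missing_rates), names(table))
  if (length(absent)) {
    stop_named("missing_rates names not in table: %s",
               paste(absent, collapse = ", "))
  }
  set.seed(seed)
  for (col in names(missing_rates)) {
    hit <- stats::runif(nrow(table)) < missing_rates[[col]]
    table[[col]][hit] <- NA
  }
  table
}

#' Write a generated cohort bundle to disk
#'
#' Cohort as UTF-8 CSV (design columns `stratum`, `psu`, `weight`), truth
#' ledger as JSON, config as YAML.
#'
#' @param bundle result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "generator_config.yaml"))
  utils::write.csv(bundle$cohort, paths[["cohort"]], row.names = FALSE,
                   fileEncoding = "UTF-8")
  truth <- bundle$truth
  truth$config <- config_to_list(truth$config)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  yaml::write_yaml(config_to_list(bundle$truth$config), paths[["config"]])
  invisible(paths)
}

# generator_config -> plain list for YAML/JSON serialization
config_to_list <- function(config) {
  out <- unclass(config)
  out$biomarker_means <- as.list(out$biomarker_means)
  out$biomarker_cov <- apply(out$biomarker_cov, 1, as.list,
                             simplify = FALSE)
  out$marker_loadings <- as.list(out$marker_loadings)
  if (!is.null(out$missing_rates)) {
    out$missing_rates <- as.list(out$missing_rates)
  }
  out
}
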