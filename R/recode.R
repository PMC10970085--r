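#' Average of poverty-guideline endpoints
#'
#' The poverty cutoff behind the binary poverty recode is derived as the
#' arithmetic mean of the federal poverty-guideline range endpoints over
#' the survey period (endpoints 17650 and 18850 dollars for 2001-2004,
#' giving 18250), which is then rounded up to the nearest coarse income
#' bracket boundary ($20,000) for classification.
#'
#' @param endpoints numeric vector of guideline endpoints in dollars.
#' @return their arithmetic mean.
#' @examples
#' poverty_line_average(c(17650, 18850)) # 18250
#' @export
poverty_line_average <- function(endpoints = c(17650, 18850)) {
  if (!is.numeric(endpoints) || length(endpoints) < 1 || anyNA(endpoints)) {
    stop_named("endpoints must be non-missing numeric values")
  }
  mean(endpoints)
}

# canonical income vocabulary: normalized label -> poverty flag
.income_vocab <- function() {
  fine <- .income_brackets
  v <- stats::setNames(as.integer(fine$upper <= 20000),
                       normalize_label(fine$label))
  c(v,
    stats::setNames(1L, normalize_label("Less than $20,000")),
    stats::setNames(0L, normalize_label("More than $20,000")),
    stats::setNames(0L, normalize_label("Over $20,000")),
    stats::setNames(1L, normalize_label("Under $20,000")))
}

#' Recode income bracket to binary poverty status
#'
#' A bracket maps to poverty (1) iff its upper bound is at or below
#' $20,000, or the coarse alternative "Less than $20,000" was reported;
#' all other brackets map to 0. Missing input propagates to missing
#' output.
#'
#' @param income_label character vector of bracket labels (the eleven fine
#'   brackets or the coarse "More/Less than $20,000" alternatives;
#'   matching is tolerant to case, "$", "," and dash style).
#' @return integer vector of 0/1 poverty flags.
#' @examples
#' recode_poverty(c("$15,000-$19,999", "$75,000 and over"))
#' @export
recode_poverty <- function(income_label) {
  vocab <- .income_vocab()
  key <- normalize_label(income_label)
  out <- vocab[key]
  bad <- !is.na(income_label) & is.na(out)
  if (any(bad)) {
    stop_named("unknown income bracket label(s): %s",
               paste(unique(income_label[bad]), collapse = "; "))
  }
  out[is.na(income_label)] <- NA_integer_
  unname(out)
}

.education_vocab <- function() {
  highrisk <- c("Less than 9th grade",
                "9-11th grade (Includes 12th grade without diploma)",
                "9-11th grade")
  lowrisk <- c("High school graduate/GED or equivalent",
               "High school graduate or GED equivalent",
               "Some college or AA degree",
               "College graduate or above")
  c(stats::setNames(rep(1L, length(highrisk)), normalize_label(highrisk)),
    stats::setNames(rep(0L, length(lowrisk)), normalize_label(lowrisk)))
}

#' Recode education level to binary high-risk flag
#'
#' Levels below a high-school diploma ("Less than 9th grade" and
#' "9-11th grade (Includes 12th grade without diploma)") are high-risk (1);
#' diploma/GED and above are 0.
#'
#' @param level character vector in the five-level education vocabulary.
#' @return integer 0/1 vector; missing propagates.
#' @export
recode_education <- function(level) {
  vocab <- .education_vocab()
  key <- normalize_label(level)
  # tolerate parenthetical variants by also matching the pre-parenthesis stem
  out <- vocab[key]
  stem <- normalize_label(sub("\\(.*\\)", "", level))
  out[is.na(out)] <- vocab[stem[is.na(out)]]
  bad <- !is.na(level) & is.na(out)
  if (any(bad)) {
    stop_named("unknown education level(s): %s",
               paste(unique(level[bad]), collapse = "; "))
  }
  out[is.na(level)] <- NA_integer_
  unname(out)
}

.yesno <- function(x, yes = 1L, no = 0L, what = "value",
                   extra = character(0), extra_code = integer(0)) {
  key <- normalize_label(x)
  map <- c(yes = yes, no = no,
           stats::setNames(extra_code, normalize_label(extra)))
  out <- map[key]
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop_named("invalid %s: %s", what,
               paste(unique(x[bad]), collapse = "; "))
  }
  out[is.na(x)] <- NA_integer_
  unname(out)
}

#' Recode current smoking (smoked at least one cigarette in the past month)
#'
#' @param smoked_past_month "Yes"/"No" responses.
#' @return integer 0/1; missing propagates.
#' @export
recode_smoking <- function(smoked_past_month) {
  .yesno(smoked_past_month, what = "smoking response")
}

#' Recode alcohol use (12 or more drinks in a year)
#'
#' Accepts either a nonnegative drinks-per-year count (high-risk iff
#' count >= 12, boundary inclusive) or a coded "Yes"/"No" response.
#'
#' @param drinks_per_year numeric counts or character codes.
#' @return integer 0/1; missing propagates.
#' @export
recode_alcohol <- function(drinks_per_year) {
  if (is.numeric(drinks_per_year)) {
    if (any(drinks_per_year < 0, na.rm = TRUE)) {
      stop_named("drinks_per_year must be nonnegative")
    }
    return(as.integer(drinks_per_year >= 12))
  }
  .yesno(drinks_per_year, what = "alcohol response")
}

#' Recode physical activity participation
#'
#' Participation ("Yes") is protective (0); "No" is high-risk (1).
#' "Unable to Do" is treated as non-participation, hence high-risk (1) —
#' the conservative reading, since only participation is defined as
#' protective.
#'
#' @param response "Yes"/"No"/"Unable to Do".
#' @return integer 0/1; missing propagates.
#' @export
recode_physical_activity <- function(response) {
  .yesno(response, yes = 0L, no = 1L, what = "physical activity response",
         extra = "Unable to Do", extra_code = 1L)
}

#' Default occupation-to-activity map
#'
#' Two-column table (occupation, activity) classifying occupation titles
#' as low occupational activity (professional, managerial, administrative,
#' clerical) or high (manual labor, skilled trades, service and protective
#' occupations). Shipped as an editable CSV in `extdata`; users analyzing
#' real extracts should extend it to their occupation vocabulary.
#'
#' @return data.frame with columns `occupation`, `activity`.
#' @export
default_occupation_map <- function() {
  path <- system.file("extdata", "occupation_activity.csv",
                      package = "stressindex")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Classify an occupation title as low or high occupational activity
#'
#' Pure lookup in the supplied map; unmapped titles are an error listing
#' the offending labels.
#'
#' @param occupation character vector of titles.
#' @param map data.frame with columns `occupation`, `activity`
#'   (default [default_occupation_map()]).
#' @return character vector of "low"/"high"; missing propagates.
#' @export
classify_occupation_activity <- function(occupation,
                                         map = default_occupation_map()) {
  if (anyDuplicated(normalize_label(map$occupation))) {
    stop_named("occupation map contains duplicate titles")
  }
  lut <- stats::setNames(tolower(map$activity),
                         normalize_label(map$occupation))
  if (!all(lut %in% c("low", "high"))) {
    stop_named("occupation map activity classes must be 'low' or 'high'")
  }
  out <- lut[normalize_label(occupation)]
  bad <- !is.na(occupation) & is.na(out)
  if (any(bad)) {
    stop_named("unmapped occupation title(s): %s",
               paste(unique(occupation[bad]), collapse = "; "))
  }
  out[is.na(occupation)] <- NA_character_
  unname(out)
}

#' Recoding rules
#'
#' Bundles the vocabularies and predicates used by [recode_all()]:
#' the poverty cutoff, the high-risk education levels, and the occupation
#' activity map. Serialize with [yaml::write_yaml()] if a run needs to
#' archive its rules.
#'
#' @param poverty_cutoff dollar amount (classification bound; brackets with
#'   upper bound at or below it are poverty).
#' @param occupation_map data.frame (occupation, activity).
#' @return object of class `recode_rules`.
#' @export
recode_rules <- function(poverty_cutoff = 20000,
                         occupation_map = default_occupation_map()) {
  structure(list(poverty_cutoff = poverty_cutoff,
                 occupation_map = occupation_map),
            class = "recode_rules")
}

#' Apply all recodes to a cohort table
#'
#' Adds the binary analysis columns used by the indices and models —
#' `risk_poverty`, `risk_education`, `risk_smoking`, `risk_alcohol`,
#' `risk_inactivity`, the activity classes `coa`/`loa` (factors, "High"
#' reference) and modeling factors `poverty_status` ("At or Below"
#' reference), `smoker`, `alcohol` ("No" reference). Raw columns are never
#' mutated; missing values propagate; the operation is idempotent.
#'
#' @param table cohort data.frame with raw columns `income_bracket`,
#'   `education`, `smoked_past_month`, `drinks_per_year`,
#'   `physical_activity`, `occupation_current`, `occupation_longest`.
#' @param rules a [recode_rules()] object.
#' @return the table with recoded columns appended/replaced.
#' @export
recode_all <- function(table, rules = recode_rules()) {
  required <- c("income_bracket", "education", "smoked_past_month",
                "drinks_per_year", "physical_activity",
                "occupation_current", "occupation_longest")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    stop_named("required raw column(s) missing: %s",
               paste(missing_cols, collapse = ", "))
  }
  table$risk_poverty <- recode_poverty(table$income_bracket)
  table$risk_education <- recode_education(table$education)
  table$risk_smoking <- recode_smoking(table$smoked_past_month)
  table$risk_alcohol <- recode_alcohol(table$drinks_per_year)
  table$risk_inactivity <- recode_physical_activity(table$physical_activity)
  coa <- classify_occupation_activity(table$occupation_current,
                                      rules$occupation_map)
  loa <- classify_occupation_activity(table$occupation_longest,
                                      rules$occupation_map)
  cap <- function(x) factor(ifelse(x == "low", "Low", "High"),
                            levels = c("High", "Low"))
  table$coa <- cap(coa)
  table$loa <- cap(loa)
  table$poverty_status <- factor(
    ifelse(is.na(table$risk_poverty), NA,
           ifelse(table$risk_poverty == 1L, "At or Below", "Above")),
    levels = c("At or Below", "Above"))
  table$smoker <- factor(ifelse(is.na(table$risk_smoking), NA,
                                ifelse(table$risk_smoking == 1L, "Yes",
                                       "No")),
                         levels = c("No", "Yes"))
  table$alcohol <- factor(ifelse(is.na(table$risk_alcohol), NA,
                                 ifelse(table$risk_alcohol == 1L, "Yes",
                                        "No")),
                          levels = c("No", "Yes"))
  table
}
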