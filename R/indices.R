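#' Index specifications for the CSI and AL composites
#'
#' Each index sums ten binary risk components. The Chronic Stress
#' Indicator (CSI) combines five socio-behavioral binaries (education
#' below high school, poverty, alcohol use, tobacco use, physical
#' inactivity) with five biomarkers flagged in the top quartile of the
#' study distribution (SBP, DBP, TC, HbA1c, BMI); scores of 5 and above
#' are high-risk. Allostatic Load (AL) uses ten biomarkers — the same
#' five plus TG, CRP and creatinine clearance flagged in the top quartile,
#' and the protective markers HDL and albumin flagged in the bottom
#' quartile; scores of 3 and above are high-risk.
#'
#' Component directions are configurable; the creatinine-clearance
#' direction in particular is ambiguous in practice and defaults to
#' top-quartile risk.
#'
#' @param quartile quantile defining "top 25 percent" cutoffs (0.75).
#' @param cutoff_weighting "unweighted" (default: sample quantiles of the
#'   analyzed records) or "weighted" (survey-weighted quantiles).
#' @param risk_threshold integer score at or above which a record is
#'   high-risk.
#' @return an object of class `index_spec` with fields `name`,
#'   `components` (data.frame: column, kind, direction), `risk_threshold`,
#'   `quartile`, `cutoff_weighting`.
#' @examples
#' csi_spec()$risk_threshold # 5
#' al_spec()$risk_threshold  # 3
#' @name index_spec
NULL

new_index_spec <- function(name, components, risk_threshold, quartile,
                           cutoff_weighting) {
  stopifnot(nrow(components) == 10L)
  if (risk_threshold < 0 || risk_threshold > 10) {
    stop_named("risk_threshold must lie in [0,10]")
  }
  cutoff_weighting <- match.arg(cutoff_weighting,
                                c("unweighted", "weighted"))
  structure(list(name = name, components = components,
                 risk_threshold = as.integer(risk_threshold),
                 quartile = quartile,
                 cutoff_weighting = cutoff_weighting),
            class = "index_spec")
}

#' @rdname index_spec
#' @export
csi_spec <- function(quartile = 0.75, cutoff_weighting = "unweighted",
                     risk_threshold = 5L) {
  components <- data.frame(
    column = c("risk_education", "risk_poverty", "risk_alcohol",
               "risk_smoking", "risk_inactivity",
               "sbp", "dbp", "tc", "hba1c", "bmi"),
    kind = c(rep("binary", 5), rep("quartile", 5)),
    direction = c(rep(NA_character_, 5), rep("high", 5)),
    stringsAsFactors = FALSE)
  new_index_spec("CSI", components, risk_threshold, quartile,
                 cutoff_weighting)
}

#' @rdname index_spec
#' @export
al_spec <- function(quartile = 0.75, cutoff_weighting = "unweighted",
                    risk_threshold = 3L) {
  components <- data.frame(
    column = c("sbp", "dbp", "tc", "hba1c", "bmi",
               "tg", "hdl", "albumin", "clcr", "crp"),
    kind = "quartile",
    direction = c("high", "high", "high", "high", "high",
                  "high", "low", "low", "high", "high"),
    stringsAsFactors = FALSE)
  new_index_spec("AL", components, risk_threshold, quartile,
                 cutoff_weighting)
}

#' @export
print.index_spec <- function(x, ...) {
  cat(sprintf("%s index: 10 components, high-risk at score >= %d (%s %s)\n",
              x$name, x$risk_threshold, x$cutoff_weighting,
              "quartile cutoffs"))
  print(x$components)
  invisible(x)
}

#' Weighted quantile
#'
#' Returns the smallest observed value whose left-inclusive weighted CDF
#' reaches `q` — i.e. the `q`-quantile of the discrete distribution placing
#' mass `w_i / sum(w)` on `x_i`. With integer weights this equals the
#' same-convention empirical quantile of the weight-expanded multiset, and
#' with equal weights it is the type-1 empirical-CDF quantile.
#'
#' @param values numeric vector (NAs dropped with their weights).
#' @param weights positive numeric weights.
#' @param q quantile in (0, 1).
#' @return the weighted quantile (scalar).
#' @examples
#' weighted_quantile(c(1, 2, 3, 4), rep(1, 4), 0.75) # 3
#' weighted_quantile(c(1, 2, 3, 4), c(1, 1, 1, 100), 0.5) # 4
#' @export
weighted_quantile <- function(values, weights = rep(1, length(values)),
                              q = 0.75) {
  if (length(values) != length(weights)) {
    stop_named("values and weights must have equal length")
  }
  keep <- !is.na(values) & !is.na(weights)
  values <- values[keep]
  weights <- weights[keep]
  if (!length(values)) stop_named("no non-missing values for quantile")
  if (any(weights <= 0)) stop_named("weights must be positive")
  if (q <= 0 || q >= 1) stop_named("q must lie in (0,1)")
  o <- order(values)
  cw <- cumsum(weights[o]) / sum(weights)
  values[o][which(cw >= q - 1e-12)[1]]
}

#' Derive quartile cutoffs for an index
#'
#' One cutoff per quartile-type component: the `q` (default 0.75) quantile
#' for "high"-direction markers and the `1 - q` quantile for "low"-
#' direction (protective) markers. Cutoffs are computed on all records
#' non-missing for that marker — before complete-case filtering — either
#' unweighted (default) or survey-weighted per the spec. Provenance
#' (quantile, weighting, n used) is recorded per marker.
#'
#' @param table recoded cohort data.frame.
#' @param spec an [index_spec].
#' @param design optional [svy_design()]; required for weighted cutoffs.
#' @return data.frame of class `cutoff_set`: marker, direction, quantile,
#'   cutoff, weighting, n_used.
#' @export
derive_cutoffs <- function(table, spec, design = NULL) {
  comp <- spec$components[spec$components$kind == "quartile", ]
  if (spec$cutoff_weighting == "weighted" && is.null(design)) {
    stop_named("weighted cutoffs require a design")
  }
  rows <- lapply(seq_len(nrow(comp)), function(i) {
    marker <- comp$column[i]
    if (is.null(table[[marker]])) {
      stop_named("marker column absent from table: %s", marker)
    }
    x <- table[[marker]]
    ok <- !is.na(x)
    if (sum(ok) < 8) {
      stop_named("marker %s has %d non-missing values (need >= 8)",
                 marker, sum(ok))
    }
    qq <- if (comp$direction[i] == "high") spec$quartile else
      1 - spec$quartile
    w <- if (spec$cutoff_weighting == "weighted") design$weight[ok] else
      rep(1, sum(ok))
    data.frame(marker = marker, direction = comp$direction[i],
               quantile = qq,
               cutoff = weighted_quantile(x[ok], w, qq),
               weighting = spec$cutoff_weighting, n_used = sum(ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cutoff_set", class(out))
  out
}

#' Score the ten binary components of an index
#'
#' Binary components are taken as-is from their recoded 0/1 columns;
#' quartile components score 1 when the marker is at or beyond its cutoff
#' (value >= cutoff for "high" direction — "within the top 25 percent"
#' read inclusively — value <= cutoff for "low"). Records missing any
#' component are flagged incomplete rather than erroring.
#'
#' @param table recoded cohort data.frame (one or more records).
#' @param cutoffs a `cutoff_set` from [derive_cutoffs()].
#' @param spec the matching [index_spec].
#' @return list with `components` (n x 10 0/1 matrix, NA where missing)
#'   and `complete` (logical vector).
#' @export
score_components <- function(table, cutoffs, spec) {
  n <- nrow(table)
  comp <- spec$components
  M <- matrix(NA_integer_, n, nrow(comp),
              dimnames = list(NULL, comp$column))
  for (i in seq_len(nrow(comp))) {
    colname <- comp$column[i]
    if (is.null(table[[colname]])) {
      stop_named("component column absent from table: %s", colname)
    }
    x <- table[[colname]]
    if (comp$kind[i] == "binary") {
      if (!all(x %in% c(0L, 1L, NA))) {
        stop_named("binary component %s must be 0/1", colname)
      }
      M[, i] <- as.integer(x)
    } else {
      cut <- cutoffs$cutoff[cutoffs$marker == colname]
      if (!length(cut)) stop_named("no cutoff for marker %s", colname)
      M[, i] <- if (comp$direction[i] == "high") {
        as.integer(x >= cut)
      } else {
        as.integer(x <= cut)
      }
    }
  }
  list(components = M, complete = !apply(is.na(M), 1, any))
}

#' Sum a complete component vector into an index score
#'
#' @param components 0/1 vector or n x 10 matrix of scored components.
#' @return integer score(s) in \[0, 10\]; NA where any component missing.
#' @export
compute_index <- function(components) {
  if (is.matrix(components)) {
    out <- rowSums(components)
    out[apply(is.na(components), 1, any)] <- NA
    return(as.integer(out))
  }
  if (anyNA(components)) return(NA_integer_)
  as.integer(sum(components))
}

#' Classify an index score as low or high risk
#'
#' High iff score >= the index's risk threshold (CSI: 5, AL: 3).
#'
#' @param score integer score(s) in \[0, 10\].
#' @param spec an [index_spec].
#' @return factor with levels c("low", "high"); NA propagates.
#' @export
classify_risk <- function(score, spec) {
  if (any(score < 0 | score > 10, na.rm = TRUE)) {
    stop_named("scores must lie in [0,10]")
  }
  factor(ifelse(score >= spec$risk_threshold, "high", "low"),
         levels = c("low", "high"))
}

#' Build the per-participant index table
#'
#' Derives cutoffs (before complete-case filtering, on all records
#' non-missing per marker), scores all records, sums, classifies, and
#' flags completeness. Only complete records carry a score; the number of
#' complete records — the per-index analysis sample — is reported in a
#' message.
#'
#' @param table recoded cohort data.frame with a `participant_id` column.
#' @param spec an [index_spec].
#' @param design optional [svy_design()] (needed for weighted cutoffs).
#' @return list with `index` (data.frame: participant_id, the ten
#'   component columns prefixed by the index name, score, risk, complete)
#'   and `cutoffs` (the `cutoff_set` used).
#' @export
build_index_table <- function(table, spec, design = NULL) {
  cutoffs <- derive_cutoffs(table, spec, design)
  sc <- score_components(table, cutoffs, spec)
  score <- compute_index(sc$components)
  risk <- classify_risk(score, spec)
  comp_df <- as.data.frame(sc$components)
  names(comp_df) <- paste0(tolower(spec$name), "_c_", names(comp_df))
  out <- data.frame(participant_id = table$participant_id,
                    comp_df,
                    score = score, risk = risk, complete = sc$complete,
                    stringsAsFactors = FALSE)
  names(out)[names(out) == "score"] <- paste0(tolower(spec$name), "_score")
  names(out)[names(out) == "risk"] <- paste0(tolower(spec$name), "_risk")
  names(out)[names(out) == "complete"] <-
    paste0(tolower(spec$name), "_complete")
  message(sprintf("%s: %d of %d records complete and scored",
                  spec$name, sum(sc$complete), nrow(table)))
  list(index = out, cutoffs = cutoffs)
}
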