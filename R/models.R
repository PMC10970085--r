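#' Survey-weighted binary logistic regression
#'
#' Maximizes the weighted pseudo-log-likelihood
#' `sum w_i [y_i log mu_i + (1 - y_i) log(1 - mu_i)]` by iteratively
#' reweighted least squares (Newton scoring, convergence when the maximum
#' absolute score falls below `tol`), and estimates the coefficient
#' covariance by the Taylor-linearized sandwich: `A^-1 B A^-1` with `A`
#' the weighted information and `B` the stratified between-PSU covariance
#' of the per-record score contributions. Confidence intervals and
#' p-values use a t reference on the design degrees of freedom
#' (PSUs - strata), so the fitted odds ratios and intervals are invariant
#' to rescaling all weights by a positive constant.
#'
#' The reported AIC is the normalized-weight pseudo-AIC: the
#' pseudo-log-likelihood is evaluated with weights rescaled to sum to the
#' sample size, then `AIC = -2 ll + 2 k`. A design-weighted
#' pseudo-likelihood has no unique AIC, so this value is comparable
#' across models fitted here but not across software.
#'
#' @param formula model formula, e.g. `risk ~ age + sex + smoker`; the
#'   outcome may be 0/1 numeric, logical, or a two-level factor (second
#'   level = event).
#' @param data data.frame holding outcome and predictors; rows with
#'   missing values in any model variable are dropped along with their
#'   design rows.
#' @param design a [svy_design()] aligned with `data`.
#' @param tol convergence tolerance on the maximum absolute score
#'   component (weights normalized to mean 1 internally).
#' @param max_iter maximum IRLS iterations.
#' @param lonely_psu see [weighted_mean_se()].
#' @return object of class `svy_logistic`: coefficients, se, or, ci_low,
#'   ci_high, p per term, aic, df_design, n, convergence record
#'   (iterations, score norm), and the terms/levels metadata.
#' @examples
#' g <- generate_cohort(generator_config(n_strata = 8, records_per_psu = 40))
#' fit <- fit_survey_logistic(latent_high ~ age + sex, g$cohort, g$design)
#' odds_ratio_table(fit)
#' @export
fit_survey_logistic <- function(formula, data, design, tol = 1e-8,
                                max_iter = 50L, lonely_psu = "fail") {
  stopifnot(inherits(design, "svy_design"))
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  keep <- stats::complete.cases(mf)
  mf <- mf[keep, , drop = FALSE]
  d <- design_subset(design, keep)
  y <- stats::model.response(mf)
  if (is.factor(y)) {
    if (nlevels(droplevels(y)) != 2) stop_named("outcome must be binary")
    y <- as.numeric(y == levels(droplevels(y))[2])
  } else if (is.logical(y)) {
    y <- as.numeric(y)
  }
  if (!all(y %in% c(0, 1))) stop_named("outcome must be binary (0/1)")
  if (length(unique(y)) < 2) stop_named("outcome has a single level")
  X <- stats::model.matrix(stats::terms(mf), mf)
  constant <- apply(X[, colnames(X) != "(Intercept)", drop = FALSE], 2,
                    function(col) length(unique(col)) == 1)
  if (any(constant)) {
    stop_named("constant predictor column(s): %s",
               paste(names(constant)[constant], collapse = ", "))
  }
  k <- ncol(X)
  if (length(y) <= k) stop_named("n must exceed the parameter count")
  # scale-free weights: normalize to mean 1 (all reported quantities are
  # invariant to the weight scale)
  w <- d$weight / mean(d$weight)

  beta <- numeric(k)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, w * (y - mu)))
    trace <- c(trace, max(abs(score)))
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    A <- crossprod(X, X * (w * mu * (1 - mu)))
    step <- tryCatch(solve(A, score), error = function(e) NULL)
    if (is.null(step)) {
      stop_named("singular information matrix at iteration %d", it)
    }
    beta <- beta + step
    if (max(abs(beta)) > 30) {
      worst <- colnames(X)[which.max(abs(beta))]
      stop_named(paste0("apparent separation: coefficient for '%s' is ",
                        "diverging (|beta| > 30)"), worst)
    }
  }
  if (!converged) {
    stop_named("IRLS did not converge in %d iterations (score trace: %s)",
               max_iter, paste(signif(utils::tail(trace, 5), 3),
                               collapse = ", "))
  }

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  A <- crossprod(X, X * (w * mu * (1 - mu)))
  U <- X * (w * (y - mu))          # score contributions
  B <- psu_cov(U, d, lonely_psu = lonely_psu)
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  se <- sqrt(diag(V))
  df <- degf(d)
  tcrit <- stats::qt(0.975, df)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)

  wn <- w * length(y) / sum(w)
  ll <- sum(wn * (y * log(mu) + (1 - y) * log1p(-mu)))
  aic <- -2 * ll + 2 * k

  structure(list(
    terms = colnames(X),
    coefficients = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    vcov = V,
    or = stats::setNames(exp(beta), colnames(X)),
    ci_low = stats::setNames(exp(beta - tcrit * se), colnames(X)),
    ci_high = stats::setNames(exp(beta + tcrit * se), colnames(X)),
    p = stats::setNames(pval, colnames(X)),
    aic = aic, df_design = df, n = length(y),
    convergence = list(iterations = it, score_norm = max(abs(trace[it])),
                       trace = trace),
    formula = formula,
    xlevels = stats::.getXlevels(stats::terms(mf), mf)),
    class = "svy_logistic")
}

#' @export
print.svy_logistic <- function(x, ...) {
  cat(sprintf(
    "Survey-weighted logistic fit: n = %d, design df = %d, AIC = %.2f\n",
    x$n, x$df_design, x$aic))
  print(odds_ratio_table(x), row.names = FALSE)
  invisible(x)
}

#' Odds-ratio table for a survey logistic fit
#'
#' One row per non-reference term with the odds ratio, 95% confidence
#' bounds and p-value; factor reference levels appear as "Reference"
#' rows. The model AIC is attached as an attribute (printed as a footer).
#'
#' @param fit a converged [fit_survey_logistic()] result.
#' @return data.frame: term, or, ci_low, ci_high, p (NA on reference
#'   rows), with attribute `aic`.
#' @export
odds_ratio_table <- function(fit) {
  stopifnot(inherits(fit, "svy_logistic"))
  rows <- list()
  nonref <- setdiff(fit$terms, "(Intercept)")
  # walk terms in model order, inserting each factor's reference row
  # before its first coefficient
  ref_done <- character(0)
  or_row <- function(cc) data.frame(
    term = cc, or = unname(fit$or[fit$terms == cc]),
    ci_low = unname(fit$ci_low[fit$terms == cc]),
    ci_high = unname(fit$ci_high[fit$terms == cc]),
    p = unname(fit$p[cc]), reference = FALSE, stringsAsFactors = FALSE)
  for (cc in nonref) {
    v <- NULL
    for (cand in names(fit$xlevels)) {
      if (cc %in% paste0(cand, fit$xlevels[[cand]][-1])) v <- cand
    }
    if (!is.null(v) && !v %in% ref_done) {
      rows[[length(rows) + 1]] <- data.frame(
        term = paste(v, fit$xlevels[[v]][1]), or = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
        reference = TRUE, stringsAsFactors = FALSE)
      ref_done <- c(ref_done, v)
    }
    rows[[length(rows) + 1]] <- or_row(cc)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "aic") <- fit$aic
  out
}

#' Compare the AL and CSI indices across candidate variables
#'
#' For each candidate variable and each index risk class, computes the
#' design-based association test on that index's complete-case sample —
#' Rao-Scott chi-square for categorical candidates, design-based rank-sum
#' for continuous ones — or, for candidates named in a supplied model
#' fit, takes the term's model p-value. A cell is marked significant when
#' p < alpha. Candidates unavailable (all-missing or constant) in one
#' index's sample are marked not evaluable rather than dropped.
#'
#' @param table cohort data.frame already joined with both index results
#'   (columns `al_risk`, `csi_risk` and the candidates).
#' @param design a [svy_design()] aligned with `table`.
#' @param candidates character vector of candidate column names.
#' @param fits optional named list `list(al = fit, csi = fit)` of
#'   [fit_survey_logistic()] results; a candidate matching a model term
#'   or factor variable name takes its p from the fit instead.
#' @param alpha significance level (default 0.05).
#' @param lonely_psu see [weighted_mean_se()].
#' @return data.frame of class `comparison_matrix`: candidate, index,
#'   significant, p, method, n.
#' @export
compare_indices <- function(table, design, candidates, fits = NULL,
                            alpha = 0.05, lonely_psu = "fail") {
  if (alpha <= 0 || alpha >= 1) stop_named("alpha must lie in (0,1)")
  for (col in c("al_risk", "csi_risk")) {
    if (is.null(table[[col]])) {
      stop_named("index risk column absent: %s", col)
    }
  }
  cells <- list()
  for (index in c("al", "csi")) {
    risk <- table[[paste0(index, "_risk")]]
    fit <- fits[[index]]
    for (cand in candidates) {
      x <- table[[cand]]
      if (is.null(x)) stop_named("candidate column absent: %s", cand)
      p <- NA_real_
      method <- NA_character_
      n <- sum(!is.na(x) & !is.na(risk))
      status <- "evaluated"
      fit_p <- fit_term_p(fit, cand)
      if (!is.null(fit_p)) {
        p <- fit_p
        method <- "logistic model term"
      } else if (n < 8 || length(unique(x[!is.na(x) & !is.na(risk)])) < 2) {
        status <- "not evaluable"
      } else if (is.numeric(x) && length(unique(stats::na.omit(x))) > 2) {
        keep <- !is.na(x) & !is.na(risk)
        p <- survey_ranksum(x[keep], risk[keep],
                            design_subset(design, keep), lonely_psu)$p
        method <- "design-based rank-sum"
      } else {
        keep <- !is.na(x) & !is.na(risk)
        p <- tryCatch(
          rao_scott_chisq(x[keep], risk[keep],
                          design_subset(design, keep), lonely_psu)$p,
          error = function(e) NA_real_)
        method <- "Rao-Scott chi-square"
        if (is.na(p)) status <- "not evaluable"
      }
      cells[[length(cells) + 1]] <- data.frame(
        candidate = cand, index = toupper(index),
        significant = if (status == "evaluated") p < alpha else NA,
        p = p, method = method, n = n, status = status,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, cells)
  attr(out, "alpha") <- alpha
  class(out) <- c("comparison_matrix", class(out))
  out
}

# p-value of the model term(s) matching a candidate name, or NULL
fit_term_p <- function(fit, cand) {
  if (is.null(fit)) return(NULL)
  if (cand %in% names(fit$p)) return(unname(fit$p[cand]))
  if (cand %in% names(fit$xlevels)) {
    cols <- paste0(cand, fit$xlevels[[cand]][-1])
    cols <- cols[cols %in% names(fit$p)]
    if (length(cols)) return(min(fit$p[cols]))
  }
  NULL
}
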