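#' Cramer's V association statistic
#'
#' Classical (uncorrected) Cramer's V:
#' `V = sqrt(chi2 / (n * min(r - 1, c - 1)))` with the Pearson chi-square
#' on the unweighted contingency table. Symmetric in its arguments and
#' invariant to level relabeling.
#'
#' @param x,y categorical vectors (>= 2 observed levels each, pairwise
#'   n >= 4).
#' @return V in \[0, 1\].
#' @examples
#' cramers_v(rep(c("a", "b"), 10), rep(c("u", "v"), 10)) # 1
#' @export
cramers_v <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  fx <- droplevels(factor(x[keep]))
  fy <- droplevels(factor(y[keep]))
  n <- sum(keep)
  if (n < 4) stop_named("need at least 4 complete pairs")
  if (nlevels(fx) < 2 || nlevels(fy) < 2) {
    stop_named("both variables must have >= 2 observed levels")
  }
  tab <- table(fx, fy)
  chi2 <- suppressWarnings(
    stats::chisq.test(tab, correct = FALSE)$statistic)
  unname(sqrt(chi2 / (n * min(nrow(tab) - 1, ncol(tab) - 1))))
}

#' Pairwise association matrix (Cramer's V or Pearson correlation)
#'
#' For `method = "pearson"`, pairwise-complete Pearson correlations over
#' the named continuous columns (binary risk classes may be included as
#' 0/1, giving point-biserial correlations); optionally survey-weighted.
#' For `method = "cramers_v"`, the unweighted [cramers_v()] per pair of
#' categorical columns.
#'
#' @param table data.frame.
#' @param variables character vector of column names.
#' @param method "pearson" or "cramers_v".
#' @param weights optional positive weights for weighted Pearson
#'   correlations (ignored for Cramer's V, which is defined unweighted
#'   here).
#' @return object of class `association_matrix`: list with `matrix`
#'   (symmetric, unit diagonal), `n` (pairwise complete counts), `method`.
#' @export
correlation_matrix <- function(table, variables,
                               method = c("pearson", "cramers_v"),
                               weights = NULL) {
  method <- match.arg(method)
  absent <- setdiff(variables, names(table))
  if (length(absent)) {
    stop_named("variable(s) absent from table: %s",
               paste(absent, collapse = ", "))
  }
  p <- length(variables)
  M <- diag(1, p)
  N <- matrix(NA_integer_, p, p)
  dimnames(M) <- dimnames(N) <- list(variables, variables)
  diag(N) <- vapply(variables,
                    function(v) sum(!is.na(table[[v]])), integer(1))
  for (i in seq_len(p)) {
    for (j in seq_len(i - 1)) {
      x <- table[[variables[i]]]
      y <- table[[variables[j]]]
      keep <- !is.na(x) & !is.na(y)
      nij <- sum(keep)
      if (method == "pearson") {
        if (nij < 3) stop_named("fewer than 3 complete pairs for %s ~ %s",
                                variables[i], variables[j])
        r <- if (is.null(weights)) {
          stats::cor(x[keep], y[keep])
        } else {
          w <- weights[keep]
          mx <- sum(w * x[keep]) / sum(w)
          my <- sum(w * y[keep]) / sum(w)
          sum(w * (x[keep] - mx) * (y[keep] - my)) /
            sqrt(sum(w * (x[keep] - mx)^2) * sum(w * (y[keep] - my)^2))
        }
      } else {
        r <- cramers_v(x, y)
      }
      M[i, j] <- M[j, i] <- r
      N[i, j] <- N[j, i] <- nij
    }
  }
  structure(list(matrix = M, n = N, method = method),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("%s association matrix (%d variables)\n",
              x$method, ncol(x$matrix)))
  print(round(x$matrix, digits))
  invisible(x)
}

#' Variance inflation factors
#'
#' For each predictor j, `VIF_j = 1 / (1 - R2_j)` from the least-squares
#' regression of predictor j on all the others. Categorical predictors are
#' expanded to indicator columns and reported per original variable as the
#' generalized VIF (determinant ratio of correlation submatrices), with
#' the df-adjusted value `GVIF^(1/(2 df))` alongside. Exact collinearity
#' is reported as an infinite VIF on the offending variables, not as an
#' error.
#'
#' @param table data.frame.
#' @param predictors character vector of column names (numeric or factor).
#' @return data.frame: variable, vif (GVIF for categorical), df,
#'   vif_adjusted (`GVIF^(1/(2 df))`, equal to `sqrt(vif)` for df = 1).
#' @export
vif <- function(table, predictors) {
  absent <- setdiff(predictors, names(table))
  if (length(absent)) {
    stop_named("predictor(s) absent from table: %s",
               paste(absent, collapse = ", "))
  }
  dat <- table[predictors]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  mm <- stats::model.matrix(~ ., dat)[, -1, drop = FALSE]
  if (nrow(mm) <= ncol(mm) + 1) {
    stop_named("need n > number of expanded predictors + 1")
  }
  assign_idx <- attr(stats::model.matrix(~ ., dat), "assign")[-1]
  R <- suppressWarnings(stats::cor(mm))
  detR <- det(R)
  out <- lapply(seq_along(predictors), function(j) {
    cols <- which(assign_idx == j)
    df_j <- length(cols)
    if (abs(detR) < 1e-12) {
      # exact collinearity somewhere: flag variables whose own R2 is 1
      others <- mm[, -cols, drop = FALSE]
      r2 <- if (ncol(others)) {
        # a perfect fit here is the collinearity being probed for
        suppressWarnings(
          summary(stats::lm(mm[, cols[1]] ~ others))$r.squared)
      } else 0
      v <- if (r2 > 1 - 1e-10) Inf else {
        # fall back to the determinant formula on the non-degenerate part
        tryCatch(det(R[cols, cols, drop = FALSE]) *
                   det(R[-cols, -cols, drop = FALSE]) / detR,
                 error = function(e) Inf)
      }
    } else {
      v <- det(R[cols, cols, drop = FALSE]) *
        det(R[-cols, -cols, drop = FALSE]) / detR
    }
    if (is.finite(v) && v < 1) v <- max(v, 1)  # guard tiny negative slack
    data.frame(variable = predictors[j], vif = v, df = df_j,
               vif_adjusted = v^(1 / (2 * df_j)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
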