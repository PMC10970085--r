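#' Survey-weighted mean with Taylor-linearized standard error
#'
#' Estimates the population mean as the ratio `sum(w x) / sum(w)` and its
#' variance by Taylor linearization with the stratified between-PSU
#' estimator: each record contributes `u_i = w_i (x_i - xbar) / W`, and
#' the variance of the estimated total of `u` is accumulated over PSU
#' totals within strata. With equal weights and every record its own PSU
#' in one stratum this reduces to the classical simple-random-sampling
#' formula `sum((x - xbar)^2) * n / ((n-1) n^2)`.
#'
#' @param values numeric vector; records with missing values are dropped
#'   pairwise (with their design rows).
#' @param design a [svy_design()].
#' @param lonely_psu "fail" (default) errors on single-PSU strata;
#'   "certainty" lets them contribute zero variance (with a warning).
#' @return object of class `design_estimate`: estimate, se, n_unweighted,
#'   n_weighted, df_design.
#' @examples
#' d <- svy_design(rep(1, 6), 1:6, rep(1, 6))
#' weighted_mean_se(c(3, 1, 4, 1, 5, 9), d)
#' @export
weighted_mean_se <- function(values, design, lonely_psu = "fail") {
  stopifnot(inherits(design, "svy_design"))
  if (length(values) != design$n) {
    stop_named("values length must match design")
  }
  keep <- !is.na(values)
  if (!sum(keep)) stop_named("no non-missing values")
  d <- design_subset(design, keep)
  x <- values[keep]
  if (nlevels(d$psu) < 2) stop_named("need at least 2 PSUs for a variance")
  W <- sum(d$weight)
  est <- sum(d$weight * x) / W
  u <- d$weight * (x - est) / W
  v <- psu_cov(matrix(u, ncol = 1), d, lonely_psu = lonely_psu)[1, 1]
  structure(list(estimate = est, se = sqrt(v),
                 n_unweighted = length(x), n_weighted = W,
                 df_design = degf(d)),
            class = "design_estimate")
}

#' @export
print.design_estimate <- function(x, ...) {
  cat(sprintf("%.6g (SE %.6g), n = %d, weighted N = %.6g, design df = %d\n",
              x$estimate, x$se, x$n_unweighted, x$n_weighted, x$df_design))
  invisible(x)
}

#' Survey-weighted proportions with linearized standard errors
#'
#' One [weighted_mean_se()] per observed level (indicator-variable means);
#' proportions sum to 1 over non-missing levels.
#'
#' @param values factor/character vector.
#' @param design a [svy_design()].
#' @param lonely_psu see [weighted_mean_se()].
#' @return data.frame: level, proportion, se, n_unweighted, n_weighted.
#' @export
weighted_proportions <- function(values, design, lonely_psu = "fail") {
  f <- droplevels(factor(values))
  if (!nlevels(f)) stop_named("no non-missing levels")
  rows <- lapply(levels(f), function(lv) {
    est <- weighted_mean_se(as.numeric(f == lv), design,
                            lonely_psu = lonely_psu)
    data.frame(level = lv, proportion = est$estimate, se = est$se,
               n_unweighted = sum(f == lv, na.rm = TRUE),
               n_weighted = est$n_weighted * est$estimate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rao-Scott second-order corrected chi-square test
#'
#' Tests independence of two categorical variables under a complex
#' design. The Pearson statistic is computed on survey-weighted cell
#' proportions scaled to the unweighted sample size; its null distribution
#' is corrected with the estimated generalized design-effect matrix
#' (linearized covariance of the cell-proportion estimators against the
#' multinomial covariance, projected onto the interaction contrast space).
#' The second-order (Satterthwaite) version reports
#' `F = X2 / tr(Delta)` on `(d0, d0 * df_design)` degrees of freedom with
#' `d0 = tr(Delta)^2 / tr(Delta^2)`, the standard F reference for
#' design-corrected contingency tests.
#'
#' @param row_var,col_var categorical vectors (>= 2 observed levels each);
#'   records missing either variable are dropped pairwise.
#' @param design a [svy_design()].
#' @param lonely_psu see [weighted_mean_se()].
#' @return object of class `svy_test`: statistic (F), df (numerator),
#'   ddf (denominator), p, method.
#' @export
rao_scott_chisq <- function(row_var, col_var, design,
                            lonely_psu = "fail") {
  stopifnot(inherits(design, "svy_design"))
  keep <- !is.na(row_var) & !is.na(col_var)
  r <- droplevels(factor(row_var[keep]))
  c_ <- droplevels(factor(col_var[keep]))
  if (nlevels(r) < 2 || nlevels(c_) < 2) {
    stop_named("both variables must have >= 2 observed levels")
  }
  d <- design_subset(design, keep)
  n <- length(r)
  nr <- nlevels(r)
  nc <- nlevels(c_)

  cell <- interaction(r, c_, lex.order = TRUE)  # cells in row-major order
  W <- sum(d$weight)
  phat <- as.vector(tapply(d$weight, cell, sum, default = 0)) / W
  # linearized covariance of the cell proportion vector
  Ind <- outer(cell, levels(cell), `==`) * 1
  U <- d$weight * sweep(Ind, 2, phat) / W
  V <- psu_cov(U, d, lonely_psu = lonely_psu)

  P <- matrix(phat, nr, nc, byrow = TRUE)
  p0 <- outer(rowSums(P), colSums(P))
  X2 <- n * sum((P - p0)^2 / p0)

  # generalized design-effect matrix on the interaction contrast space
  mf <- expand.grid(col = factor(seq_len(nc)), row = factor(seq_len(nr)))
  X1 <- stats::model.matrix(~ row + col, mf)
  X12 <- stats::model.matrix(~ row * col, mf)
  Cmat <- qr.resid(qr(X1), X12[, -seq_len(ncol(X1)), drop = FALSE])
  iD <- ifelse(phat == 0, 0, 1 / phat)
  Cmat <- Cmat * iD
  Vsrs <- (diag(phat) - tcrossprod(phat)) / n
  denom <- t(Cmat) %*% Vsrs %*% Cmat
  numr <- t(Cmat) %*% V %*% Cmat
  Delta <- solve(denom, numr)
  trD <- sum(diag(Delta))
  trD2 <- sum(Delta * t(Delta))
  d0 <- trD^2 / trD2

  Fstat <- X2 / trD
  ddf <- d0 * degf(d)
  p <- stats::pf(Fstat, d0, ddf, lower.tail = FALSE)
  structure(list(statistic = Fstat, df = d0, ddf = ddf, p = p,
                 n = n,
                 method = "Rao-Scott second-order chi-square (F)"),
            class = "svy_test")
}

#' @export
print.svy_test <- function(x, ...) {
  cat(sprintf("%s\nstatistic = %.4g, df = %.3g%s, p = %.4g (n = %d)\n",
              x$method, x$statistic, x$df,
              if (!is.null(x$ddf)) sprintf(", ddf = %.3g", x$ddf) else "",
              x$p, x$n))
  invisible(x)
}

#' Design-based Wilcoxon rank-sum test for complex samples
#'
#' Each value is replaced by its estimated population rank — the weighted
#' mid-CDF score `(F_w(x-) + F_w(x)) / 2` scaled to \[0, 1\] by the total
#' weight — and equality of the two groups' population means of that rank
#' score is tested with a design-based Wald statistic (difference of
#' domain ratio means over its linearized SE), referred to a t
#' distribution on the design degrees of freedom.
#'
#' @param values numeric vector.
#' @param group two-level grouping vector.
#' @param design a [svy_design()].
#' @param lonely_psu see [weighted_mean_se()].
#' @return object of class `svy_test` with the t statistic, df, p, and the
#'   estimated difference in mean rank score.
#' @export
survey_ranksum <- function(values, group, design, lonely_psu = "fail") {
  stopifnot(inherits(design, "svy_design"))
  keep <- !is.na(values) & !is.na(group)
  g <- droplevels(factor(group[keep]))
  if (nlevels(g) != 2) stop_named("group must have exactly 2 observed levels")
  x <- values[keep]
  d <- design_subset(design, keep)
  w <- d$weight
  W <- sum(w)

  # weighted mid-CDF rank score in [0,1]
  o <- order(x)
  xo <- x[o]
  wo <- w[o]
  # per unique value: (weight below + half weight equal) / W
  grp <- cumsum(!duplicated(xo))
  w_eq <- as.vector(rowsum(wo, grp))
  w_below <- cumsum(c(0, w_eq[-length(w_eq)]))
  score_u <- (w_below + w_eq / 2) / W
  rscore <- numeric(length(x))
  rscore[o] <- score_u[grp]

  i1 <- g == levels(g)[2]
  m <- vapply(list(!i1, i1),
              function(idx) sum(w[idx] * rscore[idx]) / sum(w[idx]),
              numeric(1))
  diffm <- m[2] - m[1]
  # joint linearization of the two domain means
  U <- cbind(w * (!i1) * (rscore - m[1]) / sum(w[!i1]),
             w * i1 * (rscore - m[2]) / sum(w[i1]))
  V <- psu_cov(U, d, lonely_psu = lonely_psu)
  se <- sqrt(V[1, 1] + V[2, 2] - 2 * V[1, 2])
  df <- degf(d)
  tstat <- diffm / se
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(statistic = tstat, df = df, p = p, estimate = diffm,
                 n = length(x),
                 method = "Design-based Wilcoxon rank-sum (t)"),
            class = "svy_test")
}

#' Grouped weighted summary table
#'
#' The machine-readable twin of a grouped descriptive table: for each
#' requested variable, survey-weighted overall and per-group estimates
#' with linearized SEs (continuous variables) or weighted proportions
#' (categorical variables, with each level's share across the two groups),
#' plus the appropriate design-based p-value — rank-sum for continuous,
#' Rao-Scott chi-square for categorical. Missing values are dropped
#' pairwise per variable; each row reports its unweighted n.
#'
#' @param table data.frame of analysis columns.
#' @param group two-level risk-class vector (aligned with `table` rows).
#' @param variables character vector of column names to summarize.
#' @param design a [svy_design()].
#' @param lonely_psu see [weighted_mean_se()].
#' @return data.frame: variable, level (NA for continuous), type, overall,
#'   overall_se, per-group estimate/se columns, p, n.
#' @export
grouped_summary <- function(table, group, variables, design,
                            lonely_psu = "fail") {
  g <- droplevels(factor(group))
  if (nlevels(g) != 2) stop_named("group must have exactly 2 levels")
  absent <- setdiff(variables, names(table))
  if (length(absent)) {
    stop_named("variable(s) absent from table: %s",
               paste(absent, collapse = ", "))
  }
  gl <- levels(g)
  rows <- list()
  for (v in variables) {
    x <- table[[v]]
    if (is.numeric(x)) {
      keep <- !is.na(x) & !is.na(g)
      ov <- weighted_mean_se(x[keep], design_subset(design, keep),
                             lonely_psu)
      per <- lapply(gl, function(l) {
        idx <- keep & g == l & !is.na(g)
        weighted_mean_se(x[idx], design_subset(design, idx), lonely_psu)
      })
      p <- survey_ranksum(x[keep], g[keep], design_subset(design, keep),
                          lonely_psu)$p
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = NA_character_, type = "continuous",
        overall = ov$estimate, overall_se = ov$se,
        g1 = per[[1]]$estimate, g1_se = per[[1]]$se,
        g2 = per[[2]]$estimate, g2_se = per[[2]]$se,
        p = p, n = sum(keep), stringsAsFactors = FALSE)
    } else {
      keep <- !is.na(x) & !is.na(g)
      f <- droplevels(factor(x[keep]))
      dsub <- design_subset(design, keep)
      ov <- weighted_proportions(f, dsub, lonely_psu)
      p <- rao_scott_chisq(f, g[keep], dsub, lonely_psu)$p
      for (lv in levels(f)) {
        # share of this level's weighted mass falling in each group
        in_lv <- f == lv
        wlv <- dsub$weight[in_lv]
        shares <- vapply(gl, function(l) {
          sum(wlv[g[keep][in_lv] == l]) / sum(wlv)
        }, numeric(1))
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = lv, type = "categorical",
          overall = ov$proportion[ov$level == lv],
          overall_se = ov$se[ov$level == lv],
          g1 = shares[1], g1_se = NA_real_,
          g2 = shares[2], g2_se = NA_real_,
          p = p, n = sum(in_lv), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "g1"] <- gl[1]
  names(out)[names(out) == "g1_se"] <- paste0(gl[1], "_se")
  names(out)[names(out) == "g2"] <- gl[2]
  names(out)[names(out) == "g2_se"] <- paste0(gl[2], "_se")
  out
}
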