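#' Maximum-likelihood exploratory factor analysis of index components
#'
#' Fits a k-factor ML solution on the Pearson correlation matrix of the
#' supplied component matrix (0/1 scored components by default in this
#' package's pipeline; raw continuous markers are equally accepted).
#' Reports unrotated loadings, per-factor SS loadings (column sums of
#' squared loadings), cumulative variance `cumsum(ss)/p`, uniquenesses,
#' and the Bartlett-corrected chi-square test of the hypothesis that k
#' factors suffice:
#' `chisq = (n - 1 - (2p + 5)/6 - 2k/3) * discrepancy`,
#' `df = ((p - k)^2 - (p + k)) / 2`.
#' `k = 0` is admitted and gives Bartlett's test of sphericity (all
#' variables uncorrelated), the natural "no factors needed" null.
#'
#' SS loadings and cumulative variance are invariant under orthogonal
#' rotation, so no rotation is applied for reporting. A Heywood case
#' (uniqueness at the lower bound) is flagged in the fit record, not an
#' error.
#'
#' @param x n x p numeric matrix/data.frame of components, or a p x p
#'   correlation matrix if `n_obs` is given.
#' @param n_factors number of factors k (0 allowed).
#' @param n_obs number of observations when `x` is a correlation matrix.
#' @param nstart random restarts passed to the optimizer (guards against
#'   local optima).
#' @param seed RNG seed for the random restarts (fixed seed -> identical
#'   fit).
#' @return object of class `efa_fit`: n_factors, loadings, ss_loadings,
#'   cumulative_variance, uniquenesses, heywood, statistic, df, p, n_obs.
#' @examples
#' g <- generate_cohort(generator_config(n_strata = 6, records_per_psu = 60))
#' fit_efa(g$cohort[, c("sbp", "dbp", "tc", "hdl", "tg")], 1)
#' @export
fit_efa <- function(x, n_factors, n_obs = NULL, nstart = 10L, seed = 1L) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(n_obs)) {
    n_obs <- nrow(x)
    R <- stats::cor(x, use = "pairwise.complete.obs")
  } else {
    R <- x
  }
  p <- ncol(R)
  if (n_obs <= p) stop_named("need more observations than variables")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop_named(
      "correlation matrix is not positive definite (smallest eigenvalue %.3g)",
      min(ev))
  }
  k <- as.integer(n_factors)
  if (k < 0) stop_named("n_factors must be >= 0")
  if (k > 0 && (p - k)^2 < p + k) {
    stop_named("n_factors = %d inadmissible for p = %d: need (p-k)^2 >= p+k",
               k, p)
  }

  if (k == 0) {
    # Bartlett's sphericity test: discrepancy -log|R| at Psi = I
    stat <- (n_obs - 1 - (2 * p + 5) / 6) * (-determinant(R)$modulus[1])
    df <- p * (p - 1) / 2
    fit <- list(n_factors = 0L,
                loadings = matrix(numeric(0), p, 0,
                                  dimnames = list(colnames(R), NULL)),
                ss_loadings = numeric(0),
                cumulative_variance = numeric(0),
                uniquenesses = stats::setNames(rep(1, p), colnames(R)),
                heywood = FALSE,
                statistic = as.numeric(stat), df = df,
                p = stats::pchisq(stat, df, lower.tail = FALSE),
                n_obs = n_obs)
    class(fit) <- "efa_fit"
    return(fit)
  }

  set.seed(seed)
  fa <- stats::factanal(covmat = R, factors = k, n.obs = n_obs,
                        rotation = "none",
                        control = list(nstart = as.integer(nstart)))
  L <- unclass(fa$loadings)
  ss <- colSums(L^2)
  o <- order(ss, decreasing = TRUE)
  L <- L[, o, drop = FALSE]
  ss <- ss[o]
  colnames(L) <- paste0("F", seq_len(k))
  names(ss) <- colnames(L)
  df <- ((p - k)^2 - (p + k)) / 2
  heywood <- any(fa$uniquenesses <= 0.005 + 1e-9)
  # enforce the communality identity exactly: uniqueness = 1 - sum(l^2)
  # (the optimizer's uniquenesses can drift from it by its tolerance)
  uniq <- stats::setNames(pmax(1 - rowSums(L^2), 0), rownames(L))
  fit <- list(n_factors = k,
              loadings = L,
              ss_loadings = ss,
              cumulative_variance = cumsum(ss) / p,
              uniquenesses = uniq,
              heywood = heywood,
              statistic = if (df > 0) unname(fa$STATISTIC) else NA_real_,
              df = df,
              p = if (df > 0) unname(fa$PVAL) else NA_real_,
              n_obs = n_obs)
  class(fit) <- "efa_fit"
  fit
}

#' @export
print.efa_fit <- function(x, ...) {
  cat(sprintf("ML factor analysis: %d factor(s), n = %d\n",
              x$n_factors, x$n_obs))
  if (x$n_factors > 0) {
    cat("SS loadings:        ",
        paste(sprintf("%.3f", x$ss_loadings), collapse = "  "), "\n")
    cat("Cumulative variance:",
        paste(sprintf("%.3f", x$cumulative_variance), collapse = "  "),
        "\n")
  }
  if (!is.na(x$statistic)) {
    cat(sprintf("chi-square = %.3f on %g df, p = %.4g%s\n",
                x$statistic, x$df, x$p,
                if (isTRUE(x$heywood)) " [Heywood case]" else ""))
  }
  invisible(x)
}

#' Scan over the number of factors
#'
#' One ML fit per k = 1..max_factors (inadmissible k are truncated with a
#' warning), summarized as a factor-number table: the last factor's SS
#' loadings and the cumulative variance at each k, with a significance
#' star where the k-factor chi-square test rejects at `alpha` (more
#' factors needed).
#'
#' @inheritParams fit_efa
#' @param max_factors largest k to fit.
#' @param alpha star threshold for the chi-square p-value.
#' @return list with `fits` (list of `efa_fit`) and `summary`
#'   (data.frame: n_factors, ss_loading, cumulative_variance, statistic,
#'   df, p, reject).
#' @export
factor_number_scan <- function(x, max_factors, n_obs = NULL,
                               nstart = 10L, seed = 1L, alpha = 0.05) {
  if (is.data.frame(x)) x <- as.matrix(x)
  p <- if (is.null(n_obs)) ncol(x) else ncol(x)
  admissible <- which(vapply(seq_len(max_factors),
                             function(k) (p - k)^2 >= p + k, logical(1)))
  if (length(admissible) < max_factors) {
    warning(sprintf("truncating scan at k = %d (df condition)",
                    max(admissible)), call. = FALSE)
  }
  fits <- lapply(admissible, function(k) {
    fit_efa(x, k, n_obs = n_obs, nstart = nstart,
            seed = derive_seed(seed, paste0("efa", k)))
  })
  summary <- do.call(rbind, lapply(fits, function(f) {
    k <- f$n_factors
    data.frame(n_factors = k,
               ss_loading = unname(f$ss_loadings[k]),
               cumulative_variance = unname(f$cumulative_variance[k]),
               statistic = f$statistic, df = f$df, p = f$p,
               reject = !is.na(f$p) & f$p < alpha,
               stringsAsFactors = FALSE)
  }))
  list(fits = fits, summary = summary)
}
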