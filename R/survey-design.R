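#' Complex survey design descriptor
#'
#' Bundles the per-record design information — stratum id, primary sampling
#' unit (PSU) id and sampling weight — that every design-based estimator in
#' the package consumes. Variances are estimated by Taylor linearization
#' with the stratified between-PSU estimator, the standard approach for
#' stratified multi-stage samples released with pseudo-strata and
#' pseudo-PSUs (as NHANES is).
#'
#' @param strata vector of stratum identifiers (coerced to factor).
#' @param psu vector of PSU identifiers; PSU ids are interpreted as nested
#'   within strata, so the same PSU label may recur across strata.
#' @param weight positive numeric sampling weights.
#' @return An object of class `svy_design` with elements `strata` (factor),
#'   `psu` (factor of within-stratum PSU), `weight`, and `n`.
#' @examples
#' d <- svy_design(strata = rep(1:2, each = 4),
#'                 psu = rep(1:4, each = 2),
#'                 weight = runif(8, 1, 3))
#' degf(d)
#' @export
svy_design <- function(strata, psu, weight) {
  n <- length(weight)
  if (length(strata) != n || length(psu) != n) {
    stop_named("strata, psu and weight must have equal length")
  }
  if (anyNA(strata) || anyNA(psu) || anyNA(weight)) {
    stop_named("design columns (strata, psu, weight) must not contain NA")
  }
  weight <- as.numeric(weight)
  if (any(weight <= 0)) stop_named("all sampling weights must be positive")
  strata <- factor(strata)
  psu <- factor(paste(strata, psu, sep = "\r"))
  structure(list(strata = strata, psu = psu, weight = weight, n = n),
            class = "svy_design")
}

#' @export
print.svy_design <- function(x, ...) {
  cat(sprintf(
    "Survey design: %d records, %d strata, %d PSUs (design df = %d)\n",
    x$n, nlevels(x$strata), nlevels(x$psu), degf(x)))
  invisible(x)
}

#' Design degrees of freedom
#'
#' Number of PSUs minus number of strata, the conventional degrees of
#' freedom for design-based t and F references.
#'
#' @param design a [svy_design()] object.
#' @return integer degrees of freedom.
#' @export
degf <- function(design) {
  stopifnot(inherits(design, "svy_design"))
  nlevels(design$psu) - nlevels(design$strata)
}

# Subset a design to the records in `idx` (logical or integer), dropping
# now-empty strata/PSU levels.
design_subset <- function(design, idx) {
  svy_design(droplevels(design$strata[idx]),
             droplevels(design$psu[idx]),
             design$weight[idx])
}

# Stratified between-PSU covariance of estimated totals.
#
# U is an n x K matrix of per-record linearized contributions u_i; the
# estimator of Cov(sum_i u_i) is
#   sum_h n_h/(n_h - 1) * sum_j (t_hj - tbar_h)(t_hj - tbar_h)'
# over PSU totals t_hj within stratum h. Strata with a single PSU are an
# error unless lonely_psu = "certainty", in which case they contribute no
# variance (treated as selected with certainty) and a warning is issued.
psu_cov <- function(U, design, lonely_psu = c("fail", "certainty")) {
  lonely_psu <- match.arg(lonely_psu)
  U <- as.matrix(U)
  K <- ncol(U)
  totals <- rowsum(U, design$psu, reorder = TRUE)
  # PSU factor levels are "<stratum>\r<psu>", so the stratum of each PSU
  # total can be read back off the rowname
  psu_stratum <- sub("\r.*$", "", rownames(totals))
  V <- matrix(0, K, K)
  lonely <- character(0)
  for (h in levels(design$strata)) {
    Th <- totals[psu_stratum == h, , drop = FALSE]
    nh <- nrow(Th)
    if (nh < 2) {
      lonely <- c(lonely, h)
      next
    }
    D <- sweep(Th, 2, colMeans(Th))
    V <- V + crossprod(D) * nh / (nh - 1)
  }
  if (length(lonely)) {
    if (lonely_psu == "fail") {
      stop_named(paste0(
        "stratum with a single PSU (variance undefined): %s; ",
        "set lonely_psu = \"certainty\" to treat such strata as ",
        "certainty units contributing zero variance"),
        paste(lonely, collapse = ", "))
    }
    warning(sprintf(
      "lonely PSU strata treated as certainty units (zero variance): %s",
      paste(lonely, collapse = ", ")), call. = FALSE)
  }
  V
}
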