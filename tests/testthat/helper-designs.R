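# Shared fixtures: designs and small cohorts built in code.

# "iid" design: equal weights, one stratum, each record its own PSU —
# the setting where every design-based estimator must reduce to its
# classical counterpart.
iid_design <- function(n, weight = 1) {
  svy_design(rep(1L, n), seq_len(n), rep(weight, n))
}

# clustered two-stage design with lognormal weights: H strata x m PSUs x k
# records
clustered_design <- function(H = 10, m = 2, k = 15, wsd = 0.3) {
  n <- H * m * k
  svy_design(rep(seq_len(H), each = m * k),
             rep(rep(seq_len(m), each = k), H),
             stats::rlnorm(n, 0, wsd))
}

# cluster index (one id per PSU) for generating intra-PSU correlated data
cluster_id <- function(H = 10, m = 2, k = 15) {
  rep(seq_len(H * m), each = k)
}

# small fully recoded synthetic cohort for index/model/pipeline tests
small_cohort <- function(seed = 1, H = 6, m = 2, k = 30, ...) {
  g <- generate_cohort(generator_config(n_strata = H,
                                        psus_per_stratum = m,
                                        records_per_psu = k,
                                        seed = seed, ...))
  g$cohort <- recode_all(g$cohort)
  g
}

# brute-force weighted quantile by integer-weight expansion: repeat each
# value w_i times and take the smallest value with empirical CDF >= q
expansion_quantile <- function(values, int_weights, q) {
  expanded <- sort(rep(values, int_weights))
  cdf <- seq_along(expanded) / length(expanded)
  expanded[which(cdf >= q - 1e-12)[1]]
}
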