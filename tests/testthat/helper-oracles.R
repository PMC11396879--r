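# Independent oracles used across the suite. Each recomputes the quantity by
# a different route than the implementation (term-by-term literals, normal
# equations, exhaustive enumeration) so agreement is evidence, not tautology.

# term-by-term index arithmetic with the published literal coefficients
oracle_ivx <- function(glyca, shdlp) {
  terms <- c(9, -0.0027 * glyca, -0.46079 * shdlp, 0.0006325 * glyca * shdlp)
  sum(terms)
}

oracle_mmx <- function(leu, val, ile, cit) {
  leu_part <- 0.75097 * sum(c(4, -0.02234 * leu, 0.0000528 * leu * leu))
  val_part <- 0.55737 * sum(c(7, -0.02895 * val, 0.0000608 * val * val))
  ile_part <- 0.00867 * ile
  cit_part <- 0.65649 * sum(c(1, 0.0025 * cit, 0.0000167 * cit * cit))
  leu_part + val_part + ile_part + cit_part
}

oracle_mvx <- function(ivx, mmx) {
  sum(c(2.72923 * ivx, 11.96062 * log(mmx), -1.12749 * ivx * log(mmx)))
}

# brute-force least squares through the normal equations
oracle_ols_coef <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# two-sided Fisher exact p for a 2x2 table by exhaustive hypergeometric
# enumeration over all tables with the observed margins
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0L, k - n2); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k))
  }, numeric(1))
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ntile-rule block sizes: earlier blocks take the extras
oracle_ntile_sizes <- function(n, groups = 3L) {
  base <- n %/% groups
  extra <- n %% groups
  base + as.integer(seq_len(groups) <= extra)
}

# small cohort configuration reused by the simulation tests
small_config <- function(...) {
  cohort_config(n = c(hc = 40L, rr = 40L, pms = 25L), ...)
}

# one-analyte config for targeted parameter-recovery runs
shift_config <- function(n = c(hc = 153L, rr = 187L, pms = 91L), metabolites) {
  cohort_config(n = n, metabolites = metabolites)
}

# replicate the generate -> adjusted-OLS pipeline and collect the estimate of
# one group coefficient for one analyte; seeds are explicit for determinism
recover_group_betas <- function(config, analyte, term, reps, seed_base) {
  vapply(seq_len(reps), function(r) {
    demo <- generate_demographics(config, seed = seed_base + r)
    pan <- generate_metabolites(demo, config, seed = seed_base + r)
    if (analyte == "bcaa") pan$bcaa <- pan$valine + pan$leucine + pan$isoleucine
    fit <- fit_adjusted_ols(pan, analyte, "group")
    fit$coefficients$estimate[fit$coefficients$term == term]
  }, numeric(1))
}
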