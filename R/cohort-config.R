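#' Configuration for the synthetic three-group cohort generator
#'
#' Bundles every tunable of the simulator into one serializable list so a run
#' is reproducible from config + seed alone. Defaults emulate the published
#' three-group study design: 153 healthy controls (HC), 187
#' relapsing-remitting MS (RR), and 91 progressive MS (PMS), with per-group
#' demographics matching the published baseline table. Healthy-control
#' metabolite baselines and residual SDs are implementation defaults at
#' physiological scale (the source study reports group contrasts, not
#' baselines); the per-group metabolite shifts default to the published
#' adjusted regression coefficients so parameter-recovery exercises have
#' well-defined truth.
#'
#' @param n named integer vector `c(hc=, rr=, pms=)`, subjects per group.
#' @param demographics per-group list with `age` (mean, sd; truncated at 18),
#'   `bmi` (mean, sd; truncated at 12), `female` and `heart_problem`
#'   (Bernoulli fractions), and for MS groups `duration` (mean, sd, years,
#'   truncated at 0.5), `edss` (median and quartiles on the 0-10 half-point
#'   grid) and `t25fw` (meanlog, sdlog of a log-normal walk time in seconds).
#' @param metabolites named list, one entry per analyte with `mean` and `sd`
#'   (HC baseline, µmol/L) and `beta_rr`, `beta_pms` (additive group shifts).
#'   Shifts are injected independently of age/sex/BMI, so the
#'   covariate-adjusted OLS group coefficient is unbiased for the shift.
#' @param mri per-group mean/sd for the seven volumetric measures (mL),
#'   plus `couplings`, a list of `list(measure=, biomarker=, slope=)` linear
#'   couplings added on top of the group structure.
#' @return list of class `"cohort_config"`.
#' @examples
#' cfg <- cohort_config(n = c(hc = 20, rr = 20, pms = 10))
#' cfg$metabolites$valine
#' @export
cohort_config <- function(n = c(hc = 153L, rr = 187L, pms = 91L),
                          demographics = default_demographics(),
                          metabolites = default_metabolites(),
                          mri = default_mri()) {
  if (length(n) != 3L || is.null(names(n)) ||
      !setequal(names(n), c("hc", "rr", "pms"))) {
    stop("'n' must be a named vector with entries hc, rr, pms", call. = FALSE)
  }
  n <- as.integer(n[c("hc", "rr", "pms")])
  names(n) <- c("hc", "rr", "pms")
  if (any(is.na(n)) || any(n <= 0L)) {
    stop("group sizes must be positive integers", call. = FALSE)
  }
  for (g in names(demographics)) {
    d <- demographics[[g]]
    for (fld in c("age", "bmi")) {
      if (d[[fld]][["sd"]] <= 0) {
        stop(sprintf("demographics$%s$%s sd must be > 0", g, fld), call. = FALSE)
      }
    }
    for (fld in c("female", "heart_problem")) {
      p <- d[[fld]]
      if (!is.numeric(p) || p < 0 || p > 1) {
        stop(sprintf("demographics$%s$%s must be a fraction in [0, 1]", g, fld),
             call. = FALSE)
      }
    }
  }
  for (a in names(metabolites)) {
    m <- metabolites[[a]]
    need <- c("mean", "sd", "beta_rr", "beta_pms")
    if (!all(need %in% names(m))) {
      stop(sprintf("metabolites$%s must have fields %s", a,
                   paste(need, collapse = ", ")), call. = FALSE)
    }
    if (m$sd < 0) stop(sprintf("metabolites$%s$sd must be >= 0", a), call. = FALSE)
  }
  # fit the EDSS beta-distribution shapes once, up front, so replicated
  # generation does not repeat the optimization
  for (g in c("rr", "pms")) {
    demographics[[g]]$edss_shape <-
      fit_edss_beta(demographics[[g]]$edss)
  }
  structure(list(n = n, demographics = demographics,
                 metabolites = metabolites, mri = mri),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_demographics <- function() {
  list(
    hc = list(age = c(mean = 45.9, sd = 13.9),
              bmi = c(mean = 28.0, sd = 5.94),
              female = 0.556, heart_problem = 0.20),
    rr = list(age = c(mean = 44.3, sd = 9.65),
              bmi = c(mean = 27.1, sd = 6.15),
              female = 0.754, heart_problem = 0.23,
              duration = c(mean = 12.1, sd = 8.47),
              edss = c(q1 = 1.5, median = 2.5, q3 = 3.5),
              t25fw = c(meanlog = log(6), sdlog = 0.35)),
    pms = list(age = c(mean = 54.1, sd = 8.82),
               bmi = c(mean = 25.6, sd = 5.44),
               female = 0.725, heart_problem = 0.22,
               duration = c(mean = 21.5, sd = 11.4),
               edss = c(q1 = 5.0, median = 6.0, q3 = 6.5),
               t25fw = c(meanlog = log(12), sdlog = 0.5))
  )
}

#' @rdname cohort_config
#' @export
default_metabolites <- function() {
  # HC baselines/SDs are implementation defaults at physiological scale;
  # the group shifts are the published adjusted coefficients (RR, PMS vs HC)
  list(
    valine     = list(mean = 230, sd = 40, beta_rr = -18.2,  beta_pms = -21.6),
    leucine    = list(mean = 130, sd = 25, beta_rr = -14.5,  beta_pms = -19.5),
    isoleucine = list(mean = 60,  sd = 12, beta_rr = -6.92,  beta_pms = -8.01),
    alanine    = list(mean = 350, sd = 60, beta_rr = -35.9,  beta_pms = -44.1),
    citrate    = list(mean = 120, sd = 25, beta_rr = 0.965,  beta_pms = 2.03),
    glyca      = list(mean = 400, sd = 60, beta_rr = 16.4,   beta_pms = 27.5),
    shdlp      = list(mean = 15,  sd = 4,  beta_rr = -0.176, beta_pms = -0.439)
  )
}

#' @rdname cohort_config
#' @export
default_mri <- function() {
  # plausible volumetric scales (mL); lesions only meaningful in MS
  list(
    rr = list(t2_lv = c(mean = 10, sd = 8),  t1_lv = c(mean = 2.5, sd = 2.5),
              wbv = c(mean = 1520, sd = 80), gmv = c(mean = 790, sd = 50),
              dgmv = c(mean = 60, sd = 6),   cv = c(mean = 630, sd = 45),
              lvv = c(mean = 30, sd = 14)),
    pms = list(t2_lv = c(mean = 20, sd = 14), t1_lv = c(mean = 6, sd = 5),
               wbv = c(mean = 1440, sd = 85), gmv = c(mean = 745, sd = 52),
               dgmv = c(mean = 54, sd = 6.5), cv = c(mean = 595, sd = 48),
               lvv = c(mean = 48, sd = 20)),
    couplings = list()
  )
}

# Fit the (a, b) shapes of a beta distribution on [0, 10] whose quartiles
# match the target EDSS median/IQR; the simulator then discretizes draws to
# the 0.5-point grid. Bounded and skewable, hence grid-compatible.
fit_edss_beta <- function(edss_quartiles) {
  q <- edss_quartiles[c("q1", "median", "q3")] / 10
  obj <- function(par) {
    a <- exp(par[1L]); b <- exp(par[2L])
    sum((stats::qbeta(c(0.25, 0.5, 0.75), a, b) - q)^2)
  }
  fit <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  c(a = exp(fit$par[1L]), b = exp(fit$par[2L]))
}
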