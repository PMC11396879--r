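#' Generate demographics for a synthetic three-group cohort
#'
#' Draws one subject record per configured slot: group sizes exactly as
#' configured; age and BMI from per-group normal distributions (age truncated
#' at 18 years, BMI at 12 kg/m² by resampling); sex and heart-problem flags
#' Bernoulli with per-group fractions; for the MS groups, disease duration
#' (truncated normal), EDSS from a scaled beta distribution discretized to
#' the 0-10 half-point grid, and timed 25-foot walk (seconds) log-normal.
#' The obesity flag is derived as BMI >= 30 kg/m².
#'
#' @param config a [cohort_config()].
#' @param seed integer root seed for this stage.
#' @return data frame with columns `subject_id`, `group` (factor HC/RR/PMS,
#'   HC first so it is the regression reference), `age`, `sex` (factor
#'   female/male), `bmi`, `obese`, `heart_problem`, `disease_duration`,
#'   `edss`, `t25fw` (the last three NA for HC).
#' @examples
#' demo <- generate_demographics(cohort_config(), seed = 1)
#' table(demo$group)
#' @export
generate_demographics <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  total <- sum(n)
  group <- factor(rep(c("HC", "RR", "PMS"), times = n),
                  levels = c("HC", "RR", "PMS"))
  out <- with_seed(child_seed(seed, "demographics"), {
    age <- numeric(total); bmi <- numeric(total)
    sex <- character(total); heart <- logical(total)
    duration <- rep(NA_real_, total); edss <- rep(NA_real_, total)
    t25fw <- rep(NA_real_, total)
    offset <- 0L
    for (g in c("hc", "rr", "pms")) {
      d <- config$demographics[[g]]
      idx <- offset + seq_len(n[[g]])
      age[idx] <- rnorm_truncated(n[[g]], d$age[["mean"]], d$age[["sd"]], lower = 18)
      bmi[idx] <- rnorm_truncated(n[[g]], d$bmi[["mean"]], d$bmi[["sd"]], lower = 12)
      sex[idx] <- ifelse(stats::runif(n[[g]]) < d$female, "female", "male")
      heart[idx] <- stats::runif(n[[g]]) < d$heart_problem
      if (g != "hc") {
        duration[idx] <- rnorm_truncated(n[[g]], d$duration[["mean"]],
                                         d$duration[["sd"]], lower = 0.5)
        sh <- d$edss_shape
        edss[idx] <- pmin(pmax(round(10 * stats::rbeta(n[[g]], sh[["a"]], sh[["b"]]) * 2) / 2, 0), 10)
        t25fw[idx] <- stats::rlnorm(n[[g]], d$t25fw[["meanlog"]], d$t25fw[["sdlog"]])
      }
      offset <- offset + n[[g]]
    }
    data.frame(
      subject_id = sprintf("S%04d", seq_len(total)),
      group = group,
      age = age,
      sex = factor(sex, levels = c("female", "male")),
      bmi = bmi,
      obese = bmi >= 30,
      heart_problem = heart,
      disease_duration = duration,
      edss = edss,
      t25fw = t25fw,
      stringsAsFactors = FALSE
    )
  })
  out
}

# truncated-normal draws by resampling; the truncation points sit far in the
# tail for every default, so resampling is cheap and the mean is essentially
# unshifted
rnorm_truncated <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- x < lower
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmax(x, lower)
}

#' Generate metabolite panels with additive group shifts
#'
#' Each analyte is drawn as HC baseline mean + beta_rr·1\[group=RR\] +
#' beta_pms·1\[group=PMS\] + Gaussian residual. Residuals are independent of
#' age, sex, and BMI by construction, so the covariate-adjusted OLS group
#' coefficient is an unbiased estimator of the configured shift. Draws below
#' zero are floored at 0 and counted (attribute `n_floored`; with the default
#' baselines more than six residual SDs above zero, flooring never triggers).
#'
#' @param subjects data frame from [generate_demographics()].
#' @param config a [cohort_config()]; `config$metabolites` names the analytes.
#' @param seed integer root seed for this stage.
#' @return `subjects` with one numeric column appended per configured analyte
#'   and attribute `n_floored` (named count of floored draws per analyte).
#' @export
generate_metabolites <- function(subjects, config, seed) {
  stopifnot(is.data.frame(subjects), inherits(config, "cohort_config"))
  mets <- config$metabolites
  if (length(mets) == 0L) stop("no metabolites configured", call. = FALSE)
  is_rr <- subjects$group == "RR"
  is_pms <- subjects$group == "PMS"
  n <- nrow(subjects)
  floored <- integer(length(mets))
  names(floored) <- names(mets)
  out <- with_seed(child_seed(seed, "metabolites"), {
    for (a in names(mets)) {
      m <- mets[[a]]
      x <- m$mean + m$beta_rr * is_rr + m$beta_pms * is_pms +
        stats::rnorm(n, 0, m$sd)
      floored[a] <- sum(x < 0)
      subjects[[a]] <- pmax(x, 0)
    }
    subjects
  })
  if (sum(floored) > 0L) {
    warning(sum(floored), " metabolite draws floored at 0", call. = FALSE)
  }
  attr(out, "n_floored") <- floored
  out
}

#' Generate index scores coupled linearly to a disability outcome
#'
#' Simulates a per-subject index score as intercept + slope · predictor +
#' Gaussian noise, the generative model under which the adjusted OLS slope
#' recovery of the disability regressions is well-defined. The predictor is
#' either `edss` or the base-10 logarithm of the timed 25-foot walk. Scores
#' are returned unmodified; draws outside \[1, 100\] are only counted
#' (attribute `n_outside`), because truncating them would bias slope
#' recovery — calibrate intercept/noise so the count stays negligible.
#'
#' @param subjects data frame with `edss`/`t25fw` present for every row
#'   (i.e. the MS subset of a cohort).
#' @param predictor `"edss"` or `"log10_t25fw"`.
#' @param intercept,slope,noise_sd generative parameters (score units;
#'   `noise_sd >= 0`).
#' @param seed integer root seed for this stage.
#' @return numeric vector of scores, one per subject, with attribute
#'   `n_outside`.
#' @export
generate_outcome_coupled_scores <- function(subjects, predictor = c("edss", "log10_t25fw"),
                                            intercept, slope, noise_sd, seed) {
  predictor <- match.arg(predictor)
  stopifnot(is.data.frame(subjects), noise_sd >= 0)
  x <- if (predictor == "edss") subjects$edss else {
    if (any(is.na(subjects$t25fw))) {
      stop("t25fw missing for ", sum(is.na(subjects$t25fw)),
           " subjects; coupled scores need a complete predictor", call. = FALSE)
    }
    log10_walk(subjects$t25fw)
  }
  if (any(is.na(x))) {
    stop(predictor, " missing for ", sum(is.na(x)),
         " subjects; coupled scores need a complete predictor", call. = FALSE)
  }
  scores <- with_seed(child_seed(seed, paste0("coupled_", predictor)), {
    intercept + slope * x + stats::rnorm(length(x), 0, noise_sd)
  })
  attr(scores, "n_outside") <- sum(scores < 1 | scores > 100)
  scores
}

#' Generate MRI volumetrics for the MS subjects
#'
#' Draws the seven volumetric measures (T2 and T1 lesion volumes, whole-brain,
#' gray-matter, deep-gray-matter, cortical, and lateral-ventricle volumes, mL)
#' from per-group normal distributions, optionally adding linear couplings to
#' a biomarker column already present in `subjects`
#' (`volume += slope · (biomarker − mean(biomarker))`). Healthy controls
#' receive NA (imaging is acquired in patients). Volumes are floored at a
#' small positive value and the events counted (attribute `n_floored_mri`).
#'
#' @param subjects cohort data frame (any biomarker a coupling refers to must
#'   already be a column).
#' @param config a [cohort_config()]; `config$mri` holds per-group parameters
#'   and `couplings`.
#' @param seed integer root seed for this stage.
#' @return `subjects` with columns `t2_lv`, `t1_lv`, `wbv`, `gmv`, `dgmv`,
#'   `cv`, `lvv` appended.
#' @export
generate_mri <- function(subjects, config, seed) {
  stopifnot(is.data.frame(subjects), inherits(config, "cohort_config"))
  measures <- c("t2_lv", "t1_lv", "wbv", "gmv", "dgmv", "cv", "lvv")
  for (cp in config$mri$couplings) {
    if (!all(c("measure", "biomarker", "slope") %in% names(cp))) {
      stop("each MRI coupling needs fields measure, biomarker, slope",
           call. = FALSE)
    }
    if (!cp$measure %in% measures) {
      stop("unknown MRI measure in coupling: ", cp$measure, call. = FALSE)
    }
    if (!cp$biomarker %in% names(subjects)) {
      stop("MRI coupling refers to absent biomarker column: ", cp$biomarker,
           call. = FALSE)
    }
  }
  is_ms <- subjects$group %in% c("RR", "PMS")
  floored <- 0L
  out <- with_seed(child_seed(seed, "mri"), {
    for (meas in measures) {
      x <- rep(NA_real_, nrow(subjects))
      for (g in c("rr", "pms")) {
        p <- config$mri[[g]][[meas]]
        idx <- which(subjects$group == toupper_group(g))
        x[idx] <- stats::rnorm(length(idx), p[["mean"]], p[["sd"]])
      }
      for (cp in config$mri$couplings) {
        if (cp$measure == meas) {
          b <- subjects[[cp$biomarker]]
          ctr <- b - mean(b[is_ms], na.rm = TRUE)
          x[is_ms] <- x[is_ms] + cp$slope * ctr[is_ms]
        }
      }
      low <- !is.na(x) & x < 0.1
      floored <- floored + sum(low)
      x[low] <- 0.1
      subjects[[meas]] <- x
    }
    subjects
  })
  attr(out, "n_floored_mri") <- floored
  out
}

toupper_group <- function(g) c(hc = "HC", rr = "RR", pms = "PMS")[[g]]

#' Simulate a complete scored cohort
#'
#' End-to-end generator: demographics, metabolite panels, MRI volumetrics,
#' and vulnerability scores, all derived from one root seed via per-stage
#' child streams. Identical config + seed reproduces the cohort bit-for-bit.
#'
#' @param config a [cohort_config()].
#' @param seed integer root seed.
#' @param anchors anchors for [score_panel()].
#' @param mri whether to attach MRI volumetrics.
#' @return one flat data frame joining subject records, metabolite panel,
#'   MRI columns, and the seven score columns.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n = c(hc = 20, rr = 20, pms = 10)), seed = 7)
#' head(cohort[, c("subject_id", "group", "valine", "mvx_score")])
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L,
                            anchors = default_anchors(), mri = TRUE) {
  subjects <- generate_demographics(config, seed)
  subjects <- generate_metabolites(subjects, config, seed)
  if (mri) subjects <- generate_mri(subjects, config, seed)
  score_panel(subjects, anchors)
}
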