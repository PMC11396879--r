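# canonical biomarker panel of the association suite: display name -> column
suite_biomarkers <- function() {
  c(Valine = "valine", Leucine = "leucine", Isoleucine = "isoleucine",
    BCAA = "bcaa", Alanine = "alanine", Citrate = "citrate",
    sHDLP = "shdlp", GlycA = "glyca",
    IVX = "ivx_score", MMX = "mmx_score", MVX = "mvx_score")
}

mri_measures <- function() c("t2_lv", "t1_lv", "wbv", "gmv", "dgmv", "cv", "lvv")

#' Run the full covariate-adjusted association suite
#'
#' Reproduces the analysis layout of the source design over a scored cohort:
#' for each of the eleven biomarkers (valine, leucine, isoleucine, BCAA,
#' alanine, citrate, sHDLP, GlycA, and the IVX/MMX/MVX scores) it fits
#' \enumerate{
#'   \item the group-status model `biomarker ~ group + age + sex + bmi`
#'     (with an optional heart-problem sensitivity variant),
#'   \item in the MS subset, the disability models with EDSS and with
#'     log10 timed ambulation as the predictor, and
#'   \item in the MS subset, one model per MRI volumetric measure.
#' }
#' Each cell reports the predictor's joint Type II generalized eta-squared,
#' its partial-F p-value, the coefficient(s), the complete-case n, and the
#' dropped-row count.
#'
#' @param cohort scored cohort data frame ([simulate_cohort()] output or a
#'   real table with the same columns).
#' @param heart_sensitivity also fit the group models with heart-problem
#'   status as an extra covariate.
#' @param mri fit the MRI models (requires the volumetric columns).
#' @return list of data frames: `group` (one row per biomarker: eta_sq, p,
#'   beta_rr, beta_pms, effect label, n, n_dropped), optionally
#'   `group_heart`, `disability` (biomarker x predictor long form), `mri`
#'   (long form) and `mri_eta_wide` (11 biomarkers x 7 measures, eta-squared).
#' @examples
#' cohort <- simulate_cohort(cohort_config(n = c(hc = 40, rr = 40, pms = 20)), seed = 5)
#' res <- run_full_association_suite(cohort)
#' res$group
#' @export
run_full_association_suite <- function(cohort, heart_sensitivity = TRUE,
                                       mri = TRUE) {
  bio <- suite_biomarkers()
  need <- c(unname(bio), "group", "age", "sex", "bmi", "edss", "t25fw")
  if (mri) need <- c(need, mri_measures())
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  group_row <- function(col, include_heart) {
    fit <- fit_adjusted_ols(cohort, col, "group", include_heart = include_heart)
    est <- fit$coefficients
    data.frame(
      biomarker = names(bio)[bio == col],
      eta_sq = generalized_eta_squared(fit, "group"),
      p_value = fit$terms$p_value[fit$terms$term == "group"],
      beta_rr = est$estimate[est$term == "groupRR"],
      beta_pms = est$estimate[est$term == "groupPMS"],
      effect = effect_size_label(generalized_eta_squared(fit, "group")),
      n = fit$n, n_dropped = fit$n_dropped, stringsAsFactors = FALSE
    )
  }
  out <- list(group = do.call(rbind, lapply(bio, group_row, include_heart = FALSE)))
  rownames(out$group) <- NULL
  if (heart_sensitivity) {
    out$group_heart <- do.call(rbind, lapply(bio, group_row, include_heart = TRUE))
    rownames(out$group_heart) <- NULL
  }

  ms <- cohort[cohort$group %in% c("RR", "PMS"), , drop = FALSE]
  ms$log10_t25fw <- ifelse(is.na(ms$t25fw), NA_real_, log10_walk(ms$t25fw))

  dis_row <- function(col, pred) {
    fit <- fit_adjusted_ols(ms, col, pred)
    data.frame(
      biomarker = names(bio)[bio == col],
      predictor = if (pred == "edss") "EDSS" else "log10_t25fw",
      eta_sq = generalized_eta_squared(fit, pred),
      p_value = fit$terms$p_value[fit$terms$term == pred],
      beta = fit$coefficients$estimate[fit$coefficients$term == pred],
      effect = effect_size_label(generalized_eta_squared(fit, pred)),
      n = fit$n, n_dropped = fit$n_dropped, stringsAsFactors = FALSE
    )
  }
  out$disability <- do.call(rbind, c(
    lapply(bio, dis_row, pred = "edss"),
    lapply(bio, dis_row, pred = "log10_t25fw")))
  rownames(out$disability) <- NULL

  if (mri) {
    mri_row <- function(col, meas) {
      fit <- fit_adjusted_ols(ms, col, meas)
      data.frame(
        biomarker = names(bio)[bio == col], measure = meas,
        eta_sq = generalized_eta_squared(fit, meas),
        p_value = fit$terms$p_value[fit$terms$term == meas],
        beta = fit$coefficients$estimate[fit$coefficients$term == meas],
        effect = effect_size_label(generalized_eta_squared(fit, meas)),
        n = fit$n, n_dropped = fit$n_dropped, stringsAsFactors = FALSE
      )
    }
    out$mri <- do.call(rbind, lapply(mri_measures(), function(meas) {
      do.call(rbind, lapply(bio, mri_row, meas = meas))
    }))
    rownames(out$mri) <- NULL
    wide <- stats::reshape(out$mri[, c("biomarker", "measure", "eta_sq")],
                           idvar = "biomarker", timevar = "measure",
                           direction = "wide")
    names(wide) <- sub("^eta_sq\\.", "", names(wide))
    wide <- wide[match(names(bio), wide$biomarker), , drop = FALSE]
    rownames(wide) <- NULL
    out$mri_eta_wide <- wide
  }
  out
}
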