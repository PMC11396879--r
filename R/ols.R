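#' Covariate-adjusted ordinary least squares with effect sizes
#'
#' Fits `outcome ~ predictor + age + sex + bmi` (optionally + heart-problem
#' status) by QR-decomposed least squares, on complete cases, and decomposes
#' the model into per-term Type II sums of squares: each term's SS is the
#' increase in residual SS when that term alone is dropped from the full
#' model (there are no interactions, so this is the marginal term SS).
#' A 3-level group predictor (treatment-coded, HC reference) contributes a
#' joint 2-df term whose dummy coefficients are the RR-vs-HC and PMS-vs-HC
#' contrasts; a continuous predictor (EDSS, log10 walk time, an MRI volume)
#' contributes 1 df. Per-term generalized eta-squared is
#' SS_term / (SS_term + SS_error); term p-values come from the partial F
#' test, coefficient p-values from two-sided t tests on residual df.
#'
#' @param data data frame holding outcome, predictor, and covariates.
#' @param outcome name of the dependent-variable column.
#' @param predictor name of the predictor-of-interest column (factor or
#'   continuous).
#' @param covariates names of adjustment columns; default age, sex, bmi.
#' @param include_heart add `heart_problem` to the covariates.
#' @return object of class `"metavulx_fit"`: list with `outcome`,
#'   `predictor`, `n` (complete cases used), `n_dropped`, `coefficients`
#'   (term, estimate, std_error, p_value), `terms` (term, df, sum_sq,
#'   eta_sq, p_value), `ss_error`, `df_error`, and the underlying `lm`
#'   object in `model`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n = c(hc = 40, rr = 40, pms = 20)), seed = 3)
#' fit <- fit_adjusted_ols(cohort, "valine", "group")
#' fit$terms
#' @export
fit_adjusted_ols <- function(data, outcome, predictor,
                             covariates = c("age", "sex", "bmi"),
                             include_heart = FALSE) {
  stopifnot(is.data.frame(data))
  if (include_heart) covariates <- union(covariates, "heart_problem")
  vars <- c(outcome, predictor, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0L) {
    stop("columns absent from data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- data[vars]
  cc <- stats::complete.cases(df)
  n_dropped <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  if (is.character(df[[predictor]])) df[[predictor]] <- factor(df[[predictor]])
  if (is.factor(df[[predictor]])) df[[predictor]] <- droplevels(df[[predictor]])

  rhs <- paste(c(predictor, covariates), collapse = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))
  X <- stats::model.matrix(form, df)
  p <- ncol(X)
  if (nrow(df) < max(10L, p + 1L)) {
    stop(sprintf("only %d complete cases for %d parameters; need at least %d",
                 nrow(df), p, max(10L, p + 1L)), call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("rank-deficient design; collinear columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  fit <- stats::lm(form, data = df)
  sm <- summary(fit)
  coefs <- data.frame(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, "Estimate"],
    std_error = sm$coefficients[, "Std. Error"],
    p_value = sm$coefficients[, "Pr(>|t|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )

  rss_full <- sum(stats::residuals(fit)^2)
  # round-off guard: sums of squares below machine noise relative to the
  # outcome's total variation are exact zeros (noise-free designs)
  ss_total <- sum((df[[outcome]] - mean(df[[outcome]]))^2)
  # scale the floor to the outcome's magnitude so a constant (or exactly
  # fitted) outcome yields exact-zero SS, not round-off ratios
  noise_floor <- 1e-12 * max(ss_total, sum(df[[outcome]]^2) * .Machine$double.eps,
                             .Machine$double.eps)
  if (rss_full < noise_floor) rss_full <- 0
  df_error <- fit$df.residual
  term_labels <- attr(stats::terms(fit), "term.labels")
  terms_tab <- data.frame(term = term_labels, df = NA_real_, sum_sq = NA_real_,
                          eta_sq = NA_real_, p_value = NA_real_,
                          stringsAsFactors = FALSE)
  for (i in seq_along(term_labels)) {
    kept <- setdiff(term_labels, term_labels[i])
    reduced_rhs <- if (length(kept) > 0L) paste(kept, collapse = " + ") else "1"
    reduced <- stats::lm(
      stats::as.formula(paste(outcome, "~", reduced_rhs)), data = df)
    rss_red <- sum(stats::residuals(reduced)^2)
    ss_term <- max(rss_red - rss_full, 0)
    if (ss_term < noise_floor) ss_term <- 0
    df_term <- reduced$df.residual - df_error
    terms_tab$df[i] <- df_term
    terms_tab$sum_sq[i] <- ss_term
    terms_tab$eta_sq[i] <- if (ss_term + rss_full > 0) ss_term / (ss_term + rss_full) else 0
    terms_tab$p_value[i] <- if (rss_full == 0) {
      # noise-free design: the partial F test is degenerate
      if (ss_term == 0) NA_real_ else 0
    } else {
      fstat <- (ss_term / df_term) / (rss_full / df_error)
      stats::pf(fstat, df_term, df_error, lower.tail = FALSE)
    }
  }

  structure(list(outcome = outcome, predictor = predictor,
                 covariates = covariates, n = nrow(df), n_dropped = n_dropped,
                 coefficients = coefs, terms = terms_tab,
                 ss_error = rss_full, df_error = df_error, model = fit),
            class = "metavulx_fit")
}

#' @export
print.metavulx_fit <- function(x, ...) {
  cat(sprintf("Adjusted OLS: %s ~ %s + %s  (n = %d, dropped = %d)\n",
              x$outcome, x$predictor, paste(x$covariates, collapse = " + "),
              x$n, x$n_dropped))
  tt <- x$terms
  tt$label <- vapply(tt$eta_sq, effect_size_label, character(1))
  print(tt, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Generalized eta-squared of a fitted term
#'
#' `eta^2_g = SS_term / (SS_term + SS_error)` with the term's Type II sum of
#' squares (term dropped last among non-interacting terms), the standard
#' effect-size measure for terms of an additive OLS model.
#'
#' @param result a [fit_adjusted_ols()] object.
#' @param term term label as it appears in `result$terms$term`.
#' @return eta-squared in \[0, 1\].
#' @export
generalized_eta_squared <- function(result, term) {
  stopifnot(inherits(result, "metavulx_fit"))
  i <- match(term, result$terms$term)
  if (is.na(i)) {
    stop("term '", term, "' not in model; have: ",
         paste(result$terms$term, collapse = ", "), call. = FALSE)
  }
  result$terms$eta_sq[i]
}

#' Qualitative label for a generalized eta-squared effect size
#'
#' Thresholds: below 0.01 negligible; at least 0.01 small; at least 0.06
#' medium; at least 0.14 large (boundaries inclusive).
#'
#' @param eta2 scalar in \[0, 1\].
#' @return one of `"negligible"`, `"small"`, `"medium"`, `"large"`.
#' @examples
#' effect_size_label(0.039)  # "small"
#' effect_size_label(0.14)   # "large"
#' @export
effect_size_label <- function(eta2) {
  if (!is.numeric(eta2) || length(eta2) != 1L || is.na(eta2) ||
      eta2 < 0 || eta2 > 1) {
    stop("eta2 must be a single value in [0, 1]", call. = FALSE)
  }
  if (eta2 >= 0.14) "large"
  else if (eta2 >= 0.06) "medium"
  else if (eta2 >= 0.01) "small"
  else "negligible"
}
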