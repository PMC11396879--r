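#' Base-10 logarithm of timed ambulation
#'
#' The timed 25-foot walk is right-skewed; the analyses regress on its
#' base-10 logarithm.
#'
#' @param t25fw walk time in seconds, strictly positive (NA propagates).
#' @return log10-transformed values.
#' @examples
#' log10_walk(10)  # 1
#' @export
log10_walk <- function(t25fw) {
  check_finite(t25fw, "t25fw")
  bad <- !is.na(t25fw) & t25fw <= 0
  if (any(bad)) {
    stop(sprintf("t25fw must be > 0 seconds (element %d: %g)",
                 which(bad)[1L], t25fw[bad][1L]), call. = FALSE)
  }
  log10(t25fw)
}

#' Baseline group comparisons for demographic and clinical variables
#'
#' For each requested variable, compares groups the way baseline tables in
#' this literature do: continuous variables with Welch's two-sample t-test,
#' binary variables with the two-sided Fisher exact test, and categorical
#' variables with more than two levels with the chi-square test. The default
#' comparison is healthy controls versus the relapsing-remitting group
#' (matching the published baseline table's footnote); `comparison =
#' "omnibus"` instead tests across all three groups (one-way ANOVA for
#' continuous variables, chi-square otherwise).
#'
#' @param data data frame with a `group` factor and the variables.
#' @param variables character vector of column names to compare.
#' @param comparison `"hc_vs_rr"` (default) or `"omnibus"`.
#' @return data frame: `variable`, `type` (continuous/binary/categorical),
#'   `test`, `statistic`, `p_value`, `n`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n = c(hc = 40, rr = 40, pms = 20)), seed = 2)
#' baseline_group_comparison(cohort, c("age", "bmi", "sex", "heart_problem"))
#' @export
baseline_group_comparison <- function(data, variables,
                                      comparison = c("hc_vs_rr", "omnibus")) {
  comparison <- match.arg(comparison)
  stopifnot(is.data.frame(data), "group" %in% names(data))
  missing_cols <- setdiff(variables, names(data))
  if (length(missing_cols) > 0L) {
    stop("variables absent from data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  sub <- if (comparison == "hc_vs_rr") {
    droplevels(data[data$group %in% c("HC", "RR"), , drop = FALSE])
  } else data

  rows <- lapply(variables, function(v) {
    x <- sub[[v]]
    g <- sub$group
    keep <- !is.na(x)
    x <- x[keep]; g <- droplevels(g[keep])
    if (is.numeric(x)) {
      if (stats::sd(x) == 0) {
        stop("variable '", v, "' has zero variance; t-test undefined",
             call. = FALSE)
      }
      if (comparison == "hc_vs_rr") {
        tt <- stats::t.test(x ~ g)
        data.frame(variable = v, type = "continuous", test = "t",
                   statistic = unname(tt$statistic), p_value = tt$p.value,
                   n = length(x), stringsAsFactors = FALSE)
      } else {
        av <- summary(stats::aov(x ~ g))[[1L]]
        data.frame(variable = v, type = "continuous", test = "anova_F",
                   statistic = av[["F value"]][1L], p_value = av[["Pr(>F)"]][1L],
                   n = length(x), stringsAsFactors = FALSE)
      }
    } else {
      f <- if (is.logical(x)) factor(x, levels = c(FALSE, TRUE)) else factor(x)
      tab <- table(g, f)
      if (nlevels(f) == 2L && nlevels(g) == 2L) {
        # Fisher exact for 2x2 regardless of cell counts
        ft <- stats::fisher.test(tab)
        data.frame(variable = v, type = "binary", test = "fisher",
                   statistic = NA_real_, p_value = ft$p.value,
                   n = length(x), stringsAsFactors = FALSE)
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab))
        data.frame(variable = v, type = "categorical", test = "chisq",
                   statistic = unname(ct$statistic), p_value = ct$p.value,
                   n = length(x), stringsAsFactors = FALSE)
      }
    }
  })
  do.call(rbind, rows)
}
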