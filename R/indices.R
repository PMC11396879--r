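#' Raw Inflammatory Vulnerability Index (IVX)
#'
#' Bilinear composite of GlycA (an NMR inflammation signal from glycan
#' residues of acute-phase glycoproteins) and small HDL particle
#' concentration (particles < 9 nm):
#' \deqn{IVX = 9 - 0.0027\,GlycA - 0.46079\,sHDLP + 0.0006325\,GlycA \times sHDLP}
#' The coefficients originate from a Cox proportional-hazards fit to 3-year
#' mortality and are taken as printed constants. No clamping is applied;
#' negative raw values are legitimate inputs to [anchor_score()].
#'
#' @param glyca GlycA concentration, µmol/L (finite, >= 0; NA propagates).
#' @param shdlp small HDL particle concentration, µmol/L of particles.
#' @return numeric vector of raw (dimensionless) index values.
#' @examples
#' raw_ivx(0, 0)      # 9
#' raw_ivx(400, 15)   # 4.80315
#' @export
raw_ivx <- function(glyca, shdlp) {
  check_concentration(glyca, "glyca")
  check_concentration(shdlp, "shdlp")
  9 - 0.0027 * glyca - 0.46079 * shdlp + 0.0006325 * glyca * shdlp
}

#' Raw Metabolic Malnutrition Index (MMX)
#'
#' Weighted sum of quadratics in leucine and valine, a linear isoleucine
#' term, and a quadratic in citrate (concentrations in µmol/L):
#' \deqn{MMX = 0.75097(4 - 0.02234\,Leu + 0.0000528\,Leu^2)
#'   + 0.55737(7 - 0.02895\,Val + 0.0000608\,Val^2)
#'   + 0.00867\,Ile
#'   + 0.65649(1 + 0.0025\,Cit + 0.0000167\,Cit^2)}
#'
#' @param leu,val,ile,cit leucine, valine, isoleucine, citrate (µmol/L).
#' @return numeric vector of raw index values.
#' @examples
#' raw_mmx(0, 0, 0, 0)  # 7.56196
#' @export
raw_mmx <- function(leu, val, ile, cit) {
  check_concentration(leu, "leu")
  check_concentration(val, "val")
  check_concentration(ile, "ile")
  check_concentration(cit, "cit")
  0.75097 * (4 - 0.02234 * leu + 0.0000528 * leu^2) +
    0.55737 * (7 - 0.02895 * val + 0.0000608 * val^2) +
    0.00867 * ile +
    0.65649 * (1 + 0.0025 * cit + 0.0000167 * cit^2)
}

#' Raw Metabolic Vulnerability Index (MVX)
#'
#' Combines the raw inflammatory and metabolic-malnutrition indices,
#' including their synergistic interaction:
#' \deqn{MVX = 2.72923\,IVX + 11.96062\,\ln(MMX) - 1.12749\,IVX \ln(MMX)}
#' Both arguments are the \emph{raw} (unscaled) indices; the 1-100 anchor
#' rescaling is applied only at the final score step.
#'
#' @param ivx_raw raw IVX from [raw_ivx()].
#' @param mmx_raw raw MMX from [raw_mmx()]; must be strictly positive
#'   (the logarithm is undefined otherwise).
#' @return numeric vector of raw index values.
#' @examples
#' raw_mvx(2.0, 1.0)  # ln(1) = 0, leaves 2.72923 * 2
#' @export
raw_mvx <- function(ivx_raw, mmx_raw) {
  check_finite(ivx_raw, "ivx_raw")
  check_finite(mmx_raw, "mmx_raw")
  bad <- !is.na(mmx_raw) & mmx_raw <= 0
  if (any(bad)) {
    stop(sprintf("mmx_raw must be > 0 for the logarithm (element %d: %g)",
                 which(bad)[1L], mmx_raw[bad][1L]), call. = FALSE)
  }
  lm_ <- log(mmx_raw)
  2.72923 * ivx_raw + 11.96062 * lm_ - 1.12749 * ivx_raw * lm_
}

#' Total branched-chain amino acids
#'
#' Sum of the valine, leucine, and isoleucine concentrations.
#'
#' @param val,leu,ile concentrations in µmol/L.
#' @return numeric vector, µmol/L.
#' @examples
#' bcaa_total(230, 130, 60)  # 420
#' @export
bcaa_total <- function(val, leu, ile) {
  check_concentration(val, "val")
  check_concentration(leu, "leu")
  check_concentration(ile, "ile")
  val + leu + ile
}

# analytes the index formulas consume; alanine is carried for the association
# analyses only and may be absent at scoring time
required_analytes <- c("valine", "leucine", "isoleucine", "citrate",
                       "glyca", "shdlp")

#' Compute all vulnerability scores for one metabolite panel
#'
#' Computes raw IVX, MMX, and MVX, rescales each to its 1-100 score via its
#' index's anchors, and totals the branched-chain amino acids. MVX is
#' evaluated on the raw (unscaled) IVX and MMX.
#'
#' @param panel named list or one-row data frame with (at least) `valine`,
#'   `leucine`, `isoleucine`, `citrate`, `glyca`, `shdlp` in µmol/L.
#'   `alanine` is optional: no index uses it.
#' @param anchors an [default_anchors()] object.
#' @return named list with `ivx_raw`, `mmx_raw`, `mvx_raw`, `ivx_score`,
#'   `mmx_score`, `mvx_score`, `bcaa`.
#' @examples
#' compute_scores(list(valine = 230, leucine = 130, isoleucine = 60,
#'                     citrate = 120, glyca = 400, shdlp = 15))
#' @export
compute_scores <- function(panel, anchors = default_anchors()) {
  missing_fields <- setdiff(required_analytes, names(panel))
  if (length(missing_fields) > 0L) {
    stop("panel is missing required analytes: ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  if (!inherits(anchors, "index_anchors")) {
    stop("'anchors' must be created with default_anchors()", call. = FALSE)
  }
  ivx <- raw_ivx(panel$glyca, panel$shdlp)
  mmx <- raw_mmx(panel$leucine, panel$valine, panel$isoleucine, panel$citrate)
  mvx <- raw_mvx(ivx, mmx)
  list(
    ivx_raw = ivx,
    mmx_raw = mmx,
    mvx_raw = mvx,
    ivx_score = anchor_score(ivx, anchors$ivx),
    mmx_score = anchor_score(mmx, anchors$mmx),
    mvx_score = anchor_score(mvx, anchors$mvx),
    bcaa = bcaa_total(panel$valine, panel$leucine, panel$isoleucine)
  )
}

#' Score a whole panel table
#'
#' Vectorized [compute_scores()] over a subjects-by-analytes table, appending
#' the seven score columns. Rows with NA in a required analyte receive NA
#' scores (missingness propagates, it is never imputed).
#'
#' @param panels data frame with one row per subject and the analyte columns
#'   of [compute_scores()] (plus anything else, e.g. `subject_id`).
#' @param anchors an [default_anchors()] object.
#' @return `panels` with columns `ivx_raw`, `mmx_raw`, `mvx_raw`,
#'   `ivx_score`, `mmx_score`, `mvx_score`, `bcaa` appended.
#' @export
score_panel <- function(panels, anchors = default_anchors()) {
  if (!is.data.frame(panels)) stop("'panels' must be a data frame", call. = FALSE)
  missing_fields <- setdiff(required_analytes, names(panels))
  if (length(missing_fields) > 0L) {
    stop("panel table is missing required analytes: ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  if (!inherits(anchors, "index_anchors")) {
    stop("'anchors' must be created with default_anchors()", call. = FALSE)
  }
  ivx <- raw_ivx(panels$glyca, panels$shdlp)
  mmx <- raw_mmx(panels$leucine, panels$valine, panels$isoleucine, panels$citrate)
  # raw_mvx() rejects non-positive MMX; NA rows must still pass through
  mvx <- rep(NA_real_, nrow(panels))
  ok <- !is.na(ivx) & !is.na(mmx)
  if (any(ok)) mvx[ok] <- raw_mvx(ivx[ok], mmx[ok])
  panels$ivx_raw <- ivx
  panels$mmx_raw <- mmx
  panels$mvx_raw <- mvx
  panels$ivx_score <- anchor_score(ivx, anchors$ivx)
  panels$mmx_score <- anchor_score(mmx, anchors$mmx)
  panels$mvx_score <- anchor_score(mvx, anchors$mvx)
  panels$bcaa <- bcaa_total(panels$valine, panels$leucine, panels$isoleucine)
  panels
}
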