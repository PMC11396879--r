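#' Published anchor pairs for the vulnerability indices
#'
#' Each index is reported on a 1-100 score scale obtained by rescaling the raw
#' index between two published anchor values: the raw value mapped to score 1
#' and the raw value mapped to score 100. The defaults are the published
#' anchors: IVX 2.0 / 8.3, MMX 1.281 / 2.0, MVX 20.3 / 28.0. They are
#' configuration, not constants: the published MMX and MVX anchors are not on
#' the scale the printed raw formulas produce at typical serum concentrations,
#' so studies recalibrating the score scale can supply their own pairs.
#'
#' @param ivx,mmx,mvx numeric length-2 vectors `c(raw_min, raw_max)`; the raw
#'   index values mapped to scores 1 and 100 respectively.
#' @return A named list of class `"index_anchors"` with components `ivx`,
#'   `mmx`, `mvx`, each a list with `raw_min` and `raw_max`.
#' @examples
#' default_anchors()
#' default_anchors(mmx = c(5, 9))  # recalibrated MMX scale
#' @export
default_anchors <- function(ivx = c(2.0, 8.3),
                            mmx = c(1.281, 2.0),
                            mvx = c(20.3, 28.0)) {
  mk <- function(x, name) {
    if (!is.numeric(x) || length(x) != 2L || anyNA(x) || !all(is.finite(x))) {
      stop(sprintf("anchors for %s must be two finite numbers", name),
           call. = FALSE)
    }
    if (x[1L] >= x[2L]) {
      stop(sprintf("anchors for %s are degenerate: raw_min (%g) must be < raw_max (%g)",
                   name, x[1L], x[2L]), call. = FALSE)
    }
    list(raw_min = x[1L], raw_max = x[2L])
  }
  structure(list(ivx = mk(ivx, "IVX"), mmx = mk(mmx, "MMX"),
                 mvx = mk(mvx, "MVX")),
            class = "index_anchors")
}

#' Rescale a raw index value to the 1-100 score scale
#'
#' Linear interpolation between the two anchor correspondences
#' (`raw_min` -> 1, `raw_max` -> 100), clamped to \[1, 100\]:
#' `score = 1 + 99 * (raw - raw_min) / (raw_max - raw_min)`.
#' Only the two endpoint correspondences are published; linear interpolation
#' is the simplest mapping consistent with both.
#'
#' @param raw numeric vector of raw index values (may be negative; only
#'   non-finite values are rejected).
#' @param anchors a list with `raw_min` and `raw_max` (one component of
#'   [default_anchors()]).
#' @return numeric vector of scores in \[1, 100\]; NA propagates.
#' @examples
#' anchor_score(2.0, default_anchors()$ivx)   # 1
#' anchor_score(8.3, default_anchors()$ivx)   # 100
#' anchor_score(5.15, default_anchors()$ivx)  # midpoint -> 50.5
#' @export
anchor_score <- function(raw, anchors) {
  if (!is.list(anchors) || is.null(anchors$raw_min) || is.null(anchors$raw_max)) {
    stop("'anchors' must contain raw_min and raw_max", call. = FALSE)
  }
  lo <- anchors$raw_min
  hi <- anchors$raw_max
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    stop(sprintf("degenerate anchors: raw_min (%g) must be < raw_max (%g)", lo, hi),
         call. = FALSE)
  }
  check_finite(raw, "raw")
  score <- 1 + 99 * (raw - lo) / (hi - lo)
  pmin(pmax(score, 1), 100)
}
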