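#' Rank-based tertile assignment with ntile semantics
#'
#' Splits the ranked non-missing values into `n` contiguous, near-equal
#' blocks, earlier blocks taking the extra members when the count is not
#' divisible by `n` (so 10 values give sizes 4, 3, 3). Ties are broken by
#' input order, making the assignment deterministic. In the source analyses
#' tertiles of the index scores are computed within the MS (RR + PMS)
#' population, so pass that subset's values.
#'
#' @param values numeric vector; NA values receive NA labels.
#' @param n number of groups (default 3, tertiles).
#' @return integer vector of labels in `1:n` (NA preserved).
#' @examples
#' assign_tertiles(c(5, 1, 9, 3, 7, 2, 8, 4, 6, 10))
#' @export
assign_tertiles <- function(values, n = 3L) {
  if (!is.numeric(values)) stop("'values' must be numeric", call. = FALSE)
  n <- as.integer(n)
  stopifnot(n >= 1L)
  n_obs <- sum(!is.na(values))
  if (n_obs == 0L) stop("all values missing; cannot assign tertiles", call. = FALSE)
  if (n_obs < n) {
    stop(sprintf("only %d non-missing values for %d groups", n_obs, n),
         call. = FALSE)
  }
  r <- rank(values, ties.method = "first", na.last = "keep")
  as.integer(floor(n * (r - 1) / n_obs) + 1L)
}
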