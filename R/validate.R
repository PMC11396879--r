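# Internal argument checking shared across the scoring functions.
# Concentrations must be finite and non-negative where observed; NA is an
# explicit missing value and propagates, it is never coerced to 0.

check_concentration <- function(x, field) {
  if (!is.numeric(x)) {
    stop(sprintf("'%s' must be numeric, got %s", field, class(x)[1L]),
         call. = FALSE)
  }
  bad <- (!is.na(x) & !is.finite(x)) | is.nan(x)
  if (any(bad)) {
    stop(sprintf("'%s' contains non-finite values (e.g. element %d)",
                 field, which(bad)[1L]), call. = FALSE)
  }
  neg <- !is.na(x) & x < 0
  if (any(neg)) {
    stop(sprintf("'%s' contains negative concentrations (e.g. element %d: %g)",
                 field, which(neg)[1L], x[neg][1L]), call. = FALSE)
  }
  invisible(x)
}

check_finite <- function(x, field) {
  if (!is.numeric(x)) {
    stop(sprintf("'%s' must be numeric", field), call. = FALSE)
  }
  bad <- (!is.na(x) & !is.finite(x)) | is.nan(x)
  if (any(bad)) {
    stop(sprintf("'%s' contains non-finite values", field), call. = FALSE)
  }
  invisible(x)
}

check_flag <- function(x, field) {
  if (!(is.logical(x) && length(x) == 1L && !is.na(x))) {
    stop(sprintf("'%s' must be TRUE or FALSE", field), call. = FALSE)
  }
  invisible(x)
}
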