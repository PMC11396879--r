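# Seed plumbing: every sampling stage draws from its own child stream derived
# deterministically from one root seed, so adding a stage never perturbs the
# draws of another. Streams use R's default Mersenne-Twister; the derivation
# is a fixed multiplicative hash kept inside 32-bit integer range.

child_seed <- function(root_seed, stage) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, is.finite(root_seed))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(root_seed) %% 2147483647 * 48271 + h) %% 2147483646 + 1)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}
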