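# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Printed report values use commercial rounding (0.5 always moves away from
#' zero), not the IEEE banker's rounding of [base::round()].
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @keywords internal
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Evaluate expr under a reproducible RNG substream derived from (seed, tag),
# restoring the caller's RNG state afterwards. Each generator uses its own
# tag so adding one generator never perturbs another's draws.
with_stream <- function(seed, tag, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  # fold the tag string into a 31-bit substream offset
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  set.seed((abs(as.integer(seed)) + h * 7919L) %% .Machine$integer.max)
  force(expr)
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
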