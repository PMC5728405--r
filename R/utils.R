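#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves going up (the convention of
#' printed report percentages), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(13.55, 1)  # 13.6
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x))
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
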