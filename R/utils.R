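# Small shared helpers.

#' Round half away from zero
#'
#' Rounds `x` to `digits` decimal places with ties going away from zero
#' (so 4.5 -> 5 and -4.5 -> -5), unlike [base::round()]'s round-half-even.
#' All percentages printed by the reporting functions use this rule.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector of the same length as `x`.
#' @examples
#' round_half_away(c(4.5, 1.76, -2.5))
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a count ratio as a whole percentage
#'
#' Renders `100 * numerator / denominator` as an integer percentage string,
#' rounding half away from zero: 8 of 170 renders as "5", 3 of 170 as "2".
#'
#' @param numerator,denominator non-negative counts (vectors recycle).
#' @return character vector of whole-number percentages.
#' @examples
#' format_percent(8, 170)
#' @export
format_percent <- function(numerator, denominator) {
  stopifnot(all(denominator > 0))
  formatC(round_half_away(100 * numerator / denominator), format = "d")
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tripod <- function(msg, class) {
  stop(structure(
    class = c(class, "tripod_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
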