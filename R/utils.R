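# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half-up to a fixed number of decimals
#'
#' Base `round()` rounds half to even; reported intersection percentages use
#' conventional half-up rounding (e.g. 100 * 132/922 = 14.316... -> 14.3,
#' 0.05 -> 0.1 at one decimal).
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_cellsig <- function(...) stop(sprintf(...), call. = FALSE)

# 0-based half-open [start, end) interval overlap (>= 1 base)
.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# convert 0-based half-open interval columns to an IRanges (1-based closed)
.as_iranges <- function(start0, end0) {
  IRanges::IRanges(start = start0 + 1L, end = end0)
}
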