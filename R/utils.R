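`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Decimal rounding with ties going up in absolute value (the convention used
#' by the published report tables), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(c(0.125, 53.0056), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stopifnot with a friendlier message
.assert <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

.is_prob <- function(x) is.numeric(x) && all(x >= 0 & x <= 1)

# canonical key for case-insensitive, whitespace-squashed string matching
.norm_key <- function(x) gsub("[[:space:]]+", " ", trimws(toupper(x)))
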