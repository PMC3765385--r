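#' Round half away from zero
#'
#' Standard commercial rounding, used for all reported figures (percentages to
#' one decimal, kappa to two) so that printed reports are stable across
#' platforms. `base::round()` rounds half to even, which would print 0.45 as
#' 0.4 in some locales of IEEE doubles; half-away-from-zero is what audit
#' reports conventionally use.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(0.5, 1.5, -0.5), 0)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Canonical form of a level code for matching: trimmed, internal whitespace
# squashed, en-dash folded to ASCII hyphen, case-insensitive.
normalize_code <- function(x) {
  x <- gsub("–", "-", x)
  x <- gsub("\\s+", " ", trimws(x))
  tolower(x)
}

# Separator between category and factor in wide audit-record column names.
FIELD_SEP <- "::"

field_name <- function(category, factor) paste(category, factor, sep = FIELD_SEP)

stop_fv <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
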