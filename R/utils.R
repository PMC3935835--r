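# Small shared helpers.

BASES <- c("A", "C", "G", "T")

#' Complement nucleotide characters
#'
#' Vectorised complement of `A/C/G/T` strings (no reversal).
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of the same length.
#' @keywords internal
#' @noRd
complement_bases <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# reverse-complement of a vector of strings
revcomp <- function(x) {
  vapply(strsplit(complement_bases(x), ""), function(ch)
    paste(rev(ch), collapse = ""), character(1))
}

# round half away from zero (printed tables report integers this way;
# base round() is banker's rounding)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

is_single_base <- function(x) x %in% BASES

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
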