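# Small shared helpers.

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; allele-length stratification uses
#' conventional half-up rounding so that a healthy mean of 10.5 units falls in
#' the 11-unit stratum.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) {
  floor(x + 0.5)
}

#' Reverse complement of a DNA string
#' @param x character vector of sequences over A/C/G/T.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Derive a 32-bit sub-seed from a base seed and a stream index so independent
# stages / patients get reproducible, non-overlapping-in-practice streams.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

stopf <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
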