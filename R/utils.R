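#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero on the
#' positive axis (0.05 -> 0.1), as in conventional clinical-report rounding.
#' Base \code{round()} rounds half to even, which would print 30.25 as 30.2;
#' allele-fraction percentages in reports use half-up.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 1).
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(30.25, 1)   # 30.3
#' round_half_up(29 / 96 * 100, 1)  # 30.2
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# stopifnot-style check with a formatted message
.check <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}

# %||% for default values
`%||%` <- function(a, b) if (is.null(a)) b else a

.DNA_BASES <- c("A", "C", "G", "T")

.check_dna <- function(seq, what = "sequence") {
  .check(is.character(seq) && length(seq) == 1L, "%s must be a single string", what)
  s <- toupper(seq)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), .DNA_BASES)
  .check(length(bad) == 0L, "%s contains non-ACGT characters: %s", what,
         paste(bad, collapse = ","))
  s
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
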