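# Internal helpers shared across modules.

#' Round half-up
#'
#' Base R rounds half to even; printed report tables in this field
#' conventionally round half away from zero. A small fuzz absorbs binary
#' representation error (e.g. 0.125 stored as 0.12499...).
#'
#' @param x numeric vector (non-negative in all internal uses).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.345), c(0, 0, 2))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Reverse complement of DNA strings
#'
#' @param x character vector over the alphabet A,C,G,T,N (case-insensitive).
#' @return character vector, uppercase.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANTGCAN", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

# Validate a DNA character vector; returns uppercased sequences.
check_dna <- function(x, what = "sequence", allow_empty = FALSE) {
  if (!is.character(x)) abort(sprintf("%s must be a character vector", what))
  x <- toupper(x)
  if (!allow_empty && any(!nzchar(x))) {
    abort(sprintf("empty %s not allowed", what))
  }
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains non-ACGTN characters (first offender: %s)",
      what, x[which(bad)[1]]
    ))
  }
  x
}

# Hamming distance between two equal-length strings (N mismatches everything,
# including another N).
hamming <- function(a, b) {
  ia <- utf8ToInt(a)
  ib <- utf8ToInt(b)
  stopifnot(length(ia) == length(ib))
  n_code <- utf8ToInt("N")
  sum(ia != ib | ia == n_code)
}

# Format a percent to 2 decimals for TSV output.
fmt_pct <- function(x) sprintf("%.2f", round_half_up(x, 2))
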