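# Pairwise alignment identities and scores (compiled Gotoh kernel).
#
# Two alignment modes are used in the pipeline:
#  * "global":      Needleman-Wunsch with end gaps penalized; used for
#                   within-sample clustering, where query and centroid are
#                   fragments of the same amplicon and should align end to end.
#  * "semi-global": query aligned globally, reference locally (free end gaps
#                   on the query relative to the reference); used for
#                   query-vs-reference scoring, where a short read may cover
#                   only part of a reference haplotype.
#
# Identity is matches / alignment columns; for the semi-global mode the free
# end-gap columns of the reference are excluded. An N never counts as a
# match.

#' Alignment scoring parameters
#'
#' Unit match score with configurable penalties. A gap of length k costs
#' `gap_open + (k - 1) * gap_extend`.
#'
#' @param match match score (default +1).
#' @param mismatch mismatch score (default -1).
#' @param gap_open cost of a length-1 gap (default 2).
#' @param gap_extend cost of each additional gap position (default 1).
#' @return list of class `trnl_align_params`.
#' @export
align_params <- function(match = 1, mismatch = -1, gap_open = 2, gap_extend = 1) {
  stopifnot(match > 0, mismatch <= 0, gap_open >= gap_extend, gap_extend > 0)
  structure(
    list(match = match, mismatch = mismatch,
         gap_open = gap_open, gap_extend = gap_extend),
    class = "trnl_align_params"
  )
}

# Align one query against many references in one call (compiled Gotoh
# kernel). type "global": both sequences end to end, end gaps penalized.
# type "semi": query global, reference overhangs free and excluded from the
# alignment columns.
align_one_vs_many <- function(query, refs, type = c("global", "semi"),
                              params = align_params()) {
  type <- match.arg(type)
  stopifnot(length(query) == 1, length(refs) >= 1)
  res <- .align_batch(query, refs,
    params$match, params$mismatch, params$gap_open, params$gap_extend,
    type == "semi", -1L
  )
  tibble(
    score = res$score,
    identity = ifelse(res$columns > 0, res$matches / res$columns, 0),
    aligned_length = res$columns
  )
}

#' Score a query sequence against a reference sequence
#'
#' Semi-global alignment: the query is aligned globally, with free end gaps
#' relative to the reference, so a query that is an exact substring of a
#' longer reference attains identity 1 over the covered columns. Identity is
#' matches / alignment columns excluding the reference's free end-gap
#' overhangs.
#'
#' @param query,ref DNA strings.
#' @param params alignment scoring parameters ([align_params()]).
#' @return one-row tibble with `score`, `identity`, `aligned_length`.
#' @export
#' @examples
#' score_pair("ACGTACGT", "ACGTACGT")
score_pair <- function(query, ref, params = align_params()) {
  query <- check_dna(query, "query")
  ref <- check_dna(ref, "reference")
  align_one_vs_many(query, ref, type = "semi", params = params)
}

# Global-alignment identity of one query against many candidate sequences,
# with two exact fast paths:
#  * identical strings: identity 1 without aligning;
#  * equal length and Hamming distance small enough that the gap-free
#    alignment is provably score-optimal under the default costs (any gapped
#    global alignment of equal-length sequences scores at most L - 5, below
#    the gap-free score L - 2h whenever h <= 2): identity (L - h) / L.
# Everything else goes through the compiled kernel, banded when a
# threshold is supplied: an alignment with identity >= t has at most
# ceil(L * (1 - t) / t) gap columns, so its path stays within that many
# diagonals of the corner-to-corner corridor and the banded optimum gives
# the same join/reject decision as the full DP. A length-ratio bound
# (identity <= min(L)/max(L), since columns >= max and matches <= min) lets
# callers skip candidates that cannot reach the threshold.
global_identity <- function(query, cands, params = align_params(),
                            threshold = NULL) {
  out <- numeric(length(cands))
  todo <- logical(length(cands))
  lq <- nchar(query)
  has_n <- grepl("N", query, fixed = TRUE)
  for (j in seq_along(cands)) {
    if (!has_n && query == cands[j] && !grepl("N", cands[j], fixed = TRUE)) {
      out[j] <- 1
    } else if (nchar(cands[j]) == lq) {
      h <- hamming(query, cands[j])
      if (h <= 2) out[j] <- (lq - h) / lq else todo[j] <- TRUE
    } else {
      todo[j] <- TRUE
    }
  }
  if (any(todo)) {
    band <- if (is.null(threshold)) -1L else
      as.integer(ceiling(lq * (1 - threshold) / threshold) + 2L)
    res <- .align_batch(query, cands[todo],
      params$match, params$mismatch, params$gap_open, params$gap_extend,
      FALSE, band
    )
    out[todo] <- ifelse(res$columns > 0, res$matches / res$columns, 0)
  }
  out
}
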