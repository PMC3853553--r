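# Primer-site location and insert extraction, shared by the reference-db
# builder (full trnL introns) and the read trimmer (amplicon reads).
#
# The forward primer is matched on the given strand; the reverse primer is
# matched as its reverse complement. Matching allows substitutions only (no
# indels inside primer sites); an N in the sequence never matches a primer
# base.

#' Universal trnL P6-loop primers g and h
#'
#' The standard chloroplast trnL (UAA) P6-loop primer pair: forward primer g
#' anneals in the 5' stem, reverse primer h in the 3' stem, so the insert
#' between them is the hypervariable P6 loop.
#'
#' @return named character vector with elements `g` and `h` (both written
#'   5'-3' as ordered).
#' @export
#' @examples
#' trnl_primers()
trnl_primers <- function() {
  c(g = "GGGCAATCCTGAGCCAA", h = "CCATTGAGTCTCTGCACCTATC")
}

# Locate primer sites in a batch of sequences.
# Returns a list of integer-matrix info per sequence: forward-site matches
# (start positions) and reverse-complement-site matches.
find_sites <- function(seqs, primer, max_mismatch) {
  set <- Biostrings::DNAStringSet(seqs)
  hits <- Biostrings::vmatchPattern(primer, set,
    max.mismatch = max_mismatch, with.indels = FALSE, fixed = TRUE
  )
  Biostrings::startIndex(hits)
}

# Collapse overlapping forward-site hits (windows closer than the primer
# length) into their leftmost representative; hits at least a full primer
# length apart count as distinct non-overlapping sites.
collapse_overlaps <- function(starts, plen) {
  if (is.null(starts) || !length(starts)) return(integer(0))
  starts <- sort(unique(starts))
  keep <- starts[1]
  for (s in starts[-1]) {
    if (s - keep[length(keep)] >= plen) keep <- c(keep, s)
  }
  keep
}

#' Extract the P6-loop insert between two primer sites
#'
#' Finds the forward-primer site and the reverse-complement of the
#' reverse-primer site within each sequence, allowing up to `max_mismatch`
#' substitutions per site (no indels), and returns the insert strictly
#' between them (primers excluded). Vectorized over sequences.
#'
#' @param seqs character vector of DNA sequences (e.g. full trnL introns or
#'   amplicon reads).
#' @param primer_fwd,primer_rev primer sequences, both 5'-3'; defaults to the
#'   universal g/h pair ([trnl_primers()]).
#' @param max_mismatch maximum substitutions tolerated inside each primer
#'   site (default 0).
#' @param on_ambiguous what to do when a sequence carries two or more
#'   non-overlapping forward-primer sites: `"error"` (default, reports the
#'   positions) or `"drop"` (returns `NA` for that sequence, for streaming
#'   read data).
#' @return character vector of inserts, `NA` where either site was not found
#'   (or, with `on_ambiguous = "drop"`, where the site was ambiguous).
#' @export
#' @examples
#' p <- trnl_primers()
#' intron <- paste0("AAAA", p[["g"]], "ACGTACGT", revcomp(p[["h"]]), "TTTT")
#' extract_p6(intron)
extract_p6 <- function(seqs, primer_fwd = trnl_primers()[["g"]],
                       primer_rev = trnl_primers()[["h"]],
                       max_mismatch = 0,
                       on_ambiguous = c("error", "drop")) {
  on_ambiguous <- match.arg(on_ambiguous)
  if (!nzchar(primer_fwd) || !nzchar(primer_rev)) abort("primers must be non-empty")
  if (max_mismatch < 0) abort("max_mismatch must be >= 0")
  if (!length(seqs)) return(character(0))
  seqs <- check_dna(seqs, "input sequence")
  primer_fwd <- check_dna(primer_fwd, "forward primer")
  rev_rc <- revcomp(check_dna(primer_rev, "reverse primer"))
  plen_f <- nchar(primer_fwd)
  plen_r <- nchar(rev_rc)

  fwd_hits <- find_sites(seqs, primer_fwd, max_mismatch)
  rev_hits <- find_sites(seqs, rev_rc, max_mismatch)

  out <- rep(NA_character_, length(seqs))
  for (i in seq_along(seqs)) {
    f <- collapse_overlaps(fwd_hits[[i]], plen_f)
    if (length(f) > 1) {
      if (on_ambiguous == "error") {
        abort(sprintf(
          "ambiguous primer site in sequence %d: non-overlapping forward-primer matches at positions %s",
          i, paste(f, collapse = ", ")
        ))
      }
      next
    }
    if (!length(f)) next
    insert_start <- f[1] + plen_f
    r <- sort(unique(rev_hits[[i]]))
    r <- r[r >= insert_start]
    if (!length(r)) next
    out[i] <- substr(seqs[i], insert_start, r[1] - 1)
  }
  out
}

#' Trim amplification primers off amplicon reads
#'
#' Applies the same primer-site contract as [extract_p6()] to demultiplexed
#' reads: the returned sequence is the insert strictly between the forward
#' primer and the reverse-complemented reverse primer. Reads with ambiguous
#' forward sites are dropped (logged as `NA`) rather than aborting a run.
#'
#' @inheritParams extract_p6
#' @param reads tibble with a `seq` column (e.g. from [demultiplex()]), or a
#'   plain character vector.
#' @param pass_through if `TRUE`, a read in which neither primer site is
#'   found is passed through unchanged (for data that arrive pre-trimmed);
#'   default `FALSE`, where such reads yield `NA`.
#' @return the input tibble with `seq` replaced by the trimmed insert and a
#'   `trim_ok` logical column (for a character input, a character vector
#'   with `NA` for failed reads).
#' @export
trim_primers <- function(reads, primer_fwd = trnl_primers()[["g"]],
                         primer_rev = trnl_primers()[["h"]],
                         max_mismatch = 0, pass_through = FALSE) {
  vec_input <- is.character(reads)
  seqs <- if (vec_input) reads else reads$seq
  trimmed <- extract_p6(seqs, primer_fwd, primer_rev,
    max_mismatch = max_mismatch, on_ambiguous = "drop"
  )
  if (pass_through) {
    no_site <- is.na(trimmed)
    trimmed[no_site] <- toupper(seqs[no_site])
  }
  if (vec_input) return(trimmed)
  reads$seq <- trimmed
  reads$trim_ok <- !is.na(trimmed)
  reads
}
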