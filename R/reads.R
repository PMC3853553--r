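# Read processing: MID demultiplexing, dereplication, greedy centroid
# clustering at 98% global-alignment identity, and the length/abundance
# cluster filters.

#' Demultiplex MID-tagged reads
#'
#' Routes each read to the unique sample whose MID tag matches the read
#' prefix within `max_mid_mismatch` substitutions, and strips the tag from
#' routed reads. Reads matching no tag, or two or more tags at the same
#' minimal distance, are left unassigned.
#'
#' @param reads tibble with columns `read_id`, `seq` (from [read_fasta()] /
#'   [read_fastq()] or the simulator).
#' @param mids MID map tibble (`mid_tag`, `sample_id`); validated with
#'   [validate_mid_map()].
#' @param max_mid_mismatch maximum substitutions tolerated in the tag
#'   prefix (default 0, exact matching).
#' @return the input tibble with a `sample_id` column (`NA` = unassigned)
#'   and tags stripped from assigned reads.
#' @export
demultiplex <- function(reads, mids, max_mid_mismatch = 0) {
  mids <- validate_mid_map(mids)
  stopifnot(max_mid_mismatch >= 0)
  if (!nrow(reads)) {
    reads$sample_id <- character(0)
    return(reads)
  }
  seqs <- check_dna(reads$seq, "read")
  if (max_mid_mismatch == 0) {
    # exact prefix matching; prefix-uniqueness guarantees at most one hit
    hit_tag <- rep(NA_integer_, length(seqs))
    for (L in unique(nchar(mids$mid_tag))) {
      j <- match(substr(seqs, 1, L), mids$mid_tag)
      hit_tag[is.na(hit_tag) & !is.na(j)] <- j[is.na(hit_tag) & !is.na(j)]
    }
    # an N never matches, even an N in the tag itself
    pref_n <- !is.na(hit_tag) &
      grepl("N", substr(seqs, 1, nchar(mids$mid_tag)[pmax(hit_tag, 1L)]), fixed = TRUE)
    hit <- !is.na(hit_tag) & !pref_n
    reads$sample_id <- ifelse(hit, mids$sample_id[hit_tag], NA_character_)
    tag_len <- nchar(mids$mid_tag)[hit_tag]
    reads$seq <- ifelse(hit, substr(seqs, tag_len + 1, nchar(seqs)), seqs)
    return(reads)
  }
  n_code <- utf8ToInt("N")
  dmat <- matrix(NA_integer_, nrow(reads), nrow(mids))
  for (j in seq_len(nrow(mids))) {
    tag <- mids$mid_tag[j]
    L <- nchar(tag)
    pref <- substr(seqs, 1, L)
    tag_int <- utf8ToInt(tag)
    dmat[, j] <- vapply(pref, function(p) {
      if (nchar(p) < L) return(L)
      pi <- utf8ToInt(p)
      sum(pi != tag_int | pi == n_code)
    }, integer(1), USE.NAMES = FALSE)
  }
  best <- apply(dmat, 1, min)
  n_best <- rowSums(dmat == best)
  hit <- best <= max_mid_mismatch & n_best == 1
  which_tag <- max.col(-dmat, ties.method = "first")
  reads$sample_id <- ifelse(hit, mids$sample_id[which_tag], NA_character_)
  tag_len <- nchar(mids$mid_tag)[which_tag]
  reads$seq <- ifelse(hit, substr(seqs, tag_len + 1, nchar(seqs)), seqs)
  reads
}

#' Dereplicate sequences
#'
#' Collapses identical sequences to (sequence, count) pairs, sorted by
#' decreasing count with ties broken lexicographically, so downstream greedy
#' clustering is deterministic under any input shuffle.
#'
#' @param seqs character vector of sequences, or a tibble with a `seq`
#'   column.
#' @return tibble with columns `seq`, `count`.
#' @export
#' @examples
#' dereplicate(c("AA", "AA", "CC"))
dereplicate <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  if (!length(seqs)) return(tibble(seq = character(), count = integer()))
  tb <- table(seqs)
  out <- tibble(seq = names(tb), count = as.integer(tb))
  out[order(-out$count, out$seq), ]
}

#' Pre-clustering read quality screen
#'
#' Rejects reads whose trimmed insert is missing (primer sites not found),
#' shorter than the forward primer, or composed of more than `max_n_frac`
#' ambiguous bases; alignment identity is not meaningfully defined for such
#' fragments.
#'
#' @param reads tibble with `seq` (possibly `NA` after [trim_primers()]).
#' @param primer_fwd forward primer (its length sets the minimum usable read
#'   length).
#' @param max_n_frac maximum tolerated fraction of N bases (default 0.10).
#' @return the input tibble with a `reject_reason` column (`NA` = kept).
#' @export
screen_reads <- function(reads, primer_fwd = trnl_primers()[["g"]],
                         max_n_frac = 0.10) {
  len <- nchar(reads$seq)
  n_frac <- ifelse(len > 0,
    stringr::str_count(reads$seq, "N") / len, 1
  )
  reads$reject_reason <- dplyr::case_when(
    is.na(reads$seq) ~ "primer site not found",
    len < nchar(primer_fwd) ~ "shorter than forward primer",
    n_frac > max_n_frac ~ "more than 10% ambiguous bases",
    TRUE ~ NA_character_
  )
  reads
}

#' Greedy centroid clustering of dereplicated reads
#'
#' Scans the dereplicated sequences in their deterministic order (decreasing
#' count, ties lexicographic). Each sequence joins the first existing
#' cluster whose centroid it matches at global-alignment identity >=
#' `identity_threshold` (end gaps penalized), else founds a new cluster. The
#' centroid of every cluster is its founding -- and therefore most abundant
#' -- member. This is the standard functional replacement for contig
#' assembly of short single-locus amplicons at a 98% match.
#'
#' @param uniques tibble from [dereplicate()] (`seq`, `count`).
#' @param identity_threshold clustering identity in (0, 1] (default 0.98).
#' @param params alignment scoring parameters ([align_params()]).
#' @return tibble with columns `cluster_id`, `centroid_seq`, `read_count`
#'   and a `members` list-column of (seq, count) tibbles.
#' @export
cluster_reads <- function(uniques, identity_threshold = 0.98,
                          params = align_params()) {
  if (identity_threshold <= 0 || identity_threshold > 1) {
    abort("identity_threshold must be in (0, 1]")
  }
  n <- nrow(uniques)
  if (!n) {
    return(tibble(
      cluster_id = character(), centroid_seq = character(),
      read_count = integer(), members = list()
    ))
  }
  ord <- order(-uniques$count, uniques$seq)
  uniques <- uniques[ord, ]
  centroids <- character(0)
  centroid_len <- integer(0)
  assignment <- integer(n)
  for (i in seq_len(n)) {
    s <- uniques$seq[i]
    ls <- nchar(s)
    joined <- 0L
    if (length(centroids)) {
      # identity can never exceed min(len)/max(len): skip hopeless candidates
      ratio <- pmin(centroid_len, ls) / pmax(centroid_len, ls)
      cand <- which(ratio >= identity_threshold)
      if (length(cand)) {
        ident <- global_identity(s, centroids[cand], params, threshold = identity_threshold)
        ok <- which(ident >= identity_threshold)
        if (length(ok)) joined <- cand[ok[1]]
      }
    }
    if (joined == 0L) {
      centroids <- c(centroids, s)
      centroid_len <- c(centroid_len, ls)
      joined <- length(centroids)
    }
    assignment[i] <- joined
  }
  members <- purrr::map(seq_along(centroids), function(k) {
    uniques[assignment == k, c("seq", "count")]
  })
  tibble(
    cluster_id = sprintf("C%04d", seq_along(centroids)),
    centroid_seq = centroids,
    read_count = purrr::map_int(members, ~ sum(.x$count)),
    members = members
  )
}

#' Filter clusters by centroid length and read abundance
#'
#' Retains clusters whose centroid is at least `min_length` bp long and that
#' contain at least `min_reads` reads; short fragments and rare clusters are
#' typical sequencing artifacts. The boundary values are retained (a 40 bp
#' centroid passes the default length filter; a 4-read cluster passes the
#' default abundance filter).
#'
#' @param clusters tibble from [cluster_reads()].
#' @param min_length minimum centroid length in bp (default 40).
#' @param min_reads minimum reads per cluster (default 4).
#' @return the input tibble with `retained` (logical) and `discard_reason`
#'   (`NA` for retained clusters) columns.
#' @export
filter_clusters <- function(clusters, min_length = 40, min_reads = 4) {
  len <- nchar(clusters$centroid_seq)
  clusters$discard_reason <- dplyr::case_when(
    len < min_length & clusters$read_count < min_reads ~
      "centroid shorter than minimum; fewer reads than minimum",
    len < min_length ~ "centroid shorter than minimum length",
    clusters$read_count < min_reads ~ "fewer reads than minimum",
    TRUE ~ NA_character_
  )
  clusters$retained <- is.na(clusters$discard_reason)
  clusters
}

#' Process one sample's demultiplexed reads end to end
#'
#' Convenience wrapper: primer trim, quality screen, dereplicate, cluster,
#' filter. Returns every intermediate needed for read bookkeeping.
#'
#' @param reads tibble of one sample's reads (`read_id`, `seq`).
#' @param identity_threshold,min_length,min_reads,params,max_mismatch see
#'   the individual stage functions.
#' @param primer_fwd,primer_rev amplification primers.
#' @return list with `clusters` (filtered, all clusters with `retained`
#'   flag), `rejected` (tibble of screened-out reads with reasons), and
#'   `counts` (named integer vector of stage bookkeeping).
#' @export
process_sample_reads <- function(reads,
                                 primer_fwd = trnl_primers()[["g"]],
                                 primer_rev = trnl_primers()[["h"]],
                                 max_mismatch = 0,
                                 identity_threshold = 0.98,
                                 min_length = 40, min_reads = 4,
                                 params = align_params()) {
  trimmed <- trim_primers(reads, primer_fwd, primer_rev, max_mismatch = max_mismatch)
  screened <- screen_reads(trimmed, primer_fwd)
  kept <- screened[is.na(screened$reject_reason), ]
  rejected <- screened[!is.na(screened$reject_reason), c("read_id", "reject_reason")]
  uniques <- dereplicate(kept$seq)
  clusters <- cluster_reads(uniques, identity_threshold, params)
  clusters <- filter_clusters(clusters, min_length, min_reads)
  counts <- c(
    input = nrow(reads), rejected = nrow(rejected),
    clustered = if (nrow(clusters)) sum(clusters$read_count) else 0L,
    retained = if (nrow(clusters)) sum(clusters$read_count[clusters$retained]) else 0L
  )
  list(clusters = clusters, rejected = rejected, counts = counts)
}
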