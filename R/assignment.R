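# Taxonomic assignment of retained clusters: best semi-global alignment
# score against the haplotype-group references, exact-score ties resolved to
# the lowest taxonomic level containing all tied taxa.

#' Best-scoring reference groups for a query
#'
#' Scores the query against every haplotype-group sequence (semi-global, see
#' [score_pair()]) and returns all groups attaining the maximal score among
#' those passing the identity and aligned-length thresholds. Exact score
#' equality defines a tie: unit-cost integer scoring makes ties well
#' defined, with no tolerance band.
#'
#' @param query DNA string (cluster centroid).
#' @param groups haplotype groups tibble ([build_haplotype_groups()]).
#' @param min_identity minimum alignment identity (default 0.95).
#' @param min_aligned minimum alignment columns (default 40).
#' @param params alignment scoring parameters.
#' @return tibble of top-scoring groups with `score`, `identity`,
#'   `aligned_length` columns appended; zero rows if no group passes.
#' @export
best_hits <- function(query, groups, min_identity = 0.95, min_aligned = 40,
                      params = align_params()) {
  if (!nrow(groups)) abort("no reference loaded")
  query <- check_dna(query, "query")
  # exact shortcut: a reference containing the full query as a substring
  # attains the maximal possible semi-global score (every query base a
  # match), so no other reference can tie or beat it
  if (!grepl("N", query, fixed = TRUE)) {
    exact <- stringr::str_detect(groups$p6_seq, stringr::fixed(query))
    if (any(exact)) {
      lq <- nchar(query)
      res <- groups[exact, ]
      res$score <- lq * params$match
      res$identity <- 1
      res$aligned_length <- lq
      if (1 >= min_identity && lq >= min_aligned) return(res) else
        return(res[0, ])
    }
  }
  scored <- align_one_vs_many(query, groups$p6_seq, type = "semi", params = params)
  res <- dplyr::bind_cols(groups, scored)
  res <- res[res$identity >= min_identity & res$aligned_length >= min_aligned, ]
  if (!nrow(res)) return(res)
  res[res$score == max(res$score), ]
}

#' Lowest-common-ancestor label for a set of tied groups
#'
#' A single group keeps its own label and rank. For several tied groups the
#' assignment is lifted to the lowest rank whose single taxon contains every
#' member species of every group; a tie spanning two families rises above
#' the family rank and is reported as unassigned.
#'
#' @param tied tibble of tied haplotype groups (rows of the groups table).
#' @param taxonomy taxonomy tibble.
#' @return list with `label` and `rank` (one of `species`, `genus`,
#'   `family`, `unassigned`).
#' @export
lca_label <- function(tied, taxonomy) {
  if (!nrow(tied)) return(list(label = "unassigned", rank = "unassigned"))
  if (nrow(tied) == 1) {
    return(list(label = tied$label[1], rank = tied$label_rank[1]))
  }
  species <- unique(unlist(tied$members))
  lct <- lowest_covering_taxon(species, taxonomy)
  if (lct$rank == "above_family") {
    list(label = "unassigned", rank = "unassigned")
  } else {
    list(label = lct$label, rank = lct$rank)
  }
}

#' Assign retained clusters to plant taxa
#'
#' One assignment per retained cluster: best hits against the haplotype
#' groups, LCA tie resolution, and a tally of reads in clusters with no
#' acceptable hit. Read counts are copied unchanged from the clusters, so
#' assigned plus unassigned reads always equals the retained-cluster total.
#'
#' @param clusters tibble with columns `sample_id`, `cluster_id`,
#'   `centroid_seq`, `read_count` (retained clusters, typically from
#'   [process_sample_reads()] / [run_pipeline()]).
#' @param groups haplotype groups tibble.
#' @param taxonomy taxonomy tibble.
#' @inheritParams best_hits
#' @return tibble with one row per cluster: `sample_id`, `cluster_id`,
#'   `label`, `rank` (`species`/`genus`/`family`/`unassigned`),
#'   `read_count`, `best_identity` (`NA` when nothing passed), and a
#'   `tied_groups` list-column of group ids.
#' @export
assign_clusters <- function(clusters, groups, taxonomy,
                            min_identity = 0.95, min_aligned = 40,
                            params = align_params()) {
  taxonomy <- validate_taxonomy(taxonomy)
  if (!nrow(clusters)) {
    return(tibble(
      sample_id = character(), cluster_id = character(), label = character(),
      rank = character(), read_count = integer(),
      best_identity = double(), tied_groups = list()
    ))
  }
  rows <- purrr::map(seq_len(nrow(clusters)), function(i) {
    hits <- best_hits(clusters$centroid_seq[i], groups,
      min_identity = min_identity, min_aligned = min_aligned, params = params
    )
    lab <- lca_label(hits, taxonomy)
    tibble(
      sample_id = clusters$sample_id[i],
      cluster_id = clusters$cluster_id[i],
      label = lab$label,
      rank = lab$rank,
      read_count = clusters$read_count[i],
      best_identity = if (nrow(hits)) max(hits$identity) else NA_real_,
      tied_groups = list(sort(hits$group_id %||% character(0)))
    )
  })
  bind_rows(rows)
}

#' Summarize unassigned reads
#'
#' @param assignments tibble from [assign_clusters()].
#' @return one-row tibble with total, assigned and unassigned read counts.
#' @export
assignment_tally <- function(assignments) {
  un <- assignments$rank == "unassigned"
  tibble(
    total_reads = sum(assignments$read_count),
    assigned_reads = sum(assignments$read_count[!un]),
    unassigned_reads = sum(assignments$read_count[un])
  )
}
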