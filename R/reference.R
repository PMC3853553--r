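# Reference database: P6 extraction from full introns, exact-identity
# haplotype grouping with lowest-covering-rank labels, and discrimination
# statistics.

#' Build a P6-loop reference database from full trnL intron sequences
#'
#' Extracts the P6 insert from each intron with [extract_p6()], applies a
#' plausibility length filter, and collapses the result into haplotype
#' groups with [build_haplotype_groups()].
#'
#' @param refs tibble with columns `species_id` and `intron_seq` (or a
#'   pre-extracted `p6_seq` column, in which case extraction is skipped).
#' @param taxonomy taxonomy tibble (see [validate_taxonomy()]).
#' @inheritParams extract_p6
#' @param p6_length_range plausible insert length range; inserts outside it
#'   are dropped with a warning (default `c(50, 200)`; observed amplicons in
#'   well-curated P6 databases run roughly 66-148 bp).
#' @return list with elements `refs` (tibble `species_id`, `p6_seq`, dropped
#'   species excluded), `groups` (haplotype groups) and `dropped` (tibble of
#'   excluded species with reasons).
#' @export
build_reference_db <- function(refs, taxonomy,
                               primer_fwd = trnl_primers()[["g"]],
                               primer_rev = trnl_primers()[["h"]],
                               max_mismatch = 0,
                               p6_length_range = c(50, 200)) {
  taxonomy <- validate_taxonomy(taxonomy)
  if (anyDuplicated(refs$species_id)) {
    abort(paste(
      "duplicate species_id in reference input:",
      paste(unique(refs$species_id[duplicated(refs$species_id)]), collapse = ", ")
    ))
  }
  if (!"p6_seq" %in% names(refs)) {
    refs$p6_seq <- extract_p6(refs$intron_seq, primer_fwd, primer_rev,
      max_mismatch = max_mismatch, on_ambiguous = "error"
    )
  } else {
    refs$p6_seq <- toupper(refs$p6_seq)
  }
  len <- nchar(refs$p6_seq)
  reason <- dplyr::case_when(
    is.na(refs$p6_seq) ~ "primer site not found",
    len < p6_length_range[1] ~ "P6 insert shorter than plausible range",
    len > p6_length_range[2] ~ "P6 insert longer than plausible range",
    TRUE ~ NA_character_
  )
  dropped <- tibble(species_id = refs$species_id, reason = reason) |>
    filter(!is.na(.data$reason))
  if (nrow(dropped)) {
    warn(sprintf("%d reference species dropped during P6 extraction", nrow(dropped)))
  }
  kept <- refs[is.na(reason), c("species_id", "p6_seq")]
  groups <- build_haplotype_groups(kept, taxonomy)
  list(refs = as_tibble(kept), groups = groups, dropped = dropped)
}

# Lowest single taxon (and its rank) containing all given species.
# Returns list(label, rank) with rank in species/genus/family/above_family.
lowest_covering_taxon <- function(species, taxonomy) {
  rows <- taxonomy[match(species, taxonomy$species_id), ]
  if (anyNA(rows$species_id)) {
    abort(paste(
      "species missing from taxonomy:",
      paste(setdiff(species, taxonomy$species_id), collapse = ", ")
    ))
  }
  if (length(unique(rows$species_id)) == 1) {
    list(label = rows$species_id[1], rank = "species")
  } else if (length(unique(rows$genus)) == 1) {
    list(label = rows$genus[1], rank = "genus")
  } else if (length(unique(rows$family)) == 1) {
    list(label = rows$family[1], rank = "family")
  } else {
    list(label = "Plantae", rank = "above_family")
  }
}

#' Collapse reference sequences into haplotype groups
#'
#' Partitions the reference set by exact (case-insensitive) P6 sequence
#' identity. A single-member group is labelled with its species name; a
#' multi-member group is labelled `"Gr. <taxon><k>"`, where `<taxon>` is the
#' lowest single taxon containing every member (genus, family, or the
#' above-family root) and `k` numbers the groups sharing that taxon in order
#' of first appearance (e.g. `"Gr. Lauraceae1"`).
#'
#' @param refs tibble with columns `species_id` and `p6_seq` (all present).
#' @param taxonomy taxonomy tibble.
#' @return tibble with columns `group_id`, `p6_seq`, `label`, `label_rank`,
#'   `n_members` and a `members` list-column of species ids. Empty input
#'   gives an empty tibble.
#' @export
build_haplotype_groups <- function(refs, taxonomy) {
  taxonomy <- validate_taxonomy(taxonomy)
  if (anyDuplicated(refs$species_id)) {
    abort("duplicate species_id in reference input")
  }
  if (!nrow(refs)) {
    return(tibble(
      group_id = character(), p6_seq = character(), label = character(),
      label_rank = character(), n_members = integer(), members = list()
    ))
  }
  if (anyNA(refs$p6_seq)) abort("all reference sequences must have a P6 sequence")
  seqs <- toupper(refs$p6_seq)
  first_seen <- match(unique(seqs), seqs)
  groups <- tibble(
    p6_seq = seqs[first_seen],
    members = purrr::map(seqs[first_seen], ~ refs$species_id[seqs == .x])
  )
  lca <- purrr::map(groups$members, lowest_covering_taxon, taxonomy = taxonomy)
  groups$label_rank <- purrr::map_chr(lca, "rank")
  base_label <- purrr::map_chr(lca, "label")
  groups$n_members <- lengths(groups$members)
  multi <- groups$n_members > 1
  # number multi-member groups per covering taxon in order of first appearance
  k <- stats::ave(seq_len(nrow(groups)), base_label,
    FUN = function(i) cumsum(rep(1, length(i)))
  )
  groups$label <- ifelse(multi, paste0("Gr. ", base_label, k), base_label)
  groups$group_id <- sprintf("H%04d", seq_len(nrow(groups)))
  groups[, c("group_id", "p6_seq", "label", "label_rank", "n_members", "members")]
}

#' Taxonomic discrimination rates of a reference database
#'
#' * `Rs` (species level): distinct P6 sequences / species, as a percent.
#' * `Rg` (genus level): genera possessing at least one sequence found in no
#'   other genus / total genera, as a percent.
#' * `Rf` (per family): distinct sequences among the family's species /
#'   species in the family, as a percent.
#'
#' All rates are rounded half-up to integer percent, the convention of
#' printed discrimination tables. A single-species family always has
#' `Rf = 100`.
#'
#' @param groups haplotype groups from [build_haplotype_groups()].
#' @param taxonomy taxonomy tibble; only species that appear in `groups` are
#'   counted.
#' @return object of class `trnl_discrimination`: a list with `Rs`, `Rg`,
#'   `by_family` (tibble `family`, `n_species`, `n_sequences`, `Rf_percent`),
#'   and the counts `n_species`, `n_genera`, `n_families`,
#'   `n_distinct_sequences`. Has [tidy()] and [glance()] methods.
#' @export
discrimination_rates <- function(groups, taxonomy) {
  taxonomy <- validate_taxonomy(taxonomy)
  species <- unlist(groups$members)
  if (!length(species)) abort("empty database: no species with sequences")
  tax <- taxonomy[taxonomy$species_id %in% species, ]

  n_species <- nrow(tax)
  n_distinct <- nrow(groups)
  rs <- round_half_up(100 * n_distinct / n_species)

  # genus-exclusive sequences: groups whose members all belong to one genus
  genus_of <- setNames(tax$genus, tax$species_id)
  group_genera <- purrr::map(groups$members, ~ unique(genus_of[.x]))
  exclusive_genus <- unlist(group_genera[lengths(group_genera) == 1])
  n_genera <- length(unique(tax$genus))
  rg <- round_half_up(100 * length(unique(exclusive_genus)) / n_genera)

  fam_of <- setNames(tax$family, tax$species_id)
  per_fam_members <- split(tax$species_id, tax$family)
  by_family <- purrr::imap(per_fam_members, function(sp, fam) {
    n_seq <- sum(purrr::map_lgl(groups$members, ~ any(.x %in% sp)))
    tibble(
      family = fam, n_species = length(sp), n_sequences = n_seq,
      Rf_percent = round_half_up(100 * n_seq / length(sp))
    )
  }) |>
    bind_rows() |>
    arrange(.data$family)

  structure(
    list(
      Rs = rs, Rg = rg, by_family = by_family,
      n_species = n_species, n_genera = n_genera,
      n_families = length(per_fam_members),
      n_distinct_sequences = n_distinct
    ),
    class = "trnl_discrimination"
  )
}

#' @export
print.trnl_discrimination <- function(x, ...) {
  cat(sprintf(
    "P6-loop discrimination: %d species, %d genera, %d families, %d distinct sequences\n",
    x$n_species, x$n_genera, x$n_families, x$n_distinct_sequences
  ))
  cat(sprintf("  Rs = %d%%   Rg = %d%%   Rf range = %d-%d%%\n",
    x$Rs, x$Rg, min(x$by_family$Rf_percent), max(x$by_family$Rf_percent)
  ))
  invisible(x)
}

#' @method tidy trnl_discrimination
#' @export
tidy.trnl_discrimination <- function(x, ...) x$by_family

#' @method glance trnl_discrimination
#' @export
glance.trnl_discrimination <- function(x, ...) {
  tibble(
    Rs = x$Rs, Rg = x$Rg,
    n_species = x$n_species, n_genera = x$n_genera,
    n_families = x$n_families, n_distinct_sequences = x$n_distinct_sequences
  )
}

#' Export haplotype groups as a plain table
#'
#' @param groups haplotype groups tibble.
#' @return tibble with `members` flattened to a comma-separated column,
#'   suitable for [write_tsv_file()].
#' @export
groups_table <- function(groups) {
  groups |>
    mutate(members = purrr::map_chr(.data$members, paste, collapse = ",")) |>
    select("group_id", "label", "label_rank", "n_members", "members", "p6_seq")
}
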