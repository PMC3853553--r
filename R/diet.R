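# Diet summaries: the samples-by-taxa read-count matrix, frequency of reads
# (F_R) and of presence (F_P), per-sample richness, richness comparison
# between detection methods, monthly composition, and origin annotation.

#' Build the samples-by-taxa diet matrix
#'
#' Sums reads over clusters of the same sample assigned to the same label
#' and spreads to a wide samples x labels table. Unassigned clusters are
#' excluded: every frequency downstream uses assigned reads only.
#'
#' @param assignments tibble from [assign_clusters()].
#' @return tibble with a `sample_id` column and one integer read-count
#'   column per assigned label.
#' @export
diet_matrix <- function(assignments) {
  x <- assignments |>
    filter(.data$rank != "unassigned") |>
    group_by(.data$sample_id, .data$label) |>
    summarise(reads = sum(.data$read_count), .groups = "drop")
  if (!nrow(x)) return(tibble(sample_id = character()))
  tidyr::pivot_wider(x,
    names_from = "label", values_from = "reads", values_fill = 0L
  ) |>
    arrange(.data$sample_id)
}

# counts matrix (samples x labels) from a diet tibble
diet_counts <- function(diet) {
  m <- as.matrix(diet[, setdiff(names(diet), "sample_id"), drop = FALSE])
  rownames(m) <- diet$sample_id
  storage.mode(m) <- "double"
  m
}

#' Frequency of sequence reads (F_R) per food item
#'
#' F_R of a label is 100 x its total reads across samples divided by the
#' total assigned reads over all labels, rounded half-up to 2 decimals (the
#' printed-table convention). F_R is scale-invariant: doubling every count
#' changes nothing.
#'
#' @param diet diet matrix tibble ([diet_matrix()]), or a tibble with
#'   columns `label` and `n_reads` for pre-pooled per-taxon counts.
#' @return tibble with `label`, `n_reads`, `F_R` (percent), sorted by
#'   decreasing reads.
#' @export
frequency_of_reads <- function(diet) {
  if (all(c("label", "n_reads") %in% names(diet))) {
    totals <- tibble(label = diet$label, n_reads = diet$n_reads)
  } else {
    m <- diet_counts(diet)
    totals <- tibble(label = colnames(m), n_reads = unname(colSums(m)))
  }
  denom <- sum(totals$n_reads)
  if (denom <= 0) abort("no assigned reads: F_R undefined")
  totals |>
    mutate(F_R = round_half_up(100 * .data$n_reads / denom, 2)) |>
    arrange(desc(.data$n_reads), .data$label)
}

#' Frequency of presence (F_P) per food item
#'
#' F_P of a label is 100 x the number of samples in which it was observed
#' divided by an explicit denominator. The denominator is a parameter
#' because detection methods compared on the same sample set may have
#' different usable sample totals (e.g. 48 samples sequenced but 47 with
#' material left for microscopy).
#'
#' @param diet diet matrix tibble (any positive cell is a presence).
#' @param denominator total number of samples; defaults to the number of
#'   rows of `diet`.
#' @return tibble with `label`, `n_samples_present`, `F_P` (percent).
#' @export
frequency_of_presence <- function(diet, denominator = nrow(diet)) {
  stopifnot(denominator > 0)
  m <- diet_counts(diet)
  pres <- unname(colSums(m > 0))
  tibble(
    label = colnames(m),
    n_samples_present = pres,
    F_P = round_half_up(100 * pres / denominator, 2)
  ) |>
    arrange(desc(.data$n_samples_present), .data$label)
}

#' Per-sample taxon richness
#'
#' Counts the labels detected (cell > 0) in each sample.
#'
#' @param diet diet matrix tibble.
#' @return tibble with `sample_id`, `richness`; the mean and sample
#'   standard deviation (n - 1 denominator) are attached as attributes
#'   `mean` and `sd` and shown by [richness_summary()].
#' @export
taxa_per_sample <- function(diet) {
  m <- diet_counts(diet)
  out <- tibble(sample_id = rownames(m), richness = as.integer(rowSums(m > 0)))
  attr(out, "mean") <- mean(out$richness)
  attr(out, "sd") <- sd(out$richness)
  out
}

#' Summarize a richness vector
#' @param richness tibble from [taxa_per_sample()] or a numeric vector.
#' @return one-row tibble with `n`, `mean`, `sd`.
#' @export
richness_summary <- function(richness) {
  r <- if (is.data.frame(richness)) richness$richness else richness
  tibble(n = length(r), mean = mean(r), sd = sd(r))
}

#' Welch two-sample t-test on per-sample richness
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value, as used to compare the number of food taxa
#' detected per sample by two methods on the same sample set.
#'
#' @param a,b numeric richness vectors (or [taxa_per_sample()] tibbles).
#' @return one-row tibble with `estimate_a`, `estimate_b`, `statistic`,
#'   `df`, `p.value`.
#' @export
welch_ttest <- function(a, b) {
  if (is.data.frame(a)) a <- a$richness
  if (is.data.frame(b)) b <- b$richness
  ht <- t.test(a, b, var.equal = FALSE)
  tibble(
    estimate_a = mean(a), estimate_b = mean(b),
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p.value = ht$p.value
  )
}

#' Monthly relative frequency of major food items
#'
#' Restricts to major labels -- those present in more than
#' `major_threshold` (fraction) of all samples -- then, within each
#' calendar month, divides each major label's presence count by the sum of
#' presence counts of all major labels that month, so rows sum to 1. Months
#' with no samples (or no major-label detections) are omitted.
#'
#' @param diet diet matrix tibble.
#' @param meta metadata tibble with `sample_id` and `month` (integer) or
#'   `collection_date`.
#' @param major_threshold fraction of samples a label must exceed to count
#'   as major (default 0.10).
#' @return tibble with `month`, `label`, `n_present`, `rel_freq`.
#' @export
monthly_relative_frequency <- function(diet, meta, major_threshold = 0.10) {
  if (!"month" %in% names(meta)) {
    meta$month <- as.integer(format(as.Date(meta$collection_date), "%m"))
  }
  fp <- frequency_of_presence(diet)
  major <- fp$label[fp$F_P / 100 > major_threshold]
  if (!length(major)) {
    return(tibble(month = integer(), label = character(),
                  n_present = integer(), rel_freq = double()))
  }
  long <- diet |>
    tidyr::pivot_longer(-"sample_id", names_to = "label", values_to = "reads") |>
    filter(.data$label %in% major) |>
    left_join(meta[, c("sample_id", "month")], by = "sample_id") |>
    filter(!is.na(.data$month))
  out <- long |>
    group_by(.data$month, .data$label) |>
    summarise(n_present = sum(.data$reads > 0), .groups = "drop_last") |>
    mutate(rel_freq = .data$n_present / sum(.data$n_present)) |>
    ungroup() |>
    filter(!is.nan(.data$rel_freq))
  out
}

#' Annotate labels with native/introduced origin
#'
#' A species-level label inherits its species' origin. A haplotype-group or
#' rank-lifted label is `"native"` or `"introduced"` if all member species
#' agree and `"both"` if they mix origins. Labels matching neither a group
#' nor a taxon yield `NA`.
#'
#' @param labels character vector of assignment labels.
#' @param groups haplotype groups tibble (for `"Gr. ..."` labels).
#' @param taxonomy taxonomy tibble.
#' @return tibble with `label`, `origin`.
#' @export
annotate_origin <- function(labels, groups, taxonomy) {
  taxonomy <- validate_taxonomy(taxonomy)
  origin_of_species <- function(sp) {
    o <- unique(taxonomy$origin[taxonomy$species_id %in% sp])
    if (!length(o)) NA_character_
    else if (length(o) == 1 && o != "both") o
    else "both"
  }
  origin_one <- function(lab) {
    gi <- match(lab, groups$label)
    if (!is.na(gi)) return(origin_of_species(groups$members[[gi]]))
    if (lab %in% taxonomy$species_id) {
      return(taxonomy$origin[taxonomy$species_id == lab])
    }
    if (lab %in% taxonomy$genus) {
      return(origin_of_species(taxonomy$species_id[taxonomy$genus == lab]))
    }
    if (lab %in% taxonomy$family) {
      return(origin_of_species(taxonomy$species_id[taxonomy$family == lab]))
    }
    NA_character_
  }
  tibble(label = labels, origin = purrr::map_chr(labels, origin_one))
}

#' Diet summary table
#'
#' The per-taxon report combining origin annotation, read counts, F_R and
#' F_P for the sequencing method, and optionally F_P for an externally
#' supplied presence table from a second detection method (e.g.
#' microhistology), which may use a different sample denominator.
#'
#' @param diet diet matrix tibble.
#' @param groups,taxonomy for origin annotation; pass `NULL` to skip.
#' @param presence_alt optional tibble `label` x `sample_id` presence (long
#'   form with columns `label`, `sample_id`) from the second method.
#' @param denominator_alt sample denominator for the second method.
#' @return tibble with one row per label: `label`, `origin`, `n_reads`,
#'   `F_R`, `F_P`, and `F_P_alt` when `presence_alt` is given.
#' @export
diet_summary_table <- function(diet, groups = NULL, taxonomy = NULL,
                               presence_alt = NULL,
                               denominator_alt = NULL) {
  fr <- frequency_of_reads(diet)
  fp <- frequency_of_presence(diet)
  out <- left_join(fr, fp[, c("label", "F_P")], by = "label")
  if (!is.null(groups) && !is.null(taxonomy)) {
    out <- left_join(out, annotate_origin(out$label, groups, taxonomy), by = "label")
    out <- out[, c("label", "origin", "n_reads", "F_R", "F_P")]
  }
  if (!is.null(presence_alt)) {
    denom <- denominator_alt %||% length(unique(presence_alt$sample_id))
    alt <- presence_alt |>
      distinct(.data$label, .data$sample_id) |>
      count(.data$label, name = "n_alt") |>
      mutate(F_P_alt = round_half_up(100 * .data$n_alt / denom, 2))
    out <- left_join(out, alt[, c("label", "F_P_alt")], by = "label")
    out$F_P_alt[is.na(out$F_P_alt)] <- 0
  }
  out
}
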