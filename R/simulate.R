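# Synthetic data with known ground truth: taxonomies, reference databases
# with a controlled number of distinct haplotypes, island-structured skewed
# diets, and error-bearing MID-tagged amplicon reads.
#
# Defaults emulate a realistic fecal metabarcoding survey of an island
# frugivore: 222 species / 175 genera / 76 families collapsing to 167
# distinct P6 haplotypes of 66-148 bp, 48 samples over two islands, read
# depths around 743 +/- 338, strongly skewed multi-taxon diets with one
# dominant shared taxon, and i.i.d. substitution sequencing errors.

#' Simulation configuration
#'
#' @param seed master seed; stage seeds are derived from it, so a full
#'   dataset is bit-reproducible from this one integer.
#' @param n_species,n_genera,n_families taxonomy shape.
#' @param n_haplotypes number of distinct P6 sequences the species collapse
#'   to (must be <= `n_species`).
#' @param collapse_weights probabilities that a collapsing species reuses a
#'   haplotype from its own genus, its own family, or anywhere (summing
#'   to 1); shapes where in the tree discrimination is lost.
#' @param p6_length_range inclusive range of P6 insert lengths in bp.
#' @param p_introduced probability that a species is annotated as
#'   introduced.
#' @param n_samples number of fecal samples.
#' @param islands named integer vector of samples per island.
#' @param months integer vector of calendar months sampled (recycled over
#'   samples within island).
#' @param pool_size number of diet taxa available per island.
#' @param pool_distinct fraction of each island's pool that is exclusive to
#'   it (island-structured diets; 0 = identical pools).
#' @param richness_mean mean number of taxa per sample (Poisson, truncated
#'   at 1).
#' @param diet_alpha Dirichlet concentration for within-sample diet
#'   proportions; small values give strongly skewed diets.
#' @param dominant_taxon if `TRUE` (default), one taxon shared by both
#'   islands is present in every sample with proportion at least
#'   `dominant_share`, mimicking a dominant staple food.
#' @param dominant_share minimum read share of the dominant taxon.
#' @param depth_mean,depth_sd,depth_min per-sample read depth: normal,
#'   truncated below at `depth_min`.
#' @param error_rate per-base substitution probability on the insert.
#' @param efficiency_bias named numeric vector of per-taxon multiplicative
#'   amplification weights (unnamed taxa have weight 1).
#' @param mid_length MID tag length in bp.
#' @return list of class `trnl_sim_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_species = 222, n_genera = 175, n_families = 76,
                              n_haplotypes = 167,
                              collapse_weights = c(genus = 0.4, family = 0.5, any = 0.1),
                              p6_length_range = c(66, 148),
                              p_introduced = 0.3,
                              n_samples = 48,
                              islands = c(Chichijima = 24, Hahajima = 24),
                              months = c(9:12, 1:5),
                              pool_size = 30,
                              pool_distinct = 0.3,
                              richness_mean = 6.7,
                              diet_alpha = 0.3,
                              dominant_taxon = TRUE,
                              dominant_share = 0.35,
                              depth_mean = 743, depth_sd = 338, depth_min = 50,
                              error_rate = 0.01,
                              efficiency_bias = NULL,
                              mid_length = 10) {
  stopifnot(
    n_haplotypes <= n_species, n_genera <= n_species, n_families <= n_genera,
    p6_length_range[1] >= 50, p6_length_range[2] <= 200,
    depth_mean > 0, depth_min > 0,
    error_rate >= 0, error_rate <= 1,
    pool_distinct >= 0, pool_distinct <= 1,
    sum(islands) == n_samples
  )
  structure(
    list(
      seed = seed, n_species = n_species, n_genera = n_genera,
      n_families = n_families, n_haplotypes = n_haplotypes,
      collapse_weights = collapse_weights / sum(collapse_weights),
      p6_length_range = p6_length_range, p_introduced = p_introduced,
      n_samples = n_samples, islands = islands, months = months,
      pool_size = pool_size, pool_distinct = pool_distinct,
      richness_mean = richness_mean, diet_alpha = diet_alpha,
      dominant_taxon = dominant_taxon, dominant_share = dominant_share,
      depth_mean = depth_mean, depth_sd = depth_sd, depth_min = depth_min,
      error_rate = error_rate, efficiency_bias = efficiency_bias,
      mid_length = mid_length
    ),
    class = "trnl_sim_config"
  )
}

random_dna <- function(n, len) {
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, "")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[sample.int(length(g), 1)] <- 1
  g / sum(g)
}

#' Simulate a reference database with known discrimination structure
#'
#' Builds a random taxonomy of the requested shape, assigns species to
#' exactly `n_haplotypes` haplotype classes (collapses prefer congeners,
#' then confamilials, per `collapse_weights`), draws one distinct P6
#' sequence per class, and wraps each in primer sites and random intron
#' flanks. The realized discrimination report is returned as ground truth.
#'
#' @param cfg configuration from [simulation_config()].
#' @param seed overrides `cfg$seed` when given.
#' @return list with `taxonomy`, `refs` (tibble `species_id`, `intron_seq`,
#'   `p6_seq`), `haplotype_of` (named map species -> haplotype class), and
#'   `expected` (list `Rs`, `n_species`, `n_haplotypes`).
#' @export
simulate_reference <- function(cfg = simulation_config(), seed = NULL) {
  set.seed(seed %||% cfg$seed)
  n_sp <- cfg$n_species
  n_ge <- cfg$n_genera
  n_fa <- cfg$n_families

  # genera per family, species per genus: at least one each
  fam_of_genus <- sort(c(seq_len(n_fa), sample.int(n_fa, n_ge - n_fa, replace = TRUE)))
  genus_of_species <- sort(c(seq_len(n_ge), sample.int(n_ge, n_sp - n_ge, replace = TRUE)))
  taxonomy <- tibble(
    species_id = sprintf("Species%03d", seq_len(n_sp)),
    genus = sprintf("Genus%03d", genus_of_species),
    family = sprintf("Family%02d", fam_of_genus[genus_of_species]),
    origin = ifelse(runif(n_sp) < cfg$p_introduced, "introduced", "native")
  )

  # haplotype classes: start one per species, merge until n_haplotypes remain
  hap <- seq_len(n_sp)
  n_merge <- n_sp - cfg$n_haplotypes
  merge_order <- sample.int(n_sp)
  merged <- 0
  for (s in merge_order) {
    if (merged >= n_merge) break
    if (sum(hap == hap[s]) > 1) next # only collapse current singletons
    mode <- sample(c("genus", "family", "any"), 1, prob = cfg$collapse_weights)
    pool <- switch(mode,
      genus = which(genus_of_species == genus_of_species[s]),
      family = which(taxonomy$family == taxonomy$family[s]),
      any = seq_len(n_sp)
    )
    pool <- setdiff(pool, s)
    if (!length(pool)) pool <- setdiff(seq_len(n_sp), s)
    partner <- if (length(pool) == 1) pool else sample(pool, 1)
    hap[s] <- hap[partner]
    merged <- merged + 1
  }
  hap <- match(hap, unique(hap))
  stopifnot(length(unique(hap)) == cfg$n_haplotypes)

  lens <- sample(seq(cfg$p6_length_range[1], cfg$p6_length_range[2]),
    cfg$n_haplotypes, replace = TRUE
  )
  p6 <- random_dna(cfg$n_haplotypes, lens)
  while (anyDuplicated(p6)) {
    dup <- which(duplicated(p6))
    p6[dup] <- random_dna(length(dup), lens[dup])
  }
  primers <- trnl_primers()
  refs <- tibble(
    species_id = taxonomy$species_id,
    p6_seq = p6[hap],
    intron_seq = paste0(
      random_dna(n_sp, rep(60, n_sp)), primers[["g"]], p6[hap],
      revcomp(primers[["h"]]), random_dna(n_sp, rep(40, n_sp))
    )
  )
  list(
    taxonomy = taxonomy,
    refs = refs,
    haplotype_of = setNames(hap, taxonomy$species_id),
    expected = list(
      Rs = round_half_up(100 * cfg$n_haplotypes / n_sp),
      n_species = n_sp, n_haplotypes = cfg$n_haplotypes
    )
  )
}

#' Simulate per-sample diet proportions and metadata
#'
#' Each island draws a taxon pool (a controlled fraction exclusive to it);
#' each sample draws a taxon subset and Dirichlet proportions, optionally
#' forcing a shared dominant taxon to a large read share.
#'
#' @param cfg configuration.
#' @param reference output of [simulate_reference()].
#' @param seed overrides `cfg$seed + 1` when given.
#' @return list with `diets` (tibble `sample_id`, `species_id`,
#'   `proportion`; proportions sum to 1 per sample), `meta` (metadata
#'   tibble), and `pools` (per-island species pools).
#' @export
simulate_diet <- function(cfg = simulation_config(), reference, seed = NULL) {
  set.seed(seed %||% (cfg$seed + 1))
  tax <- reference$taxonomy
  n_excl <- round(cfg$pool_size * cfg$pool_distinct)
  n_shared <- cfg$pool_size - n_excl
  shared <- sample(tax$species_id, n_shared)
  remaining <- setdiff(tax$species_id, shared)
  pools <- purrr::map(names(cfg$islands), function(isl) {
    excl <- sample(remaining, n_excl)
    remaining <<- setdiff(remaining, excl)
    c(shared, excl)
  })
  names(pools) <- names(cfg$islands)
  dominant <- if (cfg$dominant_taxon) shared[1] else NULL

  sample_ids <- sprintf("S%02d", seq_len(cfg$n_samples))
  island_of <- rep(names(cfg$islands), cfg$islands)
  month_of <- unlist(purrr::map(cfg$islands, function(k) {
    rep_len(cfg$months, k)
  }), use.names = FALSE)
  year <- ifelse(month_of >= 9, 2010, 2011)
  meta <- tibble(
    sample_id = sample_ids,
    island = island_of,
    collection_date = as.Date(sprintf("%d-%02d-15", year, month_of)),
    month = as.integer(month_of),
    collection_mode = sample(c("observed", "nest_roost"), cfg$n_samples,
      replace = TRUE, prob = c(35, 13) / 48
    ),
    host_confirmed = TRUE
  )

  diets <- purrr::map(seq_len(cfg$n_samples), function(i) {
    pool <- pools[[island_of[i]]]
    k <- max(1, min(stats::rpois(1, cfg$richness_mean), length(pool)))
    taxa <- sample(pool, k)
    if (!is.null(dominant) && !(dominant %in% taxa)) taxa <- c(dominant, taxa[-1])
    p <- rdirichlet1(rep(cfg$diet_alpha, length(taxa)))
    if (!is.null(dominant)) {
      share <- runif(1, cfg$dominant_share, min(1, cfg$dominant_share + 0.25))
      di <- which(taxa == dominant)
      rest <- sum(p[-di])
      p[-di] <- if (rest > 0) p[-di] / rest * (1 - share) else (1 - share) / max(1, length(p) - 1)
      p[di] <- share
      if (length(taxa) == 1) p <- 1
    }
    tibble(sample_id = sample_ids[i], species_id = taxa, proportion = p)
  }) |> bind_rows()
  list(diets = diets, meta = meta, pools = pools)
}

#' Simulate MID-tagged, error-bearing amplicon reads
#'
#' Per sample: depth is a normal draw truncated below; reads are drawn
#' multinomially from the diet proportions times per-taxon efficiency
#' weights (renormalized); each read is MID + forward primer + a haplotype
#' copy with i.i.d. substitutions + reverse-complemented reverse primer.
#'
#' @param cfg configuration.
#' @param diet output of [simulate_diet()].
#' @param reference output of [simulate_reference()].
#' @param seed overrides `cfg$seed + 2` when given.
#' @return list with `reads` (tibble `read_id`, `seq`), `mids` (MID map),
#'   and `truth` (tibble `read_id`, `sample_id`, `species_id`,
#'   `haplotype`), plus `depths` (named per-sample depths).
#' @export
simulate_reads <- function(cfg = simulation_config(), diet, reference, seed = NULL) {
  set.seed(seed %||% (cfg$seed + 2))
  primers <- trnl_primers()
  sample_ids <- unique(diet$meta$sample_id)

  # distinct same-length MIDs are automatically prefix-unique
  repeat {
    mids_seq <- random_dna(length(sample_ids), rep(cfg$mid_length, length(sample_ids)))
    if (!anyDuplicated(mids_seq)) break
  }
  mids <- tibble(mid_tag = mids_seq, sample_id = sample_ids)

  hap_of <- reference$haplotype_of
  p6_of_species <- setNames(reference$refs$p6_seq, reference$refs$species_id)

  all_reads <- vector("list", length(sample_ids))
  all_truth <- vector("list", length(sample_ids))
  depths <- integer(length(sample_ids))
  for (i in seq_along(sample_ids)) {
    sid <- sample_ids[i]
    prof <- diet$diets[diet$diets$sample_id == sid, ]
    depth <- 0
    while (depth < cfg$depth_min) depth <- round(rnorm(1, cfg$depth_mean, cfg$depth_sd))
    depths[i] <- depth
    w <- prof$proportion
    if (!is.null(cfg$efficiency_bias)) {
      bias <- cfg$efficiency_bias[prof$species_id]
      bias[is.na(bias)] <- 1
      w <- w * bias
    }
    w <- w / sum(w)
    counts <- as.integer(rmultinom(1, depth, w))
    species <- rep(prof$species_id, counts)
    inserts <- p6_of_species[species]
    if (cfg$error_rate > 0) inserts <- mutate_seqs(inserts, cfg$error_rate)
    read_ids <- sprintf("%s_r%05d", sid, seq_len(depth))
    all_reads[[i]] <- tibble(
      read_id = read_ids,
      seq = paste0(mids_seq[i], primers[["g"]], inserts, revcomp(primers[["h"]]))
    )
    all_truth[[i]] <- tibble(
      read_id = read_ids, sample_id = sid, species_id = species,
      haplotype = unname(hap_of[species])
    )
  }
  list(
    reads = bind_rows(all_reads), mids = mids,
    truth = bind_rows(all_truth),
    depths = setNames(depths, sample_ids)
  )
}

# i.i.d. substitution errors at rate per base; substitutions always change
# the base (drawn from the three alternatives).
mutate_seqs <- function(seqs, rate) {
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(lens[i], n_err[i])
    s <- strsplit(seqs[i], "")[[1]]
    for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate a complete dataset
#'
#' Reference, diets and reads in one call; stage seeds are derived from the
#' master seed, so identical configurations give bit-identical datasets.
#'
#' @param cfg configuration from [simulation_config()].
#' @return list with elements `taxonomy`, `refs`, `groups_truth`
#'   (`haplotype_of`), `expected`, `diets`, `meta`, `pools`, `reads`,
#'   `mids`, `truth`, `depths`, and `cfg`.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  ref <- simulate_reference(cfg)
  di <- simulate_diet(cfg, ref)
  rd <- simulate_reads(cfg, di, ref)
  c(ref["taxonomy"], ref["refs"],
    list(haplotype_of = ref$haplotype_of, expected = ref$expected),
    di, rd, list(cfg = cfg)
  )
}
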