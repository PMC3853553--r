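small_cfg <- function(seed = 5, ...) {
  simulation_config(
    seed = seed, n_species = 40, n_genera = 25, n_families = 10,
    n_haplotypes = 30, n_samples = 10, islands = c(A = 5, B = 5),
    pool_size = 12, richness_mean = 5,
    depth_mean = 150, depth_sd = 40, ...
  )
}

test_that("simulated reference realizes the requested taxonomy shape and haplotype count", {
  cfg <- small_cfg()
  ref <- simulate_reference(cfg)
  expect_equal(nrow(ref$taxonomy), 40)
  expect_equal(length(unique(ref$taxonomy$genus)), 25)
  expect_equal(length(unique(ref$taxonomy$family)), 10)
  expect_equal(length(unique(ref$refs$p6_seq)), 30)
  expect_true(all(nchar(ref$refs$p6_seq) >= 66 & nchar(ref$refs$p6_seq) <= 148))
  # the pipeline's discrimination report agrees with the construction
  rep <- discrimination_rates(
    build_haplotype_groups(ref$refs[, c("species_id", "p6_seq")], ref$taxonomy),
    ref$taxonomy
  )
  expect_equal(rep$Rs, ref$expected$Rs)
  expect_equal(rep$n_distinct_sequences, 30)
  # extraction from the simulated introns recovers the same P6 sequences
  db <- build_reference_db(ref$refs, ref$taxonomy)
  expect_equal(db$refs$p6_seq, ref$refs$p6_seq)
})

test_that("zero collapse gives full species discrimination; full family collapse the minimum", {
  cfg0 <- simulation_config(
    seed = 2, n_species = 20, n_genera = 15, n_families = 6,
    n_haplotypes = 20, n_samples = 4, islands = c(A = 2, B = 2), pool_size = 8
  )
  ref0 <- simulate_reference(cfg0)
  rep0 <- discrimination_rates(
    build_haplotype_groups(ref0$refs[, c("species_id", "p6_seq")], ref0$taxonomy),
    ref0$taxonomy
  )
  expect_equal(rep0$Rs, 100)
  # one family of 7 species collapsed onto one haplotype: Rf = 14
  tax <- make_taxonomy(list(Lauraceae = list(G1 = paste0("s", 1:7))))
  refs <- tibble::tibble(species_id = tax$species_id,
                         p6_seq = rand_seq(87, seed = 3))
  rep1 <- discrimination_rates(build_haplotype_groups(refs, tax), tax)
  expect_equal(rep1$by_family$Rf_percent, 14)
})

test_that("diet proportions are a partition of one with island-structured pools", {
  cfg <- small_cfg()
  ref <- simulate_reference(cfg)
  di <- simulate_diet(cfg, ref)
  sums <- tapply(di$diets$proportion, di$diets$sample_id, sum)
  expect_equal(as.numeric(sums), rep(1, cfg$n_samples), tolerance = 1e-12)
  expect_equal(nrow(di$meta), cfg$n_samples)
  # island pools share the configured fraction
  ov <- length(intersect(di$pools[[1]], di$pools[[2]]))
  expect_equal(ov, cfg$pool_size - round(cfg$pool_size * cfg$pool_distinct))
  # dominant taxon present everywhere with at least the configured share
  dom <- names(which.max(table(di$diets$species_id)))
  dom_rows <- di$diets[di$diets$species_id == dom, ]
  expect_equal(nrow(dom_rows), cfg$n_samples)
  expect_true(all(dom_rows$proportion >= cfg$dominant_share - 1e-12))
})

test_that("simulated reads are conserved, tagged and bit-reproducible", {
  cfg <- small_cfg(seed = 9)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(small_cfg(seed = 9))
  expect_identical(ds1$reads, ds2$reads)
  expect_identical(ds1$truth, ds2$truth)
  expect_identical(ds1$refs, ds2$refs)
  # read counts match the multinomial ground truth exactly
  expect_equal(nrow(ds1$reads), sum(ds1$depths))
  expect_equal(nrow(ds1$truth), nrow(ds1$reads))
  per_sample <- table(ds1$truth$sample_id)
  expect_equal(as.integer(per_sample[names(ds1$depths)]), unname(ds1$depths))
  expect_true(all(ds1$depths >= cfg$depth_min))
  # every read starts with its sample's MID followed by the forward primer
  tag_of <- setNames(ds1$mids$mid_tag, ds1$mids$sample_id)
  pref <- paste0(tag_of[ds1$truth$sample_id], trnl_primers()[["g"]])
  expect_true(all(startsWith(ds1$reads$seq, pref)))
})

test_that("error-free unbiased reads reproduce the true proportions exactly through the pipeline", {
  cfg <- small_cfg(seed = 13)
  cfg$error_rate <- 0
  ds <- simulate_dataset(cfg)
  db <- build_reference_db(ds$refs, ds$taxonomy)
  run <- run_pipeline(ds$reads, ds$mids, db$groups, ds$taxonomy,
    cfg = pipeline_config(min_reads = 1, seed = 1)
  )
  # with no errors and no abundance filter, every read is assigned
  expect_equal(run$tally$unassigned_reads, 0)
  expect_equal(run$tally$total_reads, sum(ds$depths))
  # per-label read counts equal the ground-truth haplotype draws exactly
  lab_of_hap <- db$groups$label[match(ds$refs$p6_seq, db$groups$p6_seq)]
  names(lab_of_hap) <- ds$refs$species_id
  truth_counts <- table(lab_of_hap[ds$truth$species_id])
  got <- frequency_of_reads(run$diet)
  expect_equal(
    got$n_reads[match(names(truth_counts), got$label)],
    unname(as.numeric(truth_counts))
  )
})

test_that("a per-taxon efficiency bias shifts read frequencies multiplicatively", {
  cfg <- small_cfg(seed = 17)
  cfg$error_rate <- 0
  ref <- simulate_reference(cfg)
  di <- simulate_diet(cfg, ref)
  # bias the dominant shared taxon up threefold
  dom <- di$diets$species_id[which.max(di$diets$proportion)]
  cfg$efficiency_bias <- setNames(3, dom)
  rd <- simulate_reads(cfg, di, ref)
  # realized read share of the biased taxon exceeds its diet share
  truth_share <- sum(di$diets$proportion[di$diets$species_id == dom]) /
    cfg$n_samples
  read_share <- mean(rd$truth$species_id == dom)
  expect_gt(read_share, truth_share)
})
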