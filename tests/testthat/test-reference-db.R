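test_that("extract_p6 recovers the insert between exact primer sites", {
  p <- trnl_primers()
  intron <- paste0(p[["g"]], "ACGTACGT", revcomp(p[["h"]]))
  expect_equal(extract_p6(intron, max_mismatch = 0), "ACGTACGT")
  # flanks around the sites do not change the insert
  flanked <- paste0("TTTTT", intron, "AAAAA")
  expect_equal(extract_p6(flanked), "ACGTACGT")
  # no primer site at all
  expect_true(is.na(extract_p6(rand_seq(80, seed = 1))))
})

test_that("extract_p6 honors the mismatch budget, matching a window-scan oracle", {
  p <- trnl_primers()
  insert <- rand_seq(70, seed = 5)
  g_mut <- mutate_at(p[["g"]], 9) # one substitution inside the forward site
  intron <- paste0("AAAC", g_mut, insert, revcomp(p[["h"]]), "GGT")
  expect_true(is.na(extract_p6(intron, max_mismatch = 0)))
  expect_equal(extract_p6(intron, max_mismatch = 1), insert)
  # oracle agrees on the site position
  expect_identical(oracle_find_site(intron, p[["g"]], 0), integer(0))
  expect_identical(oracle_find_site(intron, p[["g"]], 1), 5L)
})

test_that("extract_p6 flags ambiguous forward sites with their positions", {
  p <- trnl_primers()
  intron <- paste0(p[["g"]], "ACGT", p[["g"]], "CCCC", revcomp(p[["h"]]))
  expect_error(extract_p6(intron), "ambiguous primer site")
  expect_true(is.na(extract_p6(intron, on_ambiguous = "drop")))
})

test_that("haplotype groups partition by exact sequence and label at the covering rank", {
  tax <- make_taxonomy(list(
    FamA = list(Gen1 = c("sp1", "sp2"), Gen2 = "sp3"),
    FamB = list(Gen3 = "sp4")
  ))
  # all distinct: one species-level group each
  refs <- tibble::tibble(
    species_id = tax$species_id,
    p6_seq = vapply(1:4, function(i) rand_seq(70, seed = i), "")
  )
  g <- build_haplotype_groups(refs, tax)
  expect_equal(nrow(g), 4)
  expect_true(all(g$label_rank == "species"))
  expect_setequal(g$label, tax$species_id)

  # two congeners share a sequence: genus-level group
  refs2 <- refs
  refs2$p6_seq[2] <- refs2$p6_seq[1]
  g2 <- build_haplotype_groups(refs2, tax)
  expect_equal(nrow(g2), 3)
  shared <- g2[g2$n_members == 2, ]
  expect_equal(shared$label, "Gr. Gen11")
  expect_equal(shared$label_rank, "genus")

  # cross-genus sharing within one family: family-level group
  refs3 <- refs
  refs3$p6_seq[3] <- refs3$p6_seq[1]
  g3 <- build_haplotype_groups(refs3, tax)
  expect_equal(g3$label_rank[g3$n_members == 2], "family")
  expect_equal(g3$label[g3$n_members == 2], "Gr. FamA1")
})

test_that("seven confamilial species on one haplotype form a single family group", {
  tax <- make_taxonomy(list(Lauraceae = list(
    Machilus = c("s1", "s2"), Neolitsea = c("s3", "s4"), Litsea = c("s5", "s6", "s7")
  )))
  seq1 <- rand_seq(87, seed = 9)
  refs <- tibble::tibble(species_id = tax$species_id, p6_seq = seq1)
  g <- build_haplotype_groups(refs, tax)
  expect_equal(nrow(g), 1)
  expect_equal(g$label, "Gr. Lauraceae1")
  expect_equal(g$label_rank, "family")
  expect_equal(g$n_members, 7L)
  # and its family discrimination is 1 sequence over 7 species = 14%
  rep <- discrimination_rates(g, tax)
  expect_equal(rep$by_family$Rf_percent, 14)
})

test_that("single-member groups iff species rank; empty and duplicate inputs error", {
  tax <- make_taxonomy(list(FamA = list(Gen1 = c("sp1", "sp2"))))
  refs <- tibble::tibble(species_id = c("sp1", "sp2"),
                         p6_seq = c(rand_seq(60, 1), rand_seq(60, 2)))
  g <- build_haplotype_groups(refs, tax)
  expect_true(all((g$n_members == 1) == (g$label_rank == "species")))
  expect_equal(nrow(build_haplotype_groups(refs[0, ], tax)), 0)
  dup <- refs
  dup$species_id <- c("sp1", "sp1")
  expect_error(build_haplotype_groups(dup, tax), "duplicate species_id")
})

test_that("discrimination rates follow the distinct-haplotype counting rules", {
  # every species its own sequence: all rates 100
  tax <- make_taxonomy(list(
    FamA = list(Gen1 = c("a1", "a2"), Gen2 = "a3"),
    FamB = list(Gen3 = c("b1", "b2"))
  ))
  refs <- tibble::tibble(
    species_id = tax$species_id,
    p6_seq = vapply(seq_len(nrow(tax)), function(i) rand_seq(75, seed = 100 + i), "")
  )
  rep <- discrimination_rates(build_haplotype_groups(refs, tax), tax)
  expect_equal(rep$Rs, 100)
  expect_equal(rep$Rg, 100)
  expect_true(all(rep$by_family$Rf_percent == 100))

  # genus-exclusive reading of Rg: a sequence shared across genera counts
  # for neither genus
  refs2 <- refs
  refs2$p6_seq[3] <- refs2$p6_seq[1] # Gen1's a1 and Gen2's a3 now share
  rep2 <- discrimination_rates(build_haplotype_groups(refs2, tax), tax)
  # Gen1 still owns a2's exclusive sequence; Gen2 owns nothing; Gen3 fine
  expect_equal(rep2$Rg, round_half_up(100 * 2 / 3))
  expect_error(
    discrimination_rates(build_haplotype_groups(refs[0, ], tax), tax),
    "empty database"
  )
})

test_that("Rs is invariant under species permutation and never rises when haplotypes merge", {
  set.seed(77)
  tax <- make_taxonomy(list(
    F1 = list(G1 = paste0("x", 1:5), G2 = paste0("y", 1:3)),
    F2 = list(G3 = paste0("z", 1:4))
  ))
  seqs <- vapply(1:8, function(i) rand_seq(66 + i, seed = 200 + i), "")
  refs <- tibble::tibble(species_id = tax$species_id,
                         p6_seq = seqs[sample.int(8, 12, replace = TRUE)])
  base <- discrimination_rates(build_haplotype_groups(refs, tax), tax)
  for (i in 1:5) {
    perm <- refs[sample.int(nrow(refs)), ]
    rep_p <- discrimination_rates(build_haplotype_groups(perm, tax), tax)
    expect_equal(rep_p$Rs, base$Rs)
    expect_equal(
      dplyr::arrange(rep_p$by_family, family),
      dplyr::arrange(base$by_family, family)
    )
  }
  # merging two distinct haplotypes can only lower (or keep) Rs and Rf
  hap <- unique(refs$p6_seq)
  merged <- refs
  merged$p6_seq[merged$p6_seq == hap[1]] <- hap[2]
  rep_m <- discrimination_rates(build_haplotype_groups(merged, tax), tax)
  expect_lte(rep_m$Rs, base$Rs)
  expect_true(all(rep_m$by_family$Rf_percent <= base$by_family$Rf_percent))
})

test_that("a synthetic database with the published family structure reproduces its Rf column", {
  fam <- woodpigeon_family_structure()
  # build one taxonomy/reference pair with exactly that per-family shape:
  # n_species species, the first n_sequences of which get distinct
  # haplotypes and the rest reuse the first haplotype
  rows <- list()
  refs <- list()
  seq_i <- 0
  for (i in seq_len(nrow(fam))) {
    sp <- sprintf("%s_sp%02d", fam$family[i], seq_len(fam$n_species[i]))
    rows[[i]] <- tibble::tibble(
      species_id = sp,
      genus = sprintf("%s_gen%02d", fam$family[i],
                      pmin(seq_along(sp), fam$n_sequences[i])),
      family = fam$family[i], origin = "native"
    )
    hap <- vapply(seq_len(fam$n_sequences[i]), function(k) {
      rand_seq(66 + ((seq_i + k) %% 80), seed = 3000 + seq_i + k)
    }, "")
    seq_i <- seq_i + fam$n_sequences[i]
    refs[[i]] <- tibble::tibble(
      species_id = sp,
      p6_seq = c(hap, rep(hap[1], fam$n_species[i] - fam$n_sequences[i]))
    )
  }
  tax <- dplyr::bind_rows(rows)
  refs <- dplyr::bind_rows(refs)
  rep <- discrimination_rates(build_haplotype_groups(refs, tax), tax)
  got <- rep$by_family[match(fam$family, rep$by_family$family), ]
  expect_equal(got$n_species, fam$n_species)
  expect_equal(got$n_sequences, fam$n_sequences)
  # arithmetic Rf always matches round(100 * seq / sp)
  expect_equal(got$Rf_percent, round_half_up(100 * fam$n_sequences / fam$n_species))
  # and matches the published column on its arithmetically consistent rows
  expect_equal(got$Rf_percent[fam$consistent], fam$Rf_published[fam$consistent])
  expect_equal(sum(!fam$consistent), 4) # known inconsistent printed rows
  expect_equal(min(got$Rf_percent), 14) # worst family: 7 species, 1 haplotype
})
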