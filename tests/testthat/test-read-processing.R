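test_that("demultiplex routes by tag prefix, strips tags, and conserves reads", {
  mids <- tibble::tibble(mid_tag = c("ACGT", "TTGC", "GGAT"),
                         sample_id = c("S1", "S2", "S3"))
  reads <- tibble::tibble(
    read_id = paste0("r", 1:4),
    seq = c(paste0("ACGT", "AAACCC"), paste0("TTGC", "GGGTTT"),
            paste0("CCCC", "AAAAAA"), paste0("GGAT", "ACACAC"))
  )
  out <- demultiplex(reads, mids)
  expect_equal(out$sample_id, c("S1", "S2", NA, "S3"))
  expect_equal(out$seq[1], "AAACCC") # tag stripped
  expect_equal(out$seq[3], "CCCCAAAAAA") # unassigned read untouched
  # conservation: every read in exactly one bin
  expect_equal(sum(!is.na(out$sample_id)) + sum(is.na(out$sample_id)), nrow(reads))
})

test_that("demultiplex treats equal-distance tag ties as unassigned", {
  mids <- tibble::tibble(mid_tag = c("AAAA", "AAAT"), sample_id = c("S1", "S2"))
  # read prefix AAAG: Hamming 1 to both tags
  reads <- tibble::tibble(read_id = "r1", seq = "AAAGCCCCCC")
  out <- demultiplex(reads, mids, max_mid_mismatch = 1)
  expect_true(is.na(out$sample_id))
  # distance 1 to a unique tag routes fine
  out2 <- demultiplex(tibble::tibble(read_id = "r", seq = "ATATCCCCCC"),
                      mids, max_mid_mismatch = 1)
  expect_equal(out2$sample_id, "S2")
})

test_that("non-prefix-unique MID maps are rejected at load time", {
  bad <- tibble::tibble(mid_tag = c("ACGT", "ACGTAA"), sample_id = c("S1", "S2"))
  expect_error(demultiplex(tibble::tibble(read_id = "r", seq = "ACGTACGT"), bad),
               "prefix-unique")
  expect_error(validate_mid_map(bad), "prefix-unique")
})

test_that("trim_primers applies the primer-site contract to reads", {
  p <- trnl_primers()
  insert <- rand_seq(66, seed = 11)
  reads <- tibble::tibble(
    read_id = c("ok", "one_mm", "bare"),
    seq = c(
      paste0(p[["g"]], insert, revcomp(p[["h"]])),
      paste0(mutate_at(p[["g"]], 3), insert, revcomp(p[["h"]])),
      insert
    )
  )
  t0 <- trim_primers(reads)
  expect_equal(t0$seq[1], insert)
  expect_true(is.na(t0$seq[2])) # mismatch not allowed at 0
  expect_true(is.na(t0$seq[3]))
  t1 <- trim_primers(reads, max_mismatch = 1)
  expect_equal(t1$seq[2], insert)
  tp <- trim_primers(reads, pass_through = TRUE)
  expect_equal(tp$seq[3], insert) # pre-trimmed read passes through
})

test_that("dereplicate counts, orders deterministically, and conserves totals", {
  expect_equal(
    dereplicate(c("AA", "AA", "BB"))$count, c(2L, 1L)
  )
  expect_equal(nrow(dereplicate(character(0))), 0)
  # count ties break lexicographically, invariant to shuffles
  set.seed(4)
  seqs <- c(rep("TT", 3), rep("AA", 3), rep("CC", 1))
  for (i in 1:5) {
    d <- dereplicate(sample(seqs))
    expect_equal(d$seq, c("AA", "TT", "CC"))
    expect_equal(sum(d$count), length(seqs))
  }
})

test_that("cluster_reads joins by global-alignment identity against the threshold", {
  base <- rand_seq(100, seed = 21)
  # identical sequences merge and sum counts
  cl <- cluster_reads(tibble::tibble(seq = c(base, base), count = c(5L, 3L)))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$read_count, 8L)
  # one substitution in 100 bp: identity 0.99 >= 0.98, same cluster
  one_off <- mutate_at(base, 50)
  cl1 <- cluster_reads(tibble::tibble(seq = c(base, one_off), count = c(5L, 3L)))
  expect_equal(nrow(cl1), 1)
  expect_equal(cl1$centroid_seq, base) # centroid is the most abundant member
  # three substitutions: identity 0.97 < 0.98, two clusters
  three_off <- mutate_at(base, c(10, 50, 90))
  cl3 <- cluster_reads(tibble::tibble(seq = c(base, three_off), count = c(5L, 3L)))
  expect_equal(nrow(cl3), 2)
  expect_error(cluster_reads(cl3, identity_threshold = 0), "identity_threshold")
})

test_that("clustering at threshold 1 reduces to dereplication and is shuffle-invariant", {
  set.seed(31)
  pool <- vapply(1:6, function(i) rand_seq(80, seed = 300 + i), "")
  seqs <- sample(pool, 60, replace = TRUE)
  u <- dereplicate(seqs)
  cl <- cluster_reads(u, identity_threshold = 1)
  expect_equal(nrow(cl), nrow(u))
  expect_equal(sort(cl$read_count), sort(u$count))
  # deterministic under within-tie input shuffles
  base_cl <- cluster_reads(u)
  for (i in 1:3) {
    shuffled <- dereplicate(sample(seqs))
    expect_equal(cluster_reads(shuffled), base_cl)
  }
})

test_that("filter_clusters drops short and rare clusters with reasons, keeping boundaries", {
  clusters <- tibble::tibble(
    cluster_id = c("C1", "C2", "C3"),
    centroid_seq = c(rand_seq(66, 1), rand_seq(40, 2), rand_seq(39, 3)),
    read_count = c(5L, 4L, 3L),
    members = list(NULL, NULL, NULL)
  )
  out <- filter_clusters(clusters)
  expect_equal(out$retained, c(TRUE, TRUE, FALSE))
  expect_match(out$discard_reason[3], "shorter")
  # a 3-read cluster of fine length is dropped for abundance
  few <- clusters[1, ]
  few$read_count <- 3L
  expect_false(filter_clusters(few)$retained)
  expect_match(filter_clusters(few)$discard_reason, "fewer reads")
})

test_that("read conservation holds through a whole sample and centroids match truth on clean reads", {
  p <- trnl_primers()
  set.seed(8)
  haps <- vapply(1:3, function(i) rand_seq(70 + 10 * i, seed = 400 + i), "")
  counts <- c(30, 12, 5)
  reads <- tibble::tibble(
    read_id = sprintf("r%02d", 1:47),
    seq = paste0(p[["g"]], rep(haps, counts), revcomp(p[["h"]]))
  )
  res <- process_sample_reads(reads)
  expect_equal(unname(res$counts["input"]), 47L)
  expect_equal(unname(res$counts["rejected"]) + unname(res$counts["clustered"]), 47L)
  retained <- res$clusters[res$clusters$retained, ]
  expect_setequal(retained$centroid_seq, haps)
  expect_equal(sort(retained$read_count), sort(counts))
})
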