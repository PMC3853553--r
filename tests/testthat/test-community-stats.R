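test_that("pearson_chisq matches the closed-form oracle and handles degenerate margins", {
  m <- matrix(c(10, 0, 0, 10), 2, byrow = TRUE)
  got <- pearson_chisq(m)
  expect_equal(got$statistic, 20)
  expect_equal(got$df, 2 - 1)
  # identical columns: no association at all
  same <- pearson_chisq(matrix(c(5, 7, 5, 7), 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # random tables vs independent formula evaluation
  set.seed(130)
  for (i in 1:5) {
    tab <- matrix(rpois(12, 20), 4, 3)
    got_i <- pearson_chisq(tab)
    ora <- oracle_chisq(tab)
    expect_equal(got_i$statistic, ora$x2, tolerance = 1e-10)
    expect_equal(got_i$df, ora$df)
    expect_equal(got_i$p.value, ora$p, tolerance = 1e-10)
  }
  # zero margins dropped with a warning
  z <- matrix(c(3, 4, 2, 0, 0, 0, 5, 1, 2), 3)
  expect_warning(pearson_chisq(z), "all-zero")
})

test_that("chao dissimilarity has the right endpoints and matches the formula oracle", {
  x <- c(4, 3, 0, 2)
  expect_equal(chao_dissimilarity(x, x), 0)
  expect_equal(chao_dissimilarity(c(4, 3, 0), c(0, 0, 5)), 1) # disjoint supports
  expect_error(chao_dissimilarity(c(0, 0), c(1, 2)), "empty sample")
  # no singleton/doubleton correction triggered
  a <- c(4, 3, 0)
  b <- c(2, 0, 5)
  expect_equal(chao_dissimilarity(a, b), oracle_chao(a, b))
  # correction path triggered: shared species that are singletons/doubletons
  a2 <- c(4, 1, 2, 0, 6)
  b2 <- c(1, 3, 2, 5, 0)
  expect_equal(chao_dissimilarity(a2, b2), oracle_chao(a2, b2))
  set.seed(140)
  for (i in 1:20) {
    x <- rpois(10, 2)
    y <- rpois(10, 2)
    if (sum(x) == 0 || sum(y) == 0) next
    expect_equal(chao_dissimilarity(x, y), oracle_chao(x, y))
    # symmetry
    expect_equal(chao_dissimilarity(x, y), chao_dissimilarity(y, x))
    # invariant to species absent from both samples
    expect_equal(chao_dissimilarity(c(x, 0, 0), c(y, 0, 0)),
                 chao_dissimilarity(x, y))
  }
})

test_that("chao dissimilarity agrees with the community-ecology reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(141)
  for (i in 1:10) {
    x <- rpois(15, 3)
    y <- rpois(15, 3)
    if (sum(x) == 0 || sum(y) == 0) next
    expect_equal(
      chao_dissimilarity(x, y),
      as.numeric(vegan::vegdist(rbind(x, y), method = "chao")),
      tolerance = 1e-12
    )
  }
  # binary mode reduces to classic Jaccard
  x <- c(1, 5, 0, 2, 0)
  y <- c(3, 0, 0, 1, 4)
  expect_equal(chao_dissimilarity(x, y, binary = TRUE), 1 - 2 / 4)
  expect_equal(
    chao_dissimilarity(x, y, binary = TRUE),
    as.numeric(vegan::vegdist(rbind(x, y), method = "jaccard", binary = TRUE))
  )
})

test_that("nmds recovers perfectly embeddable configurations with near-zero stress", {
  pts <- matrix(c(0, 0, 1, 0, 0, 1, 1.5, 1.2), ncol = 2, byrow = TRUE)
  d <- dist(pts)
  fit <- nmds(d, k = 2, n_starts = 3, seed = 1)
  expect_lt(fit$stress, 0.01)
  # coordinates are centered
  expect_equal(colSums(fit$points), c(NMDS1 = 0, NMDS2 = 0), tolerance = 1e-8)
})

test_that("nmds stress is non-increasing within a start and reproducible by seed", {
  set.seed(150)
  m <- matrix(runif(81), 9)
  d <- stats::as.dist((m + t(m)) / 2)
  fit <- nmds(d, k = 2, n_starts = 4, max_iter = 60, seed = 7)
  expect_true(all(diff(fit$trace) <= 1e-12))
  fit2 <- nmds(d, k = 2, n_starts = 4, max_iter = 60, seed = 7)
  expect_identical(fit$points, fit2$points)
  expect_identical(fit$stress, fit2$stress)
  # stress is invariant under orthogonal rotation of the configuration
  theta <- 0.7
  rot <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2)
  dh_rot <- dist(fit$points %*% rot)
  dvec <- as.matrix(d)[lower.tri(as.matrix(d))]
  ord <- order(dvec)
  blocks <- cumsum(!duplicated(dvec[ord]))
  s_orig <- trnldiet:::.stress_iso(as.numeric(dist(fit$points)), ord, blocks,
                                   max(blocks))$stress
  s_rot <- trnldiet:::.stress_iso(as.numeric(dh_rot), ord, blocks,
                                  max(blocks))$stress
  expect_equal(s_rot, s_orig, tolerance = 1e-10)
})

test_that("anosim reaches R = 1 on perfectly separated groups and matches vegan", {
  # all between-group dissimilarities strictly above all within-group
  d <- matrix(0, 6, 6)
  within <- 0.1
  between <- 0.9
  grp <- rep(c("A", "B"), each = 3)
  for (i in 1:5) for (j in (i + 1):6) {
    d[i, j] <- d[j, i] <- if (grp[i] == grp[j]) within + 0.01 * (i + j) else
      between + 0.01 * (i + j)
  }
  res <- anosim_test(d, grp, n_perm = 199, seed = 1)
  expect_equal(res$R, 1)
  skip_if_not_installed("vegan")
  set.seed(160)
  m <- matrix(runif(144), 12)
  dr <- stats::as.dist((m + t(m)) / 2)
  g <- rep(c("A", "B"), 6)
  expect_equal(anosim_test(dr, g, n_perm = 99)$R,
               unname(vegan::anosim(dr, g, permutations = 9)$statistic))
})

test_that("anosim permutation p-value agrees with exhaustive enumeration at n = 6", {
  set.seed(170)
  m <- matrix(runif(36), 6)
  d <- (m + t(m)) / 2
  diag(d) <- 0
  grp <- rep(c("A", "B"), each = 3)
  obs <- anosim_test(d, grp, n_perm = 1999, seed = 3)
  # exhaustive: all choose(6, 3) = 20 label assignments
  combos <- utils::combn(6, 3)
  r_all <- apply(combos, 2, function(ix) {
    g <- rep("B", 6)
    g[ix] <- "A"
    anosim_test(d, g, n_perm = 1, seed = 1)$R
  })
  p_exact <- mean(r_all >= obs$R - 1e-12)
  expect_lt(abs(obs$p.value - p_exact), 0.05) # Monte-Carlo error margin
  # R is invariant under strictly monotone transforms of the dissimilarities
  obs_sq <- anosim_test(d^2, grp, n_perm = 1, seed = 1)
  expect_equal(obs_sq$R, obs$R)
})

test_that("anosim R is centered near zero under random labels", {
  set.seed(180)
  rs <- replicate(60, {
    m <- matrix(runif(64), 8)
    d <- (m + t(m)) / 2
    diag(d) <- 0
    anosim_test(d, sample(rep(c("A", "B"), 4)), n_perm = 1, seed = 1)$R
  })
  expect_lt(abs(mean(rs)), 0.08)
})
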