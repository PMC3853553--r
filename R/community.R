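# Between-group community comparisons: Pearson chi-square on pooled tables,
# abundance-based Chao-Jaccard dissimilarity, nonmetric multidimensional
# scaling (Kruskal stress-1 with isotonic regression), and ANOSIM.

#' Pearson chi-square test on a pooled contingency table
#'
#' Classic Pearson statistic sum((O - E)^2 / E) with expectations from the
#' row/column margins, df = (r - 1)(c - 1), no continuity correction. Any
#' all-zero row or column is dropped with a warning before testing.
#'
#' @param tab numeric matrix (e.g. labels x islands, read or presence
#'   counts) or data frame convertible to one.
#' @return one-row tibble with `statistic`, `df`, `p.value`.
#' @export
pearson_chisq <- function(tab) {
  m <- as.matrix(tab)
  zr <- rowSums(m) == 0
  zc <- colSums(m) == 0
  if (any(zr) || any(zc)) {
    warn(sprintf("dropping %d all-zero rows and %d all-zero columns", sum(zr), sum(zc)))
    m <- m[!zr, !zc, drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 2) abort("contingency table needs at least 2x2 non-zero margins")
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p.value = ht$p.value
  )
}

# Chao-Jaccard abundance estimator term: the estimated fraction of
# individuals in x that belong to species shared with y, corrected upward
# for unseen shared species via species that are singletons/doubletons in y.
chao_u <- function(x, y) {
  n <- sum(x)
  m <- sum(y)
  shared <- x > 0 & y > 0
  if (!any(shared)) return(0)
  f1 <- sum(shared & y == 1) # shared species that are singletons in y
  f2 <- sum(shared & y == 2) # ... doubletons in y
  if (f2 == 0) f2 <- 1
  u <- sum(x[shared]) / n +
    ((m - 1) / m) * (f1 / (2 * f2)) * sum(x[shared & y == 1]) / n
  min(u, 1)
}

#' Abundance-based Chao-Jaccard dissimilarity between two count vectors
#'
#' Computes the Chao et al. abundance-based Jaccard similarity, which
#' corrects the raw shared-abundance fractions U and V for unseen shared
#' species using shared singletons and doubletons, and returns
#' `1 - UV / (U + V - UV)`. With `binary = TRUE` the counts are reduced to
#' presence/absence and the classic Jaccard dissimilarity is returned
#' instead.
#'
#' @param x,y non-negative count vectors over the same taxa.
#' @param binary reduce to presence/absence first (default `FALSE`).
#' @return dissimilarity in `[0, 1]`; 0 for identical positive vectors, 1
#'   for disjoint supports.
#' @export
chao_dissimilarity <- function(x, y, binary = FALSE) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  if (sum(x) == 0 || sum(y) == 0) abort("empty sample: dissimilarity undefined")
  if (binary) {
    a <- x > 0
    b <- y > 0
    return(1 - sum(a & b) / sum(a | b))
  }
  u <- chao_u(x, y)
  v <- chao_u(y, x)
  if (u == 0 || v == 0) return(1)
  sim <- u * v / (u + v - u * v)
  1 - sim
}

#' Chao dissimilarity matrix for a diet table
#'
#' @param diet diet matrix tibble ([diet_matrix()]) or samples x taxa count
#'   matrix.
#' @param binary presence/absence mode (classic Jaccard).
#' @return a [stats::dist] object with sample labels.
#' @export
chao_distance <- function(diet, binary = FALSE) {
  m <- if (is.data.frame(diet)) diet_counts(diet) else as.matrix(diet)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- chao_dissimilarity(m[i, ], m[j, ], binary = binary)
    }
  }
  stats::as.dist(d)
}

# The isotonic fit and stress-1 evaluation live in compiled code
# (src/isotonic.cpp): weighted pool-adjacent-violators over tie blocks of
# the input dissimilarities, so tied values share one fitted value.

#' Nonmetric multidimensional scaling
#'
#' Minimizes Kruskal stress-1, `sqrt(sum((dhat - f)^2) / sum(dhat^2))`,
#' where `dhat` are configuration distances and `f` is the isotonic
#' regression of `dhat` on the rank order of the input dissimilarities
#' (tied dissimilarities share one fitted value). Optimization alternates a
#' Guttman majorization step with the isotonic fit; a backtracking
#' line-search guarantees the stress trace is non-increasing within each
#' start. The first start is the classical (metric) MDS configuration, the
#' rest are random; the lowest-stress solution wins. Runs are bit-for-bit
#' repeatable given `seed`.
#'
#' @param d a [stats::dist] object or symmetric dissimilarity matrix.
#' @param k target dimension (default 2).
#' @param n_starts number of starts including the metric start (default 20).
#' @param max_iter iteration cap per start (default 200).
#' @param tol convergence tolerance on the stress decrease (default 1e-6).
#' @param seed integer seed for the random starts.
#' @return object of class `trnl_nmds`: list with `points` (n x k matrix,
#'   centered), `stress`, `trace` (stress per iteration of the best start),
#'   `converged`, `n_starts`, `seed`. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
nmds <- function(d, k = 2, n_starts = 20, max_iter = 200, tol = 1e-6, seed = 1) {
  dm <- as.matrix(stats::as.dist(d))
  n <- nrow(dm)
  if (n < 3) abort("need at least 3 samples for ordination")
  lower <- lower.tri(dm)
  dvec <- dm[lower]
  ord <- order(dvec)
  blocks <- cumsum(!duplicated(dvec[ord]))
  nblock <- blocks[length(blocks)]
  eval_stress <- function(dh) .stress_iso(dh, ord, blocks, nblock)

  run_start <- function(x0) {
    x <- x0
    dh <- as.matrix(dist(x))[lower]
    s <- eval_stress(dh)$stress
    trace <- s
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      f <- eval_stress(dh)$fit
      # Guttman transform toward the disparities f
      fm <- matrix(0, n, n)
      fm[lower] <- f
      fm <- fm + t(fm)
      dm_full <- matrix(0, n, n)
      dm_full[lower] <- dh
      dm_full <- dm_full + t(dm_full)
      ratio <- ifelse(dm_full > 0, fm / dm_full, 0)
      b <- -ratio
      diag(b) <- rowSums(ratio)
      x_new <- b %*% x / n
      # backtracking so stress never increases
      step <- 1
      s_new <- s
      x_try <- x
      repeat {
        x_cand <- x + step * (x_new - x)
        dh_cand <- as.matrix(dist(x_cand))[lower]
        s_cand <- eval_stress(dh_cand)$stress
        if (s_cand <= s) {
          x_try <- x_cand
          s_new <- s_cand
          dh <- dh_cand
          break
        }
        step <- step / 2
        if (step < 1e-8) break
      }
      x <- x_try
      trace <- c(trace, s_new)
      if (s - s_new < tol) {
        s <- s_new
        converged <- TRUE
        break
      }
      s <- s_new
    }
    list(x = x, stress = s, trace = trace, converged = converged)
  }

  set.seed(seed)
  starts <- vector("list", n_starts)
  x_metric <- suppressWarnings(cmdscale(dm, k = k))
  if (ncol(x_metric) < k) {
    x_metric <- cbind(x_metric, matrix(0, n, k - ncol(x_metric)))
  }
  starts[[1]] <- x_metric
  for (i in seq_len(n_starts - 1)) {
    starts[[i + 1]] <- matrix(rnorm(n * k), n, k)
  }
  fits <- purrr::map(starts, run_start)
  best <- fits[[which.min(purrr::map_dbl(fits, "stress"))]]
  pts <- scale(best$x, center = TRUE, scale = FALSE)
  dimnames(pts) <- list(rownames(dm), paste0("NMDS", seq_len(k)))
  structure(
    list(
      points = pts, stress = best$stress, trace = best$trace,
      converged = best$converged, n_starts = n_starts, seed = seed
    ),
    class = "trnl_nmds"
  )
}

#' @export
print.trnl_nmds <- function(x, ...) {
  cat(sprintf(
    "NMDS (%d points, k = %d): stress-1 = %.4f, %s after %d iterations, %d starts\n",
    nrow(x$points), ncol(x$points), x$stress,
    if (x$converged) "converged" else "not converged", length(x$trace) - 1, x$n_starts
  ))
  invisible(x)
}

#' @method tidy trnl_nmds
#' @export
tidy.trnl_nmds <- function(x, ...) {
  as_tibble(x$points, rownames = "sample_id")
}

#' @method glance trnl_nmds
#' @export
glance.trnl_nmds <- function(x, ...) {
  tibble(
    stress = x$stress, converged = x$converged,
    n_starts = x$n_starts, n_iter = length(x$trace) - 1, seed = x$seed
  )
}

#' Analysis of similarities (ANOSIM)
#'
#' Ranks all n(n-1)/2 dissimilarities (tied values get mean ranks) and
#' computes `R = (mean between-group rank - mean within-group rank) /
#' (n(n-1)/4)`. The p-value is estimated from random label permutations
#' with the add-one estimator `p = (1 + #(R_perm >= R_obs)) / (1 + n_perm)`,
#' which can never report exactly zero. R is invariant under any strictly
#' monotone transform of the dissimilarities.
#'
#' @param d a [stats::dist] object or symmetric dissimilarity matrix.
#' @param groups grouping vector (one value per sample, in `d`'s order) or
#'   a named vector matched to `d`'s labels.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return object of class `trnl_anosim`: list with `R`, `p.value`,
#'   `n_perm`, `seed`, `perm_R` (the permuted statistics). Has [tidy()] and
#'   [glance()] methods.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1) {
  dm <- as.matrix(stats::as.dist(d))
  n <- nrow(dm)
  if (!is.null(names(groups)) && !is.null(rownames(dm))) {
    groups <- groups[rownames(dm)]
  }
  stopifnot(length(groups) == n)
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) abort("need at least two groups")
  lower <- lower.tri(dm)
  r <- rank(dm[lower]) # mean ranks for ties
  pair_idx <- which(lower, arr.ind = TRUE)
  denom <- n * (n - 1) / 4

  stat <- function(g) {
    between <- g[pair_idx[, 1]] != g[pair_idx[, 2]]
    (mean(r[between]) - mean(r[!between])) / denom
  }
  r_obs <- stat(groups)
  set.seed(seed)
  perm_r <- vapply(seq_len(n_perm), function(i) stat(sample(groups)), numeric(1))
  p <- (1 + sum(perm_r >= r_obs)) / (1 + n_perm)
  structure(
    list(R = r_obs, p.value = p, n_perm = n_perm, seed = seed, perm_R = perm_r),
    class = "trnl_anosim"
  )
}

#' @export
print.trnl_anosim <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations)\n",
              x$R, x$p.value, x$n_perm))
  invisible(x)
}

#' @method tidy trnl_anosim
#' @export
tidy.trnl_anosim <- function(x, ...) {
  tibble(statistic = x$R, p.value = x$p.value, n_perm = x$n_perm)
}

#' @method glance trnl_anosim
#' @export
glance.trnl_anosim <- function(x, ...) tidy(x)
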