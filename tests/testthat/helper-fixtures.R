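# Fixtures built in code: tiny taxonomies, references and reads with known
# structure, plus independent brute-force oracles.

# taxonomy from a spec list: list(FamilyA = list(GenusA1 = c("sp1","sp2")))
make_taxonomy <- function(spec, origin = "native") {
  rows <- list()
  for (fam in names(spec)) {
    for (gen in names(spec[[fam]])) {
      for (sp in spec[[fam]][[gen]]) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          species_id = sp, genus = gen, family = fam
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$origin <- rep_len(origin, nrow(out))
  out
}

rand_seq <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# substitute k positions of a sequence (always to a different base)
mutate_at <- function(seq, pos) {
  s <- strsplit(seq, "")[[1]]
  for (p in pos) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
  paste(s, collapse = "")
}

# brute-force primer-site scan: best window start with <= max_mm mismatches
oracle_find_site <- function(seq, primer, max_mm) {
  L <- nchar(primer)
  n <- nchar(seq)
  hits <- integer(0)
  for (st in seq_len(max(0, n - L + 1))) {
    win <- substr(seq, st, st + L - 1)
    mm <- sum(strsplit(win, "")[[1]] != strsplit(primer, "")[[1]])
    if (mm <= max_mm) hits <- c(hits, st)
  }
  hits
}

# independent Welch t-test from the closed-form formulas
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# independent Pearson chi-square from the formulas
oracle_chisq <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  x2 <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(x2 = x2, df = df, p = pchisq(x2, df, lower.tail = FALSE))
}

# straight-from-formula Chao-Jaccard dissimilarity
oracle_chao <- function(x, y) {
  u_term <- function(x, y) {
    n <- sum(x); m <- sum(y)
    sh <- which(x > 0 & y > 0)
    if (!length(sh)) return(0)
    f1 <- sum(y[sh] == 1); f2 <- sum(y[sh] == 2)
    if (f2 == 0) f2 <- 1
    u <- sum(x[sh]) / n + ((m - 1) / m) * f1 / (2 * f2) * sum(x[sh][y[sh] == 1]) / n
    min(1, u)
  }
  u <- u_term(x, y); v <- u_term(y, x)
  if (u == 0 || v == 0) return(1)
  1 - u * v / (u + v - u * v)
}

# 4-species toy reference over 2 families used by several assignment tests
toy_reference <- function() {
  tax <- make_taxonomy(list(
    Lauraceae = list(Machilus = c("Machilus kobu", "Machilus boninensis"),
                     Neolitsea = "Neolitsea aurata"),
    Moraceae = list(Ficus = c("Ficus iidaiana", "Ficus nishimurae"))
  ), origin = c("native", "native", "native", "native", "introduced"))
  set.seed(421)
  shared_laura <- rand_seq(80)
  ficus1 <- rand_seq(90)
  ficus2 <- mutate_at(ficus1, c(10, 40)) # congeneric, 2 substitutions apart
  refs <- tibble::tibble(
    species_id = tax$species_id,
    p6_seq = c(shared_laura, shared_laura, shared_laura, ficus1, ficus2)
  )
  list(tax = tax, refs = refs,
       groups = build_haplotype_groups(refs, tax))
}
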