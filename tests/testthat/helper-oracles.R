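# Independent oracles, deliberately brute-force: they share no code with
# the package implementation.

# character-level pairwise difference counter
oracle_pair_diff <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  called <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  c(d = sum(a[called] != b[called]), c = sum(called))
}

# per-column polymorphism scan
oracle_variable_sites <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  sum(apply(mat, 2, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2
  }))
}

# all permutations of 1..n (n <= 8)
all_perms <- function(n) {
  rec <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L))
    do.call(rbind, lapply(seq_along(v),
                          function(i) cbind(v[i], rec(v[-i]))))
  }
  rec(seq_len(n))
}

# exact null of a co-occurrence statistic under uniform reassignment of the
# reef-label multiset: returns every permutation's statistic value
oracle_cooccur_null <- function(group, reef, statistic = "pairs",
                                size_range = c(2, 10)) {
  n <- length(reef)
  P <- all_perms(n)
  sizes <- table(group[!is.na(group)])
  rare <- names(sizes)[sizes >= size_range[1] & sizes <= size_range[2]]
  apply(P, 1, function(idx) {
    r <- reef[idx]
    k <- table(group[!is.na(group)], r[!is.na(group)])
    if (statistic == "pairs") {
      sum(choose(k, 2))
    } else {
      sum(apply(k[rownames(k) %in% rare, , drop = FALSE] >= 2, 1, any))
    }
  })
}

# brute-force three-level AMOVA: explicit pair loops for the sums of
# squares, textbook unequal-size coefficients, and a linear solve of the
# expected-mean-square equations
oracle_amova <- function(delta2, reef, region) {
  n <- nrow(delta2)
  ss_of <- function(idx) {
    s <- 0
    for (i in idx) for (j in idx) if (i < j) s <- s + delta2[i, j]
    s / length(idx)
  }
  reefs <- unique(reef); regions <- unique(region)
  ss_total <- ss_of(seq_len(n))
  ss_within <- sum(vapply(reefs, function(r) ss_of(which(reef == r)), 0))
  ss_reg_lvl <- sum(vapply(regions, function(g) ss_of(which(region == g)), 0))
  ss_b <- ss_reg_lvl - ss_within
  ss_a <- ss_total - ss_reg_lvl
  P <- length(reefs); R <- length(regions)
  df <- c(R - 1, P - R, n - P)
  ms <- c(ss_a, ss_b, ss_within) / df

  nig <- table(reef)
  reg_of <- tapply(region, reef, `[`, 1)
  Ng <- table(region)
  nig2_by_reg <- tapply(as.vector(nig)^2, reg_of[names(nig)], sum)
  s1 <- sum(nig2_by_reg / as.vector(Ng[names(nig2_by_reg)]))
  s2 <- sum(as.vector(nig)^2) / n
  s3 <- sum(as.vector(Ng)^2) / n
  n1 <- (n - s1) / df[2]
  n2 <- (s1 - s2) / df[1]
  n3 <- (n - s3) / df[1]
  # E[MS] = A %*% sigma, solve for sigma
  A <- rbind(c(n3, n2, 1),
             c(0,  n1, 1),
             c(0,  0,  1))
  sigma <- solve(A, ms)
  list(ss = c(ss_a, ss_b, ss_within, ss_total), df = df, ms = ms,
       sigma = stats::setNames(sigma, c("regions", "reefs", "within")))
}
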