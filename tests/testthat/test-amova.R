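# Strata metadata for AMOVA toys: reef vector + reef->region map
amova_toy <- function(seqs, reef, region) {
  a <- toy_alignment(seqs, ids = sprintf("c%02d", seq_along(seqs)))
  m <- toy_metadata(a$ids, reef, region)
  list(dm = pairwise_difference_matrix(a), m = m)
}

test_that("perfect between-reef separation gives PhiST = 1", {
  t <- amova_toy(c("AAAA", "AAAA", "GGGG", "GGGG"),
                 reef = c("R1", "R1", "R2", "R2"),
                 region = c("G1", "G1", "G2", "G2"))
  am <- amova(t$dm, t$m, permutations = 0)
  expect_equal(unname(am$sigma["within"]), 0)
  expect_equal(unname(am$phi["PhiST"]), 1)
  expect_true(am$two_level)
  expect_true(is.na(am$phi["PhiPR"]))
  expect_equal(unname(am$phi["PhiRT"]), unname(am$phi["PhiST"]))
})

test_that("identical sequences everywhere give zero components, flagged Phi", {
  t <- amova_toy(rep("ACGT", 6),
                 reef = rep(c("R1", "R2", "R3"), each = 2),
                 region = rep(c("G1", "G2"), c(4, 2)))
  am <- amova(t$dm, t$m, permutations = 50)
  expect_true(am$degenerate)
  expect_equal(unname(am$sigma), c(0, 0, 0))
  expect_true(all(is.na(am$phi)))
  expect_true(all(is.na(am$p)))
})

test_that("df and SS are additive and invariant to relabeling", {
  set.seed(31)
  for (rep in 1:4) {
    n <- 12
    seqs <- random_seqs(n, 20, p_n = 0.05)
    reef <- sample(sprintf("R%d", 1:4), n, replace = TRUE)
    reef_region <- c(R1 = "G1", R2 = "G1", R3 = "G2", R4 = "G2")
    while (length(unique(reef)) < 4) reef <- sample(sprintf("R%d", 1:4), n, replace = TRUE)
    t <- amova_toy(seqs, reef, unname(reef_region[reef]))
    am <- amova(t$dm, t$m, permutations = 0)
    expect_equal(sum(am$tab$df[1:3]), n - 1)
    expect_equal(sum(am$tab$SS[1:3]), am$tab$SS[4], tolerance = 1e-12)

    # relabel reefs/regions/colonies: identical decomposition
    m2 <- t$m
    m2$reef <- paste0("x", m2$reef); m2$region <- paste0("y", m2$region)
    am2 <- amova(t$dm, as_metadata(as.data.frame(m2)), permutations = 0)
    expect_equal(am2$sigma, am$sigma)
    expect_equal(am2$phi, am$phi)
  }
})

test_that("variance components match the brute-force EMS oracle", {
  set.seed(77)
  for (rep in 1:5) {
    n <- sample(8:12, 1)
    seqs <- random_seqs(n, 25, p_n = 0.05)
    repeat {
      reef <- sample(sprintf("R%d", 1:4), n, replace = TRUE)
      if (length(unique(reef)) == 4 && all(table(reef) >= 1)) break
    }
    reef_region <- c(R1 = "G1", R2 = "G1", R3 = "G2", R4 = "G2")
    region <- unname(reef_region[reef])
    t <- amova_toy(seqs, reef, region)
    am <- amova(t$dm, t$m, permutations = 0)
    o <- oracle_amova(t$dm$D * 1.0, reef, region)
    expect_equal(unname(am$sigma), unname(o$sigma), tolerance = 1e-10)
    expect_equal(am$tab$SS[1:3], o$ss[1:3], tolerance = 1e-10)
    expect_equal(am$tab$df[1:3], o$df)
  }
})

test_that("the squared-distance switch changes delta^2 as documented", {
  t <- amova_toy(c("AAAA", "AATT", "GGGG", "GGTT"),
                 reef = c("R1", "R1", "R2", "R2"),
                 region = c("G1", "G1", "G2", "G2"))
  am1 <- amova(t$dm, t$m, permutations = 0, distance = "counts")
  am2 <- amova(t$dm, t$m, permutations = 0, distance = "squared")
  expect_gt(am2$tab$SS[4], am1$tab$SS[4])
  o <- oracle_amova(t$dm$D^2, t$m$reef[match(t$dm$ids, t$m$colony)],
                    t$m$region[match(t$dm$ids, t$m$colony)])
  expect_equal(am2$tab$SS[4], o$ss[4], tolerance = 1e-12)
})

test_that("permutation p-values are seed-reproducible and well-behaved", {
  set.seed(19)
  seqs <- c(random_seqs(6, 30), random_seqs(6, 30))
  reef <- rep(c("R1", "R2", "R3", "R4"), each = 3)
  region <- rep(c("G1", "G2"), each = 6)
  t <- amova_toy(seqs, reef, region)
  am1 <- amova(t$dm, t$m, permutations = 99, seed = 123)
  am2 <- amova(t$dm, t$m, permutations = 99, seed = 123)
  expect_equal(am1$p, am2$p)
  expect_true(all(am1$p > 0 & am1$p <= 1, na.rm = TRUE))
  expect_warning(amova(t$dm, t$m, permutations = 20, seed = 1), "coarse")
})

test_that("per-group chi-square flags only truly uneven regional spreads", {
  # group A spread proportionally to regional totals -> statistic 0, p 1
  colony <- sprintf("c%d", 1:12)
  region <- rep(c("G1", "G2", "G3"), each = 4)
  m <- toy_metadata(colony, reef = paste0("R", rep(1:6, each = 2)), region)
  asg <- data.frame(colony = colony,
                    group = c(1, 1, 2, 2, 1, 1, 2, 2, 1, 1, 2, 2),
                    kind = "core", d_to_consensus = 0,
                    stringsAsFactors = FALSE)
  h <- structure(list(assignment = asg, sizes = c(6L, 6L), n_groups = 2L,
                      consensus = NULL, mode = "haplogroup",
                      fold_log = NULL,
                      violations = data.frame()), class = "mito_haplogroups")
  res <- chisq_regional_homogeneity(h, m)
  expect_equal(res$statistic, c(0, 0))
  expect_equal(res$p, c(1, 1))

  # a group of 3 packed into one small region among 3 -> small p
  asg2 <- asg
  asg2$group <- c(1, 1, 1, 2, 2, 2, 2, 2, 2, 2, 2, 2)
  h2 <- h; h2$assignment <- asg2
  res2 <- chisq_regional_homogeneity(h2, m)
  o <- suppressWarnings(stats::chisq.test(c(3, 0, 0), p = c(1, 1, 1) / 3))
  expect_equal(res2$p[1], o$p.value, tolerance = 1e-12)
  expect_true(res2$low_expected[1])
  expect_true(all(res2$p_adj >= res2$p))
})
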