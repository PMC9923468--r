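test_that("haversine distances match closed-form references", {
  expect_equal(haversine_km(7.3, 134.5, 7.3, 134.5), 0)
  # one degree of latitude on the meridian
  expect_equal(haversine_km(0, 0, 1, 0), 6371.0088 * pi / 180,
               tolerance = 1e-6)
  expect_equal(haversine_km(0, 0, 1, 0), 111.19, tolerance = 1e-3)
  # antipodal points: half the great circle
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371.0088, tolerance = 1e-6)
  expect_error(haversine_km(91, 0, 0, 0), "latitude")
  expect_error(haversine_km(0, 200, 0, 0), "longitude")
})

test_that("haversine is symmetric and satisfies the triangle inequality", {
  set.seed(55)
  for (rep in 1:20) {
    p <- cbind(runif(3, -90, 90), runif(3, -180, 180))
    d12 <- haversine_km(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    d21 <- haversine_km(p[2, 1], p[2, 2], p[1, 1], p[1, 2])
    d13 <- haversine_km(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    d23 <- haversine_km(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    expect_equal(d12, d21)
    expect_lte(d12, d13 + d23 + 1e-9)
  }
})

test_that("reef pair table matches hand enumeration on a 3-reef toy", {
  # reef A: two identical colonies (group 1); reef B: one group-1 colony and
  # one ungrouped; reef C: a group-2 pair
  seqs <- c(a1 = "AAAAAA", a2 = "AAAAAA", b1 = "AAAAAA", b2 = "AATTTT",
            c1 = "GGGGGG", c2 = "GGGGGG")
  a <- toy_alignment(seqs)
  m <- toy_metadata(names(seqs), reef = c("A", "A", "B", "B", "C", "C"),
                    lat = c(0, 0, 0, 0, 1, 1), lon = c(0, 0, 1, 1, 0, 0),
                    heat = c(0.1, 0.1, 0.3, 0.3, 0.2, 0.2))
  dm <- pairwise_difference_matrix(a)
  h <- assign_haplogroups(a, dm)
  t <- reef_pair_table(dm, h, m)
  expect_equal(nrow(t), 3)
  ab <- t[t$reef1 == "A" & t$reef2 == "B", ]
  # cross pairs A-B: d(a,b1)=0 twice, d(a,b2)=4 twice -> mean 2
  expect_equal(ab$nuc_dist, 2)
  # sharing: a1-b1 and a2-b1 share group 1 -> 2 of 4 cross pairs
  expect_equal(ab$share, 0.5)
  expect_equal(ab$heat_diff, 0.2)
  ac <- t[t$reef1 == "A" & t$reef2 == "C", ]
  expect_equal(ac$share, 0)    # no shared groups
  expect_equal(ac$nuc_dist, 6)
  # identical colonies across reefs A and B drive share_rare too (group 1
  # has 3 members: rare)
  expect_equal(ab$share_rare, 0.5)
})

test_that("two reefs of identical colonies share everything at distance 0", {
  seqs <- c(x1 = "ACGT", x2 = "ACGT", y1 = "ACGT", y2 = "ACGT")
  a <- toy_alignment(seqs)
  m <- toy_metadata(names(seqs), reef = c("A", "A", "B", "B"))
  dm <- pairwise_difference_matrix(a)
  h <- assign_haplogroups(a, dm)
  t <- reef_pair_table(dm, h, m)
  expect_equal(t$nuc_dist, 0)
  expect_equal(t$share, 1)
})

test_that("OLS regression recovers exact and null relationships", {
  t <- data.frame(reef1 = "A", reef2 = "B",
                  geo_km = 1:20, nuc_dist = 2 * (1:20))
  r <- suppressWarnings(ibd_regression(t, "nuc_dist", "geo_km"))  # exact fit
  expect_equal(unname(r$coefficients["geo_km", "Estimate"]), 2)
  expect_equal(r$r_squared, 1)

  set.seed(6)
  t2 <- data.frame(geo_km = runif(500), nuc_dist = rnorm(500))
  r2 <- ibd_regression(t2, "nuc_dist", "geo_km")
  expect_lt(abs(r2$coefficients["geo_km", "Estimate"]), 0.5)
  expect_gt(r2$overall_p, 0.001)

  # row order is irrelevant
  perm <- sample(nrow(t2))
  r3 <- ibd_regression(t2[perm, ], "nuc_dist", "geo_km")
  expect_equal(r3$coefficients, r2$coefficients)

  expect_error(ibd_regression(data.frame(geo_km = rep(1, 5),
                                         nuc_dist = rnorm(5)),
                              "nuc_dist", "geo_km"), "zero-variance")
  expect_error(ibd_regression(t2[1:2, ], "nuc_dist", "geo_km"), "3 complete")
})

test_that("multiple regression accepts heat difference alongside distance", {
  set.seed(16)
  n <- 80
  t <- data.frame(geo_km = runif(n, 0, 50), heat_diff = runif(n, 0, 0.3))
  t$nuc_dist <- 1 + 0.1 * t$geo_km + 5 * t$heat_diff + rnorm(n, sd = 0.5)
  r <- ibd_regression(t, "nuc_dist", c("geo_km", "heat_diff"))
  expect_equal(unname(r$coefficients["geo_km", "Estimate"]), 0.1,
               tolerance = 0.05)
  expect_equal(unname(r$coefficients["heat_diff", "Estimate"]), 5,
               tolerance = 0.6)
  expect_lte(r$adj_r_squared, r$r_squared)
})

test_that("molecular rate arithmetic follows the pairwise convention", {
  # 18,642 bases at 0.1% per Myr: one mutation every ~53,600 years
  expect_equal(mutation_wait_time(18642, 0.1), 1 / (18642 * 1e-9))
  expect_equal(mutation_wait_time(18642, 0.1), 53642.3, tolerance = 0.1)
  # doubling the rate halves the wait
  expect_equal(mutation_wait_time(18642, 0.2),
               mutation_wait_time(18642, 0.1) / 2)
  expect_equal(mutation_wait_time(1e6, 1), 100)
  expect_equal(mutation_wait_time(18642, 0.1, convention = "lineage"),
               2 * mutation_wait_time(18642, 0.1))
  expect_error(mutation_wait_time(0, 0.1), "positive")

  expect_equal(divergence_time(0.2, 0.1), 2)
  expect_equal(divergence_time(0, 0.1), 0)
  expect_equal(divergence_time(0.4, 0.1), 2 * divergence_time(0.2, 0.1))
  expect_equal(divergence_time(0.2, 0.1, convention = "lineage"), 1)
  expect_error(divergence_time(0.2, 0), "positive")
})

test_that("simulated mutation clock is consistent with the rate arithmetic", {
  # colonies at divergence d from their founder after one transmission step:
  # the generator's per-transmission mutation mass matches pair_count-scale
  # expectations only qualitatively; here we check the closed-form identity
  # wait_time * L * rate/1e8 == 1 on random inputs
  set.seed(4)
  for (rep in 1:10) {
    L <- sample(1e3:1e5, 1)
    rate <- runif(1, 0.01, 1)
    w <- mutation_wait_time(L, rate)
    expect_equal(w * L * (rate / 100 / 1e6), 1, tolerance = 1e-12)
  }
})
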