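test_that("identity groups are zero-distance components with stable labels", {
  # two identical pairs + one singleton
  a <- toy_alignment(c(p1 = "AAAA", p2 = "AAAA", q1 = "GGGG", q2 = "GGGG",
                       s1 = "AAGG"))
  g <- build_identity_groups(pairwise_difference_matrix(a))
  expect_equal(length(g$groups), 2)
  expect_equal(lengths(g$groups), c(2L, 2L))
  expect_equal(g$singletons, "s1")
  # label 1 goes to the group with the smallest member id on size ties
  expect_equal(g$groups[[1]], c("p1", "p2"))

  all_diff <- toy_alignment(c(a = "AAAA", b = "GGGG", c = "TTTT"))
  g2 <- build_identity_groups(pairwise_difference_matrix(all_diff))
  expect_equal(length(g2$groups), 0)
  expect_equal(sort(g2$singletons), c("a", "b", "c"))
})

test_that("group labels are invariant to the input ordering of sequences", {
  set.seed(5)
  sim <- simulate_reefs(quick_config(seed = 5))
  a <- sim$alignment
  h1 <- assign_haplogroups(a)
  perm <- sample(a$n)
  f <- tempfile(fileext = ".fasta")
  writeLines(c(rbind(paste0(">", a$ids[perm]),
                     apply(a$seq[perm, , drop = FALSE], 1, paste0,
                           collapse = ""))), f)
  h2 <- assign_haplogroups(read_alignment(f))
  asg1 <- h1$assignment[order(h1$assignment$colony), ]
  asg2 <- h2$assignment[order(h2$assignment$colony), ]
  expect_equal(asg1$group, asg2$group)
  expect_equal(asg1$kind, asg2$kind)
})

test_that("single-base variants fold into the right group", {
  # v is 1 base from the AAAA group, 3 from the GGGA group
  a <- toy_alignment(c(a1 = "AAAA", a2 = "AAAA", b1 = "GGGA", b2 = "GGGA",
                       v = "AAAT"))
  h <- assign_haplogroups(a)
  asg <- h$assignment
  expect_equal(asg["v", "kind"], "folded")
  expect_equal(asg["v", "group"], asg["a1", "group"])
  expect_equal(asg["v", "d_to_consensus"], 1)
  expect_equal(h$fold_log$colony, "v")
  expect_false(h$fold_log$ambiguous)
  expect_true(h$fold_log$allele_unique)

  # u is 2+ bases from every consensus -> ungrouped
  a2 <- toy_alignment(c(a1 = "AAAA", a2 = "AAAA", u = "AATT"))
  h2 <- assign_haplogroups(a2)
  expect_equal(h2$assignment["u", "kind"], "ungrouped")
  expect_true(is.na(h2$assignment["u", "group"]))
})

test_that("ambiguous folds go to the largest group and are logged", {
  # v is 1 base from both consensuses; group A has 3 cores, B has 2
  a <- toy_alignment(c(a1 = "AAAAG", a2 = "AAAAG", a3 = "AAAAG",
                       b1 = "AAGGG", b2 = "AAGGG",
                       v  = "AAAGG"))
  h <- assign_haplogroups(a)
  expect_equal(h$assignment["v", "kind"], "folded")
  expect_equal(h$assignment["v", "group"], h$assignment["a1", "group"])
  expect_true(h$fold_log$ambiguous[h$fold_log$colony == "v"])
})

test_that("kinds partition the colonies in both modes", {
  sim <- simulate_reefs(quick_config(seed = 9, mutation_prob = 0.3))
  for (mode in c("haplogroup", "strict")) {
    h <- assign_haplogroups(sim$alignment, mode = mode)
    expect_equal(nrow(h$assignment), sim$alignment$n)
    expect_true(all(h$assignment$kind %in% c("core", "folded", "ungrouped")))
    grouped <- !is.na(h$assignment$group)
    expect_equal(grouped, h$assignment$kind != "ungrouped")
    if (mode == "strict") expect_true(all(h$assignment$kind != "folded"))
  }
})

test_that("strict mode keeps only cores: members form a subset of full mode", {
  sim <- simulate_reefs(quick_config(seed = 13, mutation_prob = 0.4))
  dm <- pairwise_difference_matrix(sim$alignment)
  g <- build_identity_groups(dm)
  h_full <- fold_single_base_variants(g, dm, sim$alignment)
  h_strict <- strict_identity_assignment(g, sim$alignment)
  in_full <- h_full$assignment$colony[h_full$assignment$kind != "ungrouped"]
  in_strict <- h_strict$assignment$colony[h_strict$assignment$kind != "ungrouped"]
  expect_true(all(in_strict %in% in_full))
  expect_lte(length(in_strict), length(in_full))
  # strict groups of size >= 2 only; folded members never counted
  expect_true(all(h_strict$sizes[h_strict$sizes > 0] >= 2))
})

test_that("group size spectrum flags rare groups by the inclusive 2-10 rule", {
  sim <- simulate_reefs(quick_config(seed = 2))
  h <- assign_haplogroups(sim$alignment)
  spec <- group_size_spectrum(h)
  expect_equal(spec$size, h$sizes)
  expect_equal(spec$rare, h$sizes >= 2 & h$sizes <= 10)
  expect_error(group_size_spectrum(h, rare_range = c(10, 2)), "range")
  # folded members count toward the size
  n_members <- sum(h$assignment$kind %in% c("core", "folded"))
  expect_equal(sum(spec$size), n_members)
})

test_that("missing-data intransitivity is detected and logged", {
  # a=b and b=c over jointly called sites, but a != c
  a <- toy_alignment(c(a = "AAAA", b = "AAAN", c = "AAAG"))
  # check premise: a~b d=0, b~c d=0, a~c d=1 over jointly called
  dm <- pairwise_difference_matrix(a)
  expect_equal(dm$D["a", "b"], 0L)
  expect_equal(dm$D["b", "c"], 0L)
  expect_equal(dm$D["a", "c"], 1L)
  g <- build_identity_groups(dm)
  expect_equal(length(g$groups), 1)   # one component holds all three
  expect_equal(nrow(g$violations), 1)
  expect_setequal(unlist(g$violations[, c("colony1", "colony2")]), c("a", "c"))
})
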