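test_that("support, growth and confidence follow their definitions", {
  m <- matrix(FALSE, 10, 2,
              dimnames = list(sprintf("P%02d", 1:10), c("a:UP", "b:DOWN")))
  m[1:8, "a:UP"] <- TRUE
  m[, "b:DOWN"] <- TRUE
  expect_equal(pattern_support(m, "a:UP"), 0.8)
  expect_equal(pattern_support(m, "b:DOWN"), 1.0)
  expect_error(pattern_support(m[0, , drop = FALSE], "a:UP"), "empty")

  expect_equal(growth_rate(0.9, 0.45), 2.0)
  expect_equal(growth_rate(0.45, 0.9), 2.0)        # symmetry
  expect_equal(growth_rate(0.5, 0.5), 1.0)
  expect_equal(growth_rate(0.8, 0, cap = 100), 100)
  expect_error(growth_rate(0, 0), "nowhere")

  # confidence of the rule pattern => subgroup
  m2 <- matrix(FALSE, 8, 1, dimnames = list(sprintf("P%d", 1:8), "a:UP"))
  m2[1:3, ] <- TRUE
  expect_equal(pattern_confidence(m2, "a:UP", sprintf("P%d", 1:3)), 1.0)
  m2[4, ] <- TRUE
  expect_equal(pattern_confidence(m2, "a:UP", sprintf("P%d", 1:3)), 0.75)
  expect_no_error(pattern_confidence(m2, "a:UP", "P8"))
  m2[] <- FALSE
  expect_error(pattern_confidence(m2, "a:UP", "P1"), "absent")
})

test_that("support agrees with a brute-force row scan on random matrices", {
  set.seed(101)
  for (trial in 1:10) {
    m <- random_item_matrix(12, 6)
    for (k in 1:3) {
      set <- sample(colnames(m), k)
      brute <- sum(apply(m[, set, drop = FALSE], 1, all)) / nrow(m)
      expect_equal(pattern_support(m, set), brute)
    }
  }
})

test_that("the miner reproduces the worked six-patient contrast example", {
  # subgroup P1-P3; A:UP exclusive to it, B:DOWN also in P4
  m <- matrix(FALSE, 6, 2,
              dimnames = list(paste0("P", 1:6), c("A:UP", "B:DOWN")))
  m[1:3, "A:UP"] <- TRUE
  m[1:4, "B:DOWN"] <- TRUE
  pats <- mine_contrast_patterns(m, paste0("P", 1:3))
  expect_equal(pats$items, c("A:UP", "A:UP;B:DOWN"))
  expect_equal(pats$s1, c(1, 1))
  expect_equal(pats$s2, c(0, 0))
  expect_equal(pats$growth, c(100, 100))
  expect_equal(pats$confidence, c(1, 1))
  # B:DOWN alone fails the exclusivity (confidence) filter
  expect_false("B:DOWN" %in% pats$items)
})

test_that("items exclusive to and universal in the subgroup are all retained", {
  m <- matrix(FALSE, 8, 3,
              dimnames = list(paste0("P", 1:8),
                              c("a:UP", "b:UP", "c:DOWN")))
  m[1:4, ] <- TRUE
  pats <- mine_contrast_patterns(m, paste0("P", 1:4))
  expect_equal(nrow(pats), 7)  # every nonempty subset of three items
  expect_true(all(pats$s1 == 1 & pats$s2 == 0 & pats$confidence == 1))
})

test_that("the miner equals exhaustive enumeration on random instances", {
  set.seed(202)
  ctrl <- mining_control(max_pattern_len = 8)
  for (trial in 1:20) {
    m <- random_item_matrix(20, 8)
    sg <- sample(rownames(m), 6)
    got <- mine_contrast_patterns(m, sg, ctrl)
    want <- oracle_mine(m, sg, ctrl)
    expect_equal(as.data.frame(got), want)
  }
})

test_that("focus support is anti-monotone under item addition", {
  set.seed(303)
  for (trial in 1:10) {
    m <- random_item_matrix(15, 6)
    set <- sample(colnames(m), 3)
    s_all <- pattern_support(m, set)
    for (k in 1:2)
      expect_gte(pattern_support(m, set[1:k]), s_all)
  }
})

test_that("closed and maximal filters prune patterns with redundant support sets", {
  m <- matrix(FALSE, 6, 2,
              dimnames = list(paste0("P", 1:6), c("A:UP", "B:UP")))
  m[1:3, ] <- TRUE   # A and B perfectly co-occur
  sg <- paste0("P", 1:3)
  all_p <- mine_contrast_patterns(m, sg, mining_control(filter = "all"))
  expect_equal(all_p$items, c("A:UP", "B:UP", "A:UP;B:UP"))
  closed <- mine_contrast_patterns(m, sg, mining_control(filter = "closed"))
  expect_equal(closed$items, "A:UP;B:UP")
  maximal <- mine_contrast_patterns(m, sg,
                                    mining_control(filter = "maximal"))
  expect_equal(maximal$items, "A:UP;B:UP")
})

test_that("the J-value is the Bayesian blend of subgroup and reference quality", {
  pats <- toy_patterns()
  pats$growth <- c(3, 5)                      # Jorg = 4
  expect_equal(j_value(pats, random_jorgs = 2, T = 30, M = 30), 3.0)
  expect_equal(j_value(pats, random_jorgs = 4, T = 10, M = 10), 4.0)
  expect_equal(j_value(pats, random_jorgs = 2, T = 0, M = 30), 2.0)
  expect_equal(pattern_jorg(pats, "sum"), 8)
  expect_error(j_value(pats[0, ], 2, 30, 30), "no contrast pattern")

  set.seed(404)
  for (trial in 1:20) {
    pats$growth <- runif(2, 1, 100)
    jorg <- mean(pats$growth)
    javg <- runif(1, 1, 100)
    Tw <- runif(1, 0, 50); M <- runif(1, 1, 50)
    j <- j_value(pats, javg, Tw, M)
    expect_gte(j, min(jorg, javg) - 1e-12)
    expect_lte(j, max(jorg, javg) + 1e-12)
  }
})

test_that("reference subgroups are reproducible and summarize cohort structure", {
  case <- simulated_case(5, small_sim_control())
  ref1 <- reference_subgroups(case$cohort$clinical, case$cohort$items,
                              R = 15, seed = 9)
  ref2 <- reference_subgroups(case$cohort$clinical, case$cohort$items,
                              R = 15, seed = 9)
  expect_identical(ref1, ref2)
  expect_length(ref1$jorgs, 15)
  expect_true(all(ref1$jorgs >= 1))
  expect_equal(ref1$M, mean(ref1$sizes))
})

test_that("mining guards its preconditions", {
  m <- random_item_matrix(6, 3)
  expect_error(mine_contrast_patterns(m, character(0)), "empty")
  expect_error(mine_contrast_patterns(m, rownames(m)), "strict subset")
  expect_error(mine_contrast_patterns(m, "nope"), "unknown patient")
})
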