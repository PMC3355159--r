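test_that("dualize maps listed features to ranks and rejects invalid lists", {
  u <- feature_universe(c("g1", "g2", "g3", "g4"))
  tau <- dualize(ranked_list(c("g3", "g1"), u), u)
  expect_identical(tau, c(g3 = 1L, g1 = 2L))
  expect_false(any(c("g2", "g4") %in% names(tau)))

  full <- dualize(ranked_list(c("g2", "g4", "g1", "g3"), u), u)
  expect_setequal(unname(full), 1:4)

  expect_error(ranked_list(c("g1", "g1"), u), class = "canberra_input_error")
  expect_error(ranked_list("g9", u), class = "canberra_input_error")
})

test_that("support partition sizes always add up to p", {
  u <- feature_universe(size = 100)
  L <- ranked_list(u$features[1:10], u)
  part <- partition_support(L, L, u)
  expect_identical(part$z, 10L)
  expect_identical(part$u, 90L)

  M <- ranked_list(u$features[11:20], u)
  expect_identical(partition_support(L, M, u)$z, 0L)

  u6 <- feature_universe(size = 6)
  A <- ranked_list(u6$features[c(2, 5, 1)], u6)
  B <- ranked_list(u6$features[c(4, 1, 6, 3)], u6)
  pt <- partition_support(A, B, u6)
  expect_identical(pt$z + (pt$l1 - pt$z) + (pt$l2 - pt$z) + pt$u, pt$p)
})

test_that("identical partial lists reproduce the reference normalized Complete value", {
  u <- feature_universe(size = 100)
  L <- ranked_list(u$features[1:10], u)
  for (bd in list(measure_closed(L, L, u), measure_marginal(L, L, u))) {
    expect_identical(bd$core, 0)
    expect_equal(bd$complete_normalized, 0.692830, tolerance = 5e-6)
  }
})

test_that("on complete lists the measure collapses to the plain Canberra distance", {
  p <- 12
  u <- feature_universe(size = p)
  set.seed(TEST_SEED)
  L1 <- ranked_list(u$features[sample.int(p)], u)
  L2 <- ranked_list(u$features[sample.int(p)], u)
  bd <- measure_closed(L1, L2, u)
  expect_identical(bd$t2, 0)
  expect_identical(bd$t3, 0)
  d <- canberra_rank_distance(dualize(L1, u)[u$features],
                              dualize(L2, u)[u$features])
  expect_equal(bd$complete, d, tolerance = 1e-12)
  expect_equal(measure_bruteforce(L1, L2, u), d, tolerance = 1e-12)
})

test_that("the three strategies agree, including the 3-vs-4 list example at p = 6", {
  u <- feature_universe(size = 6)
  A <- ranked_list(u$features[c(2, 5, 1)], u)
  B <- ranked_list(u$features[c(4, 1, 6, 3)], u)
  m <- measure_marginal(A, B, u)
  cl <- measure_closed(A, B, u)
  bf <- measure_bruteforce(A, B, u)      # (6-3)! * (6-4)! = 12 pairs
  oracle <- r_completion_mean(A, B, u)
  expect_equal(bf, oracle, tolerance = 1e-12)
  expect_equal(m$complete, oracle, tolerance = 1e-10)
  expect_equal(cl$complete, oracle, tolerance = 1e-10)
  for (f in c("t1", "t2", "t3", "core", "complete"))
    expect_equal(cl[[f]], m[[f]], tolerance = 1e-9)
})

test_that("strategies agree on random instances with mixed lengths", {
  set.seed(TEST_SEED)
  for (k in 1:60) {
    p <- sample(4:9, 1)
    l1 <- p - sample(0:min(4, p), 1)
    l2 <- p - sample(0:min(4, p), 1)
    inst <- random_instance(p, l1, l2)
    m <- measure_marginal(inst$L1, inst$L2, inst$u)
    cl <- measure_closed(inst$L1, inst$L2, inst$u)
    bf <- measure_bruteforce(inst$L1, inst$L2, inst$u)
    expect_equal(cl$complete, bf, tolerance = 1e-9)
    for (f in c("t1", "t2", "t3", "core", "complete"))
      expect_equal(cl[[f]], m[[f]], tolerance = 1e-9)
  }
})

test_that("the measure is symmetric in its two lists", {
  set.seed(TEST_SEED)
  for (k in 1:10) {
    inst <- random_instance(12, 5, 8)
    a <- measure_closed(inst$L1, inst$L2, inst$u)
    b <- measure_closed(inst$L2, inst$L1, inst$u)
    for (f in c("t1", "t2", "t3", "core", "complete", "complete_normalized"))
      expect_equal(a[[f]], b[[f]], tolerance = 1e-12)
  }
})

test_that("self-dissimilarity: core zero always, complete positive for genuinely partial lists", {
  u <- feature_universe(size = 15)
  for (l in c(1, 7, 13)) {
    L <- ranked_list(u$features[seq_len(l)], u)
    bd <- measure_closed(L, L, u)
    expect_identical(bd$core, 0)
    expect_gt(bd$complete, 0)
  }
  full <- ranked_list(u$features, u)
  expect_identical(measure_closed(full, full, u)$complete, 0)
  # boundary l = p - 1: the completion is unique, so the self-distance
  # collapses to zero just as for complete lists
  near <- ranked_list(u$features[1:14], u)
  bd <- measure_closed(near, near, u)
  expect_identical(bd$complete, 0)
  expect_equal(measure_bruteforce(near, near, u), 0, tolerance = 1e-15)
})

test_that("shared-support pairs decompose as identical-complete plus core", {
  u <- feature_universe(size = 40)
  set.seed(TEST_SEED)
  support <- u$features[sample.int(40, 8)]
  L1 <- ranked_list(support[sample.int(8)], u)
  L2 <- ranked_list(support[sample.int(8)], u)
  pair <- measure_closed(L1, L2, u)
  ident <- measure_closed(L1, L1, u)
  expect_equal(pair$complete, ident$complete + pair$core, tolerance = 1e-12)
})

test_that("T3 ignores the ordering inside the lists (bit-identical)", {
  u <- feature_universe(size = 30)
  set.seed(TEST_SEED)
  s1 <- u$features[sample.int(30, 6)]
  s2 <- u$features[sample.int(30, 9)]
  ref <- measure_closed(ranked_list(s1, u), ranked_list(s2, u), u)
  for (k in 1:5) {
    bd <- measure_closed(ranked_list(sample(s1), u),
                         ranked_list(sample(s2), u), u)
    expect_identical(bd$t3, ref$t3)
  }
})

test_that("normalization divides by E(p) and never clamps values above one", {
  expect_identical(normalize_measure(0, 10), 0)
  E10 <- expected_canberra(10)
  expect_equal(normalize_measure(E10, 10), 1, tolerance = 1e-12)
  md <- max_distant_ordering(10)
  expect_gt(normalize_measure(attr(md, "distance"), 10), 1)
  expect_error(normalize_measure(1, 1), class = "canberra_input_error")
})

test_that("empty lists are legal: the measure degenerates to the unselected term", {
  p <- 7
  u <- feature_universe(size = p)
  empty <- ranked_list(character(0), u)
  bd <- measure_closed(empty, empty, u)
  expect_identical(bd$core, 0)
  expect_identical(bd$u, as.integer(p))
  # both completions are unconstrained uniform permutations, so the mean
  # distance is exactly E(p)
  expect_equal(bd$complete_normalized, 1, tolerance = 1e-10)
  L <- ranked_list(u$features[1:3], u)
  expect_equal(measure_closed(empty, L, u)$complete,
               r_completion_mean(empty, L, u), tolerance = 1e-10)
})

test_that("enumeration refuses problems beyond its cap with a capability error", {
  u <- feature_universe(size = 30)
  L <- ranked_list(u$features[1:3], u)
  expect_error(measure_bruteforce(L, L, u), class = "canberra_cap_error")
  expect_error(measure_bruteforce(L, L, u), "completion pairs")
})
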