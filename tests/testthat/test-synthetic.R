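test_that("random complete lists are seeded permutations of the universe", {
  S <- random_complete_lists(4, 9, seed = TEST_SEED)
  for (L in S$lists) expect_setequal(L$items, S$universe$features)
  S2 <- random_complete_lists(4, 9, seed = TEST_SEED)
  expect_identical(lapply(S$lists, `[[`, "items"),
                   lapply(S2$lists, `[[`, "items"))
  expect_identical(attr(S, "seed"), TEST_SEED)
  expect_error(random_complete_lists(1, 5), class = "canberra_input_error")
})

test_that("every feature leads a random complete list at the uniform rate", {
  S <- random_complete_lists(1e4, 5, seed = TEST_SEED)
  first <- vapply(S$lists, function(L) L$items[1], character(1))
  freq <- table(factor(first, levels = S$universe$features)) / 1e4
  se <- sqrt(0.2 * 0.8 / 1e4)
  expect_true(all(abs(freq - 0.2) < 3 * se))
})

test_that("random partial lists respect length, distinctness and shared support", {
  S <- random_partial_lists(6, 40, 12, seed = TEST_SEED)
  for (L in S$lists) {
    expect_identical(L$length, 12L)
    expect_false(anyDuplicated(L$items) > 0)
  }
  Sh <- random_partial_lists(6, 40, 12, seed = TEST_SEED,
                             shared_support = TRUE)
  supports <- lapply(Sh$lists, function(L) sort(L$items))
  for (s in supports[-1]) expect_identical(s, supports[[1]])
  expect_error(random_partial_lists(3, 10, 11),
               class = "canberra_input_error")
})

test_that("shared-support random pairs average to E(l)/E(p) after normalization", {
  set.seed(TEST_SEED)
  n_pairs <- 300
  vals <- vapply(seq_len(n_pairs), function(k) {
    S <- random_partial_lists(2, 100, 10, shared_support = TRUE)
    measure_closed(S$lists[[1]], S$lists[[2]], S$universe)$core_normalized
  }, numeric(1))
  target <- expected_canberra(10) / expected_canberra(100)
  se <- stats::sd(vals) / sqrt(n_pairs)
  expect_lt(abs(mean(vals) - target), 3 * se)
})

test_that("the maximally distant ordering is found by exhaustive search", {
  md2 <- max_distant_ordering(2)
  expect_identical(as.integer(md2), c(2L, 1L))
  expect_equal(attr(md2, "distance"), 2 / 3, tolerance = 1e-12)

  P <- perms_all(3)
  oracle <- max(apply(P, 1, canberra_vec, b = 1:3))
  expect_equal(attr(max_distant_ordering(3), "distance"), oracle,
               tolerance = 1e-12)

  expect_error(max_distant_ordering(11), class = "canberra_cap_error")
})

test_that("replicated stability runs are reproducible with nonnegative variance", {
  r1 <- replicate_table1(5, 10, replicates = 5, seed = TEST_SEED)
  r2 <- replicate_table1(5, 10, replicates = 5, seed = TEST_SEED)
  expect_identical(r1, r2)
  expect_gte(r1[["variance"]], 0)
  expect_error(replicate_table1(5, 10, replicates = 1),
               class = "canberra_input_error")
})

test_that("reference pairs at p = 100 reproduce the deterministic rows and decompose additively", {
  tab <- replicate_table2(2, seed = TEST_SEED)
  id <- tab[tab$lists == "identical", ]
  expect_identical(id$core, 0)
  expect_equal(id$complete, 0.692830, tolerance = 5e-6)
  mx <- tab[tab$lists == "max_distant", ]
  expect_equal(mx$core, 0.128448, tolerance = 5e-6)
  expect_equal(mx$complete, 0.821278, tolerance = 5e-6)
  for (cc in 2:3) {
    t <- replicate_table2(cc, seed = TEST_SEED)
    expect_equal(t$complete[t$lists == "max_distant"],
                 t$complete[t$lists == "identical"] +
                   t$core[t$lists == "max_distant"],
                 tolerance = 1e-12)
    expect_equal(t$complete[t$lists == "random"],
                 t$complete[t$lists == "identical"] +
                   t$core[t$lists == "random"],
                 tolerance = 1e-12)
  }
  expect_error(replicate_table2(1), class = "canberra_input_error")
  expect_error(replicate_table2(6), class = "canberra_input_error")
})

test_that("core/complete ratio of sparse random pairs decreases as the universe grows", {
  set.seed(TEST_SEED)
  l <- 10
  ratio_at <- function(p) {
    mean(vapply(1:20, function(k) {
      S <- random_partial_lists(2, p, l, shared_support = TRUE)
      bd <- measure_closed(S$lists[[1]], S$lists[[2]], S$universe)
      bd$core / bd$complete
    }, numeric(1)))
  }
  ratios <- vapply(c(100, 300, 1000), ratio_at, numeric(1))
  expect_true(all(diff(ratios) < 0))
})
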