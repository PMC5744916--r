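test_that("leverage follows the joint-minus-expected frequency definition", {
  r <- list(n = 7936, cover_count = 2459, support_count = 1714,
            consequent_count = 2453)
  expect_equal(leverage_of(r), 1714 / 7936 - (2459 / 7936) * (2453 / 7936))
  expect_equal(round(leverage_of(r), 3), 0.120)
  # exact independence in a 4-row construction
  indep <- list(n = 4, cover_count = 2, support_count = 1,
                consequent_count = 2)
  expect_equal(leverage_of(indep), 0)
  # empty antecedent cover
  z <- list(n = 100, cover_count = 0, support_count = 0,
            consequent_count = 40)
  expect_equal(leverage_of(z), 0)
  expect_error(leverage_of(list(n = 0, cover_count = 0, support_count = 0,
                                consequent_count = 0)), "n = 0")
})

test_that("productivity test equals the one-sided Fisher/hypergeometric tail", {
  # printed 2x2: fluid in 1714/2459 hypotension vs 739/5477 others
  co <- build_fixture(fixture_margins(2))
  M <- encode_records(co, "first_call_patient")
  p <- productivity_test(
    list(antecedent = "trigger=hypotension_sbp_le_90",
         consequent = "iv_fluid"), M)
  expect_lt(p, 1e-15)
  expect_equal(p, stats::phyper(1714 - 1, 2453, 7936 - 2453, 2459,
                                lower.tail = FALSE))
  # cross-check the max-over-generalisations path against fisher.test
  for (seed in 1:5) {
    Mx <- rand_item_matrix(120, 6, seed)
    rule <- list(antecedent = c("a1", "a2"), consequent = "y")
    p_imp <- productivity_test(rule, Mx)
    ps <- vapply(1:2, function(d) {
      g <- rule$antecedent[-d]
      in_g <- Mx[, g]
      in_a <- Mx[, "a1"] & Mx[, "a2"]
      k <- sum(in_a & Mx[, "y"]); na <- sum(in_a)
      N <- sum(in_g); K <- sum(in_g & Mx[, "y"])
      tab <- matrix(c(k, na - k, K - k, N - K - na + k), 2, 2)
      stats::fisher.test(tab, alternative = "greater")$p.value
    }, 0)
    expect_equal(p_imp, max(ps), tolerance = 1e-10)
  }
})

test_that("unproductive specialisations get large p-values", {
  # an everywhere-true item leaves the cover unchanged -> no improvement
  M <- cbind(a = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
             b = rep(TRUE, 6),
             y = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  p <- productivity_test(list(antecedent = c("a", "b"),
                              consequent = "y"), M)
  expect_gte(p, 0.5)
})

test_that("Bonferroni filter divides alpha by the searched-space size", {
  rules <- data.frame(p_productive = c(1e-5, 1e-4))
  out <- bonferroni_filter(rules, search_space_size = 1000, alpha = 0.05)
  expect_equal(out$significant, c(TRUE, FALSE))
  expect_error(bonferroni_filter(rules, 0), "search_space_size")
  expect_equal(rule_search_space(12, 3), 12 + 66 + 220)
})

test_that("mining equals the exhaustive brute-force oracle on random instances", {
  for (seed in 1:10) {
    M <- rand_item_matrix(200, 11, seed, assoc = seed %% 2 == 0)
    got <- mine_rules(M, mining_config("y", k = 15))
    want <- oracle_mine(M, "y", k = 15)
    expect_equal(nrow(got), if (is.null(want)) 0L else nrow(want))
    if (!is.null(want) && nrow(want)) {
      expect_equal(got$antecedent, want$antecedent)
      expect_equal(got$cover_count, want$cover_count)
      expect_equal(got$support_count, want$support_count)
      expect_equal(got$leverage, want$leverage, tolerance = 1e-12)
      expect_equal(got$p_productive, want$p_productive, tolerance = 1e-9)
    }
  }
})

test_that("pruned and exhaustive search return identical results", {
  co <- build_fixture(fixture_margins(2))
  M <- encode_records(co, "first_call_patient")
  a <- mine_rules(M, mining_config("iv_fluid", k = 25))
  b <- mine_rules(M, mining_config("iv_fluid", k = 25, exhaustive = TRUE))
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("the leverage upper bound never underestimates a specialisation", {
  M <- rand_item_matrix(150, 8, 99)
  n <- nrow(M); q <- sum(M[, "y"])
  items <- paste0("a", 1:8)
  for (i in items) {
    sup_i <- sum(M[, i] & M[, "y"])
    ub <- metminer:::leverage_upper_bound(sup_i, n, q)
    others <- setdiff(items, i)
    for (j in others) {
      for (k in setdiff(others, j)) {
        cov <- sum(M[, i] & M[, j] & M[, k])
        sup <- sum(M[, i] & M[, j] & M[, k] & M[, "y"])
        lev <- sup / n - (cov / n) * (q / n)
        expect_lte(lev, ub + 1e-12)
      }
    }
  }
})

test_that("degenerate targets yield an empty result with a warning", {
  M <- rand_item_matrix(50, 5, 1)
  M[, "y"] <- TRUE
  expect_warning(r <- mine_rules(M, mining_config("y")), "degenerate")
  expect_equal(nrow(r), 0)
})

test_that("output is sorted by the ranking measure with deterministic tie-breaks", {
  # plant a genuine interaction so several productive rules exist
  set.seed(5)
  n <- 600
  A <- matrix(stats::runif(n * 6) < 0.4, n,
              dimnames = list(NULL, paste0("a", 1:6)))
  p_y <- ifelse(A[, 1] & A[, 2], 0.9, ifelse(A[, 1] | A[, 2], 0.55, 0.1))
  M <- cbind(A, y = stats::runif(n) < p_y)
  r <- mine_rules(M, mining_config("y", k = 50))
  expect_gt(nrow(r), 1)           # the planted associations must surface
  expect_true(all(diff(r$leverage) <= 1e-12))
  r2 <- mine_rules(M, mining_config("y", k = 50,
                                    ranking_measure = "strength"))
  expect_gt(nrow(r2), 1)
  expect_true(all(diff(r2$strength) <= 1e-12))
})

test_that("encoded matrices have the right shape and column sums", {
  co <- tiny_cohort()
  M <- encode_records(co, "first_call_patient")
  expect_equal(nrow(M), 3)
  expect_equal(sum(M[, "trigger=hypotension_sbp_le_90"]), 2)
  expect_equal(sum(M[, "iv_fluid"]), 1)
  Mc <- encode_records(co, "call")
  expect_equal(nrow(Mc), 5)
  expect_equal(sum(Mc[, "trigger=hypotension_sbp_le_90"]), 3)
  # column sums at call level equal the vocabulary frequency table
  expect_equal(sum(Mc[, "ecg"]),
               sum(metminer:::cell_has(co$calls$interventions, "ecg")))
  empty <- met_cohort(co$episodes[0, ], co$calls[0, ])
  expect_error(encode_records(empty), "empty cohort")
})
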