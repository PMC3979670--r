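test_that("Kruskal-Wallis handles degenerate and textbook inputs", {
  ident <- list(a = rep(2, 5), b = rep(2, 5), c = rep(2, 5))
  kw <- kruskal_wallis(ident)
  expect_equal(kw$H, 0)
  expect_equal(kw$p, 1)
  # brute-force rank arithmetic for two clean groups (no ties):
  # H = 12/(N(N+1)) * sum(R_g^2/n_g) - 3(N+1)
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6))
  kw2 <- kruskal_wallis(g)
  H_oracle <- 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7
  expect_equal(kw2$H, H_oracle)
  expect_equal(kw2$df, 1)
  expect_error(kruskal_wallis(list(a = 1:3)), "2 groups")
  expect_error(kruskal_wallis(list(a = 1:3, b = numeric(0))), "empty")
})

test_that("Kruskal-Wallis agrees with the rank-sum chi-square form for 2 groups", {
  set.seed(41)
  x <- rpois(11, 6); y <- rpois(11, 9)
  kw <- kruskal_wallis(list(a = x, b = y))
  wt <- stats::kruskal.test(list(x, y))
  expect_equal(kw$H, unname(wt$statistic))
  expect_equal(kw$p, wt$p.value)
})

test_that("Kruskal-Wallis type-I error is nominal on a simulated null", {
  set.seed(42)
  rej <- replicate(1000, {
    g <- lapply(1:5, function(i) rlnorm(11, 1, 0.6))
    kruskal_wallis(g)$p < 0.05
  })
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})

test_that("Dunn's comparisons produce coherent letters", {
  ident <- list(a = rep(1:4, 3), b = rep(1:4, 3), c = rep(1:4, 3))
  d <- dunn_posthoc(ident)
  expect_true(all(!d$comparisons$significant))
  expect_equal(unname(d$letters), rep("a", 3))
  # two widely separated groups among five get distinct letters
  set.seed(43)
  g <- list(d1 = rnorm(11, 0, 0.1), d2 = rnorm(11, 0.3, 0.1),
            d3 = rnorm(11, 0.5, 0.1), d4 = rnorm(11, 9.7, 0.1),
            d6 = rnorm(11, 10, 0.1))
  d2 <- dunn_posthoc(g)
  l <- d2$letters
  expect_true(!any(strsplit(l[["d1"]], "")[[1]] %in%
                     strsplit(l[["d6"]], "")[[1]]))
  expect_error(dunn_posthoc(list(a = 1:3, b = 4:6)), "3 groups")
})

test_that("Dunn's test separates day-1-like from day-6-like lunge rates", {
  set.seed(44)
  hits <- replicate(200, {
    g <- list(d1 = rpois(11, 0.5), d2 = rpois(11, 2), d3 = rpois(11, 8),
              d4 = rpois(11, 14), d6 = rpois(11, 20))
    d <- dunn_posthoc(g)
    cmp <- d$comparisons
    cmp$significant[cmp$group1 == "d1" & cmp$group2 == "d6"]
  })
  expect_gte(mean(hits), 0.95)
})

test_that("arcsine proportion comparisons transform correctly and detect change", {
  b <- list(a = c(0, 100), b = c(100, 100))
  r <- arcsine_proportion_comparisons(b)
  expect_equal(unname(r$transformed), c(0, pi / 2))
  same <- list(a = c(30, 100), b = c(30, 100), c = c(30, 100))
  expect_true(all(!arcsine_proportion_comparisons(same)$comparisons$significant))
  expect_error(arcsine_proportion_comparisons(list(a = c(2, 1), b = c(1, 2))),
               "proportions")
  # day-1 vs day-3 grooming-sized change at cohort-scale denominators:
  # oracle two-proportion normal computation gives |z| >> 1.96
  p1 <- 0.20; p3 <- 0.37; n <- 3000
  z_oracle <- abs(asin(sqrt(p1)) - asin(sqrt(p3))) / sqrt(1 / (4 * n) * 2)
  expect_gt(z_oracle, 10)
  r2 <- arcsine_proportion_comparisons(list(d1 = c(p1 * n, n),
                                            d3 = c(p3 * n, n)))
  expect_true(all(r2$comparisons$significant))
})

test_that("dominance test builds the binomial reference histogram", {
  rec <- data.frame(pair_id = letters[1:4], n1 = c(1, 2, 3, 2),
                    n_total = c(2, 4, 6, 4))
  r <- dominance_test(rec)
  expect_equal(r$mean, 0.5)
  expect_equal(r$df, 10)
  expect_equal(sum(r$expected), r$n_pairs)   # conservation
  expect_equal(sum(r$observed), r$n_pairs)
  expect_equal(which.max(r$observed), 6)     # all pairs at 0.5, central bin
  # one pair with n_total = 2: mass (0.25, 0.5, 0.25) at {0, 0.5, 1}
  one <- dominance_test(data.frame(pair_id = "a", n1 = 1, n_total = 2))
  expect_equal(one$expected[c(1, 6, 11)], c(0.25, 0.5, 0.25))
  expect_equal(sum(one$expected), 1)
  # eligibility filter
  expect_error(dominance_test(data.frame(pair_id = "a", n1 = 0, n_total = 1),
                              min_total = 2), "eligible")
})

test_that("dominance test keeps its size under the binomial null", {
  set.seed(46)
  keep <- replicate(200, {
    n_tot <- pmax(rpois(55, 10), 1)
    n1 <- rbinom(55, n_tot, 0.5)
    dominance_test(data.frame(pair_id = seq_len(55), n1 = n1,
                              n_total = n_tot))$p > 0.05
  })
  expect_gte(mean(keep), 0.90)
})

test_that("escalation test is null-calibrated and detects doubling rates", {
  ident <- matrix(3, nrow = 8, ncol = 5)
  r <- escalation_test(list(d3 = ident))
  expect_equal(r$H, 0)
  expect_equal(r$p, 1)
  expect_error(escalation_test(list(d3 = matrix(1, 4, 1))), "2 intervals")
  set.seed(47)
  null_p <- replicate(200, {
    m <- matrix(rpois(11 * 5, 4), 11, 5)
    escalation_test(list(d3 = m))$p
  })
  expect_gte(mean(null_p > 0.05), 0.90)
  esc_p <- replicate(200, {
    m <- sapply(0:4, function(i) rpois(11, 1.5 * 2^i))
    escalation_test(list(d3 = m))$p
  })
  expect_gte(mean(esc_p < 0.05), 0.90)
})

test_that("rank tests are invariant under monotone relabeling of groups", {
  set.seed(48)
  g <- list(a = rpois(9, 5), b = rpois(9, 7), c = rpois(9, 9))
  g2 <- stats::setNames(g, c("z10", "z20", "z30"))
  expect_equal(kruskal_wallis(g)$H, kruskal_wallis(g2)$H)
  expect_equal(unname(dunn_posthoc(g)$comparisons$Q),
               unname(dunn_posthoc(g2)$comparisons$Q))
})
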