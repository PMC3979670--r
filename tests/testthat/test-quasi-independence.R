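eth <- default_ethogram()

test_that("IPF reproduces the symmetric fixed point exactly", {
  n <- matrix(5L, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(n) <- 0L
  e <- fit_quasi_independence(transition_counts(n))
  expect_equal(e[row(e) != col(e)], rep(5, 6), tolerance = 1e-9)
})

test_that("IPF agrees with the alternating-scaling oracle", {
  # fixed 3x3 case
  n <- matrix(c(0, 2, 8, 4, 0, 6, 3, 7, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tc <- transition_counts(n)
  expect_equal(fit_quasi_independence(tc), ipf_oracle(n), tolerance = 1e-9)
  # random 4x4 matrices
  for (s in 1:10) {
    tc <- random_tc(4, seed = 100 + s)
    expect_equal(fit_quasi_independence(tc), ipf_oracle(tc$n),
                 tolerance = 1e-9)
  }
})

test_that("fitted margins conserve the observed margins", {
  for (s in 1:5) {
    tc <- random_tc(6, seed = 200 + s, lambda = 15)
    e <- fit_quasi_independence(tc)
    expect_lt(max(abs(rowSums(e) - rowSums(tc$n))), 1e-9)
    expect_lt(max(abs(colSums(e) - colSums(tc$n))), 1e-9)
    expect_true(all(diag(e) == 0))
  }
  tc <- day3_transition_matrix()
  e <- fit_quasi_independence(tc)
  expect_equal(unname(rowSums(e)["U"]), 408, tolerance = 1e-9)
  expect_equal(unname(colSums(e)["Sta"]), 1013, tolerance = 1e-9)
})

test_that("G statistic is zero at the fit's own expecteds and df follows k", {
  tc <- random_tc(4, seed = 301)
  e <- fit_quasi_independence(tc)
  # a table equal to its expecteds gives G = 0
  n0 <- round(e)
  mode(n0) <- "integer"
  diag(n0) <- 0L
  tc0 <- transition_counts(n0)
  g0 <- g_statistic(tc0, n0)
  expect_equal(g0$G, 0)
  expect_equal(g_statistic(tc, e)$df, 4^2 - 3 * 4 + 1)
  expect_equal(g_statistic(day3_transition_matrix(),
                           fit_quasi_independence(day3_transition_matrix()))$df,
               209)
  expect_error(g_statistic(tc, e[1:3, 1:3]), "shape")
})

test_that("Freeman-Tukey deviates follow the closed form and monotonicity", {
  n <- matrix(c(0, 0, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tc <- transition_counts(n)
  m <- matrix(c(0, 0, 2, 0), 2, 2)
  z <- freeman_tukey_deviates(tc, m)
  expect_equal(z["a", "b"], sqrt(2) + sqrt(3) - 3)  # n=2, m=2
  expect_equal(z["b", "a"], 0)                       # n=0, m=0
  m2 <- matrix(c(0, 2, 0, 0), 2, 2)
  z2 <- freeman_tukey_deviates(tc, m2)
  expect_equal(z2["b", "a"], 1 - 3)                  # n=0, m=2
  expect_true(all(is.na(diag(z))))
  # strictly increasing in n at fixed m, decreasing in m at fixed n
  zf <- function(n, m) sqrt(n) + sqrt(n + 1) - sqrt(4 * m + 1)
  expect_true(all(diff(zf(0:20, 5)) > 0))
  expect_true(all(diff(zf(5, seq(0.5, 20, by = 0.5))) < 0))
  expect_error(freeman_tukey_deviates(tc, -m), "negative")
})

test_that("the simultaneous criterion behaves as a chi-square partition", {
  expect_equal(significance_criterion(0.05, 209, 240), 1.0077, tolerance = 1e-3)
  # oracle recomputation from the chi-square quantile
  expect_equal(significance_criterion(0.05, 209, 240),
               sqrt(qchisq(0.95, 209) / 240), tolerance = 1e-12)
  # the criterion decreases monotonically toward 0 as alpha -> 1
  cs <- vapply(c(0.05, 0.5, 0.99, 1 - 1e-12), significance_criterion,
               0, df = 209, n_cells = 240)
  expect_true(all(diff(cs) < 0))
  expect_lt(cs[4], cs[1] / 1.5)
  # chi-square median is close to df for large df
  expect_equal(significance_criterion(0.5, 500, 500), 1, tolerance = 0.01)
})

test_that("only positive deviates beyond the criterion are significant", {
  tc <- random_tc(5, seed = 55, lambda = 30)
  fit <- qi_fit(tc)
  sig <- significant_transitions(fit)
  expect_true(all(sig$deviate > fit$criterion))
  expect_equal(sum(fit$significant), nrow(sig))
  # observed == expected everywhere -> empty set
  n <- matrix(6L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(n) <- 0L
  expect_equal(nrow(significant_transitions(qi_fit(transition_counts(n)))), 0)
})

test_that("high-intensity involvement summary counts ordered pairs", {
  sig <- data.frame(from = c("W", "L", "Ap", "U"),
                    to = c("Ap", "Wr", "L", "W"),
                    stringsAsFactors = FALSE)
  hi <- classify_hi_involvement(sig, eth)
  expect_equal(hi$involving_hi, 2)
  expect_equal(hi$hi_to_hi, 1)
  expect_equal(hi$distinct_non_hi_precursors, 1)  # only Ap -> L
  expect_equal(unname(hi$to_counts[c("Ap", "Wr", "L", "W")]), rep(1L, 4))
  empty <- classify_hi_involvement(sig[0, ], eth)
  expect_equal(empty$involving_hi, 0)
  expect_equal(empty$hi_to_hi, 0)
})

test_that("type-I error of the G test is nominal under its own model", {
  # parametric bootstrap at k = 6: simulate from the fitted expecteds and
  # compare G to the chi-square reference
  set.seed(61)
  k <- 6
  tc <- random_tc(k, seed = 600, lambda = 40)
  e <- fit_quasi_independence(tc)
  off <- which(row(e) != col(e))
  p <- e[off] / sum(e[off])
  N <- sum(tc$n)
  df <- k^2 - 3 * k + 1
  rej <- replicate(500, {
    n <- matrix(0L, k, k, dimnames = dimnames(e))
    n[off] <- as.integer(stats::rmultinom(1, N, p))
    tcb <- transition_counts(n)
    g <- g_statistic(tcb, fit_quasi_independence(tcb))
    g$p < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("margin-by-age tests have the right df and vanish for identical cohorts", {
  tc <- random_tc(16, seed = 71, lambda = 12)
  cs <- list(`1` = tc, `2` = tc, `3` = tc, `4` = tc, `6` = tc)
  for (ax in c("first", "second")) {
    r <- marginal_by_age_test(cs, ax)
    expect_equal(r$df, 60)
    expect_equal(r$G, 0, tolerance = 1e-9)
    expect_equal(r$p, 1, tolerance = 1e-9)
  }
  # a cohort with structurally shifted margins is detected
  n2 <- tc$n
  n2[1:4, ] <- n2[1:4, ] * 4L
  diag(n2) <- 0L
  r2 <- marginal_by_age_test(list(`1` = tc, `3` = transition_counts(n2)),
                             "first")
  expect_equal(r2$df, 15)
  expect_lt(r2$p, 1e-6)
})

test_that("homogeneity test is zero for identical cohorts with stated df", {
  tc <- random_tc(16, seed = 81, lambda = 10)
  cs <- list(`1` = tc, `2` = tc, `3` = tc, `4` = tc, `6` = tc)
  r <- homogeneity_across_ages(cs)
  expect_equal(r$df, 4 * (16^2 - 3 * 16 + 1))  # 836
  expect_equal(r$G, 0, tolerance = 1e-6)
  k6 <- lapply(1:3, function(i) random_tc(6, seed = 90 + i, lambda = 20))
  names(k6) <- c(1, 2, 3)
  expect_equal(homogeneity_across_ages(k6)$df, 2 * (36 - 18 + 1))
})

test_that("homogeneity test is calibrated for cohorts from one common chain", {
  set.seed(92)
  P <- test_chain(6, seed = 920)
  a <- 5
  df_exp <- (a - 1) * (6^2 - 3 * 6 + 1)
  rej <- replicate(500, {
    counts <- simulate_chain_counts(P, steps = 1000, n_chain = a)
    cs <- lapply(counts, transition_counts)
    names(cs) <- seq_len(a)
    r <- homogeneity_across_ages(cs)
    stopifnot(r$df == df_exp)
    r$p < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("persistence classes partition the significant transitions", {
  mk_fit <- function(seed) qi_fit(random_tc(6, seed, lambda = 25))
  f <- mk_fit(131)
  fits_same <- list(`1` = f, `2` = f, `3` = f, `4` = f, `6` = f)
  pc <- cohort_persistence_classes(fits_same)
  expect_equal(nrow(pc$common_all), sum(f$significant))
  expect_equal(nrow(pc$appears_from_day), 0)
  expect_equal(nrow(pc$disappears_after_day), 0)
  expect_equal(nrow(pc$other), 0)
  expect_error(cohort_persistence_classes(fits_same[1]), "two cohorts")

  fits_diff <- list(`1` = mk_fit(132), `2` = mk_fit(133), `3` = mk_fit(134),
                    `4` = mk_fit(135), `6` = mk_fit(136))
  pc2 <- cohort_persistence_classes(fits_diff)
  n_all <- length(unique(unlist(lapply(fits_diff, function(ft) {
    s <- significant_transitions(ft); paste(s$from, s$to)
  }))))
  expect_equal(nrow(pc2$common_all) + nrow(pc2$appears_from_day) +
                 nrow(pc2$disappears_after_day) + nrow(pc2$other), n_all)
  # appears/disappears semantics on a constructed pattern
  if (nrow(pc2$appears_from_day)) {
    d <- pc2$appears_from_day$day[1]
    key <- paste(pc2$appears_from_day$from[1], pc2$appears_from_day$to[1])
    for (age in names(fits_diff)) {
      s <- significant_transitions(fits_diff[[age]])
      present <- key %in% paste(s$from, s$to)
      expect_equal(present, as.numeric(age) >= d)
    }
  }
})
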