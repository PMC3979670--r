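#' Kruskal-Wallis test on grouped samples
#'
#' Rank-based omnibus comparison of per-individual (or per-pair) values
#' across cohorts, with tie correction, wrapping [stats::kruskal.test()].
#' The degenerate case of all values identical across all groups returns
#' `H = 0`, `p = 1` rather than an error.
#'
#' @param groups named list of numeric vectors, one per cohort.
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) == 0L)) stop("empty group")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  df <- length(groups) - 1L
  if (length(unique(x)) == 1L) {
    return(list(H = 0, df = df, p = 1))
  }
  g <- factor(rep(names(groups), vapply(groups, length, 0L)),
              levels = names(groups))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

# Mean ranks, tie-corrected pooled variance term for Dunn's Q.
dunn_stats <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 0L))
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  list(mean_rank = tapply(r, g, mean),
       n = tapply(r, g, length),
       var_unit = N * (N + 1) / 12 - tie_term)
}

#' Dunn's nonparametric multiple comparisons
#'
#' Pairwise post-hoc comparisons of mean ranks following a Kruskal-Wallis
#' omnibus test. Q statistics use the tie-corrected variance; familywise
#' control follows the standard-normal critical value with a Bonferroni-style
#' adjustment over all k(k-1)/2 pairs (the construction behind the usual
#' tabled critical values). A compact letter display summarizes the
#' decisions: groups sharing a letter are not significantly different.
#'
#' @param groups named list of numeric vectors (3 or more groups).
#' @param alpha familywise significance level (default 0.05).
#' @return List with `comparisons` (data frame: `group1`, `group2`, `Q`,
#'   `p_adj`, `significant`) and `letters` (named character vector).
#' @export
dunn_posthoc <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 3L) {
    stop("Dunn's test needs at least 3 groups; use a two-sample rank test instead")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  ds <- dunn_stats(groups)
  k <- length(groups)
  nm <- names(groups)
  pairs <- utils::combn(k, 2)
  Q <- p_adj <- numeric(ncol(pairs))
  for (c_i in seq_len(ncol(pairs))) {
    i <- pairs[1, c_i]; j <- pairs[2, c_i]
    se <- sqrt(ds$var_unit * (1 / ds$n[i] + 1 / ds$n[j]))
    Q[c_i] <- abs(ds$mean_rank[i] - ds$mean_rank[j]) / se
    p_adj[c_i] <- min(1, 2 * stats::pnorm(Q[c_i], lower.tail = FALSE) *
                        k * (k - 1) / 2)
  }
  comp <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                     Q = Q, p_adj = p_adj, significant = p_adj < alpha,
                     stringsAsFactors = FALSE)
  list(comparisons = comp,
       letters = letter_display(nm, comp, order_by = ds$mean_rank))
}

# Compact letter display: maximal intervals of groups (ordered by a summary
# statistic) within which no pair differs significantly.
letter_display <- function(nm, comparisons, order_by) {
  k <- length(nm)
  ord <- order(order_by)
  sig <- matrix(FALSE, k, k, dimnames = list(nm, nm))
  for (r in seq_len(nrow(comparisons))) {
    if (comparisons$significant[r]) {
      sig[comparisons$group1[r], comparisons$group2[r]] <- TRUE
      sig[comparisons$group2[r], comparisons$group1[r]] <- TRUE
    }
  }
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[nm[ord[i:(j + 1)]], nm[ord[i:(j + 1)]]])) j <- j + 1
    runs[[length(runs) + 1]] <- ord[i:j]
  }
  keep <- rep(TRUE, length(runs))
  for (i in seq_along(runs)) {
    for (j in seq_along(runs)) {
      if (i != j && keep[j] && all(runs[[i]] %in% runs[[j]])) keep[i] <- FALSE
    }
  }
  runs <- unique(runs[keep])
  out <- stats::setNames(rep("", k), nm)
  for (r in seq_along(runs)) {
    out[nm[runs[[r]]]] <- paste0(out[nm[runs[[r]]]], letters[r])
  }
  out
}

#' Tukey-type multiple comparisons of arcsine-transformed proportions
#'
#' Each cohort supplies the pooled observation amount in a behavior and the
#' pooled total (e.g. minutes in grooming vs total minutes). Proportions are
#' transformed as `p' = asin(sqrt(p))` (radians), whose variance is
#' approximately `1/(4n)` with `n` the cohort's total observation count.
#' Pairwise differences are referred to the studentized range distribution
#' with infinite degrees of freedom (Tukey-type comparison among
#' proportions).
#'
#' @param budgets named list, one element per cohort: numeric vector
#'   `c(amount, total)` (e.g. minutes in behavior, total minutes).
#' @param alpha familywise significance level.
#' @return List with `proportions`, `transformed` (radians), `comparisons`
#'   data frame and `letters`.
#' @export
arcsine_proportion_comparisons <- function(budgets, alpha = 0.05) {
  if (!is.list(budgets) || length(budgets) < 2L) stop("need at least 2 cohorts")
  if (is.null(names(budgets))) names(budgets) <- paste0("g", seq_along(budgets))
  amt <- vapply(budgets, `[`, 0, 1)
  tot <- vapply(budgets, `[`, 0, 2)
  p <- amt / tot
  if (any(p < 0 | p > 1)) stop("proportions must lie in [0, 1]")
  pt <- asin(sqrt(p))
  k <- length(budgets)
  nm <- names(budgets)
  pairs <- utils::combn(k, 2)
  q <- p_adj <- numeric(ncol(pairs))
  for (c_i in seq_len(ncol(pairs))) {
    i <- pairs[1, c_i]; j <- pairs[2, c_i]
    se <- sqrt((1 / (4 * tot[i]) + 1 / (4 * tot[j])) / 2)
    q[c_i] <- abs(pt[i] - pt[j]) / se
    p_adj[c_i] <- stats::ptukey(q[c_i], k, Inf, lower.tail = FALSE)
  }
  comp <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                     q = q, p_adj = p_adj, significant = p_adj < alpha,
                     stringsAsFactors = FALSE)
  list(proportions = stats::setNames(p, nm),
       transformed = stats::setNames(pt, nm),
       comparisons = comp,
       letters = letter_display(nm, comp, order_by = pt))
}

# Map proportions in [0,1] to 1..bins equal-width bins, boundary values to
# the lower bin (right-closed), 0 to the first bin.
proportion_bin <- function(p, bins) {
  b <- ifelse(p <= 0, 1L, ceiling(p * bins))
  pmin(as.integer(b), bins)
}

#' Dominance goodness-of-fit test
#'
#' Tests whether a focal behavior (e.g. retreat, or hold + lunge) is split
#' between the two members of each pair as expected when both members are
#' equally likely to perform it. The observed histogram of per-pair
#' proportions `n1 / n_total` over `bins` equal-width bins of [0, 1] is
#' compared against the expected histogram obtained by summing, over pairs,
#' the Binomial(n_total, 1/2) probability mass mapped through the same
#' binning; the chi-square statistic has `bins - 1` degrees of freedom.
#'
#' @param records data frame with columns `pair_id`, `n1` (count by
#'   individual 1) and `n_total` (count by both members).
#' @param bins number of histogram bins (default 11).
#' @param min_total eligibility filter: pairs with `n_total < min_total` are
#'   dropped (1 for retreat; 2 for the high-intensity analysis, which
#'   requires at least two occurrences).
#' @return List with `mean`, `sem`, `chisq`, `df`, `p`, `observed`,
#'   `expected`, `n_pairs`.
#' @export
dominance_test <- function(records, bins = 11, min_total = 1) {
  stopifnot(all(c("n1", "n_total") %in% names(records)))
  r <- records[records$n_total >= min_total, , drop = FALSE]
  if (nrow(r) == 0L) stop("no eligible pairs")
  if (any(r$n1 < 0 | r$n1 > r$n_total)) stop("need 0 <= n1 <= n_total")
  p <- r$n1 / r$n_total
  obs <- tabulate(proportion_bin(p, bins), bins)
  expc <- numeric(bins)
  for (n in r$n_total) {
    j <- 0:n
    b <- proportion_bin(j / n, bins)
    pm <- stats::dbinom(j, n, 0.5)
    for (bb in unique(b)) expc[bb] <- expc[bb] + sum(pm[b == bb])
  }
  chisq <- sum((obs - expc)^2 / ifelse(expc > 0, expc, 1))
  df <- bins - 1
  list(mean = mean(p), sem = stats::sd(p) / sqrt(length(p)),
       chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE),
       observed = obs, expected = expc, n_pairs = nrow(r))
}

#' Within-encounter escalation test
#'
#' Per cohort, a Kruskal-Wallis test across the consecutive 10-min intervals
#' on per-pair counts of high-intensity aggression (hold + lunge). A
#' non-significant result indicates a stationary aggression rate over the
#' encounter (no escalation).
#'
#' @param interval_counts_by_cohort named list (one element per cohort) of
#'   matrices with one row per pair and one column per interval, as built
#'   from [interval_counts()].
#' @return Data frame with one row per cohort: `cohort`, `H`, `df`, `p`.
#' @export
escalation_test <- function(interval_counts_by_cohort) {
  stopifnot(is.list(interval_counts_by_cohort))
  out <- lapply(names(interval_counts_by_cohort), function(ch) {
    m <- interval_counts_by_cohort[[ch]]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    if (ncol(m) < 2) stop("fewer than 2 intervals")
    groups <- stats::setNames(lapply(seq_len(ncol(m)), function(j) m[, j]),
                              paste0("interval", seq_len(ncol(m))))
    kw <- kruskal_wallis(groups)
    data.frame(cohort = ch, H = kw$H, df = kw$df, p = kw$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Tidy ontogeny statistics for a set of cohorts
#'
#' Convenience wrapper producing the cross-cohort occurrence-rate statistics
#' for a set of behaviors: per behavior, the Kruskal-Wallis omnibus across
#' cohorts and (when 3+ cohorts and a significant omnibus) Dunn's post-hoc
#' letters. The eleven behaviors entering the default rate ontogeny are the
#' aggressive and interactive behaviors plus jump, stilt and bobbing;
#' immobilized is excluded because it merely mirrors the opponent's hold.
#'
#' @param logs_by_cohort named list (cohort label -> list of [event_log]).
#' @param behaviors behavior codes to test.
#' @param alpha significance level for the post-hoc letters.
#' @return Data frame with one row per behavior: `behavior`, `H`, `df`, `p`,
#'   and one letter column per cohort.
#' @export
ontogeny_rate_stats <- function(logs_by_cohort,
                                behaviors = c("L", "H", "Wr", "Lo", "Av",
                                              "R", "T", "Ap", "J", "Sti", "B"),
                                alpha = 0.05) {
  stopifnot(is.list(logs_by_cohort), length(logs_by_cohort) >= 2L)
  nm <- names(logs_by_cohort)
  rows <- lapply(behaviors, function(b) {
    groups <- lapply(logs_by_cohort, function(lgs) occurrence_rate(lgs, b)$rates)
    kw <- kruskal_wallis(groups)
    lets <- if (length(groups) >= 3L && !is.na(kw$p) && kw$p < alpha) {
      dunn_posthoc(groups, alpha)$letters
    } else {
      stats::setNames(rep("a", length(groups)), nm)
    }
    cbind(data.frame(behavior = b, H = kw$H, df = kw$df, p = kw$p,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(lets), optional = TRUE))
  })
  do.call(rbind, rows)
}
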