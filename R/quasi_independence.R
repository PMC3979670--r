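#' Fit the quasi-independence model to a transition matrix
#'
#' Fits expected frequencies `m[i, j] = a_i * b_j` for `i != j` (and
#' `m[i, i] = 0`, the structural zeros) by iterative proportional scaling, so
#' that expected row and column sums match the observed margins. This is the
#' independence model for a contingency table whose diagonal is excluded a
#' priori, the null model for first-order behavioral transition structure.
#'
#' @param tc a [transition_counts].
#' @param tol convergence tolerance on the maximum absolute margin
#'   discrepancy (default 1e-10).
#' @param max_iter maximum scaling cycles.
#' @return Matrix of fitted expected frequencies (zero diagonal).
#' @export
fit_quasi_independence <- function(tc, tol = 1e-10, max_iter = 10000) {
  stopifnot(inherits(tc, "transition_counts"))
  n <- tc$n
  k <- nrow(n)
  rt <- rowSums(n); ct <- colSums(n)
  if (any(rt == 0) || any(ct == 0)) {
    warning("all-zero row or column: its margins fit trivially to zero")
  }
  e <- matrix(1, k, k, dimnames = dimnames(n))
  diag(e) <- 0
  disc <- Inf
  for (it in seq_len(max_iter)) {
    rs <- rowSums(e)
    e <- e * ifelse(rs > 0, rt / rs, 0)
    cs <- colSums(e)
    e <- t(t(e) * ifelse(cs > 0, ct / cs, 0))
    disc <- max(abs(rowSums(e) - rt), abs(colSums(e) - ct))
    if (disc < tol) break
  }
  if (disc >= tol) {
    stop(sprintf("IPF did not converge in %d iterations (discrepancy %.3g)",
                 max_iter, disc))
  }
  e
}

#' Likelihood-ratio G statistic against fitted expecteds
#'
#' `G = 2 * sum(n * log(n / m))` over off-diagonal cells with `n > 0`
#' (cells with `n = 0` contribute 0, the `n log n -> 0` limit). Residual
#' degrees of freedom for the quasi-independence model on a k x k zero-
#' diagonal table are `k^2 - 3k + 1` (k^2 - k cells minus 2k - 1 fitted
#' parameters).
#'
#' @param tc a [transition_counts].
#' @param expected fitted expected matrix from [fit_quasi_independence()].
#' @return List with `G`, `df`, and the chi-square tail `p`.
#' @export
g_statistic <- function(tc, expected) {
  stopifnot(inherits(tc, "transition_counts"))
  n <- tc$n
  if (!identical(dim(n), dim(expected))) stop("shape mismatch")
  k <- nrow(n)
  pos <- n > 0 & row(n) != col(n)
  G <- 2 * sum(n[pos] * log(n[pos] / expected[pos]))
  df <- k^2 - 3 * k + 1
  list(G = G, df = df, p = stats::pchisq(G, df, lower.tail = FALSE))
}

#' Freeman-Tukey deviates
#'
#' Variance-stabilized cell residuals
#' `z[i, j] = sqrt(n) + sqrt(n + 1) - sqrt(4 m + 1)` for off-diagonal cells,
#' approximately standard normal under the fitted model. Diagonal
#' (structural-zero) cells are returned as `NA`.
#'
#' @param tc a [transition_counts].
#' @param expected fitted expected matrix.
#' @return Matrix of deviates with `NA` on the diagonal.
#' @export
freeman_tukey_deviates <- function(tc, expected) {
  stopifnot(inherits(tc, "transition_counts"))
  if (any(expected < 0)) stop("negative expected frequency")
  n <- tc$n
  z <- sqrt(n) + sqrt(n + 1) - sqrt(4 * expected + 1)
  diag(z) <- NA_real_
  z
}

#' Simultaneous Freeman-Tukey significance criterion
#'
#' The threshold `c = sqrt(qchisq(1 - alpha, df) / n_cells)` that partitions
#' the model chi-square equally over the testable cells: a cell deviate
#' exceeding `c` contributes more than its share of the alpha-level
#' chi-square. For the default 16-behavior analysis, `n_cells = 240` and
#' `df = 209`, giving `c` just above 1.
#'
#' @param alpha significance level in (0, 1).
#' @param df residual degrees of freedom of the fitted model.
#' @param n_cells number of testable (off-diagonal) cells.
#' @return The criterion `c`.
#' @examples
#' significance_criterion(0.05, 209, 240)
#' @export
significance_criterion <- function(alpha, df, n_cells) {
  stopifnot(alpha > 0, alpha < 1, df > 0, n_cells > 0)
  sqrt(stats::qchisq(1 - alpha, df) / n_cells)
}

#' Fit, test and threshold a transition matrix in one step
#'
#' Runs [fit_quasi_independence()], [g_statistic()],
#' [freeman_tukey_deviates()] and [significance_criterion()] and marks the
#' cells whose positive deviate exceeds the criterion (only excesses over
#' chance count as significant).
#'
#' @param tc a [transition_counts].
#' @param alpha significance level (default 0.05).
#' @param tol,max_iter IPF controls, see [fit_quasi_independence()].
#' @return Object of class `qi_fit`: list with `counts`, `expected`, `G`,
#'   `df`, `p`, `deviates`, `alpha`, `criterion`, and the logical matrix
#'   `significant`.
#' @examples
#' fit <- qi_fit(day3_transition_matrix())
#' sum(fit$significant)
#' @export
qi_fit <- function(tc, alpha = 0.05, tol = 1e-10, max_iter = 10000) {
  expected <- fit_quasi_independence(tc, tol = tol, max_iter = max_iter)
  g <- g_statistic(tc, expected)
  z <- freeman_tukey_deviates(tc, expected)
  k <- nrow(tc$n)
  crit <- significance_criterion(alpha, g$df, k^2 - k)
  sig <- !is.na(z) & z > crit
  structure(list(counts = tc, expected = expected, G = g$G, df = g$df,
                 p = g$p, deviates = z, alpha = alpha, criterion = crit,
                 significant = sig),
            class = "qi_fit")
}

#' @export
print.qi_fit <- function(x, ...) {
  cat(sprintf(paste0("<qi_fit> k = %d, N = %d\n",
                     "  G = %.2f, df = %d, p = %.3g\n",
                     "  criterion (alpha = %g): %.4f; significant transitions: %d\n"),
              length(x$counts$labels), x$counts$total, x$G, x$df, x$p,
              x$alpha, x$criterion, sum(x$significant)))
  invisible(x)
}

#' Significant transitions of a fit
#'
#' All ordered pairs (from, to), i != j, whose Freeman-Tukey deviate exceeds
#' the simultaneous criterion, i.e. the transitions occurring more often than
#' expected by chance.
#'
#' @param fit a [qi_fit].
#' @return Data frame with columns `from`, `to`, `n`, `expected`, `deviate`,
#'   ordered by decreasing deviate.
#' @export
significant_transitions <- function(fit) {
  stopifnot(inherits(fit, "qi_fit"))
  idx <- which(fit$significant, arr.ind = TRUE)
  labs <- fit$counts$labels
  out <- data.frame(from = labs[idx[, 1]], to = labs[idx[, 2]],
                    n = fit$counts$n[idx], expected = fit$expected[idx],
                    deviate = fit$deviates[idx], stringsAsFactors = FALSE)
  out[order(-out$deviate), , drop = FALSE]
}

#' Summarize high-intensity involvement of a significant set
#'
#' Counts how the significant transitions engage the high-intensity
#' aggressive behaviors of the ethogram (for the default repertoire:
#' L, H, Wr, I).
#'
#' @param sig data frame from [significant_transitions()] (columns `from`,
#'   `to`).
#' @param ethogram an [ethogram].
#' @return List with `involving_hi` (at least one member high-intensity),
#'   `hi_to_hi` (both members), `distinct_non_hi_precursors` (distinct
#'   non-high-intensity behaviors with a significant transition into a
#'   high-intensity one), and `to_counts` (named vector of significant
#'   transitions into each behavior).
#' @export
classify_hi_involvement <- function(sig, ethogram) {
  hi <- high_intensity_codes(ethogram)
  f_hi <- sig$from %in% hi
  t_hi <- sig$to %in% hi
  to_counts <- stats::setNames(integer(nrow(ethogram)), ethogram$code)
  tb <- table(factor(sig$to, levels = ethogram$code))
  to_counts[names(tb)] <- as.integer(tb)
  list(involving_hi = sum(f_hi | t_hi),
       hi_to_hi = sum(f_hi & t_hi),
       to_hi = sum(t_hi),
       from_hi = sum(f_hi),
       distinct_non_hi_precursors = length(unique(sig$from[!f_hi & t_hi])),
       to_counts = to_counts)
}

# ---- cross-cohort log-linear comparisons -----------------------------------

check_cohort_set <- function(cs) {
  if (!is.list(cs) || length(cs) < 2L) stop("need at least 2 cohorts")
  labs <- lapply(cs, function(tc) tc$labels)
  if (!all(vapply(labs, identical, TRUE, labs[[1]]))) {
    stop("all cohort matrices must share the same behavior labels")
  }
  invisible(cs)
}

#' Margin-by-age likelihood-ratio test
#'
#' Builds the k x a table of per-behavior margins (first-member row margins
#' or second-member column margins) across the `a` age cohorts and returns
#' the likelihood-ratio G test of independence of behavior and age, with
#' `df = (k - 1)(a - 1)`. A significant result indicates age-related change
#' in behavioral frequencies.
#'
#' @param cs named list of [transition_counts], one per age cohort (names =
#'   ages).
#' @param axis `"first"` (row margins) or `"second"` (column margins).
#' @return List with `G`, `df`, `p` and the margin `table`.
#' @export
marginal_by_age_test <- function(cs, axis = c("first", "second")) {
  axis <- match.arg(axis)
  check_cohort_set(cs)
  tab <- vapply(cs, function(tc) {
    if (axis == "first") rowSums(tc$n) else colSums(tc$n)
  }, numeric(length(cs[[1]]$labels)))
  if (all(tab == 0)) stop("degenerate margin table")
  N <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / N
  pos <- tab > 0
  G <- 2 * sum(tab[pos] * log(tab[pos] / e[pos]))
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(G = G, df = df, p = stats::pchisq(G, df, lower.tail = FALSE),
       table = tab)
}

# IPF for the common-association model on an a x k x k zero-diagonal array:
# log m[c,i,j] = r[c,i] + s[c,j] + t[i,j]; margins matched are per-cohort row
# sums, per-cohort column sums, and pooled cell totals.
fit_common_association <- function(arr, tol = 1e-8, max_iter = 5000) {
  a <- dim(arr)[1]; k <- dim(arr)[2]
  offd <- row(diag(k)) != col(diag(k))
  m <- array(0, dim(arr))
  for (ci in seq_len(a)) m[ci, , ][offd] <- 1
  rt <- apply(arr, c(1, 2), sum)
  ct <- apply(arr, c(1, 3), sum)
  pt <- apply(arr, c(2, 3), sum)
  for (it in seq_len(max_iter)) {
    mr <- apply(m, c(1, 2), sum)
    for (ci in seq_len(a)) m[ci, , ] <- m[ci, , ] *
        ifelse(mr[ci, ] > 0, rt[ci, ] / mr[ci, ], 0)
    mc <- apply(m, c(1, 3), sum)
    for (ci in seq_len(a)) m[ci, , ] <- t(t(m[ci, , ]) *
        ifelse(mc[ci, ] > 0, ct[ci, ] / mc[ci, ], 0))
    mp <- apply(m, c(2, 3), sum)
    f <- ifelse(mp > 0, pt / mp, 0)
    for (ci in seq_len(a)) m[ci, , ] <- m[ci, , ] * f
    disc <- max(abs(apply(m, c(1, 2), sum) - rt),
                abs(apply(m, c(1, 3), sum) - ct))
    if (disc < tol) break
  }
  m
}

#' Test homogeneity of transition structure across age cohorts
#'
#' Likelihood-ratio G test of the common-association log-linear model
#' (cohort-specific first- and second-member margins, one shared
#' behavior-by-behavior association term, structural-zero diagonal, fitted by
#' three-way iterative proportional scaling) against per-cohort saturation.
#' A significant result means the transition probabilities differ among
#' cohorts (the three-way behavior 1 x behavior 2 x age interaction). Degrees
#' of freedom are `(a - 1)(k^2 - 3k + 1)`.
#'
#' @param cs named list of [transition_counts], one per age cohort.
#' @return List with `G`, `df`, `p`.
#' @export
homogeneity_across_ages <- function(cs) {
  check_cohort_set(cs)
  a <- length(cs)
  k <- length(cs[[1]]$labels)
  arr <- array(0, c(a, k, k))
  for (ci in seq_len(a)) arr[ci, , ] <- cs[[ci]]$n
  m <- fit_common_association(arr)
  pos <- arr > 0
  G <- 2 * sum(arr[pos] * log(arr[pos] / m[pos]))
  df <- (a - 1) * (k^2 - 3 * k + 1)
  list(G = G, df = df, p = stats::pchisq(G, df, lower.tail = FALSE))
}

#' Partition significant transitions by cross-cohort persistence
#'
#' Classifies each transition that is significant in at least one cohort
#' into: `common_all` (significant at every age), `appears_from_day` (absent
#' at all younger ages, present from day d onward, d > first age),
#' `disappears_after_day` (present through day d, absent at all older ages,
#' d < last age), or `other` (every remaining pattern).
#'
#' @param fits named list of [qi_fit] objects, names = cohort ages in days;
#'   at least two cohorts.
#' @return List of data frames `common_all`, `appears_from_day`,
#'   `disappears_after_day`, `other`; the latter three carry a `day` column.
#' @export
cohort_persistence_classes <- function(fits) {
  if (!is.list(fits) || length(fits) < 2L) {
    stop("need fits for at least two cohorts")
  }
  ages <- as.numeric(names(fits))
  if (anyNA(ages)) stop("fits must be named by cohort age in days")
  ord <- order(ages)
  fits <- fits[ord]; ages <- ages[ord]
  sets <- lapply(fits, function(f) {
    s <- significant_transitions(f)
    paste(s$from, s$to, sep = ">")
  })
  all_tr <- unique(unlist(sets))
  pres <- vapply(sets, function(s) all_tr %in% s,
                 logical(length(all_tr)))
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = length(all_tr))
  split_pair <- function(key, extra = NULL) {
    if (length(key) == 0L) {
      out <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
    } else {
      parts <- do.call(rbind, strsplit(key, ">", fixed = TRUE))
      out <- data.frame(from = parts[, 1], to = parts[, 2],
                        stringsAsFactors = FALSE)
    }
    if (!is.null(extra)) out$day <- extra[seq_len(max(nrow(out), 0))]
    out
  }
  n_age <- length(ages)
  common <- rowSums(pres) == n_age
  appears <- rep(NA_real_, length(all_tr))
  disappears <- rep(NA_real_, length(all_tr))
  for (t in seq_along(all_tr)) {
    if (common[t]) next
    p <- pres[t, ]
    first_on <- which(p)[1]
    # present from some age d onward, absent before
    if (first_on > 1 && all(p[first_on:n_age])) appears[t] <- ages[first_on]
    last_on <- max(which(p))
    if (last_on < n_age && all(p[1:last_on])) disappears[t] <- ages[last_on]
  }
  is_app <- !common & !is.na(appears)
  is_dis <- !common & !is.na(disappears)
  is_other <- !common & !is_app & !is_dis
  list(common_all = split_pair(all_tr[common]),
       appears_from_day = split_pair(all_tr[is_app], appears[is_app]),
       disappears_after_day = split_pair(all_tr[is_dis], disappears[is_dis]),
       other = split_pair(all_tr[is_other]))
}

#' Write a fit report as JSON
#'
#' Emits `G`, `df`, `p`, `alpha`, `criterion` and the significant-transition
#' list (with deviates) of a [qi_fit] as a JSON file.
#'
#' @param fit a [qi_fit].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "qi_fit"))
  rep <- list(k = length(fit$counts$labels), total = fit$counts$total,
              G = fit$G, df = fit$df, p = fit$p, alpha = fit$alpha,
              criterion = fit$criterion,
              n_significant = sum(fit$significant),
              significant = significant_transitions(fit))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
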