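# Shared in-code fixtures and independent oracles.

# Minimal record builder: make_records("fly1", "W", 0, 10, "fly1", "Ap", ...)
make_records <- function(..., session = "s1", age = 3) {
  v <- list(...)
  stopifnot(length(v) %% 4 == 0)
  i <- seq(1, length(v), by = 4)
  data.frame(session_id = session, cohort_age_days = age,
             subject_id = unlist(v[i]),
             behavior = unlist(v[i + 1]),
             onset_s = unlist(v[i + 2]),
             offset_s = unlist(v[i + 3]),
             stringsAsFactors = FALSE)
}

tiny_ethogram <- function() {
  ethogram(code = c("A", "B", "C"),
           name = c("alpha", "beta", "gamma"),
           category = c("non_interactive", "interactive_nonaggressive",
                        "high_intensity_aggression"))
}

# Random zero-diagonal count matrix with all-positive margins.
random_tc <- function(k, seed, lambda = 8) {
  set.seed(seed)
  n <- matrix(rpois(k * k, lambda) + 1L, k, k)
  diag(n) <- 0L
  dimnames(n) <- list(letters[1:k], letters[1:k])
  transition_counts(n)
}

# Independent quasi-independence oracle: explicit a_i * b_j parameterization,
# alternating closed-form margin updates, run to a tight fixed point.
ipf_oracle <- function(n, iters = 20000, tol = 1e-12) {
  k <- nrow(n)
  a <- rep(1, k); b <- rep(1, k)
  off <- 1 - diag(k)
  rt <- rowSums(n); ct <- colSums(n)
  for (i in seq_len(iters)) {
    a_new <- rt / as.vector(off %*% b)
    a_new[!is.finite(a_new)] <- 0
    b_new <- ct / as.vector(t(off) %*% a_new)
    b_new[!is.finite(b_new)] <- 0
    if (max(abs(a_new - a), abs(b_new - b)) < tol) {
      a <- a_new; b <- b_new
      break
    }
    a <- a_new; b <- b_new
  }
  m <- outer(a, b)
  diag(m) <- 0
  dimnames(m) <- dimnames(n)
  m
}

# Simulate `n_chain` independent first-order chains of `steps` transitions
# from embedded matrix P (zero diagonal) and return a list of k x k count
# matrices. Vectorized across chains.
simulate_chain_counts <- function(P, steps, n_chain) {
  k <- nrow(P)
  cum <- t(apply(P, 1, cumsum))
  states <- matrix(0L, steps + 1, n_chain)
  states[1, ] <- sample.int(k, n_chain, replace = TRUE)
  for (t in seq_len(steps)) {
    u <- runif(n_chain)
    cur <- states[t, ]
    states[t + 1, ] <- 1L + rowSums(u > cum[cur, , drop = FALSE])
  }
  lapply(seq_len(n_chain), function(ch) {
    n <- matrix(0L, k, k, dimnames = dimnames(P))
    from <- states[-(steps + 1), ch]; to <- states[-1, ch]
    for (t in seq_len(steps)) n[from[t], to[t]] <- n[from[t], to[t]] + 1L
    n
  })
}

# A zero-diagonal embedded chain on k states, rows renormalized.
test_chain <- function(k, seed) {
  set.seed(seed)
  P <- matrix(runif(k * k, 0.2, 1), k, k)
  diag(P) <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(letters[1:k], letters[1:k])
  P
}
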