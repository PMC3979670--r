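#' Construct and validate a synthetic-session configuration
#'
#' Parameters of the age-indexed semi-Markov generator of dyadic encounter
#' sessions: an embedded transition probability matrix over the ethogram
#' (zero diagonal, rows summing to 1), per-state dwell distributions
#' (log-normal, parameterized by mean and coefficient of variation), and the
#' interaction couplings (Poisson high-intensity initiations split between
#' lunge- and hold-led events, hold always immobilizing the opponent for the
#' same interval, and probabilistic avoid/retreat responses to an opponent's
#' approach).
#'
#' High-intensity states (L, H, I) are entered only through initiations and
#' coupling, never through the embedded chain, so their embedded columns must
#' be zero; this is what makes the hold/immobilized mirroring identity exact.
#'
#' @param age_days cohort age in days.
#' @param embedded k x k embedded transition probability matrix with behavior
#'   codes as dimnames.
#' @param dwell_mean_s named vector of mean dwell times (seconds).
#' @param dwell_cv named vector of dwell coefficients of variation.
#' @param interaction list with `hi_rate_per_hour` (high-intensity
#'   initiations per hour per individual), `hold_fraction` (fraction of
#'   initiations that are hold-led), `hold_duration_mean_s`,
#'   `approach_response` (named probabilities for `Av` and `R`), and
#'   `hold_triggers_immobilized` (always `TRUE`).
#' @param session_s session duration in seconds.
#' @param single_male if `TRUE`, sessions contain one subject and no
#'   interactions.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(age_days, embedded, dwell_mean_s, dwell_cv,
                         interaction, session_s = 3600, single_male = FALSE) {
  codes <- rownames(embedded)
  if (is.null(codes) || !identical(codes, colnames(embedded))) {
    stop("embedded matrix needs identical row/column behavior codes")
  }
  if (any(diag(embedded) != 0)) stop("embedded diagonal must be zero")
  if (any(embedded < 0 | embedded > 1)) stop("probabilities must lie in [0, 1]")
  if (any(abs(rowSums(embedded) - 1) > 1e-9)) {
    stop("embedded rows must sum to 1 (within 1e-9)")
  }
  if (any(dwell_mean_s[codes] <= 0) || anyNA(dwell_mean_s[codes])) {
    stop("dwell means must be positive for every behavior")
  }
  stopifnot(is.list(interaction),
            interaction$hi_rate_per_hour >= 0,
            interaction$hold_fraction >= 0, interaction$hold_fraction <= 1,
            interaction$hold_duration_mean_s > 0,
            all(interaction$approach_response >= 0),
            sum(interaction$approach_response) <= 1)
  if (!single_male) {
    for (s in intersect(c("L", "H", "I"), codes)) {
      if (any(embedded[, s] > 0)) {
        stop("embedded column into ", s,
             " must be zero: high-intensity entries are initiation-driven")
      }
    }
  }
  cfg <- structure(list(age_days = age_days, embedded = embedded,
                        dwell_mean_s = dwell_mean_s, dwell_cv = dwell_cv,
                        interaction = interaction, session_s = session_s,
                        single_male = single_male, codes = codes),
                   class = "synth_config")
  cfg$initial_probs <- stationary_state_probs(cfg)
  cfg
}

# Time-share-weighted stationary distribution of the embedded chain, used to
# draw the initial state of each subject.
stationary_state_probs <- function(cfg) {
  P <- cfg$embedded
  k <- nrow(P)
  e <- rep(1 / k, k)
  for (i in 1:200) e <- as.vector(e %*% P)
  w <- e * cfg$dwell_mean_s[cfg$codes]
  w[is.na(w) | w < 0] <- 0
  stats::setNames(w / sum(w), cfg$codes)
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> age %s d, %d behaviors, %.0f s session%s\n",
              x$age_days, length(x$codes), x$session_s,
              if (x$single_male) ", single male" else ""))
  invisible(x)
}

# Per-age parameter tables for the default profiles. Background time-share
# targets fall (walking, standing) or rise (grooming, upside-down) with age;
# high-intensity initiation rate and hold duration rise; stilt falls; jump
# and bobbing peak at day 3; avoid responses fall and retreat responses rise.
age_profile_table <- function() {
  list(
    ages = c(1, 2, 3, 4, 6),
    share = rbind(W   = c(.40, .37, .34, .31, .28),
                  Sta = c(.37, .33, .29, .22, .15),
                  G   = c(.20, .25, .31, .34, .35),
                  U   = c(.01, .03, .04, .11, .18)),
    brief = rbind(Ap  = c(24, 24, 24, 24, 24),
                  Av  = c(18, 14, 8, 6, 4),
                  R   = c(1, 2, 4, 5, 6),
                  T   = c(3, 3, 3, 3, 3),
                  J   = c(0.8, 1.5, 1.9, 1.6, 1.4),
                  B   = c(1.0, 2.2, 2.9, 2.4, 2.0),
                  Sti = c(4.0, 3.2, 2.5, 1.8, 1.2),
                  Lo  = c(3.5, 2.5, 1.7, 1.5, 1.3)),
    u_wr = c(.02, .08, .10, .10, .10),
    hi_rate = c(0.6, 2.0, 3.7, 4.5, 5.5),
    hold_duration = c(2.0, 3.5, 5.0, 6.5, 8.2),
    resp_av = c(.09, .075, .06, .05, .04),
    resp_r = c(.02, .03, .04, .05, .06))
}

# Fixed exit structure of the brief states. Rarely entered states exit
# deterministically so their configured rows stay identifiable from
# cohort-sized samples; the structured rows belong to frequently entered
# states.
brief_rows <- function() {
  list(Ap = c(Av = .25, R = .05, W = .45, Sta = .20, U = .05),
       Av = c(U = .12, G = .06, T = .04, Ap = .08, W = .45, Sta = .25),
       R = c(W = .85, Sta = .15),
       T = c(Ap = 1), J = c(Sta = 1), B = c(Sta = 1), Sti = c(Sta = 1),
       Lo = c(Av = 1), Wr = c(U = 1), L = c(Wr = 1), H = c(Wr = 1),
       I = c(Wr = 1))
}

#' Default generator parameters for an age cohort
#'
#' Returns the versioned default [synth_config] for one of the study ages
#' (1, 2, 3, 4 or 6 days). The defaults encode the study's qualitative
#' ontogeny: the high-intensity initiation rate rises from 0.6 to 5.5
#' events/hour/individual between days 1 and 6, mean hold duration rises
#' from 2.0 to 8.2 s, walking and standing time shares fall while grooming
#' and upside-down rise, and the four background states jointly occupy at
#' least 96\% of session time at every age. The embedded matrix is built
#' from the target time shares, dwell means and brief-excursion rates by
#' flow balance.
#'
#' @param age_days one of 1, 2, 3, 4, 6.
#' @param single_male build the single-subject control configuration
#'   (interactive behaviors, bobbing and jump removed; no initiations).
#' @return A [synth_config].
#' @examples
#' cfg <- default_parameters(3)
#' rowSums(cfg$embedded)[1:4]
#' @export
default_parameters <- function(age_days, single_male = FALSE) {
  prof <- age_profile_table()
  ai <- match(age_days, prof$ages)
  if (is.na(ai)) {
    stop("unsupported age: ", age_days, " (expected 1, 2, 3, 4 or 6)")
  }
  eth <- default_ethogram()
  codes <- eth$code
  bg <- c("W", "Sta", "G", "U")
  dwell_mean <- stats::setNames(rep(0.7, length(codes)), codes)
  dwell_mean[bg] <- c(W = 18, Sta = 25, G = 30, U = 8)
  dwell_mean["Wr"] <- 2.5
  dwell_mean["L"] <- 0.4
  dwell_mean["H"] <- prof$hold_duration[ai]
  dwell_mean["I"] <- prof$hold_duration[ai]
  dwell_cv <- stats::setNames(rep(0.5, length(codes)), codes)
  dwell_cv[bg] <- 0.9
  interaction <- list(
    hi_rate_per_hour = if (single_male) 0 else prof$hi_rate[ai],
    hold_fraction = 0.3,
    hold_duration_mean_s = prof$hold_duration[ai],
    approach_response = if (single_male) c(Av = 0, R = 0) else
      c(Av = prof$resp_av[ai], R = prof$resp_r[ai]),
    hold_triggers_immobilized = TRUE)
  share <- prof$share[, ai]
  brief <- prof$brief[, ai]
  if (single_male) {
    # isolated flies: no interactive behaviors, no bobbing or jump; stilt
    # peaks at day 3 instead of declining
    brief[] <- 0
    brief["Sti"] <- c(1.5, 2.5, 4.0, 3.0, 2.5)[ai]
    u_wr <- 0
    hi <- c(lunge = 0, hold = 0)
  } else {
    u_wr <- prof$u_wr[ai]
    hi <- c(lunge = interaction$hi_rate_per_hour * (1 - interaction$hold_fraction),
            hold = interaction$hi_rate_per_hour * interaction$hold_fraction)
  }
  embedded <- build_embedded(codes, share, dwell_mean, brief, u_wr, hi,
                             interaction$approach_response)
  synth_config(age_days, embedded, dwell_mean, dwell_cv, interaction,
               single_male = single_male)
}

# Build the embedded matrix by flow balance: background exit rates follow
# from the target time shares and dwell means; each background row spends
# probability t_b / E on each brief excursion and distributes the remainder
# over the other background states so that entries match targets after
# accounting for the return flows of the brief rows and of initiation-driven
# wrestling.
build_embedded <- function(codes, share, dwell_mean, brief, u_wr, hi,
                           resp) {
  bg <- names(share)
  e_bg <- share * 3600 / dwell_mean[bg]
  E <- sum(e_bg)
  br <- brief_rows()
  # brief-state entry rates: chain targets + inter-row + insertion flows
  e_b <- brief
  for (it in 1:20) {
    e_ap <- if ("Ap" %in% names(e_b)) e_b[["Ap"]] else 0
    e_b["Av"] <- brief[["Av"]] + e_ap * br$Ap[["Av"]] + e_b[["Lo"]] +
      e_ap * resp[["Av"]]
    e_b["R"] <- brief[["R"]] + e_ap * br$Ap[["R"]] + e_ap * resp[["R"]]
    e_b["T"] <- brief[["T"]] + e_b[["Av"]] * br$Av[["T"]]
    e_b["Ap"] <- brief[["Ap"]] + e_b[["Av"]] * br$Av[["Ap"]] + e_b[["T"]]
  }
  e_wr <- u_wr * e_bg[["U"]] + hi[["lunge"]] + 2 * hi[["hold"]]
  # return flows into each background state
  ret <- stats::setNames(numeric(length(bg)), bg)
  for (b in names(e_b)) {
    if (e_b[[b]] == 0) next
    for (j in intersect(names(br[[b]]), bg)) {
      ret[j] <- ret[j] + e_b[[b]] * br[[b]][[j]]
    }
  }
  ret["U"] <- ret[["U"]] + e_wr
  f <- pmax(e_bg - ret, 0.5)  # background-to-background entry targets
  k <- length(codes)
  P <- matrix(0, k, k, dimnames = list(codes, codes))
  brief_p <- brief / E
  for (x in bg) {
    P[x, names(brief)] <- brief_p
    if (x == "U") P[x, "Wr"] <- u_wr
    beta <- 1 - sum(P[x, ])
    others <- setdiff(bg, x)
    P[x, others] <- beta * f[others] / sum(f[others])
  }
  for (b in names(br)) P[b, names(br[[b]])] <- br[[b]]
  # unused rows (never entered) exit to standing to keep rows stochastic
  zero_rows <- rowSums(P) == 0
  P[zero_rows, "Sta"] <- 1
  P
}

lnorm_pars <- function(mean, cv) {
  s2 <- log(1 + cv^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate one dyadic (or single-male) session
#'
#' Simulates the configured semi-Markov process for each subject: state
#' bouts drawn from the embedded chain with log-normal dwells, Poisson
#' high-intensity initiations (lunge-led or hold-led) realized when the
#' initiator (and, for holds, the opponent) is in a background state, every
#' hold mirroring an equal-length immobilized bout in the opponent, and
#' avoid/retreat responses to an opponent's approach. Identical
#' configuration and seed give byte-identical logs. Since the two subjects
#' run symmetric processes, each retreat is performed by either member with
#' probability 1/2.
#'
#' @param config a [synth_config].
#' @param seed integer seed for the session's random stream.
#' @param session_id session label (default derived from age and seed).
#' @return An [event_log] with two subjects (`fly1`, `fly2`), or one for
#'   single-male configurations.
#' @export
generate_session <- function(config, seed,
                             session_id = sprintf("age%s_s%d",
                                                  config$age_days, seed)) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  cfg <- config
  dur <- cfg$session_s
  n_f <- if (cfg$single_male) 1L else 2L
  codes <- cfg$codes
  k <- length(codes)
  cum <- t(apply(cfg$embedded, 1, cumsum))
  is_bg <- codes %in% c("W", "Sta", "G", "U")
  i_H <- match("H", codes); i_I <- match("I", codes)
  i_L <- match("L", codes); i_Ap <- match("Ap", codes)
  lp <- lnorm_pars(cfg$dwell_mean_s[codes], cfg$dwell_cv[codes])
  mlog <- lp$meanlog; slog <- lp$sdlog
  rate_l <- cfg$interaction$hi_rate_per_hour *
    (1 - cfg$interaction$hold_fraction)
  rate_h <- cfg$interaction$hi_rate_per_hour * cfg$interaction$hold_fraction
  resp <- cfg$interaction$approach_response
  p_av <- if ("Av" %in% names(resp)) resp[["Av"]] else 0
  p_r <- if ("R" %in% names(resp)) resp[["R"]] else 0
  i_Av <- match("Av", codes); i_R <- match("R", codes)
  hrs <- dur / 3600

  # pre-drawn initiation streams, merged and time-ordered
  t_time <- numeric(0); t_fly <- integer(0); t_hold <- logical(0)
  if (n_f == 2L) {
    for (f in 1:2) {
      n_l <- stats::rpois(1, rate_l * hrs)
      n_h <- stats::rpois(1, rate_h * hrs)
      t_time <- c(t_time, stats::runif(n_l, 0, dur), stats::runif(n_h, 0, dur))
      t_fly <- c(t_fly, rep.int(f, n_l + n_h))
      t_hold <- c(t_hold, rep(c(FALSE, TRUE), c(n_l, n_h)))
    }
    o <- order(t_time)
    t_time <- t_time[o]; t_fly <- t_fly[o]; t_hold <- t_hold[o]
  }
  n_trig <- length(t_time)
  t_i <- 1L

  # preallocated per-fly record buffers
  cap <- 1024L
  r_beh <- matrix(0L, cap, n_f); r_on <- matrix(0, cap, n_f)
  r_off <- matrix(0, cap, n_f); n_rec <- integer(n_f)
  state <- integer(n_f); b_start <- numeric(n_f); b_end <- numeric(n_f)
  for (f in seq_len(n_f)) {
    state[f] <- sample.int(k, 1, prob = cfg$initial_probs)
    b_end[f] <- stats::rlnorm(1, mlog[state[f]], slog[state[f]])
  }
  push <- function(f, s, on, off) {
    if (off - on <= 0) return()
    n <- n_rec[f] + 1L
    if (n > nrow(r_beh)) {
      r_beh <<- rbind(r_beh, matrix(0L, cap, n_f))
      r_on <<- rbind(r_on, matrix(0, cap, n_f))
      r_off <<- rbind(r_off, matrix(0, cap, n_f))
    }
    r_beh[n, f] <<- s; r_on[n, f] <<- on; r_off[n, f] <<- off
    n_rec[f] <<- n
  }
  enter <- function(f, s, now, dwell = NULL) {
    push(f, state[f], b_start[f], now)
    state[f] <<- s
    b_start[f] <<- now
    b_end[f] <<- now + (if (is.null(dwell))
      stats::rlnorm(1, mlog[s], slog[s]) else dwell)
  }

  repeat {
    nt <- if (t_i <= n_trig) t_time[t_i] else Inf
    f_min <- if (n_f == 2L && b_end[2] < b_end[1]) 2L else 1L
    ne <- b_end[f_min]
    if (min(ne, nt) >= dur) break
    if (nt < ne) {  # initiation event
      f <- t_fly[t_i]; hold <- t_hold[t_i]; t_i <- t_i + 1L
      other <- 3L - f
      if (!hold) {
        if (is_bg[state[f]]) enter(f, i_L, nt)
      } else if (is_bg[state[f]] && is_bg[state[other]]) {
        d_h <- stats::rlnorm(1, mlog[i_H], slog[i_H])
        enter(f, i_H, nt, dwell = d_h)
        enter(other, i_I, nt, dwell = d_h)
      }
    } else {  # natural bout end
      f <- f_min
      nxt <- findInterval(stats::runif(1), cum[state[f], ],
                          left.open = TRUE) + 1L
      enter(f, nxt, ne)
      if (n_f == 2L && nxt == i_Ap && p_av + p_r > 0) {
        other <- 3L - f
        if (is_bg[state[other]]) {
          u <- stats::runif(1)
          if (u < p_av) enter(other, i_Av, ne)
          else if (u < p_av + p_r) enter(other, i_R, ne)
        }
      }
    }
  }
  for (f in seq_len(n_f)) push(f, state[f], b_start[f], dur)

  df <- do.call(rbind, lapply(seq_len(n_f), function(f) {
    idx <- seq_len(n_rec[f])
    data.frame(session_id = session_id, cohort_age_days = cfg$age_days,
               subject_id = paste0("fly", f), behavior = codes[r_beh[idx, f]],
               onset_s = r_on[idx, f], offset_s = r_off[idx, f],
               stringsAsFactors = FALSE)
  }))
  event_log(df, session_duration_s = dur)
}

#' Generate a cohort of sessions
#'
#' Independent sessions with per-session seeds derived from the cohort seed
#' by fixed increment; the study design used 11 pairs per age cohort (10 on
#' day 4).
#'
#' @param config a [synth_config].
#' @param n_pairs number of sessions.
#' @param seed cohort seed.
#' @return List of [event_log] objects.
#' @export
generate_cohort <- function(config, n_pairs, seed) {
  stopifnot(n_pairs >= 1)
  lapply(seq_len(n_pairs), function(i) {
    generate_session(config, seed = seed + i - 1L,
                     session_id = sprintf("age%s_pair%02d", config$age_days, i))
  })
}

#' Transition probabilities implied by a configuration
#'
#' The observed sequences of a generated session are the embedded chain
#' thinned by interruptions (initiations, partner holds, approach responses)
#' plus the insertion transitions those interruptions create. This function
#' computes, analytically from the configuration alone, the implied
#' row-normalized transition probabilities: for a background state x with
#' bout survival probability `s_x = E[exp(-rho D_x)]` (dwell D_x log-normal,
#' interruption rate rho), row x becomes `s_x P[x, ] + (1 - s_x) w`, where
#' `w` is the insertion-type distribution; brief and high-intensity states
#' are never interrupted so their rows equal the embedded rows. Entry rates
#' and time shares are solved jointly by fixed-point iteration.
#'
#' @param config a [synth_config].
#' @return List with `probs` (implied k x k row-stochastic matrix),
#'   `entry_rates_per_hour` (named), `time_shares` (named) and
#'   `lunge_rate_per_hour` (realized lunge occurrence rate).
#' @export
implied_transition_probs <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  codes <- cfg$codes
  P <- cfg$embedded
  k <- length(codes)
  bg <- intersect(c("W", "Sta", "G", "U"), codes)
  rate_l <- cfg$interaction$hi_rate_per_hour *
    (1 - cfg$interaction$hold_fraction)
  rate_h <- cfg$interaction$hi_rate_per_hour * cfg$interaction$hold_fraction
  resp <- cfg$interaction$approach_response
  surv <- function(code, rho_s) {
    if (rho_s <= 0) return(1)
    lp <- lnorm_pars(cfg$dwell_mean_s[[code]], cfg$dwell_cv[[code]])
    stats::integrate(function(d) exp(-rho_s * d) *
                       stats::dlnorm(d, lp$meanlog, lp$sdlog),
                     0, Inf, rel.tol = 1e-9)$value
  }
  e <- stats::setNames(rep(1, k), codes)
  tau_bg <- 0.97
  e_ap <- 20
  p_hat <- P
  for (it in 1:40) {
    ins <- c(L = rate_l, H = rate_h * tau_bg, I = rate_h * tau_bg,
             Av = e_ap * resp[["Av"]], R = e_ap * resp[["R"]])
    ins <- ins[ins > 0 & names(ins) %in% codes]
    rho_h <- sum(ins)
    rho_s <- rho_h / 3600
    p_hat <- P
    s_x <- stats::setNames(rep(1, k), codes)
    for (x in bg) {
      s_x[x] <- surv(x, rho_s)
      w <- stats::setNames(rep(0, k), codes)
      w[names(ins)] <- ins / rho_h
      p_hat[x, ] <- s_x[x] * P[x, ] + (1 - s_x[x]) * w
    }
    # stationary entry distribution of the implied chain
    ev <- rep(1 / k, k)
    for (i in 1:300) ev <- as.vector(ev %*% p_hat)
    names(ev) <- codes
    d_eff <- cfg$dwell_mean_s[codes]
    for (x in bg) d_eff[x] <- if (rho_s > 0) (1 - s_x[x]) / rho_s else
      cfg$dwell_mean_s[[x]]
    scale <- 3600 / sum(ev * d_eff)
    e <- ev * scale
    tau <- e * d_eff / 3600
    tau_bg <- sum(tau[bg])
    e_ap <- if ("Ap" %in% codes) e[["Ap"]] else 0
  }
  list(probs = p_hat, entry_rates_per_hour = e, time_shares = tau,
       lunge_rate_per_hour = rate_l * tau_bg)
}

#' Per-pair split records for a focal behavior set
#'
#' Builds the pair-level records used by [dominance_test()]: for each
#' session, the number of bouts of the focal behaviors performed by the
#' first subject (`n1`) and by both subjects (`n_total`).
#'
#' @param logs list of two-subject [event_log] objects.
#' @param behaviors focal behavior codes (e.g. `"R"`, or `c("H", "L")`).
#' @return Data frame with `pair_id`, `n1`, `n_total`.
#' @export
pair_split_records <- function(logs, behaviors) {
  if (inherits(logs, "event_log")) logs <- list(logs)
  out <- lapply(seq_along(logs), function(i) {
    r <- logs[[i]]$records
    subj <- sort(unique(r$subject_id))
    hit <- r$behavior %in% behaviors
    n1 <- sum(hit & r$subject_id == subj[1])
    data.frame(pair_id = if (nrow(r)) r$session_id[1] else as.character(i),
               n1 = n1, n_total = sum(hit), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
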