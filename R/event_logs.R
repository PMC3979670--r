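#' Construct an event log
#'
#' An event log holds the timed behavior records of one session: one row per
#' bout with columns `session_id`, `cohort_age_days`, `subject_id`,
#' `behavior`, `onset_s`, `offset_s`. On construction, records are sorted per
#' subject, contiguous same-behavior records of a subject are merged into a
#' single bout (same-behavior records separated by an uncoded gap remain
#' distinct bouts), and per-subject overlaps are rejected. Zero-duration
#' records (point behaviors such as jump) are permitted. Uncoded gaps between
#' bouts are allowed; they contribute to total observation time but to no
#' behavior.
#'
#' @param records data frame with the six columns above.
#' @param session_duration_s session length in seconds (default 3600).
#' @param ethogram an [ethogram] used to validate codes, or `NULL` to skip
#'   code validation.
#' @return An object of class `event_log`: a list with elements `records`,
#'   `session_duration_s`, `n_subjects`.
#' @export
event_log <- function(records, session_duration_s = 3600, ethogram = NULL) {
  need <- c("session_id", "cohort_age_days", "subject_id", "behavior",
            "onset_s", "offset_s")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("event records lack column(s): ", paste(miss, collapse = ", "))
  records <- as.data.frame(records)[need]
  records$behavior <- collapse_low_intensity(records$behavior)
  if (!is.null(ethogram)) {
    bad <- setdiff(unique(records$behavior), ethogram$code)
    if (length(bad)) stop("unknown behavior code(s) in event log: ",
                          paste(bad, collapse = ", "))
  }
  if (nrow(records)) {
    if (any(records$onset_s < 0) || any(records$offset_s < records$onset_s)) {
      stop("event records must satisfy 0 <= onset_s <= offset_s")
    }
    if (any(records$offset_s > session_duration_s + 1e-9)) {
      stop("event offset exceeds session_duration_s")
    }
    records <- records[order(records$subject_id, records$onset_s,
                             records$offset_s), , drop = FALSE]
    records <- merge_and_check(records)
    rownames(records) <- NULL
  }
  structure(list(records = records,
                 session_duration_s = session_duration_s,
                 n_subjects = max(1L, length(unique(records$subject_id)))),
            class = "event_log")
}

# Merge contiguous same-behavior records per subject into single bouts;
# error on overlap. Same-behavior records separated by an uncoded gap remain
# distinct bouts (the gap interrupts the bout but not the behavioral
# sequence, which is collapsed at extraction time).
merge_and_check <- function(records) {
  out <- lapply(split(records, records$subject_id), function(r) {
    if (nrow(r) > 1L) {
      ov <- which(r$onset_s[-1] < r$offset_s[-nrow(r)] - 1e-9)
      if (length(ov)) {
        i <- ov[1]
        stop(sprintf(
          "overlapping events for subject %s: [%g, %g] then [%g, %g]",
          r$subject_id[1], r$onset_s[i], r$offset_s[i],
          r$onset_s[i + 1], r$offset_s[i + 1]))
      }
      contiguous <- r$behavior[-1] == r$behavior[-nrow(r)] &
        abs(r$onset_s[-1] - r$offset_s[-nrow(r)]) < 1e-9
      grp <- cumsum(c(TRUE, !contiguous))
      if (any(duplicated(grp))) {
        r <- do.call(rbind, lapply(split(r, grp), function(g) {
          g$offset_s[1] <- g$offset_s[nrow(g)]
          g[1, , drop = FALSE]
        }))
      }
    }
    r
  })
  do.call(rbind, out)
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> %d records, %d subject(s), %.0f s session\n",
              nrow(x$records), x$n_subjects, x$session_duration_s))
  invisible(x)
}

#' Read a timed behavioral event log
#'
#' Reads the event-log CSV dialect (header
#' `session_id,cohort_age_days,subject_id,behavior,onset_s,offset_s`; times
#' in seconds; gzip accepted). Raw low-intensity aggression names are
#' collapsed to `"Lo"` before code validation. For single-animal control
#' sessions recorded for 60 min, `single_male = TRUE` discards the first and
#' last 5 min and uses a 50-min effective observation window.
#'
#' @param path path to the CSV (optionally `.gz`).
#' @param ethogram an [ethogram] used to validate behavior codes.
#' @param session_duration_s recording length in seconds (default 3600).
#' @param single_male if `TRUE`, trim to the central 50-min window.
#' @return An [event_log].
#' @export
read_event_log <- function(path, ethogram, session_duration_s = 3600,
                           single_male = FALSE) {
  if (!file.exists(path)) stop("event log not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (single_male) {
    trim <- 300
    hi <- session_duration_s - trim
    df <- df[df$offset_s > trim & df$onset_s < hi, , drop = FALSE]
    df$onset_s <- pmax(df$onset_s, trim) - trim
    df$offset_s <- pmin(df$offset_s, hi) - trim
    session_duration_s <- session_duration_s - 2 * trim
  }
  event_log(df, session_duration_s = session_duration_s, ethogram = ethogram)
}

#' Write an event log
#'
#' Emits the same CSV dialect that [read_event_log()] accepts.
#'
#' @param log an [event_log].
#' @param path output path (a `.gz` suffix triggers gzip compression).
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(log$records, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pooled time budget of a cohort
#'
#' Fraction of the pooled observation time occupied by each behavior,
#' pooled over all subjects and sessions of a cohort. The denominator is the
#' full observation time (subjects x session duration), so proportions over
#' mutually exclusive states sum to at most 1; uncoded time belongs to no
#' behavior.
#'
#' @param logs a list of [event_log] objects (one cohort).
#' @param behaviors behavior codes to report; default: all codes present.
#' @return A list of class `time_budget` with elements `proportions` (named
#'   numeric), `minutes` (named numeric, pooled minutes per behavior) and
#'   `total_time_s`.
#' @export
time_budget <- function(logs, behaviors = NULL) {
  if (inherits(logs, "event_log")) logs <- list(logs)
  if (length(logs) == 0L) stop("empty set of event logs")
  recs <- do.call(rbind, lapply(logs, function(l) l$records))
  total <- sum(vapply(logs, function(l) l$session_duration_s * l$n_subjects, 0))
  dur <- recs$offset_s - recs$onset_s
  by_beh <- tapply(dur, recs$behavior, sum)
  if (is.null(behaviors)) behaviors <- names(by_beh)
  secs <- stats::setNames(as.numeric(by_beh[behaviors]), behaviors)
  secs[is.na(secs)] <- 0
  structure(list(proportions = secs / total, minutes = secs / 60,
                 total_time_s = total), class = "time_budget")
}

#' Bout durations of a behavior
#'
#' One duration per bout (merged records count once), in encounter order.
#'
#' @param logs an [event_log] or list of them.
#' @param behavior a single behavior code.
#' @return Numeric vector of durations in seconds (empty if never performed).
#' @export
bout_durations <- function(logs, behavior) {
  if (inherits(logs, "event_log")) logs <- list(logs)
  unlist(lapply(logs, function(l) {
    r <- l$records[l$records$behavior == behavior, , drop = FALSE]
    r <- r[order(r$onset_s), , drop = FALSE]
    r$offset_s - r$onset_s
  }), use.names = FALSE)
}

#' Per-individual occurrence rates
#'
#' For each individual (each subject of each session), the number of bouts of
#' `behavior` divided by the observation duration in hours, reported as
#' occurrences per hour per individual together with the mean and its
#' standard error.
#'
#' @param logs an [event_log] or list of them.
#' @param behavior a single behavior code.
#' @return List with `rates` (numeric vector, one per individual), `mean`,
#'   and `sem`.
#' @export
occurrence_rate <- function(logs, behavior) {
  if (inherits(logs, "event_log")) logs <- list(logs)
  rates <- unlist(lapply(seq_along(logs), function(i) {
    l <- logs[[i]]
    if (l$session_duration_s <= 0) stop("zero-duration observation window")
    subj <- unique(l$records$subject_id)
    if (length(subj) == 0L) subj <- "subject1"
    h <- l$session_duration_s / 3600
    vapply(subj, function(s) {
      sum(l$records$subject_id == s & l$records$behavior == behavior) / h
    }, 0)
  }), use.names = FALSE)
  list(rates = rates, mean = mean(rates),
       sem = stats::sd(rates) / sqrt(length(rates)))
}

#' Per-interval counts of selected behaviors in one session
#'
#' Discards the first and last `trim_s` seconds of the session and counts,
#' per consecutive `interval_s` window, the bouts (both subjects pooled)
#' whose onset falls in the window. Intervals are half-open `[start, end)`;
#' a bout is assigned to the interval containing its onset. With the
#' defaults, a 3600-s session yields exactly five 10-min intervals.
#'
#' @param log an [event_log].
#' @param behaviors codes to count (default hold + lunge).
#' @param interval_s interval width in seconds.
#' @param trim_s seconds discarded at each end of the session.
#' @return Integer vector of counts, one per interval.
#' @export
interval_counts <- function(log, behaviors = c("H", "L"), interval_s = 600,
                            trim_s = 300) {
  stopifnot(inherits(log, "event_log"))
  dur <- log$session_duration_s
  n_int <- floor((dur - 2 * trim_s) / interval_s)
  if (n_int < 1) stop("observation window too short for a single interval")
  r <- log$records[log$records$behavior %in% behaviors, , drop = FALSE]
  on <- r$onset_s
  idx <- floor((on - trim_s) / interval_s) + 1
  idx <- idx[on >= trim_s & idx <= n_int]
  tabulate(idx, nbins = n_int)
}
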