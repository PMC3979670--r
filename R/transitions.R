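#' Construct a transition count matrix
#'
#' A k x k matrix of nonnegative integer counts `n[i, j]` of behavior i being
#' followed immediately by behavior j, with a structural-zero diagonal (only
#' changes of behavior are tabulated, so self-transitions cannot occur).
#'
#' @param n square integer matrix with matching row/column label order and a
#'   zero diagonal.
#' @param labels behavior codes; default taken from `rownames(n)`.
#' @return Object of class `transition_counts`: list with `labels`, `n`
#'   (matrix) and `total`.
#' @export
transition_counts <- function(n, labels = rownames(n)) {
  n <- as.matrix(n)
  if (nrow(n) != ncol(n)) stop("transition matrix must be square")
  if (is.null(labels)) stop("transition matrix needs behavior labels")
  if (!is.null(colnames(n)) && !identical(as.character(labels), colnames(n))) {
    stop("row and column label order must be identical")
  }
  if (any(n < 0) || any(n != round(n))) stop("counts must be nonnegative integers")
  if (any(diag(n) != 0)) stop("diagonal entries must be zero (structural zeros)")
  dimnames(n) <- list(labels, labels)
  structure(list(labels = as.character(labels), n = n, total = sum(n)),
            class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  cat(sprintf("<transition_counts> %d behaviors, %d transitions\n",
              length(x$labels), x$total))
  invisible(x)
}

#' Extract the behavior sequence of one subject
#'
#' Behavior codes in temporal order for one subject of a session. Runs of the
#' same code are collapsed so that no two consecutive codes are equal (only
#' changes from one behavior directly to another are retained; uncoded gaps
#' do not break the sequence).
#'
#' @param log an [event_log].
#' @param subject_id subject identifier present in the log.
#' @return Character vector of behavior codes (possibly empty).
#' @export
extract_sequence <- function(log, subject_id) {
  stopifnot(inherits(log, "event_log"))
  if (!subject_id %in% log$records$subject_id) {
    stop("unknown subject: ", subject_id)
  }
  r <- log$records[log$records$subject_id == subject_id, , drop = FALSE]
  s <- r$behavior[order(r$onset_s)]
  if (length(s) > 1L) s <- s[c(TRUE, s[-1] != s[-length(s)])]
  s
}

#' Build a cohort transition count matrix
#'
#' Pools, over all subjects of all sessions of one cohort, the frequencies of
#' all changes from one behavior directly to another. Chains are never
#' carried across subjects or sessions, and uncoded gaps within a subject do
#' not break the chain.
#'
#' @param logs an [event_log] or list of them (one cohort).
#' @param ethogram an [ethogram]; its codes define the matrix dimension and
#'   label order.
#' @return A [transition_counts] with k = number of ethogram behaviors.
#' @export
build_transition_counts <- function(logs, ethogram) {
  if (inherits(logs, "event_log")) logs <- list(logs)
  stopifnot(inherits(ethogram, "ethogram"))
  k <- nrow(ethogram)
  n <- matrix(0L, k, k, dimnames = list(ethogram$code, ethogram$code))
  for (l in logs) {
    for (s in unique(l$records$subject_id)) {
      seqs <- extract_sequence(l, s)
      bad <- setdiff(unique(seqs), ethogram$code)
      if (length(bad)) stop("behavior code(s) absent from ethogram: ",
                            paste(bad, collapse = ", "))
      if (length(seqs) > 1L) {
        from <- match(seqs[-length(seqs)], ethogram$code)
        to <- match(seqs[-1], ethogram$code)
        for (t in seq_along(from)) n[from[t], to[t]] <- n[from[t], to[t]] + 1L
      }
    }
  }
  transition_counts(n)
}

#' Read a transition matrix TSV
#'
#' Dialect: first cell empty, then column labels; one row per behavior; an
#' optional final margin row/column (labelled `Σ` or `Sum`) carrying row
#' and column totals. A dash (`-` or en dash) on the diagonal is read as the
#' structural zero. Printed margins, if present, are checked against
#' recomputed margins and a mismatch is an integrity error.
#'
#' @param path path to the TSV.
#' @param ethogram optional [ethogram]; if given, matrix labels must match
#'   its codes exactly (same order).
#' @return A [transition_counts].
#' @export
read_transition_matrix <- function(path, ethogram = NULL) {
  if (!file.exists(path)) stop("transition matrix file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]][-1]
  rows <- cells[-1]
  rlab <- vapply(rows, `[`, "", 1)
  is_margin <- function(x) x %in% c("Σ", "Sum", "SUM", "sum")
  body <- vapply(rows, function(r) {
    v <- r[-1]
    v[v %in% c("-", "–", "—")] <- "0"
    as.numeric(v)[seq_along(header)]
  }, numeric(length(header)))
  body <- t(body)  # rows x cols
  dimnames(body) <- list(rlab, header)
  has_mr <- is_margin(rlab[length(rlab)])
  has_mc <- is_margin(header[length(header)])
  n <- body[!is_margin(rlab), !is_margin(header), drop = FALSE]
  if (has_mc) {
    printed <- body[!is_margin(rlab), ncol(body)]
    bad <- which(abs(rowSums(n) - printed) > 1e-9)
    if (length(bad)) stop("margin mismatch in row '", rownames(n)[bad[1]],
                          "': printed ", printed[bad[1]], ", recomputed ",
                          rowSums(n)[bad[1]])
  }
  if (has_mr) {
    printed <- body[nrow(body), !is_margin(header)]
    bad <- which(abs(colSums(n) - printed) > 1e-9)
    if (length(bad)) stop("margin mismatch in column '", colnames(n)[bad[1]],
                          "': printed ", printed[bad[1]], ", recomputed ",
                          colSums(n)[bad[1]])
    if (has_mc && abs(body[nrow(body), ncol(body)] - sum(n)) > 1e-9) {
      stop("grand total margin mismatch")
    }
  }
  if (!identical(rownames(n), colnames(n))) {
    stop("row and column label order must be identical")
  }
  if (!is.null(ethogram) && !identical(rownames(n), ethogram$code)) {
    stop("matrix labels do not match ethogram codes")
  }
  transition_counts(n)
}

#' Write a transition matrix TSV
#'
#' Writes the dialect read by [read_transition_matrix()], including the
#' margin row and column, so write-then-read is the identity.
#'
#' @param tc a [transition_counts].
#' @param path output path.
#' @param margins include the margin row/column (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_transition_matrix <- function(tc, path, margins = TRUE) {
  stopifnot(inherits(tc, "transition_counts"))
  n <- tc$n
  lines <- c(paste(c("", tc$labels, if (margins) "Σ"), collapse = "\t"))
  for (i in seq_along(tc$labels)) {
    lines <- c(lines, paste(c(tc$labels[i], n[i, ],
                              if (margins) sum(n[i, ])), collapse = "\t"))
  }
  if (margins) {
    lines <- c(lines, paste(c("Σ", colSums(n), sum(n)), collapse = "\t"))
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' The packaged day-3 cohort transition matrix
#'
#' The complete 16 x 16 transition count matrix of the day-3 age cohort of
#' the paired-male encounters (5098 transitions), shipped as a TSV fixture.
#'
#' @return A [transition_counts].
#' @export
day3_transition_matrix <- function() {
  read_transition_matrix(system.file("extdata", "transition_matrix_day3.tsv",
                                     package = "ethoseq", mustWork = TRUE),
                         default_ethogram())
}
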