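## Closure "survival": event tables, percent-permeable curves, log-rank.

#' Build a closure event table from enhancement records
#'
#' Converts the longitudinal permeable/closed classifications of each focal
#' spot into one event row: the event time is the first assessment timepoint
#' at which the focus was classified closed (right-endpoint scoring of the
#' interval in which closure occurred); a focus still permeable at the last
#' timepoint is censored there. Foci not permeable at time 0 (failed
#' openings) are excluded with a warning. A focus classified closed and then
#' permeable again keeps its first closure as the event; such re-openings
#' are counted in the `reopened` attribute and reported via `message()`.
#'
#' @param records an `enhancement_records` data frame (see
#'   [quantify_series()]).
#' @return data frame of class `closure_table` with columns `mouse`, `focus`,
#'   `group`, `event_time_h`, `event` (`"closed"` or `"censored"`).
#' @export
build_closure_table <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("mouse", "focus", "timepoint_h", "permeable")
  if (!all(needed %in% names(records))) {
    stop("records must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(records$group)) records$group <- NA_character_
  tps <- sort(unique(records$timepoint_h))
  if (length(tps) < 2L || tps[1] != 0) {
    stop("records must include a time-0 assessment and at least one follow-up",
         call. = FALSE)
  }
  key <- interaction(records$mouse, records$focus, drop = TRUE)
  rows <- vector("list", nlevels(key))
  n_failed <- 0L
  n_reopened <- 0L
  for (i in seq_len(nlevels(key))) {
    rec <- records[key == levels(key)[i], , drop = FALSE]
    rec <- rec[order(rec$timepoint_h), , drop = FALSE]
    if (!identical(as.numeric(rec$timepoint_h), as.numeric(tps))) {
      stop("focus ", rec$mouse[1], "/", rec$focus[1],
           " is missing a timepoint", call. = FALSE)
    }
    if (!rec$permeable[1]) {
      n_failed <- n_failed + 1L
      next
    }
    closed_at <- which(!rec$permeable[-1])
    if (length(closed_at) == 0L) {
      ev_time <- tps[length(tps)]
      ev <- "censored"
    } else {
      ev_time <- tps[-1][closed_at[1]]
      ev <- "closed"
      if (any(rec$permeable[-1][seq_along(rec$permeable[-1]) > closed_at[1]])) {
        n_reopened <- n_reopened + 1L
      }
    }
    rows[[i]] <- data.frame(mouse = rec$mouse[1], focus = rec$focus[1],
                            group = rec$group[1], event_time_h = ev_time,
                            event = ev, stringsAsFactors = FALSE)
  }
  if (n_failed > 0L) {
    warning(n_failed, " focus/foci not permeable at time 0 excluded ",
            "(opening failed)", call. = FALSE)
  }
  if (n_reopened > 0L) {
    message(n_reopened,
            " focus/foci re-opened after first closure (classification noise);",
            " first closure kept as the event")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no foci permeable at time 0", call. = FALSE)
  rownames(out) <- NULL
  attr(out, "reopened") <- n_reopened
  class(out) <- c("closure_table", "data.frame")
  out
}

#' Percent of focal spots still permeable over time
#'
#' The closure analogue of a survival curve: at time 0 all foci are
#' permeable (100%); at each assessment time the percent is
#' `100 * (foci not yet closed) / n`.
#'
#' @param table a `closure_table`.
#' @param group group label to summarise (may be omitted if the table holds
#'   a single group).
#' @param timepoints assessment grid (hours).
#' @return data frame of class `survival_curve` with columns `timepoint_h`,
#'   `percent_permeable`, `n_at_risk`, `group`.
#' @export
#' @examples
#' recs <- quantify_group(simulate_group_images("TgCRND8-VT", seed = 17))
#' percent_permeable(build_closure_table(recs), "TgCRND8-VT")
percent_permeable <- function(table, group = NULL,
                              timepoints = c(0, 6, 12, 20)) {
  stopifnot(inherits(table, "closure_table") || is.data.frame(table))
  if (!is.null(group)) {
    table <- table[table$group == group, , drop = FALSE]
  } else {
    group <- unique(table$group)
    if (length(group) != 1L) {
      stop("table holds several groups; name one with `group`", call. = FALSE)
    }
  }
  n <- nrow(table)
  if (n < 1L) stop("no foci in group '", group, "'", call. = FALSE)
  closed <- table$event == "closed"
  pct <- vapply(timepoints, function(t) {
    100 * (n - sum(closed & table$event_time_h <= t)) / n
  }, numeric(1))
  at_risk <- vapply(timepoints, function(t) {
    sum(table$event_time_h >= t)
  }, numeric(1))
  out <- data.frame(timepoint_h = timepoints, percent_permeable = pct,
                    n_at_risk = at_risk, group = group,
                    stringsAsFactors = FALSE)
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Log-rank (Mantel-Cox) test between two closure tables
#'
#' Standard two-group Mantel-Cox statistic over the pooled distinct event
#' times: at each time with `d` pooled closures and `n1`, `n2` foci at risk,
#' the observed minus hypergeometric-expected closures in group A are
#' accumulated, and `chi^2 = (sum(O - E))^2 / sum(V)` with
#' `V = d (n1/n) (n2/n) (n - d) / (n - 1)`. The p-value comes from the
#' chi-square distribution with 1 degree of freedom.
#'
#' @param table_a,table_b `closure_table`s (or data frames with
#'   `event_time_h` and `event`).
#' @param label comparison label for reporting.
#' @return list of class `logrank_result`: `chisq`, `df`, `p`, `label`,
#'   `observed`, `expected`.
#' @export
logrank_test <- function(table_a, table_b, label = NULL) {
  grab <- function(tb) {
    stopifnot(is.data.frame(tb), all(c("event_time_h", "event") %in% names(tb)))
    list(time = as.numeric(tb$event_time_h), closed = tb$event == "closed")
  }
  a <- grab(table_a); b <- grab(table_b)
  if (length(a$time) == 0L || length(b$time) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (!any(a$closed) && !any(b$closed)) {
    stop("no closure events in either group", call. = FALSE)
  }
  event_times <- sort(unique(c(a$time[a$closed], b$time[b$closed])))
  U <- 0; V <- 0; O <- 0; E <- 0
  for (t in event_times) {
    n1 <- sum(a$time >= t); n2 <- sum(b$time >= t); n <- n1 + n2
    d1 <- sum(a$closed & a$time == t); d2 <- sum(b$closed & b$time == t)
    d <- d1 + d2
    if (d == 0L || n < 2L) next
    e1 <- d * n1 / n
    U <- U + (d1 - e1)
    V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
    O <- O + d1; E <- E + e1
  }
  chisq <- if (V > 0) U^2 / V else 0
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  structure(list(chisq = chisq, df = 1L, p = p,
                 label = label %||% "A vs B",
                 observed = O, expected = E),
            class = "logrank_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank (Mantel-Cox) %s: chisq = %.4f, df = %d, p = %.4g\n",
              x$label, x$chisq, x$df, x$p))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param n_comparisons number of comparisons, `>= 1`.
#' @return `alpha / n_comparisons` (e.g. 0.05 over 4 comparisons = 0.0125).
#' @export
bonferroni_threshold <- function(alpha, n_comparisons) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  n_comparisons <- as.integer(n_comparisons)
  if (n_comparisons < 1L) stop("`n_comparisons` must be >= 1", call. = FALSE)
  alpha / n_comparisons
}

#' Pairwise log-rank comparisons with Bonferroni correction
#'
#' Runs [logrank_test()] for each requested pair of groups and flags each
#' result significant when its p-value is below
#' `bonferroni_threshold(alpha, length(comparisons))`.
#'
#' @param table a multi-group `closure_table`.
#' @param comparisons list of length-2 character vectors of group labels.
#' @param alpha family-wise significance level.
#' @return data frame with columns `comparison`, `chisq`, `df`, `p`,
#'   `threshold`, `significant`.
#' @export
compare_all_groups <- function(table, comparisons, alpha = 0.05) {
  if (length(comparisons) == 0L) stop("no comparisons given", call. = FALSE)
  thr <- bonferroni_threshold(alpha, length(comparisons))
  groups <- unique(table$group)
  rows <- lapply(comparisons, function(pair) {
    stopifnot(length(pair) == 2L)
    if (!all(pair %in% groups)) {
      stop("unknown group in comparison: ", paste(pair, collapse = " vs "),
           call. = FALSE)
    }
    res <- logrank_test(table[table$group == pair[1], , drop = FALSE],
                        table[table$group == pair[2], , drop = FALSE],
                        label = paste(pair, collapse = " vs "))
    data.frame(comparison = res$label, chisq = res$chisq, df = res$df,
               p = res$p, threshold = thr, significant = res$p < thr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
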