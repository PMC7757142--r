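# Shared test helpers: small builders and independent oracles.

# Build a closure table directly from event times/statuses.
make_closure_table <- function(times, closed, group = "g",
                               mouse = "m1") {
  out <- data.frame(
    mouse = mouse,
    focus = seq_along(times),
    group = group,
    event_time_h = times,
    event = ifelse(closed, "closed", "censored"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("closure_table", "data.frame")
  out
}

# Draw a random closure table on the 6/12/20 h grid.
random_closure_table <- function(n, group = "g",
                                 probs = c(0.3, 0.2, 0.2, 0.3)) {
  cat_ <- sample(1:4, n, replace = TRUE, prob = probs)
  times <- c(6, 12, 20, 20)[cat_]
  closed <- cat_ != 4
  make_closure_table(times, closed, group = group)
}

# Independent brute-force Mantel-Cox oracle: explicit hypergeometric sums
# over the pooled distinct event times, written against the textbook
# formula rather than the package's code path.
brute_force_logrank_chisq <- function(table_a, table_b) {
  ta <- table_a$event_time_h; ca <- table_a$event == "closed"
  tb <- table_b$event_time_h; cb <- table_b$event == "closed"
  times <- sort(unique(c(ta[ca], tb[cb])))
  num <- 0; den <- 0
  for (t in times) {
    n1 <- sum(ta >= t); n2 <- sum(tb >= t)
    d1 <- sum(ca & ta == t); d2 <- sum(cb & tb == t)
    n <- n1 + n2; d <- d1 + d2
    if (d == 0 || n < 2) next
    num <- num + d1 - d * n1 / n
    den <- den + (n1 * n2 * d * (n - d)) / (n^2 * (n - 1))
  }
  num^2 / den
}

# Synthetic enhancement records for one focus across the 0/6/12/20 grid.
records_for_flags <- function(flags, mouse = "m1", focus = 1, group = "g") {
  data.frame(
    mouse = mouse, group = group, focus = focus,
    timepoint_h = c(0, 6, 12, 20),
    roi_mean = ifelse(flags, 200, 100),
    contra_mean = 100, contra_sd = 5,
    permeable = flags,
    stringsAsFactors = FALSE
  )
}
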