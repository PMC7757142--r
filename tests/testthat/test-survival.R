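# Closure event tables, percent-permeable curves, log-rank comparisons.

test_that("closure tables score the first closed timepoint, censor at 20 h", {
  recs <- rbind(
    records_for_flags(c(TRUE, FALSE, FALSE, FALSE), focus = 1),
    records_for_flags(c(TRUE, TRUE, TRUE, TRUE), focus = 2)
  )
  tab <- build_closure_table(recs)
  expect_equal(tab$event_time_h, c(6, 20))
  expect_equal(tab$event, c("closed", "censored"))

  # re-opening anomaly: first closure kept, anomaly surfaced
  reopen <- records_for_flags(c(TRUE, FALSE, TRUE, FALSE), focus = 3)
  expect_message(tab2 <- build_closure_table(reopen), "re-opened")
  expect_equal(tab2$event_time_h, 6)
  expect_equal(attr(tab2, "reopened"), 1L)

  # failed opening excluded with a warning
  failed <- rbind(records_for_flags(c(TRUE, TRUE, FALSE, FALSE), focus = 1),
                  records_for_flags(c(FALSE, FALSE, FALSE, FALSE), focus = 2))
  expect_warning(tab3 <- build_closure_table(failed), "not permeable at time 0")
  expect_equal(nrow(tab3), 1)

  # missing timepoint errors with the focus named
  missing <- rbind(records_for_flags(c(TRUE, TRUE, TRUE, TRUE), focus = 1),
                   records_for_flags(c(TRUE, TRUE, TRUE, TRUE), focus = 2)[-2, ])
  expect_error(build_closure_table(missing), "missing a timepoint")
})

test_that("percent-permeable curves start at 100 and are non-increasing", {
  fx <- generate_group_fixture("TgCRND8-VT")
  tab <- make_closure_table(
    times = rep(c(6, 12, 20, 20), c(fx$closed_by_6h, fx$closed_6_12h,
                                    fx$closed_12_20h, fx$permeable_20h)),
    closed = rep(c(TRUE, FALSE), c(fx$n_foci - fx$permeable_20h,
                                   fx$permeable_20h)),
    group = "TgCRND8-VT")
  curve <- percent_permeable(tab, "TgCRND8-VT")
  expect_equal(curve$percent_permeable,
               c(100, 100 * 6 / 23, 100 * 4 / 23, 100 * 3 / 23))
  expect_equal(round(curve$percent_permeable[-1]), c(26, 17, 13))
  expect_true(all(diff(curve$percent_permeable) <= 0))

  all_closed <- make_closure_table(rep(6, 5), rep(TRUE, 5))
  expect_equal(percent_permeable(all_closed)$percent_permeable, c(100, 0, 0, 0))

  fx2 <- generate_group_fixture("nonTg-PBS")
  tab2 <- make_closure_table(
    times = rep(c(6, 12, 20, 20), c(fx2$closed_by_6h, fx2$closed_6_12h,
                                    fx2$closed_12_20h, fx2$permeable_20h)),
    closed = rep(c(TRUE, FALSE), c(fx2$n_foci - fx2$permeable_20h,
                                   fx2$permeable_20h)))
  expect_equal(round(percent_permeable(tab2)$percent_permeable[-1]),
               c(83, 54, 42))
  expect_error(percent_permeable(tab2, "TgCRND8-VT"), "no foci")
})

test_that("log-rank statistic matches the hand hypergeometric evaluation", {
  a <- make_closure_table(c(6, 6, 20), c(TRUE, TRUE, FALSE))
  b <- make_closure_table(c(20, 20, 20), c(TRUE, TRUE, TRUE))
  res <- logrank_test(a, b)
  expect_equal(res$chisq, brute_force_logrank_chisq(a, b), tolerance = 1e-12)
  # frozen value from the brute-force oracle: U = 0.25, V = 0.5875
  expect_equal(res$chisq, 0.25^2 / 0.5875, tolerance = 1e-12)

  expect_equal(logrank_test(a, a)$chisq, 0)
  expect_equal(logrank_test(a, a)$p, 1)
  # symmetry under label swap
  swapped <- logrank_test(b, a)
  expect_equal(swapped$chisq, res$chisq)
  expect_equal(swapped$p, res$p)
  cens <- make_closure_table(c(20, 20), c(FALSE, FALSE))
  expect_error(logrank_test(cens, cens), "no closure events")
})

test_that("log-rank agrees with survival::survdiff on random small tables", {
  skip_if_not_installed("survival")
  set.seed(1234)
  n_checked <- 0
  while (n_checked < 50) {
    a <- random_closure_table(sample(5:30, 1), group = "a")
    b <- random_closure_table(sample(5:30, 1), group = "b")
    if (!any(a$event == "closed") && !any(b$event == "closed")) next
    mine <- logrank_test(a, b)$chisq
    d <- rbind(a, b)
    ref <- survival::survdiff(
      survival::Surv(event_time_h, event == "closed") ~ group, data = d)
    expect_equal(mine, unname(ref$chisq), tolerance = 1e-8)
    n_checked <- n_checked + 1
  }
})

test_that("Bonferroni threshold divides alpha by the comparison count", {
  expect_equal(bonferroni_threshold(0.05, 4), 0.0125)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 5), 0.002)
  expect_error(bonferroni_threshold(1.5, 4), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "n_comparisons")
})

test_that("group comparisons flag significance at the corrected threshold", {
  fxs <- closure_fixture_table()
  tabs <- lapply(seq_len(nrow(fxs)), function(i) {
    fx <- fxs[i, ]
    make_closure_table(
      times = rep(c(6, 12, 20, 20), c(fx$closed_by_6h, fx$closed_6_12h,
                                      fx$closed_12_20h, fx$permeable_20h)),
      closed = rep(c(TRUE, FALSE), c(fx$n_foci - fx$permeable_20h,
                                     fx$permeable_20h)),
      group = fx$group)
  })
  tab <- do.call(rbind, tabs)
  class(tab) <- c("closure_table", "data.frame")
  pairs <- list(c("TgCRND8-VT", "TgCRND8-PBS"), c("nonTg-VT", "nonTg-PBS"),
                c("TgCRND8-VT", "nonTg-VT"), c("TgCRND8-PBS", "nonTg-PBS"))
  res <- compare_all_groups(tab, pairs, alpha = 0.05)
  expect_equal(res$threshold, rep(0.0125, 4))
  vt <- res[res$comparison == "TgCRND8-VT vs TgCRND8-PBS", ]
  expect_lt(vt$p, 0.0125)
  expect_true(vt$significant)
  # genotype alone does not separate the PBS curves
  pbs <- res[res$comparison == "TgCRND8-PBS vs nonTg-PBS", ]
  expect_false(pbs$significant)
  expect_error(compare_all_groups(tab, list(c("TgCRND8-VT", "nope"))),
               "unknown group")
  same <- compare_all_groups(rbind(tab), list(c("TgCRND8-VT", "TgCRND8-VT")))
  expect_false(any(same$significant))
})
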