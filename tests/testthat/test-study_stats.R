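# independent kappa oracle: expand a 2x2 table into per-case label vectors
# and compute agreement directly from the raw ratings
kappa_brute <- function(a, b, c, d) {
  r1 <- c(rep(1, a), rep(1, b), rep(0, c), rep(0, d))
  r2 <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  po <- mean(r1 == r2)
  pe <- sum(vapply(c(0, 1), function(l) mean(r1 == l) * mean(r2 == l),
                   numeric(1)))
  (po - pe) / (1 - pe)
}

test_that("tables reconstruct from marginals; infeasible ones are rejected", {
  tb <- table_from_marginals(100, 55, 14, 10)
  expect_equal(unlist(tb[c("a", "b", "c", "d")]),
               c(a = 10L, b = 45L, c = 4L, d = 41L))
  tb2 <- table_from_marginals(100, 51, 13, 11)
  expect_equal(unlist(tb2[c("a", "b", "c", "d")]),
               c(a = 11L, b = 40L, c = 2L, d = 47L))
  expect_error(table_from_marginals(10, 5, 5, 6), "both_pos")
  expect_error(table_from_marginals(10, 9, 9, 2), "exceeds n")
  expect_error(two_by_two(-1, 0, 0, 5), "non-negative")
})

test_that("kappa matches the printed values and the brute-force oracle", {
  k1 <- cohen_kappa(table_from_marginals(100, 55, 14, 10))
  expect_equal(round(k1$kappa, 2), 0.09)
  expect_equal(round(k1$p_value, 3), 0.183)
  expect_equal(k1$band, "no agreement")

  k2 <- cohen_kappa(table_from_marginals(100, 51, 13, 11))
  expect_equal(round(k2$kappa, 3), 0.172)
  expect_equal(round(k2$p_value, 3), 0.009)

  expect_equal(cohen_kappa(two_by_two(50, 0, 0, 50))$kappa, 1)

  # brute-force recount oracle over assorted tables
  for (cells in list(c(10, 45, 4, 41), c(11, 40, 2, 47), c(7, 3, 5, 25),
                     c(1, 1, 1, 1), c(30, 5, 10, 5))) {
    tb <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    expect_equal(cohen_kappa(tb)$kappa, do.call(kappa_brute, as.list(cells)),
                 tolerance = 1e-12)
  }
})

test_that("kappa is symmetric in raters, zero for independent tables", {
  tb <- two_by_two(7, 13, 3, 27)
  swapped <- two_by_two(7, 3, 13, 27)   # b and c exchanged
  expect_equal(cohen_kappa(tb)$kappa, cohen_kappa(swapped)$kappa)
  # exactly independent margins: a*d == b*c
  ind <- two_by_two(12, 18, 8, 12)
  expect_equal(cohen_kappa(ind)$kappa, 0, tolerance = 1e-12)
  expect_error(cohen_kappa(two_by_two(10, 0, 0, 0)), "degenerate")
})

test_that("interpretation bands follow the printed scheme", {
  expect_equal(interpret_kappa(0.09), "no agreement")
  expect_equal(interpret_kappa(-0.5), "no agreement")
  expect_equal(interpret_kappa(0.2), "minimal agreement")
  expect_equal(interpret_kappa(0.4), "weak agreement")
  expect_equal(interpret_kappa(0.6), "strong agreement")
  expect_equal(interpret_kappa(0.8), "very strong agreement")
  expect_equal(interpret_kappa(0.9), "almost perfect agreement")
  expect_equal(interpret_kappa(0.95), "almost perfect agreement")
  expect_equal(interpret_kappa(1), "almost perfect agreement")
  expect_error(interpret_kappa(1.2), "\\[-1, 1\\]")
})

test_that("diagnostic metrics handle perfect, degenerate and general tables", {
  m <- diagnostic_metrics(two_by_two(20, 0, 0, 30))
  expect_equal(unlist(m[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))
  expect_length(m$undefined, 0)

  m2 <- diagnostic_metrics(two_by_two(0, 0, 10, 40))
  expect_equal(m2$sensitivity, 0)
  expect_equal(m2$specificity, 1)
  expect_equal(m2$npv, 0.8)
  expect_true(is.na(m2$ppv))
  expect_equal(m2$undefined, "ppv")
})

test_that("percent_of rounds half away from zero like the printed tables", {
  expect_equal(percent_of(22, 53), 42L)
  expect_equal(percent_of(15, 53), 28L)
  expect_equal(percent_of(23, 42), 55L)
  expect_equal(percent_of(14, 42), 33L)
  expect_equal(percent_of(0, 4), 0L)
  expect_equal(percent_of(1, 8), 13L)   # 12.5 rounds up, not to even
  expect_error(percent_of(5, 0), "at least 1")
  expect_error(percent_of(-1, 10), "count")
})

test_that("reproduce_stats passes on both built-in comparisons", {
  df <- reproduce_stats()
  expect_equal(nrow(df), 2L)
  expect_true(all(df$pass))
  expect_equal(df$kappa, df$kappa_expected)
  expect_equal(df$p_value, df$p_expected)
})

test_that("run_study on a tiny mix is deterministic and self-consistent", {
  ctx <- fix_ctx()
  ref <- fix_reference()
  cfg <- list(n_healthy = 2L, n_transcc = 2L, seed = 5L)
  r1 <- run_study(cfg, ctx = ctx, reference = ref)
  r2 <- run_study(cfg, ctx = ctx, reference = ref)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$cases, r2$cases)
  expect_equal(nrow(r1$cases), 4L)

  # metrics recount oracle: diagnostic_metrics on the aggregated table
  # equals a direct per-case recount
  cs <- r1$cases
  tb <- two_by_two(sum(cs$detected & cs$is_relevant),
                   sum(cs$detected & !cs$is_relevant),
                   sum(!cs$detected & cs$is_relevant),
                   sum(!cs$detected & !cs$is_relevant))
  dm <- diagnostic_metrics(tb)
  expect_equal(dm$sensitivity,
               mean(cs$detected[cs$is_relevant]))
  expect_equal(dm$specificity,
               mean(!cs$detected[!cs$is_relevant]))

  # empty categories are flagged rather than divided by zero
  r0 <- run_study(list(n_healthy = 2L, seed = 5L), ctx = ctx, reference = ref)
  expect_true(all(r0$summary$missed_count == 0))
  expect_true(all(r0$summary$empty))
  expect_true(all(is.na(r0$summary$missed_percent)))
})
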