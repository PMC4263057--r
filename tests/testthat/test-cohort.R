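test_that("Mann-Whitney U reports the exact and asymptotic p side by side", {
  # fully separated 2 vs 4: U = 0, asymptotic z = -4/sqrt(14/3)
  mw <- mann_whitney(c(238, 209), c(240, 336, 340, 342))
  expect_equal(mw$u, 0)
  expect_equal(mw$z, -4 / sqrt(2 * 4 * 7 / 12), tolerance = 1e-12)
  expect_equal(mw$p_asymptotic, 0.06407751, tolerance = 1e-6)
  expect_equal(mw$p_exact, 2 / 15, tolerance = 1e-12)
  expect_false(mw$degenerate)

  # mirror-image groups: both p-values are 1
  sym <- mann_whitney(c(1, 2), c(1, 2))
  expect_equal(sym$p_asymptotic, 1)
  expect_equal(sym$p_exact, 1)

  # all values identical across both groups: degenerate, p = 1
  dg <- mann_whitney(c(5, 5), c(5, 5, 5))
  expect_true(dg$degenerate)
  expect_equal(dg$p_asymptotic, 1)
  expect_equal(dg$p_exact, 1)

  expect_error(mann_whitney(numeric(0), 1:3), class = "pcmri_invalid_spec")
})

test_that("asymptotic Mann-Whitney matches wilcox.test without continuity correction", {
  set.seed(5)
  for (i in 1:6) {
    x <- rnorm(sample(2:5, 1)); y <- rnorm(sample(2:6, 1))
    mw <- mann_whitney(x, y)
    ref <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(mw$p_asymptotic, ref$p.value, tolerance = 1e-10)
    expect_equal(mw$u, unname(ref$statistic))
  }
})

test_that("exact Mann-Whitney p equals brute-force enumeration up to n = 8, ties included", {
  set.seed(9)
  cases <- list(
    list(x = c(238, 209), y = c(240, 336, 340, 342)),
    list(x = c(1, 1, 2), y = c(1, 2, 2)),          # heavy ties
    list(x = c(3, 3, 3, 3), y = c(3, 3, 4, 4))
  )
  for (i in 1:6) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    cases[[length(cases) + 1]] <-
      list(x = sample(1:4, n1, TRUE), y = sample(1:4, n2, TRUE))
  }
  for (cs in cases) {
    if (diff(range(c(cs$x, cs$y))) == 0) next
    expect_equal(mann_whitney(cs$x, cs$y)$p_exact,
                 oracle_mw_exact(cs$x, cs$y), tolerance = 1e-12,
                 label = paste("exact p for", paste(cs$x, collapse = ","),
                               "vs", paste(cs$y, collapse = ",")))
  }
})

test_that("Fisher exact two-sided p sums hypergeometric tables at fixed margins", {
  # 0/2 vs 3/4 exposed (hypertension-style table)
  expect_equal(fisher_exact_2x2(rbind(c(0, 2), c(3, 1)))$p, 0.4,
               tolerance = 1e-12)
  # two equally likely tables
  expect_equal(fisher_exact_2x2(rbind(c(1, 0), c(0, 1)))$p, 1)
  # empty margin: degenerate
  z <- fisher_exact_2x2(rbind(c(0, 0), c(2, 3)))
  expect_equal(z$p, 1); expect_true(z$degenerate)
})

test_that("Fisher p is invariant under transposition and agrees with fisher.test", {
  set.seed(13)
  for (i in 1:8) {
    tab <- matrix(sample(0:6, 4, TRUE), 2, 2)
    p <- fisher_exact_2x2(tab)$p
    expect_equal(fisher_exact_2x2(t(tab))$p, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1])$p, p, tolerance = 1e-12)
    expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("cohort summary reproduces mean +/- SD rows and flags degenerate groups", {
  rec <- cohort_cases()
  sm <- summarize_cohort(rec, metrics = c("q_max", "compliance"),
                         group_levels = c("control", "patient"))
  expect_equal(sm$mean_control[sm$metric == "q_max"], 541)
  expect_equal(sm$sd_control[sm$metric == "q_max"], 199.4041, tolerance = 1e-4)
  expect_equal(sm$mean_patient[sm$metric == "compliance"], 12.625)
  expect_equal(sm$sd_patient[sm$metric == "compliance"], 4.190763,
               tolerance = 1e-4)
  expect_equal(sm$n_control, c(2L, 2L))
  fmtd <- format_group_summary(sm, digits = c(q_max = 0, compliance = 1))
  expect_equal(fmtd$control[fmtd$metric == "q_max"], "541 ± 199")
  expect_equal(fmtd$patient[fmtd$metric == "compliance"], "12.6 ± 4.2")

  # single-subject group: SD is reported missing, not zero
  rec1 <- rec[rec$subject_id != "C2", ]
  sm1 <- summarize_cohort(rec1, metrics = "q_max",
                          group_levels = c("control", "patient"))
  expect_true(is.na(sm1$sd_control))
  expect_equal(sm1$n_control, 1L)

  # a missing metric names the offending subject and metric
  rec_bad <- rec; rec_bad$v_max[rec_bad$subject_id == "P2"] <- NA
  err <- expect_error(summarize_cohort(rec_bad, metrics = "v_max"),
                      class = "pcmri_missing_metric")
  expect_match(conditionMessage(err), "P2")
  expect_match(conditionMessage(err), "v_max")
})
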