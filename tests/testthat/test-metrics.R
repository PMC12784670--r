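test_that("contingency tables are built by crossing exposure and endpoint", {
  co <- micro_cohort()
  eps <- default_endpoints()
  t_bev <- build_contingency(co, exposure_definition("BEVACIZUMAB"), eps$VTE)
  expect_equal(unlist(t_bev[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 1, d = 3))
  t_tmz <- build_contingency(co, exposure_definition("TEMOZOLOMIDE"), eps$VTE)
  expect_equal(unlist(t_tmz[c("a", "b", "c", "d")]),
               c(a = 1, b = 2, c = 1, d = 2))
  # exposure matching nothing: all mass in the unexposed column
  t_none <- build_contingency(co, exposure_definition("VINCRISTINE"), eps$VTE)
  expect_equal(unlist(t_none[c("a", "b")]), c(a = 0, b = 0))
  expect_equal(t_none$c + t_none$d, n_reports(co))
  expect_error(build_contingency(filter_reports_public(co, integer(0)),
                                 exposure_definition("BEVACIZUMAB"), eps$VTE),
               "empty cohort")
})

test_that("regimen contingency contrasts the focal group with other bev regimens", {
  bev <- bev_regimen_set()
  eps <- default_endpoints()
  t_tmz <- build_regimen_contingency(bev, "BEV_TMZ", eps$VTE)
  expect_equal(unlist(t_tmz[c("a", "b", "c", "d")]),
               c(a = 2, b = 0, c = 1, d = 2))
  t_mono <- build_regimen_contingency(bev, "BEV_MONO", eps$VTE)
  expect_equal(unlist(t_mono[c("a", "b", "c", "d")]),
               c(a = 1, b = 1, c = 2, d = 1))
  # a regimen absent from the data yields an empty focal margin
  t_lom <- build_regimen_contingency(bev, "BEV_LOM", eps$CNS_BLEED)
  expect_equal(t_lom$a + t_lom$b, 1)  # the single bev+lom report
  expect_error(build_regimen_contingency(micro_cohort(), "BEV_MONO", eps$VTE),
               "bevacizumab")
})

test_that("ROR point estimate and Woolf interval match direct evaluation", {
  sym <- ror_with_ci(contingency_table(5, 5, 5, 5))
  expect_equal(sym$ror, 1)
  expect_equal(sym$low, 1 / sym$high)

  r <- ror_with_ci(contingency_table(3, 7, 30, 700))
  expect_equal(r$ror, 10, tolerance = 1e-12)
  expect_equal(r$low, 2.4635, tolerance = 1e-4)
  expect_equal(r$high, 40.5926, tolerance = 1e-4)
  expect_false(r$corrected)

  # zero cell: Haldane-Anscombe 0.5 on all four cells, flagged
  h <- ror_with_ci(contingency_table(3, 0, 10, 90))
  expect_equal(h$ror, 3.5 * 90.5 / (0.5 * 10.5), tolerance = 1e-12)
  expect_equal(h$ror, 60.3333, tolerance = 1e-4)
  expect_true(h$corrected)
})

test_that("PRR, its interval and the Pearson chi-square match direct evaluation", {
  p <- prr_with_chi2(contingency_table(3, 7, 30, 700))
  expect_equal(p$prr, 7.3, tolerance = 1e-12)
  expect_equal(p$chi2, 15.5203, tolerance = 1e-4)

  ind <- prr_with_chi2(contingency_table(10, 90, 10, 90))
  expect_equal(ind$prr, 1)
  expect_equal(ind$chi2, 0)
  expect_equal(prr_with_chi2(contingency_table(5, 5, 5, 5))$prr, 1)

  expect_error(prr_with_chi2(contingency_table(0, 0, 5, 5)),
               "undefined proportion")
})

test_that("information component matches the closed-form shrunk O/E formula", {
  ic <- bcpnn_ic(contingency_table(10, 90, 90, 810))
  expect_equal(ic$ic, 0)
  expect_equal(ic$ic025, -1.0772, tolerance = 1e-4)
  # a = 0 keeps the IC defined and negative
  ic0 <- bcpnn_ic(contingency_table(0, 100, 50, 850))
  expect_lt(ic0$ic, 0)
  expect_lt(ic0$ic025, ic0$ic)
})

test_that("the signal rule needs a >= 3 and ROR lower bound > 1", {
  expect_true(classify_signal(284, 1.87))
  expect_false(classify_signal(202, 0.82))
  expect_false(classify_signal(2, 5.0))   # a < 3 overrides a strong ROR
  # full truth table
  expect_equal(classify_signal(c(3, 3, 2, 2), c(1.01, 0.99, 1.01, 0.99)),
               c(TRUE, FALSE, FALSE, FALSE))
})

test_that("ROR and PRR never straddle the null and agree for rare events", {
  set.seed(42)
  for (i in 1:500) {
    a <- sample(1:50, 1); b <- sample(1:5000, 1)
    c <- sample(1:200, 1); d <- sample(100:20000, 1)
    t <- contingency_table(a, b, c, d)
    ror <- ror_with_ci(t)$ror
    prr <- prr_with_chi2(t)$prr
    expect_true((ror - 1) * (prr - 1) >= 0)
    expect_true(abs(ror - 1) >= abs(prr - 1) - 1e-12)
    if (a / (a + b) < 0.05 && c / (c + d) < 0.05) {
      # |ROR - PRR| / ROR = |p1 - p0| / (1 - p0) < 0.05 / 0.95 when both
      # event proportions are below 5%
      expect_lt(abs(ror - prr) / ror, 0.05 / 0.95)
    }
  }
})

test_that("chi-square vanishes exactly at independence and only there", {
  expect_equal(prr_with_chi2(contingency_table(4, 8, 10, 20))$chi2, 0)
  expect_equal(prr_with_chi2(contingency_table(3, 9, 21, 63))$chi2, 0)
  set.seed(7)
  for (i in 1:100) {
    a <- sample(1:40, 1); b <- sample(1:400, 1)
    c <- sample(1:40, 1); d <- sample(1:400, 1)
    chi2 <- prr_with_chi2(contingency_table(a, b, c, d))$chi2
    if (a * d == b * c) expect_equal(chi2, 0) else expect_gt(chi2, 0)
  }
})

test_that("analyze_pair assembles the full panel and suppresses a < 3 signals", {
  eps <- default_endpoints()
  prior <- gamma_mixture_prior(0.2, 0.1, 2, 4, 1 / 3)

  res <- analyze_pair(micro_cohort(), exposure_definition("BEVACIZUMAB"),
                      eps$VTE, prior)
  expect_false(res$analyzable)
  expect_false(res$signal)
  expect_equal(res$a, 1)
  expect_true(is.finite(res$ror))  # counts and estimates still reported

  big <- set_from_cells(3, 7, 30, 700)
  res2 <- analyze_pair(big, exposure_definition("BEVACIZUMAB"), eps$VTE, prior)
  expect_true(res2$analyzable)
  expect_true(res2$signal)        # lower bound 2.46 > 1 and a = 3
  expect_equal(res2$ror, 10, tolerance = 1e-12)
  expect_lt(res2$eb05, res2$ebgm)
  expect_lt(res2$ic025, res2$ic)

  ind <- analyze_pair(set_from_cells(10, 90, 10, 90),
                      exposure_definition("BEVACIZUMAB"), eps$VTE, prior)
  expect_false(ind$signal)
})
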