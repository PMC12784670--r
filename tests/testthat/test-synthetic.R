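test_that("generation is deterministic given config and seed", {
  cfg <- synthetic_config(n_reports = 500, seed = 99)
  s1 <- generate_reports(cfg)
  s2 <- generate_reports(cfg)
  expect_identical(s1, s2)
  # and does not disturb the caller's RNG stream
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(generate_reports(cfg)); after <- runif(3)
  expect_identical(before, after)
  # a different seed gives a different database
  expect_false(identical(s1, generate_reports(synthetic_config(
    n_reports = 500, seed = 100))))
})

test_that("deduplication removes exactly the generated duplicate versions", {
  cfg <- synthetic_config(n_reports = 1000, seed = 7, duplicate_prob = 0.1)
  s <- generate_reports(cfg)
  d <- deduplicate(s)
  expect_equal(n_reports(d), attr(s, "n_cases"))
  expect_equal(n_reports(s) - n_reports(d),
               sum(table(s$reports$report_id) > 1))
  expect_true(all(d$reports$version[duplicated(d$reports$report_id)] == 2L))
  # duplicates are version-2 near-copies: kept rows carry max version
  dup_ids <- names(which(table(s$reports$report_id) > 1))
  expect_true(all(d$reports$version[d$reports$report_id %in% dup_ids] == 2L))
})

test_that("closed-form true odds ratio matches direct pattern arithmetic", {
  # single effective drug, no co-prescription: multiplier is returned exactly
  cfg1 <- synthetic_config(
    drug_marginals = c(BEVACIZUMAB = 0.2),
    coprescription_odds = data.frame(drug1 = character(),
                                     drug2 = character(), odds = numeric()),
    effect_matrix = matrix(c(3, 1, 1), 1, 3,
                           dimnames = list("BEVACIZUMAB",
                                           c("VTE", "CNS_BLEED", "GI_BLEED"))))
  expect_equal(true_odds_ratio(cfg1, "BEVACIZUMAB", "VTE"), 3)
  expect_equal(true_odds_ratio(cfg1, "BEVACIZUMAB", "GI_BLEED"), 1)

  # neutral effects give 1 for every pair, co-prescribed or not
  cfgn <- null_config(synthetic_config())
  for (drug in names(cfgn$drug_marginals)) {
    expect_equal(true_odds_ratio(cfgn, drug, "VTE"), 1)
  }

  # two co-prescribed effective drugs: marginal OR exceeds the conditional
  # multiplier (confounding by co-exposure); check against an independent
  # 4-pattern enumeration written out longhand
  m <- matrix(c(2, 2, 1, 1, 1, 1), 2, 3,
              dimnames = list(c("A", "B"), c("VTE", "CNS_BLEED", "GI_BLEED")))
  cfg2 <- synthetic_config(
    drug_marginals = c(A = 0.3, B = 0.2),
    coprescription_odds = data.frame(drug1 = "A", drug2 = "B", odds = 4),
    effect_matrix = m)
  got <- true_odds_ratio(cfg2, "A", "VTE")
  pA <- 0.3
  oB <- 0.2 / 0.8
  pB_given_A <- 4 * oB / (1 + 4 * oB)
  pB_given_notA <- oB / (1 + oB)
  base <- cfg2$baseline_event_probs[["VTE"]]
  pe <- function(mult) plogis(qlogis(base) + log(mult))
  p1 <- pB_given_A * pe(4) + (1 - pB_given_A) * pe(2)        # A exposed
  p0 <- pB_given_notA * pe(2) + (1 - pB_given_notA) * pe(1)  # A unexposed
  want <- (p1 / (1 - p1)) / (p0 / (1 - p0))
  expect_equal(got, want, tolerance = 1e-12)
  expect_gt(got, 2)
})

test_that("null generation yields near-null reporting odds ratios", {
  cfg <- null_config(synthetic_config(n_reports = 60000, seed = 77,
                                      duplicate_prob = 0))
  co <- subset_cohort(deduplicate(generate_reports(cfg)), glioma_broad())
  eps <- default_endpoints()
  for (drug in c("BEVACIZUMAB", "TEMOZOLOMIDE")) {
    t <- build_contingency(co, exposure_definition(drug), eps$VTE)
    expect_gt(ror_with_ci(t)$ror, 0.8)
    expect_lt(ror_with_ci(t)$ror, 1.25)
  }
})

test_that("a configured effect is recovered by the estimated ROR", {
  m <- default_effect_matrix(); m[] <- 1; m["BEVACIZUMAB", "VTE"] <- 2.3
  cfg <- synthetic_config(n_reports = 60000, seed = 31, effect_matrix = m)
  co <- subset_cohort(deduplicate(generate_reports(cfg)), glioma_broad())
  r <- ror_with_ci(build_contingency(co, exposure_definition("BEVACIZUMAB"),
                                     default_endpoints()$VTE))
  expect_gt(r$ror, 1.9); expect_lt(r$ror, 2.75)
  expect_true(r$low <= 2.3 && 2.3 <= r$high)
})

test_that("estimated ROR is nondecreasing in the configured multiplier", {
  est <- vapply(c(1, 1.6, 2.5, 4), function(mult) {
    m <- default_effect_matrix(); m[] <- 1; m["BEVACIZUMAB", "VTE"] <- mult
    cfg <- synthetic_config(n_reports = 30000, seed = 55, effect_matrix = m,
                            duplicate_prob = 0)
    co <- subset_cohort(deduplicate(generate_reports(cfg)), glioma_broad())
    ror_with_ci(build_contingency(co, exposure_definition("BEVACIZUMAB"),
                                  default_endpoints()$VTE))$ror
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("demographic missingness lands near the configured rates", {
  cfg <- synthetic_config(n_reports = 10000, seed = 9, duplicate_prob = 0)
  s <- deduplicate(generate_reports(cfg))
  unk <- function(col) mean(s$reports[[col]] == "UNK")
  expect_equal(unk("sex"), cfg$missingness[["sex"]], tolerance = 0.05)
  expect_equal(unk("age_group"), cfg$missingness[["age"]] +
                 (1 - cfg$missingness[["age"]]) * 0, tolerance = 0.05)
  expect_equal(unk("weight_band"), cfg$missingness[["weight"]],
               tolerance = 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(glioma_fraction = 1.4), "probabilities")
  expect_error(synthetic_config(n_reports = 0), "n_reports")
  m <- default_effect_matrix(); m[1, 1] <- -1
  expect_error(synthetic_config(effect_matrix = m), "positive")
})
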