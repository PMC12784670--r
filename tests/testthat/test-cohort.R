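test_that("free-text cohort matching follows the broad and strict term lists", {
  s <- quick_set(drugs = vector("list", 4),
                 inds = c("Glioblastoma multiforme", "anaplastic astrocytoma",
                          "oligodendroglioma", "NON-SMALL CELL LUNG CANCER"))
  broad <- match_cohort(s, glioma_broad())
  strict <- match_cohort(s, glioma_strict())
  expect_equal(broad, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(strict, c(TRUE, TRUE, FALSE, FALSE))

  # matching is substring-based and case-insensitive
  s2 <- quick_set(drugs = vector("list", 2),
                  inds = c("recurrent GLIOBLASTOMA, left lobe", "gLiOmA"))
  expect_true(all(match_cohort(s2, glioma_broad())))

  # history text participates when selected
  s3 <- quick_set(drugs = list(NULL), inds = "metastatic disease")
  s3$reports$history_text <- "Known malignant glioma since 2019"
  expect_true(match_cohort(s3, glioma_strict()))
  expect_false(match_cohort(s3, cohort_definition("ind-only", "GLIOMA",
                                                  match_fields = "indications")))
})

test_that("cohort matching is invariant under case changes", {
  base <- c("Glioblastoma", "Anaplastic astrocytoma", "Oligodendroglioma",
            "Breast cancer", "malignant GLIOMA")
  for (f in list(toupper, tolower, identity)) {
    s <- quick_set(drugs = vector("list", 5), inds = f(base))
    expect_equal(match_cohort(s, glioma_broad()),
                 c(TRUE, TRUE, TRUE, FALSE, TRUE))
  }
})

test_that("strict cohort is a subset of the broad cohort on generated data", {
  s <- deduplicate(generate_reports(synthetic_config(n_reports = 2000, seed = 3)))
  broad <- match_cohort(s, glioma_broad())
  strict <- match_cohort(s, glioma_strict())
  expect_true(all(strict <= broad))
  expect_gt(sum(strict), 0)
  expect_lt(sum(strict), sum(broad))
})

test_that("drug names normalize through the brand map", {
  bm <- default_brand_map()
  expect_equal(normalize_drug_name("Avastin", bm), "BEVACIZUMAB")
  expect_equal(normalize_drug_name("GLIADEL", bm), "CARMUSTINE")
  expect_equal(normalize_drug_name("temozolomide  ", bm), "TEMOZOLOMIDE")
  expect_equal(normalize_drug_name(c("CeeNU", "BiCNU"), bm),
               c("LOMUSTINE", "CARMUSTINE"))
  # unknown names come back normalized-verbatim
  expect_equal(normalize_drug_name("  aspirin", bm), "ASPIRIN")
})

test_that("exposure classification honours the role filter", {
  s <- quick_set(drugs = list("BEVACIZUMAB", "TEMOZOLOMIDE"),
                 roles = list("C", "PS"))
  any_def <- exposure_definition("BEVACIZUMAB", "ANY")
  ps_def <- exposure_definition("BEVACIZUMAB", "PS_ONLY")
  expect_equal(is_exposed(s, any_def), c(TRUE, FALSE))
  expect_equal(is_exposed(s, ps_def), c(FALSE, FALSE))
  expect_equal(is_exposed(s, exposure_definition("LOMUSTINE")), c(FALSE, FALSE))
})

test_that("PS-only exposure is always a subset of any-role exposure", {
  s <- deduplicate(generate_reports(synthetic_config(n_reports = 2000, seed = 8)))
  for (drug in default_study_drugs()) {
    any_e <- is_exposed(s, exposure_definition(drug, "ANY"))
    ps_e <- is_exposed(s, exposure_definition(drug, "PS_ONLY"))
    expect_true(all(ps_e <= any_e))
  }
})

test_that("regimen assignment matches exhaustive enumeration of drug patterns", {
  combos <- expand.grid(bev = c(FALSE, TRUE), tmz = c(FALSE, TRUE),
                        lom = c(FALSE, TRUE))
  drugs <- lapply(seq_len(nrow(combos)), function(i) {
    c("DEXAMETHASONE",  # never empty, never a study drug
      if (combos$bev[i]) "BEVACIZUMAB",
      if (combos$tmz[i]) "TEMOZOLOMIDE",
      if (combos$lom[i]) "LOMUSTINE")
  })
  s <- quick_set(drugs = drugs)
  got <- assign_regimen(s)
  # independent truth table
  want <- with(combos, ifelse(!bev, "NOT_BEV",
                ifelse(tmz & lom, "BEV_OTHER_COMBO",
                ifelse(tmz, "BEV_TMZ", ifelse(lom, "BEV_LOM", "BEV_MONO")))))
  expect_equal(got, want)
})

test_that("regimen labels partition the bevacizumab-exposed reports", {
  s <- deduplicate(generate_reports(synthetic_config(n_reports = 3000, seed = 13)))
  lab <- assign_regimen(s)
  bev <- is_exposed(s, exposure_definition("BEVACIZUMAB", "ANY"))
  expect_equal(sum(lab != "NOT_BEV"), sum(bev))
  expect_true(all(lab[bev] != "NOT_BEV"))
  expect_true(all(lab[!bev] == "NOT_BEV"))
})
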