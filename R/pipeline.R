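#' Analysis plan for a disproportionality run
#'
#' Bundles the cohort definition, exposure role filter, study drugs and
#' endpoints of one analysis. Databases are never pooled: a plan is applied
#' to one [report_set()] (one database) per call.
#'
#' @param cohort_def A [cohort_definition()] (default the broad glioma
#'   definition).
#' @param role_filter `"ANY"` or `"PS_ONLY"`.
#' @param drugs Character vector of generic drug names to analyze.
#' @param endpoints Named list of [endpoint_definition()] objects.
#' @return An object of class `analysis_plan`.
#' @export
analysis_plan <- function(cohort_def = glioma_broad(),
                          role_filter = c("ANY", "PS_ONLY"),
                          drugs = default_study_drugs(),
                          endpoints = default_endpoints()) {
  if (!length(drugs)) stop("plan needs at least one drug", call. = FALSE)
  structure(list(cohort_def = cohort_def,
                 role_filter = match.arg(role_filter),
                 drugs = toupper(drugs), endpoints = endpoints),
            class = "analysis_plan")
}

# Fit the shrinkage prior on this call's (a, E) pairs; with few pairs the
# five-parameter mixture is weakly identified, so flag the fit rather than
# refuse it.
fit_call_prior <- function(tables) {
  a <- vapply(tables, function(t) t$a, numeric(1))
  E <- vapply(tables, function(t) {
    N <- t$a + t$b + t$c + t$d
    (t$a + t$b) * (t$a + t$c) / N
  }, numeric(1))
  keep <- E > 0
  low_info <- sum(keep) < 20
  prior <- tryCatch(
    fit_gamma_mixture_prior(a[keep], E[keep]),
    error = function(e) {
      if (!is.null(e$prior)) e$prior else NULL
    })
  list(prior = prior, low_info = low_info || is.null(prior))
}

#' Main disproportionality analysis for the study drugs
#'
#' Restricts the set to the plan's cohort, crosses every study drug with
#' every endpoint, and computes the full metric panel for each pair. The
#' empirical-Bayes shrinkage prior is fitted once per call on all of the
#' call's (a, E) pairs; with fewer than 20 pairs the fit is flagged
#' `prior_low_info` (EBGM/EB05 reported but to be read with caution).
#' Pairs with `a < 3` are flagged not analyzable and never signal.
#'
#' @param set A deduplicated [report_set()] (one database).
#' @param plan An [analysis_plan()].
#' @return Tibble with one row per drug-endpoint pair.
#' @export
run_main_analysis <- function(set, plan = analysis_plan()) {
  stopifnot(inherits(set, "report_set"), inherits(plan, "analysis_plan"))
  cohort <- subset_cohort(set, plan$cohort_def)
  if (n_reports(cohort) == 0) stop("empty cohort", call. = FALSE)
  grid <- expand.grid(drug = plan$drugs, event = names(plan$endpoints),
                      stringsAsFactors = FALSE)
  tables <- lapply(seq_len(nrow(grid)), function(i) {
    build_contingency(cohort,
                      exposure_definition(grid$drug[i], plan$role_filter),
                      plan$endpoints[[grid$event[i]]])
  })
  pf <- fit_call_prior(tables)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    analyze_table(tables[[i]], database = set$database,
                  label = grid$drug[i], event = grid$event[i],
                  prior = pf$prior)
  })
  out <- do.call(rbind, rows)
  out$cohort <- plan$cohort_def$name
  out$role_filter <- plan$role_filter
  out$prior_low_info <- pf$low_info
  out
}

#' Bevacizumab regimen-stratified analysis
#'
#' Restricts the cohort to bevacizumab-exposed reports (any role),
#' partitions them into regimen groups, and contrasts each focal group
#' (monotherapy, + temozolomide, + lomustine) against all other
#' bevacizumab-containing regimens for every endpoint. Focal groups with
#' `a < 3` are flagged not analyzable; triple combinations only ever
#' contribute to the comparator cells.
#'
#' @param set A deduplicated [report_set()] (one database).
#' @param plan An [analysis_plan()] (its cohort definition and endpoints
#'   are used; regimen exposure is always any-role).
#' @return Tibble with one row per regimen-endpoint pair.
#' @export
run_regimen_analysis <- function(set, plan = analysis_plan()) {
  stopifnot(inherits(set, "report_set"), inherits(plan, "analysis_plan"))
  cohort <- subset_cohort(set, plan$cohort_def)
  bev <- filter_reports(cohort,
                        is_exposed(cohort, exposure_definition("BEVACIZUMAB",
                                                               "ANY")))
  if (n_reports(bev) == 0) stop("no bevacizumab-exposed reports in cohort",
                                call. = FALSE)
  focals <- c("BEV_MONO", "BEV_TMZ", "BEV_LOM")
  grid <- expand.grid(regimen = focals, event = names(plan$endpoints),
                      stringsAsFactors = FALSE)
  tables <- lapply(seq_len(nrow(grid)), function(i) {
    build_regimen_contingency(bev, grid$regimen[i],
                              plan$endpoints[[grid$event[i]]])
  })
  pf <- fit_call_prior(tables)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    analyze_table(tables[[i]], database = set$database,
                  label = grid$regimen[i], event = grid$event[i],
                  prior = pf$prior)
  })
  out <- do.call(rbind, rows)
  out$cohort <- plan$cohort_def$name
  out$role_filter <- "ANY"
  out$prior_low_info <- pf$low_info
  out
}

#' Sensitivity analyses
#'
#' Re-runs the main analysis with one assumption swapped: `STRICT_COHORT`
#' replaces the broad glioma case definition with the strict
#' higher-certainty one; `PS_ONLY` restricts exposure to primary-suspect
#' drug entries. Everything else (endpoints, comparators, signal rule) is
#' unchanged. The output is tagged with the variant; [sensitivity_table()]
#' joins it to the main results for side-by-side comparison.
#'
#' @param set A deduplicated [report_set()] (one database).
#' @param variant `"STRICT_COHORT"` or `"PS_ONLY"`.
#' @param plan An [analysis_plan()] describing the *main* analysis.
#' @return Tibble as [run_main_analysis()] plus a `variant` column.
#' @export
run_sensitivity <- function(set, variant = c("STRICT_COHORT", "PS_ONLY"),
                            plan = analysis_plan()) {
  variant <- match.arg(variant)
  plan2 <- plan
  if (variant == "STRICT_COHORT") {
    plan2$cohort_def <- glioma_strict()
  } else {
    plan2$role_filter <- "PS_ONLY"
  }
  out <- run_main_analysis(set, plan2)
  out$variant <- variant
  out
}

#' Side-by-side main vs sensitivity comparison
#'
#' @param main Output of [run_main_analysis()].
#' @param sens Output of [run_sensitivity()].
#' @return Tibble with one row per drug-endpoint pair and paired columns
#'   (`n_main`, `ror_main`, CI and signal, vs the sensitivity analogues).
#' @export
sensitivity_table <- function(main, sens) {
  key <- c("database", "drug_or_regimen", "event")
  m <- main[c(key, "a", "ror", "ror_low", "ror_high", "signal")]
  names(m)[-(1:3)] <- paste0(c("n", "ror", "ror_low", "ror_high", "signal"),
                             "_main")
  s <- sens[c(key, "a", "ror", "ror_low", "ror_high", "signal")]
  names(s)[-(1:3)] <- paste0(c("n", "ror", "ror_low", "ror_high", "signal"),
                             "_sens")
  tibble::as_tibble(merge(m, s, by = key, sort = FALSE))
}

#' Descriptive baseline table of a cohort, by drug
#'
#' For each drug (any-role exposure) tabulates counts and percentages of
#' the sex, age and weight bands including the unknown category, plus the
#' share of health-care-professional reporters and of serious reports.
#' Percentages within each band block sum to 100 up to rounding.
#'
#' @param set A deduplicated [report_set()] (typically the cohort).
#' @param drugs Character vector of generic drug names.
#' @return Tibble with columns `drug`, `characteristic`, `level`, `n`, `pct`.
#' @export
summarize_cohort <- function(set, drugs = default_study_drugs()) {
  stopifnot(inherits(set, "report_set"))
  blocks <- list(sex = c("M", "F", "UNK"),
                 age_group = c("12-17", "18-64", "65-85", "UNK"),
                 weight_band = c("LT50", "50TO100", "GT100", "UNK"),
                 reporter = "HCP", serious = "YES")
  rows <- list()
  for (drug in drugs) {
    ex <- is_exposed(set, exposure_definition(drug, "ANY"))
    sub <- set$reports[ex, , drop = FALSE]
    total <- nrow(sub)
    for (ch in names(blocks)) {
      for (lev in blocks[[ch]]) {
        n <- sum(sub[[ch]] == lev)
        rows[[length(rows) + 1]] <- tibble::tibble(
          drug = drug, characteristic = ch, level = lev, n = n,
          pct = if (total > 0) 100 * n / total else 0)
      }
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      drug = drug, characteristic = "total", level = "reports", n = total,
      pct = if (total > 0) 100 else 0)
  }
  do.call(rbind, rows)
}

#' Export forest-plot data
#'
#' One row per result with the log2-scale plotting fields used by ROR
#' forest displays; rendering itself is out of scope, the export is the
#' interface to whatever plotting tool is preferred.
#'
#' @param results Tibble from one of the `run_*` functions.
#' @param path Optional TSV output path.
#' @return The plotting tibble (invisibly if `path` is given).
#' @export
export_forest_data <- function(results, path = NULL) {
  out <- tibble::tibble(
    database = results$database,
    drug_or_regimen = results$drug_or_regimen,
    event = results$event,
    ror = results$ror, ror_low = results$ror_low, ror_high = results$ror_high,
    log2_ror = log2(results$ror),
    log2_low = log2(results$ror_low), log2_high = log2(results$ror_high),
    signal = results$signal, analyzable = results$analyzable)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

result_columns <- c("database", "drug_or_regimen", "event", "a", "ror",
                    "ror_low", "ror_high", "signal", "prr", "chi2", "ic",
                    "ic025", "ebgm", "eb05", "analyzable",
                    "zero_cell_corrected")

#' Write analysis results as CSV / JSON
#'
#' Emits the standard reporting column set (one row per drug-or-regimen x
#' endpoint) with values rounded to 2 decimals, matching the precision of
#' published signal tables; internal computation stays at full precision.
#'
#' @param results Tibble from one of the `run_*` functions.
#' @param path Output file path.
#' @return Invisibly, the exported data frame.
#' @export
write_results_csv <- function(results, path) {
  out <- results[intersect(result_columns, names(results))]
  num <- vapply(out, is.numeric, logical(1)) & !(names(out) %in% "a")
  out[num] <- lapply(out[num], round, 2)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' @rdname write_results_csv
#' @export
write_results_json <- function(results, path) {
  out <- results[intersect(result_columns, names(results))]
  jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
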