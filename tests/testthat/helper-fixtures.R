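# Compact report_set builder: one report per element of `drugs`/`pts`,
# glioma indications by default so every report lands in the broad cohort.
quick_set <- function(drugs, pts = vector("list", length(drugs)),
                      inds = rep("Glioblastoma", length(drugs)),
                      db = "FAERS", versions = rep(1L, length(drugs)),
                      roles = NULL, sex = NULL) {
  n <- length(drugs)
  ids <- sprintf("R%03d", seq_len(n))
  reports <- tibble::tibble(
    report_id = ids, version = versions,
    sex = if (is.null(sex)) rep("UNK", n) else sex,
    age_group = "UNK", weight_band = "UNK", reporter = "UNK",
    serious = "UNK", history_text = "")
  drug_rows <- lapply(seq_len(n), function(i) {
    dd <- drugs[[i]]
    if (!length(dd)) return(NULL)
    rr <- if (is.null(roles)) rep("PS", length(dd)) else rep_len(roles[[i]], length(dd))
    tibble::tibble(report_id = ids[i], version = versions[i],
                   drug_seq = seq_along(dd), verbatim_name = dd,
                   generic_name = toupper(dd), role = rr)
  })
  pt_rows <- lapply(seq_len(n), function(i) {
    pp <- pts[[i]]
    if (!length(pp)) return(NULL)
    tibble::tibble(report_id = ids[i], version = versions[i], pt = pp)
  })
  ind_rows <- tibble::tibble(report_id = ids, version = versions,
                             indication_text = inds)
  report_set(db,
             reports,
             do.call(rbind, c(drug_rows, list(empty_drugs()))),
             do.call(rbind, c(pt_rows, list(empty_reactions()))),
             ind_rows)
}

# The six-report micro cohort: bev+VTE; bev+other; tmz+VTE; tmz+other(x2);
# lom+other.
micro_cohort <- function() {
  quick_set(
    drugs = list("BEVACIZUMAB", "BEVACIZUMAB", "TEMOZOLOMIDE",
                 "TEMOZOLOMIDE", "TEMOZOLOMIDE", "LOMUSTINE"),
    pts = list("DEEP VEIN THROMBOSIS", "NAUSEA", "PULMONARY EMBOLISM",
               "NAUSEA", "HEADACHE", "FATIGUE"))
}

# Five bevacizumab reports for the regimen fixture: 2 mono (one with VTE),
# 2 bev+tmz (both VTE), 1 bev+lom (no VTE).
bev_regimen_set <- function() {
  quick_set(
    drugs = list("BEVACIZUMAB", "BEVACIZUMAB",
                 c("BEVACIZUMAB", "TEMOZOLOMIDE"),
                 c("BEVACIZUMAB", "TEMOZOLOMIDE"),
                 c("BEVACIZUMAB", "LOMUSTINE")),
    pts = list("DEEP VEIN THROMBOSIS", "NAUSEA",
               "PULMONARY EMBOLISM", "DEEP VEIN THROMBOSIS", "NAUSEA"))
}

# Build a cohort realizing exact 2x2 cells for one drug-endpoint pair.
set_from_cells <- function(a, b, c, d, drug = "BEVACIZUMAB",
                           pt = "DEEP VEIN THROMBOSIS") {
  n <- a + b + c + d
  exposed <- c(rep(TRUE, a + b), rep(FALSE, c + d))
  event <- c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c), rep(FALSE, d))
  quick_set(
    drugs = lapply(exposed, function(e) if (e) drug else "DEXAMETHASONE"),
    pts = lapply(event, function(e) if (e) pt else "NAUSEA"))
}

# Deterministic 2-case set used for the FAERS golden-file test.
golden_two_case_set <- function() {
  quick_set(
    drugs = list(c("Avastin", "TEMOZOLOMIDE"), "Gliadel"),
    pts = list(c("DEEP VEIN THROMBOSIS", "NAUSEA"), "MELAENA"),
    inds = c("Glioblastoma multiforme", "Anaplastic astrocytoma"),
    sex = c("M", "UNK"), roles = list(c("PS", "C"), "SS"))
}

filter_reports_public <- function(set, idx) pvsignal:::filter_reports(set, idx)

expect_same_reports <- function(x, y) {
  cols <- c("report_id", "version", "sex", "age_group", "weight_band",
            "reporter")
  expect_equal(as.data.frame(x$reports[cols]), as.data.frame(y$reports[cols]))
}

# Independent oracle: numerical integration of the posterior gamma mixture.
ebgm_oracle <- function(a, E, pr) {
  lq1 <- log(pr$w) +
    dnbinom(a, size = pr$alpha1, prob = pr$beta1 / (pr$beta1 + E), log = TRUE)
  lq2 <- log(1 - pr$w) +
    dnbinom(a, size = pr$alpha2, prob = pr$beta2 / (pr$beta2 + E), log = TRUE)
  Q <- 1 / (1 + exp(lq2 - lq1))
  dens <- function(x) {
    Q * dgamma(x, pr$alpha1 + a, rate = pr$beta1 + E) +
      (1 - Q) * dgamma(x, pr$alpha2 + a, rate = pr$beta2 + E)
  }
  m <- integrate(function(x) log(x) * dens(x), 0, Inf, rel.tol = 1e-10)$value
  cdf <- function(t) integrate(dens, 0, t, rel.tol = 1e-11)$value
  q05 <- uniroot(function(t) cdf(t) - 0.05, c(1e-9, 500), tol = 1e-11)$root
  list(ebgm = exp(m), eb05 = q05)
}

random_prior <- function() {
  gamma_mixture_prior(runif(1, 0.1, 3), runif(1, 0.1, 3),
                      runif(1, 0.5, 5), runif(1, 0.5, 5), runif(1, 0.1, 0.9))
}
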