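#' Generative specification for a synthetic reporting database
#'
#' Defines every distribution the synthetic spontaneous-report generator
#' draws from, so that a simulated database has a fully known ground truth.
#' Effects are *odds multipliers* on the per-report event probability
#' (logistic-odds model), so the population reporting odds ratio implied by
#' a configuration is available in closed form via [true_odds_ratio()].
#'
#' Defaults emulate a glioma-enriched oncology slice of a spontaneous
#' reporting database: most reports carry a glioma indication (mostly with
#' higher-certainty malignant wording), the four study drugs appear with
#' realistic marginals and bevacizumab is preferentially co-prescribed with
#' temozolomide and lomustine, and demographic missingness mirrors the
#' published baseline table for bevacizumab reports (about 40% missing sex,
#' 45% missing age, 71% missing weight). The default effect matrix encodes
#' the published bevacizumab signal profile (VTE and GI bleeding odds
#' multipliers 2.3, CNS bleeding 1.5) with all other drugs neutral.
#'
#' @param database Database code for the generated set.
#' @param n_reports Number of distinct cases to generate.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @param glioma_fraction Probability a report carries a glioma indication.
#' @param strict_fraction_within_glioma Probability a glioma indication uses
#'   one of the strict (higher-certainty malignant) terms.
#' @param drug_marginals Named vector of baseline exposure probabilities for
#'   the study drugs.
#' @param coprescription_odds Data frame (`drug1`, `drug2`, `odds`) of odds
#'   multipliers applied to `drug2`'s exposure odds when `drug1` is present
#'   (drugs are drawn in the order of `drug_marginals`).
#' @param role_distribution Probabilities over drug roles `PS`, `SS`, `C`.
#' @param baseline_event_probs Named per-report probabilities of at least
#'   one PT of each endpoint, for a report exposed to no study drug.
#' @param effect_matrix Numeric matrix (drugs x endpoints) of odds
#'   multipliers.
#' @param background_drugs Named vector of exposure probabilities for
#'   non-study concomitant drugs.
#' @param background_pt_weights Named vector of sampling weights for
#'   non-endpoint reaction PTs.
#' @param missingness Named vector of UNK probabilities for `sex`, `age`,
#'   `weight`, `reporter`.
#' @param serious_prob Probability a report is flagged serious.
#' @param duplicate_prob Probability a case is also emitted as a version-2
#'   near-copy (one perturbed demographic field), exercising deduplication.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    database = "FAERS",
    n_reports = 5000,
    seed = 1L,
    glioma_fraction = 0.75,
    strict_fraction_within_glioma = 0.8,
    drug_marginals = c(BEVACIZUMAB = 0.30, TEMOZOLOMIDE = 0.35,
                       LOMUSTINE = 0.06, CARMUSTINE = 0.02),
    coprescription_odds = data.frame(
      drug1 = c("BEVACIZUMAB", "BEVACIZUMAB"),
      drug2 = c("TEMOZOLOMIDE", "LOMUSTINE"),
      odds = c(2.0, 1.5)),
    role_distribution = c(PS = 0.5, SS = 0.2, C = 0.3),
    baseline_event_probs = c(VTE = 0.03, CNS_BLEED = 0.02, GI_BLEED = 0.012),
    effect_matrix = default_effect_matrix(),
    background_drugs = c(DEXAMETHASONE = 0.30, LEVETIRACETAM = 0.20,
                         ONDANSETRON = 0.15),
    background_pt_weights = c(
      NAUSEA = 10, FATIGUE = 9, HEADACHE = 8, VOMITING = 7, SEIZURE = 5,
      THROMBOCYTOPENIA = 5, NEUTROPENIA = 4, RASH = 4, PYREXIA = 4,
      DIARRHOEA = 3, ANAEMIA = 3, `DECREASED APPETITE` = 3,
      `OEDEMA PERIPHERAL` = 2, HYPERTENSION = 2, CONSTIPATION = 2),
    missingness = c(sex = 0.40, age = 0.45, weight = 0.71, reporter = 0.10),
    serious_prob = 0.18,
    duplicate_prob = 0.05) {
  drugs <- names(drug_marginals)
  endpoints <- names(baseline_event_probs)
  if (is.null(dimnames(effect_matrix))) {
    dimnames(effect_matrix) <- list(drugs, endpoints)
  }
  probs <- c(glioma_fraction, strict_fraction_within_glioma, drug_marginals,
             baseline_event_probs, missingness, serious_prob, duplicate_prob,
             role_distribution, background_drugs)
  if (any(probs < 0) || any(probs > 1)) {
    stop("config probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(effect_matrix <= 0) || any(coprescription_odds$odds <= 0)) {
    stop("odds multipliers must be positive", call. = FALSE)
  }
  if (n_reports < 1) stop("n_reports must be >= 1", call. = FALSE)
  if (!setequal(rownames(effect_matrix), drugs) ||
      !setequal(colnames(effect_matrix), endpoints)) {
    stop("effect_matrix dimnames must match drugs and endpoints", call. = FALSE)
  }
  structure(list(
    database = database, n_reports = as.integer(n_reports),
    seed = as.integer(seed), glioma_fraction = glioma_fraction,
    strict_fraction_within_glioma = strict_fraction_within_glioma,
    drug_marginals = drug_marginals,
    coprescription_odds = coprescription_odds,
    role_distribution = role_distribution / sum(role_distribution),
    baseline_event_probs = baseline_event_probs,
    effect_matrix = effect_matrix[drugs, endpoints, drop = FALSE],
    background_drugs = background_drugs,
    background_pt_weights = background_pt_weights,
    missingness = missingness, serious_prob = serious_prob,
    duplicate_prob = duplicate_prob),
    class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_effect_matrix <- function() {
  m <- matrix(1, nrow = 4, ncol = 3,
              dimnames = list(c("BEVACIZUMAB", "TEMOZOLOMIDE", "LOMUSTINE",
                                "CARMUSTINE"),
                              c("VTE", "CNS_BLEED", "GI_BLEED")))
  m["BEVACIZUMAB", ] <- c(2.3, 1.5, 2.3)
  m
}

#' Neutral (all effects 1) variant of a configuration
#'
#' Convenience for null-calibration studies: the same reporting database
#' structure with every drug-endpoint odds multiplier set to 1, so every
#' true reporting odds ratio equals 1.
#'
#' @param config A [synthetic_config()].
#' @return A [synthetic_config()] with a unit effect matrix.
#' @export
null_config <- function(config = synthetic_config()) {
  config$effect_matrix[] <- 1
  config
}

# Indication wordings; mixed case on purpose (matching is case-insensitive).
glioma_terms_strict_pool <- c("Glioblastoma", "Glioblastoma multiforme",
                              "Malignant glioma", "Anaplastic astrocytoma")
glioma_terms_broad_only_pool <- c("Glioma", "Astrocytoma", "Oligodendroglioma",
                                  "Anaplastic oligodendroglioma")
non_glioma_pool <- c("Non-small cell lung cancer", "Breast cancer",
                     "Colorectal cancer", "Ovarian cancer",
                     "Renal cell carcinoma", "Multiple myeloma")

# Verbatim spellings per generic, exercising brand mapping and case noise.
verbatim_pool <- list(
  BEVACIZUMAB = c("Avastin", "BEVACIZUMAB", "bevacizumab"),
  TEMOZOLOMIDE = c("Temodar", "TEMOZOLOMIDE", "temozolomide  "),
  LOMUSTINE = c("Gleostine", "CeeNU", "LOMUSTINE"),
  CARMUSTINE = c("Gliadel", "BiCNU", "CARMUSTINE"),
  DEXAMETHASONE = "DEXAMETHASONE",
  LEVETIRACETAM = "Levetiracetam",
  ONDANSETRON = "Ondansetron"
)

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic spontaneous reporting database
#'
#' Draws, for each case: a glioma or non-glioma free-text indication; study
#' drug exposures sequentially with co-prescription odds tilting; drug
#' roles; endpoint events from the logistic-odds model
#' `logit(p) = logit(baseline) + sum(log(multiplier))` over exposed drugs,
#' realized as 1-2 PTs from the endpoint's term set; 1-4 background PTs;
#' demographics with configured missingness; and, for a random subset of
#' cases, a version-2 near-duplicate differing in one demographic field.
#' The output is *pre-deduplication*; [deduplicate()] removes exactly the
#' extra versions. Deterministic given the config (including its seed).
#'
#' @param config A [synthetic_config()].
#' @param endpoints Endpoint definitions whose PT sets realize the events
#'   (default [default_endpoints()]); names must cover the configured
#'   `baseline_event_probs`.
#' @return A [report_set()] with attribute `n_cases` (distinct case count).
#' @export
generate_reports <- function(config, endpoints = default_endpoints()) {
  stopifnot(inherits(config, "synthetic_config"))
  stopifnot(all(names(config$baseline_event_probs) %in% names(endpoints)))
  with_seed(config$seed, {
    n <- config$n_reports
    drugs <- names(config$drug_marginals)
    epn <- names(config$baseline_event_probs)

    # indications
    glioma <- stats::runif(n) < config$glioma_fraction
    strict <- stats::runif(n) < config$strict_fraction_within_glioma
    ind <- character(n)
    ind[glioma & strict] <- sample(glioma_terms_strict_pool,
                                   sum(glioma & strict), replace = TRUE)
    ind[glioma & !strict] <- sample(glioma_terms_broad_only_pool,
                                    sum(glioma & !strict), replace = TRUE)
    ind[!glioma] <- sample(non_glioma_pool, sum(!glioma), replace = TRUE)

    # sequential study-drug exposure with co-prescription tilting
    exposed <- matrix(FALSE, n, length(drugs), dimnames = list(NULL, drugs))
    for (k in seq_along(drugs)) {
      p <- config$drug_marginals[k]
      odds <- rep(p / (1 - p), n)
      co <- config$coprescription_odds
      for (j in which(co$drug2 == drugs[k])) {
        prev <- co$drug1[j]
        if (prev %in% drugs[seq_len(k - 1)]) {
          odds <- odds * ifelse(exposed[, prev], co$odds[j], 1)
        }
      }
      exposed[, k] <- stats::runif(n) < odds / (1 + odds)
    }

    # endpoint events via the logistic-odds model
    event <- matrix(FALSE, n, length(epn), dimnames = list(NULL, epn))
    for (e in epn) {
      base <- config$baseline_event_probs[e]
      lg <- stats::qlogis(base) +
        exposed %*% log(config$effect_matrix[drugs, e])
      event[, e] <- stats::runif(n) < stats::plogis(as.numeric(lg))
    }

    report_id <- sprintf("%s-%07d", config$database, seq_len(n))

    # demographics
    draw_cat <- function(levels, probs, miss) {
      x <- sample(levels, n, replace = TRUE, prob = probs)
      x[stats::runif(n) < miss] <- "UNK"
      x
    }
    sex <- draw_cat(c("M", "F"), c(0.55, 0.45), config$missingness["sex"])
    age <- draw_cat(c("12-17", "18-64", "65-85"), c(0.02, 0.62, 0.36),
                    config$missingness["age"])
    wt <- draw_cat(c("LT50", "50TO100", "GT100"), c(0.08, 0.77, 0.15),
                   config$missingness["weight"])
    rptr <- draw_cat(c("HCP", "NONHCP"), c(0.65, 0.35),
                     config$missingness["reporter"])
    serious <- ifelse(stats::runif(n) < config$serious_prob, "YES", "NO")

    reports <- tibble::tibble(
      report_id = report_id, version = 1L, sex = sex, age_group = age,
      weight_band = wt, reporter = rptr, serious = serious, history_text = "")

    # drugs table: study drugs (with roles) + background concomitants
    all_drugs <- c(drugs, names(config$background_drugs))
    drug_rows <- lapply(all_drugs, function(dr) {
      on <- if (dr %in% drugs) exposed[, dr] else
        stats::runif(n) < config$background_drugs[dr]
      idx <- which(on)
      if (!length(idx)) return(NULL)
      role <- if (dr %in% drugs) {
        sample(names(config$role_distribution), length(idx), replace = TRUE,
               prob = config$role_distribution)
      } else "C"
      verb <- sample(verbatim_pool[[dr]], length(idx), replace = TRUE)
      tibble::tibble(report_id = report_id[idx], version = 1L,
                     verbatim_name = verb,
                     generic_name = dr, role = role)
    })
    drugs_tbl <- do.call(rbind, drug_rows)
    if (is.null(drugs_tbl)) {
      drugs_tbl <- empty_drugs()
    } else {
      ridx <- match(drugs_tbl$report_id, report_id)
      drugs_tbl <- drugs_tbl[order(ridx), ]
      r <- sort(ridx)
      first_pos <- which(!duplicated(r))
      drugs_tbl$drug_seq <- seq_along(r) - first_pos[cumsum(!duplicated(r))] + 1L
    }

    # reactions: endpoint PTs for events, plus background PTs
    reac_rows <- list()
    for (e in epn) {
      idx <- which(event[, e])
      if (!length(idx)) next
      k <- 1L + (stats::runif(length(idx)) < 0.3)
      rid <- rep(report_id[idx], k)
      pts <- sample(endpoints[[e]]$pts, length(rid), replace = TRUE)
      reac_rows[[e]] <- tibble::tibble(report_id = rid, version = 1L, pt = pts)
    }
    nbg <- sample(1:4, n, replace = TRUE)
    bg_id <- rep(report_id, nbg)
    bg_pt <- sample(names(config$background_pt_weights), length(bg_id),
                    replace = TRUE, prob = config$background_pt_weights)
    reac_rows$background <- tibble::tibble(report_id = bg_id, version = 1L,
                                           pt = bg_pt)
    reactions <- do.call(rbind, reac_rows)
    ridx <- match(reactions$report_id, report_id)
    ptidx <- match(reactions$pt, unique(reactions$pt))
    keep <- !duplicated(ridx * 1e4 + ptidx)  # one row per (report, PT)
    reactions <- reactions[keep, ]
    reactions <- reactions[order(ridx[keep]), ]

    indications <- tibble::tibble(report_id = report_id, version = 1L,
                                  indication_text = ind)

    # version-2 near-duplicates (one perturbed demographic field)
    dup <- which(stats::runif(n) < config$duplicate_prob)
    if (length(dup)) {
      d2 <- reports[dup, ]
      d2$version <- 2L
      flip <- sample(c("sex", "age_group", "weight_band"), length(dup),
                     replace = TRUE)
      for (f in unique(flip)) {
        rows <- which(flip == f)
        d2[[f]][rows] <- "UNK"
      }
      reports <- rbind(reports, d2)
      bump <- function(df) {
        extra <- df[df$report_id %in% report_id[dup], ]
        extra$version <- 2L
        rbind(df, extra)
      }
      drugs_tbl <- bump(drugs_tbl)
      reactions <- bump(reactions)
      indications <- bump(indications)
    }

    out <- report_set(config$database, reports, drugs_tbl, reactions,
                      indications)
    attr(out, "n_cases") <- n
    out
  })
}

#' Closed-form population odds ratio implied by a configuration
#'
#' Enumerates all exposure patterns of the configured study drugs exactly
#' (chain-rule probabilities of the sequential co-prescription draw),
#' computes each pattern's event probability under the logistic-odds model,
#' and marginalizes to the population reporting odds ratio contrasting
#' reports with vs without the drug. With no co-prescription tilting and
#' all other drugs neutral this equals the configured multiplier exactly;
#' with correlated exposures to other effective drugs it quantifies the
#' confounding by co-exposure that a disproportionality analysis actually
#' estimates.
#'
#' @param config A [synthetic_config()].
#' @param drug,endpoint Names of the pair.
#' @return Positive scalar odds ratio.
#' @export
true_odds_ratio <- function(config, drug, endpoint) {
  stopifnot(inherits(config, "synthetic_config"))
  drugs <- names(config$drug_marginals)
  stopifnot(drug %in% drugs, endpoint %in% names(config$baseline_event_probs))
  K <- length(drugs)
  patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), K)))
  colnames(patterns) <- drugs

  pat_prob <- apply(patterns, 1, function(x) {
    p <- 1
    for (k in seq_len(K)) {
      base <- config$drug_marginals[k]
      odds <- base / (1 - base)
      co <- config$coprescription_odds
      for (j in which(co$drug2 == drugs[k])) {
        prev <- co$drug1[j]
        if (prev %in% drugs[seq_len(k - 1)] && x[prev]) odds <- odds * co$odds[j]
      }
      pk <- odds / (1 + odds)
      p <- p * if (x[k]) pk else 1 - pk
    }
    p
  })
  base <- config$baseline_event_probs[endpoint]
  p_event <- stats::plogis(
    stats::qlogis(base) +
      patterns %*% log(config$effect_matrix[drugs, endpoint]))
  on <- patterns[, drug]
  odds_of <- function(sel) {
    pe <- sum(pat_prob[sel] * p_event[sel]) / sum(pat_prob[sel])
    pe / (1 - pe)
  }
  unname(odds_of(on) / odds_of(!on))
}
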