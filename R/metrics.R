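#' 2x2 contingency table of report counts
#'
#' Cells follow the standard disproportionality layout: `a` target drug +
#' target event, `b` target drug + other events, `c` other drugs + target
#' event, `d` other drugs + other events. All cells are counts of distinct
#' deduplicated reports; `N = a + b + c + d` must be positive.
#'
#' @param a,b,c,d Nonnegative integer report counts.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
             d = as.numeric(d))
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("contingency cells must be nonnegative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("contingency table is empty (N = 0)", call. = FALSE)
  structure(as.list(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<2x2 table: a=%g b=%g c=%g d=%g (N=%g)>\n",
              x$a, x$b, x$c, x$d, x$a + x$b + x$c + x$d))
  invisible(x)
}

#' Build the drug-event 2x2 table within a cohort
#'
#' Exposure and endpoint flags are crossed over the cohort's deduplicated
#' reports; cells always sum to the cohort size, so the comparator ("other
#' drugs") is the rest of the cohort, not the full database background.
#'
#' @param cohort A deduplicated [report_set()] restricted to the analysis
#'   cohort.
#' @param exp An [exposure_definition()].
#' @param endpoint An [endpoint_definition()].
#' @return A [contingency_table()].
#' @export
build_contingency <- function(cohort, exp, endpoint) {
  if (n_reports(cohort) == 0) stop("empty cohort", call. = FALSE)
  ex <- is_exposed(cohort, exp)
  ev <- has_endpoint(cohort, endpoint)
  contingency_table(sum(ex & ev), sum(ex & !ev), sum(!ex & ev), sum(!ex & !ev))
}

#' Build the regimen-stratified 2x2 table
#'
#' Within the bevacizumab-exposed reports, cells `a`/`b` come from the focal
#' regimen and `c`/`d` from all other bevacizumab-containing regimens
#' (including triple combinations labelled `BEV_OTHER_COMBO`). Bevacizumab
#' monotherapy serves as the reference regimen for presentation only; the
#' cells are computed identically for every focal group.
#'
#' @param bev_reports A deduplicated [report_set()] containing only
#'   bevacizumab-exposed reports.
#' @param focal Focal regimen label: `"BEV_MONO"`, `"BEV_TMZ"`, `"BEV_LOM"`
#'   or `"BEV_OTHER_COMBO"`.
#' @param endpoint An [endpoint_definition()].
#' @return A [contingency_table()].
#' @export
build_regimen_contingency <- function(bev_reports, focal, endpoint) {
  focal <- match.arg(focal, setdiff(regimen_levels, "NOT_BEV"))
  lab <- assign_regimen(bev_reports)
  if (any(lab == "NOT_BEV")) {
    stop("bev_reports must contain only bevacizumab-exposed reports", call. = FALSE)
  }
  ev <- has_endpoint(bev_reports, endpoint)
  f <- lab == focal
  contingency_table(sum(f & ev), sum(f & !ev), sum(!f & ev), sum(!f & !ev))
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' `ROR = (a/c) / (b/d) = ad / bc`, with the log-normal (Woolf) interval
#' `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is zero
#' the Haldane-Anscombe correction adds 0.5 to all four cells first and the
#' result is flagged `corrected`.
#'
#' @param t A [contingency_table()].
#' @param level Confidence level (default 0.95).
#' @return List with `ror`, `low`, `high`, `corrected`.
#' @export
ror_with_ci <- function(t, level = 0.95) {
  stopifnot(inherits(t, "contingency_table"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  cells <- c(t$a, t$b, t$c, t$d)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  ror <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  list(ror = ror, low = ror * exp(-z * se), high = ror * exp(z * se),
       corrected = corrected)
}

#' Proportional reporting ratio with confidence interval and chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`, with the log-normal interval
#' `exp(ln PRR +/- 1.96 * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`. The
#' chi-square is the Pearson statistic on the *uncorrected* cells,
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, without continuity correction;
#' zero cells are Haldane-corrected for the PRR and its interval only.
#'
#' @param t A [contingency_table()].
#' @param level Confidence level (default 0.95).
#' @return List with `prr`, `low`, `high`, `chi2`, `corrected`.
#' @export
prr_with_chi2 <- function(t, level = 0.95) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$a + t$b == 0 || t$c + t$d == 0) {
    stop("undefined proportion: an exposure margin is zero", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  cells <- c(t$a, t$b, t$c, t$d)
  chi2 <- pearson_chi2(t$a, t$b, t$c, t$d)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  prr <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  list(prr = prr, low = prr * exp(-z * se), high = prr * exp(z * se),
       chi2 = chi2, corrected = corrected)
}

# Pearson chi-square without continuity correction; 0 when a margin is empty.
pearson_chi2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  out <- N * (a * d - b * c)^2 / den
  out[den == 0] <- 0
  out
}

# Yates continuity-corrected variant (used by the recovery oracle, which
# accepts either convention when inverting published rows).
yates_chi2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  u <- pmax(abs(a * d - b * c) - N / 2, 0)
  out <- N * u^2 / den
  out[den == 0] <- 0
  out
}

#' Information component with credibility lower bound
#'
#' The Bayesian confidence propagation information component in its shrunk
#' observed/expected form: with `E = (a+b)(a+c)/N`,
#' `IC = log2((a + 0.5) / (E + 0.5))` and the closed-form 95% credibility
#' lower bound `IC025 = IC - 3.3 (a+0.5)^(-1/2) - 2 (a+0.5)^(-3/2)`.
#'
#' @param t A [contingency_table()].
#' @return List with `ic`, `ic025`, `expected`.
#' @export
bcpnn_ic <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  N <- t$a + t$b + t$c + t$d
  E <- (t$a + t$b) * (t$a + t$c) / N
  ic <- log2((t$a + 0.5) / (E + 0.5))
  ic025 <- ic - 3.3 * (t$a + 0.5)^(-0.5) - 2 * (t$a + 0.5)^(-1.5)
  list(ic = ic, ic025 = ic025, expected = E)
}

#' Positive-signal rule
#'
#' A drug-event pair is a positive signal when it has at least 3 target
#' reports and the lower bound of the 95% confidence interval of the ROR
#' exceeds 1.
#'
#' @param a Number of target drug + target event reports.
#' @param ror_low Lower bound of the 95% CI of the ROR.
#' @return Logical.
#' @export
classify_signal <- function(a, ror_low) {
  a >= 3 & ror_low > 1
}

#' Full disproportionality analysis of one drug-event pair
#'
#' Assembles the 2x2 table and all four metrics (ROR/CI, PRR/CI/chi-square,
#' IC/IC025, EBGM/EB05) plus the signal flag into a one-row tibble. Pairs
#' with `a < 3` are flagged `analyzable = FALSE` and never signal; their
#' statistics are still reported for transparency, mirroring how sparse
#' rows are displayed (but not interpreted) in published signal tables.
#'
#' @param cohort A deduplicated [report_set()] (the analysis cohort).
#' @param exp An [exposure_definition()].
#' @param endpoint An [endpoint_definition()].
#' @param prior Optional [gamma_mixture_prior()]; when supplied, EBGM/EB05
#'   are computed under it, otherwise they are `NA`.
#' @param label Label used for the `drug_or_regimen` column (defaults to
#'   the exposure's drug names).
#' @return One-row tibble (see [write_results_csv()] for the column
#'   contract).
#' @export
analyze_pair <- function(cohort, exp, endpoint, prior = NULL, label = NULL) {
  t <- build_contingency(cohort, exp, endpoint)
  if (is.null(label)) label <- paste(exp$generic_names, collapse = "+")
  analyze_table(t, database = cohort$database, label = label,
                event = endpoint$name, prior = prior)
}

# Shared row assembly for main, regimen and sensitivity analyses. A drug
# absent from the cohort leaves the PRR margin undefined; such rows carry
# NA proportions instead of aborting the whole analysis.
analyze_table <- function(t, database, label, event, prior = NULL) {
  ror <- ror_with_ci(t)
  if (t$a + t$b == 0 || t$c + t$d == 0) {
    prr <- list(prr = NA_real_, low = NA_real_, high = NA_real_,
                chi2 = NA_real_)
  } else {
    prr <- prr_with_chi2(t)
  }
  ic <- bcpnn_ic(t)
  if (!is.null(prior)) {
    eb <- ebgm_eb05(t$a, ic$expected, prior)
  } else {
    eb <- list(ebgm = NA_real_, eb05 = NA_real_)
  }
  analyzable <- t$a >= 3
  # pull components out first: tibble() would resolve `ror$low` against the
  # freshly created `ror` column, not the list
  ror_v <- ror$ror; ror_lo <- ror$low; ror_hi <- ror$high
  prr_v <- prr$prr; prr_lo <- prr$low; prr_hi <- prr$high
  chi2_v <- prr$chi2; corrected <- ror$corrected
  ic_v <- ic$ic; ic025_v <- ic$ic025; expected_v <- ic$expected
  ebgm_v <- eb$ebgm; eb05_v <- eb$eb05
  tibble::tibble(
    database = database, drug_or_regimen = label, event = event,
    a = t$a, b = t$b, c = t$c, d = t$d,
    ror = ror_v, ror_low = ror_lo, ror_high = ror_hi,
    signal = analyzable && classify_signal(t$a, ror_lo),
    prr = prr_v, prr_low = prr_lo, prr_high = prr_hi, chi2 = chi2_v,
    ic = ic_v, ic025 = ic025_v, expected = expected_v,
    ebgm = ebgm_v, eb05 = eb05_v,
    analyzable = analyzable,
    zero_cell_corrected = corrected
  )
}
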