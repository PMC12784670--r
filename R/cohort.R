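#' Cohort definition by free-text term matching
#'
#' A cohort definition is a named list of uppercase search terms matched
#' case-insensitively as contiguous substrings of the report's indication
#' and/or history text. Substring (not word-boundary) semantics are
#' intentional: "ASTROCYTOMA" should match "ANAPLASTIC ASTROCYTOMA"; the
#' shipped term lists are closed under this so no over-capture arises
#' within them.
#'
#' @param name Label for the definition (e.g. `"broad"`, `"strict"`).
#' @param terms Nonempty character vector of search terms.
#' @param match_fields Which free-text fields to search; any subset of
#'   `"indications"` and `"history_text"`.
#' @return An object of class `cohort_definition`.
#' @export
cohort_definition <- function(name, terms,
                              match_fields = c("indications", "history_text")) {
  terms <- toupper(trimws(as.character(terms)))
  terms <- terms[nzchar(terms)]
  if (!length(terms)) stop("cohort definition needs at least one term", call. = FALSE)
  match_fields <- match.arg(match_fields, several.ok = TRUE)
  structure(list(name = name, terms = unique(terms), match_fields = match_fields),
            class = "cohort_definition")
}

#' Match reports against a cohort definition
#'
#' A report matches if any definition term occurs as a contiguous substring
#' of the uppercased concatenation of its selected free-text fields (all
#' indication texts, and/or the history text). Empty fields never match.
#'
#' @param set A [report_set()].
#' @param def A [cohort_definition()].
#' @return Logical vector, one element per row of `set$reports`.
#' @export
match_cohort <- function(set, def) {
  stopifnot(inherits(set, "report_set"), inherits(def, "cohort_definition"))
  rep <- set$reports
  uni <- unique(rep$report_id)
  rkey <- pair_key(rep$report_id, rep$version, uni)
  match_any <- function(text) {
    text <- toupper(text)
    hit <- rep_len(FALSE, length(text))
    for (term in def$terms) hit <- hit | grepl(term, text, fixed = TRUE)
    hit
  }
  out <- rep_len(FALSE, nrow(rep))
  if ("indications" %in% def$match_fields && nrow(set$indications)) {
    ind <- set$indications
    hit <- match_any(ind$indication_text)
    out <- out | rkey %in% pair_key(ind$report_id[hit], ind$version[hit], uni)
  }
  if ("history_text" %in% def$match_fields) {
    out <- out | match_any(rep$history_text)
  }
  out
}

#' Restrict a report set to a cohort
#'
#' @inheritParams match_cohort
#' @return A [report_set()] containing the matching reports only.
#' @export
subset_cohort <- function(set, def) {
  filter_reports(set, match_cohort(set, def))
}

#' Normalize verbatim drug names to generic tokens
#'
#' Uppercases and trims the verbatim name, then replaces exact brand-token
#' hits using the brand-to-generic map; unknown names are returned in their
#' normalized verbatim form.
#'
#' @param verbatim Character vector of verbatim drug names.
#' @param brand_map Named character vector, brand token to generic token
#'   (see [default_brand_map()]).
#' @return Character vector of generic tokens.
#' @export
normalize_drug_name <- function(verbatim, brand_map = default_brand_map()) {
  x <- toupper(trimws(as.character(verbatim)))
  hit <- x %in% names(brand_map)
  x[hit] <- unname(brand_map[x[hit]])
  x
}

#' Exposure definition
#'
#' Marks a report "exposed" if any of its drug entries carries one of the
#' target generic names, either in any role (`ANY`: primary suspect,
#' secondary suspect or concomitant -- the main-analysis definition, chosen
#' because role coding is heterogeneous in oncology reports) or restricted
#' to primary-suspect entries (`PS_ONLY`, the sensitivity definition).
#'
#' @param generic_names Nonempty character vector of normalized generic names.
#' @param role_filter `"ANY"` or `"PS_ONLY"`.
#' @return An object of class `exposure_definition`.
#' @export
exposure_definition <- function(generic_names, role_filter = c("ANY", "PS_ONLY")) {
  generic_names <- toupper(trimws(as.character(generic_names)))
  generic_names <- generic_names[nzchar(generic_names)]
  if (!length(generic_names)) stop("exposure definition needs at least one drug", call. = FALSE)
  structure(list(generic_names = unique(generic_names),
                 role_filter = match.arg(role_filter)),
            class = "exposure_definition")
}

#' Classify reports as exposed or unexposed
#'
#' @param set A [report_set()].
#' @param exp An [exposure_definition()].
#' @return Logical vector, one element per row of `set$reports`.
#' @export
is_exposed <- function(set, exp) {
  stopifnot(inherits(set, "report_set"), inherits(exp, "exposure_definition"))
  drg <- set$drugs
  hit <- drg$generic_name %in% exp$generic_names
  if (exp$role_filter == "PS_ONLY") hit <- hit & drg$role == "PS"
  uni <- unique(set$reports$report_id)
  keys <- pair_key(drg$report_id[hit], drg$version[hit], uni)
  pair_key(set$reports$report_id, set$reports$version, uni) %in% keys
}

regimen_levels <- c("BEV_MONO", "BEV_TMZ", "BEV_LOM", "BEV_OTHER_COMBO", "NOT_BEV")

#' Assign bevacizumab regimen labels
#'
#' Partitions reports by co-reported chemotherapy into mutually exclusive
#' bevacizumab regimen groups, using any-role exposure: `NOT_BEV` (no
#' bevacizumab), `BEV_MONO` (bevacizumab without temozolomide or lomustine),
#' `BEV_TMZ` (bevacizumab + temozolomide, no lomustine), `BEV_LOM`
#' (bevacizumab + lomustine, no temozolomide), and `BEV_OTHER_COMBO`
#' (bevacizumab with both temozolomide and lomustine -- triple combinations
#' belong to no focal group and only ever contribute to the
#' "other bevacizumab-containing regimens" comparator cells).
#'
#' @param set A [report_set()] with normalized generic drug names.
#' @return Character vector of regimen labels, one per row of `set$reports`.
#' @export
assign_regimen <- function(set) {
  stopifnot(inherits(set, "report_set"))
  has <- function(drug) is_exposed(set, exposure_definition(drug, "ANY"))
  bev <- has("BEVACIZUMAB"); tmz <- has("TEMOZOLOMIDE"); lom <- has("LOMUSTINE")
  out <- rep("NOT_BEV", nrow(set$reports))
  out[bev & !tmz & !lom] <- "BEV_MONO"
  out[bev & tmz & !lom] <- "BEV_TMZ"
  out[bev & !tmz & lom] <- "BEV_LOM"
  out[bev & tmz & lom] <- "BEV_OTHER_COMBO"
  out
}
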