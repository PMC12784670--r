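#' Construct a set of individual case safety reports
#'
#' A `report_set` is the package's in-memory representation of a spontaneous
#' reporting database extract: a relational bundle of one-row-per-entity
#' tables keyed by `(report_id, version)`. It deliberately mirrors how
#' spontaneous reporting systems deliver data (a demographic table plus
#' drug, reaction and indication detail tables) rather than nesting
#' everything into one object, so that all downstream operations can be
#' vectorized joins.
#'
#' @param database Database code, `"FAERS"` or `"CVARD"`.
#' @param reports Data frame with columns `report_id`, `version`, `sex`
#'   (`M`/`F`/`UNK`), `age_group` (`12-17`/`18-64`/`65-85`/`UNK`),
#'   `weight_band` (`LT50`/`50TO100`/`GT100`/`UNK`), `reporter`
#'   (`HCP`/`NONHCP`/`UNK`), `serious` (`YES`/`NO`/`UNK`), `history_text`.
#' @param drugs Data frame with columns `report_id`, `version`, `drug_seq`,
#'   `verbatim_name`, `generic_name`, `role` (`PS`/`SS`/`C`).
#' @param reactions Data frame with columns `report_id`, `version`, `pt`
#'   (MedDRA preferred term).
#' @param indications Data frame with columns `report_id`, `version`,
#'   `indication_text`.
#'
#' @return An object of class `report_set`.
#' @export
report_set <- function(database, reports,
                       drugs = empty_drugs(),
                       reactions = empty_reactions(),
                       indications = empty_indications()) {
  database <- match.arg(toupper(database), c("FAERS", "CVARD"))
  reports <- tibble::as_tibble(reports)
  drugs <- tibble::as_tibble(drugs)
  reactions <- tibble::as_tibble(reactions)
  indications <- tibble::as_tibble(indications)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s table is missing required column(s): %s",
                   what, paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(reports, c("report_id", "version", "sex", "age_group", "weight_band",
                  "reporter", "serious", "history_text"), "reports")
  need(drugs, c("report_id", "version", "drug_seq", "verbatim_name",
                "generic_name", "role"), "drugs")
  need(reactions, c("report_id", "version", "pt"), "reactions")
  need(indications, c("report_id", "version", "indication_text"), "indications")

  reports$report_id <- as.character(reports$report_id)
  reports$version <- as.integer(reports$version)
  if (nrow(reports)) {
    if (any(is.na(reports$report_id) | !nzchar(reports$report_id))) {
      stop("report_id must be nonempty", call. = FALSE)
    }
    if (any(is.na(reports$version) | reports$version < 1L)) {
      stop("version must be a positive integer", call. = FALSE)
    }
    for (col in c("sex", "age_group", "weight_band", "reporter", "serious")) {
      reports[[col]] <- norm_category(reports[[col]], category_levels(col))
    }
    reports$history_text <- ifelse(is.na(reports$history_text), "",
                                   as.character(reports$history_text))
  }
  if (nrow(drugs)) {
    drugs$report_id <- as.character(drugs$report_id)
    drugs$version <- as.integer(drugs$version)
    drugs$drug_seq <- as.integer(drugs$drug_seq)
    if (any(is.na(drugs$verbatim_name) | !nzchar(trimws(drugs$verbatim_name)))) {
      stop("drug verbatim_name must be nonempty", call. = FALSE)
    }
    drugs$role <- norm_category(drugs$role, c("PS", "SS", "C"), default = "C")
    key <- pair_key(drugs$report_id, drugs$version * 10000 + drugs$drug_seq)
    if (anyDuplicated(key)) {
      stop("duplicate (report_id, version, drug_seq) in drugs table", call. = FALSE)
    }
  }
  if (nrow(reactions)) {
    reactions$report_id <- as.character(reactions$report_id)
    reactions$version <- as.integer(reactions$version)
    reactions$pt <- toupper(trimws(as.character(reactions$pt)))
    if (any(!nzchar(reactions$pt))) {
      stop("reaction preferred terms must be nonempty", call. = FALSE)
    }
  }
  if (nrow(indications)) {
    indications$report_id <- as.character(indications$report_id)
    indications$version <- as.integer(indications$version)
    indications$indication_text <- as.character(indications$indication_text)
  }

  structure(
    list(database = database, reports = reports, drugs = drugs,
         reactions = reactions, indications = indications),
    class = "report_set"
  )
}

empty_reports <- function() {
  tibble::tibble(report_id = character(), version = integer(),
                 sex = character(), age_group = character(),
                 weight_band = character(), reporter = character(),
                 serious = character(), history_text = character())
}

empty_drugs <- function() {
  tibble::tibble(report_id = character(), version = integer(),
                 drug_seq = integer(), verbatim_name = character(),
                 generic_name = character(), role = character())
}

empty_reactions <- function() {
  tibble::tibble(report_id = character(), version = integer(), pt = character())
}

empty_indications <- function() {
  tibble::tibble(report_id = character(), version = integer(),
                 indication_text = character())
}

category_levels <- function(field) {
  switch(field,
    sex = c("M", "F", "UNK"),
    age_group = c("12-17", "18-64", "65-85", "UNK"),
    weight_band = c("LT50", "50TO100", "GT100", "UNK"),
    reporter = c("HCP", "NONHCP", "UNK"),
    serious = c("YES", "NO", "UNK"),
    stop("unknown categorical field: ", field)
  )
}

# Numeric key for (report_id, version) pairs -- avoids string pasting in
# the hot joins. `universe` fixes the id hashing; versions are assumed
# < 10^7 (spontaneous reporting case versions are single digits).
pair_key <- function(ids, vers, universe = ids) {
  match(ids, universe) * 1e7 + as.numeric(vers)
}

# Out-of-band category codes map to UNK (unless a different default fits,
# e.g. unknown drug roles map to concomitant).
norm_category <- function(x, levels, default = "UNK") {
  x <- as.character(x)
  # fast path: entries already equal to a (canonical, uppercase) level are
  # left untouched; only deviants pay for trimming and case folding
  bad <- is.na(x) | !(x %in% levels)
  if (any(bad)) {
    y <- toupper(trimws(x[bad]))
    y[is.na(y) | !(y %in% levels)] <- default
    x[bad] <- y
  }
  x
}

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf("<report_set: %s, %d report rows (%d unique ids), %d drug rows, %d reactions, %d indications>\n",
              x$database, nrow(x$reports), length(unique(x$reports$report_id)),
              nrow(x$drugs), nrow(x$reactions), nrow(x$indications)))
  invisible(x)
}

#' Number of report rows in a report set
#'
#' @param set A [report_set()].
#' @return Integer count of rows in the demographic table (pre-deduplication
#'   sets count every version).
#' @export
n_reports <- function(set) {
  stopifnot(inherits(set, "report_set"))
  nrow(set$reports)
}

#' Keep only the latest version of every case
#'
#' Spontaneous reports are submitted in successive versions as follow-up
#' information arrives; analyses must count each case once, so for every
#' `(database, report_id)` only the report with the maximal `version` is
#' retained, along with its drug, reaction and indication rows. The relative
#' order of surviving reports is preserved and the operation is idempotent.
#' Ties on `(report_id, version)` keep the last-read record and emit a
#' warning.
#'
#' @param set A [report_set()].
#' @return A deduplicated [report_set()] with unique `report_id`s.
#' @export
deduplicate <- function(set) {
  stopifnot(inherits(set, "report_set"))
  rep <- set$reports
  if (!nrow(rep)) return(set)

  n <- nrow(rep)
  o <- order(rep$report_id, rep$version, seq_len(n))  # read order breaks ties
  ids_s <- rep$report_id[o]
  vs <- rep$version[o]
  if (n > 1) {
    tie <- ids_s[-1] == ids_s[-n] & vs[-1] == vs[-n]
    if (any(tie)) {
      warning(sprintf("tied versions for %d case id(s) (e.g. %s); keeping the last-read record",
                      length(unique(ids_s[-1][tie])), ids_s[-1][tie][1]),
              call. = FALSE)
    }
  }
  keep_idx <- sort(o[!duplicated(ids_s, fromLast = TRUE)])
  rep <- rep[keep_idx, , drop = FALSE]

  keep_detail <- function(df) {
    if (!nrow(df)) return(df)
    m <- match(df$report_id, rep$report_id)
    ok <- !is.na(m) & df$version == rep$version[m]
    df[ok, , drop = FALSE]
  }
  out <- set
  out$reports <- rep
  out$drugs <- keep_detail(set$drugs)
  out$reactions <- keep_detail(set$reactions)
  out$indications <- keep_detail(set$indications)
  out
}

# Restrict a report_set to a logical mask (or ids) over its report rows,
# carrying the detail tables along. Used by cohort construction and the
# pipeline; assumes `set` is deduplicated if `mask` is id-based.
filter_reports <- function(set, mask) {
  stopifnot(inherits(set, "report_set"))
  rep <- set$reports[mask, , drop = FALSE]
  uni <- unique(set$reports$report_id)
  kept <- pair_key(rep$report_id, rep$version, uni)
  keep_detail <- function(df) {
    if (!nrow(df)) return(df)
    df[pair_key(df$report_id, df$version, uni) %in% kept, , drop = FALSE]
  }
  out <- set
  out$reports <- rep
  out$drugs <- keep_detail(set$drugs)
  out$reactions <- keep_detail(set$reactions)
  out$indications <- keep_detail(set$indications)
  out
}
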