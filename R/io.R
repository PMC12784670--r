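#' Read a report set from the normalized TSV schema
#'
#' The normalized schema stores one entity per row across four UTF-8
#' tab-separated files with header rows: a reports table
#' (`database, report_id, version, sex, age_group, weight_band, reporter,
#' serious, history_text`), a drugs table
#' (`report_id, version, drug_seq, verbatim_name, generic_name, role`),
#' a reactions table (`report_id, version, pt`) and an indications table
#' (`report_id, version, indication_text`). Detail rows are joined to the
#' reports on `(report_id, version)`; unknown category codes map to `UNK`.
#' The returned set is *not* deduplicated (see [deduplicate()]).
#'
#' @param reports_path,drugs_path,reactions_path,indications_path File paths.
#' @return A [report_set()].
#' @export
read_normalized <- function(reports_path, drugs_path, reactions_path,
                            indications_path) {
  rd <- function(path) {
    utils::read.delim(path, sep = "\t", colClasses = "character",
                      na.strings = NULL, quote = "", check.names = TRUE)
  }
  rep <- rd(reports_path)
  if (!"database" %in% names(rep)) {
    stop("reports table is missing required column(s): database", call. = FALSE)
  }
  database <- unique(toupper(rep$database))
  if (length(database) != 1L) {
    stop("reports file must contain exactly one database code", call. = FALSE)
  }
  drg <- rd(drugs_path)
  if (nrow(drg)) {
    if (!"generic_name" %in% names(drg)) {
      stop("drugs table is missing required column(s): generic_name", call. = FALSE)
    }
    drg$generic_name <- toupper(trimws(drg$generic_name))
    blank <- !nzchar(drg$generic_name)
    drg$generic_name[blank] <- toupper(trimws(drg$verbatim_name[blank]))
  }
  report_set(database,
             rep[setdiff(names(rep), "database")],
             drg, rd(reactions_path), rd(indications_path))
}

#' Write a report set in the normalized TSV schema
#'
#' @param set A [report_set()].
#' @param dir Output directory; files `reports.tsv`, `drugs.tsv`,
#'   `reactions.tsv`, `indications.tsv` are (over)written there.
#' @return Invisibly, the four file paths.
#' @export
write_normalized <- function(set, dir) {
  stopifnot(inherits(set, "report_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    path
  }
  rep <- cbind(database = set$database, set$reports)
  invisible(c(wr(rep, "reports.tsv"), wr(set$drugs, "drugs.tsv"),
              wr(set$reactions, "reactions.tsv"),
              wr(set$indications, "indications.tsv")))
}

# ---- FAERS quarterly ASCII dialect --------------------------------------

faers_role_map <- c(PS = "PS", SS = "SS", C = "C", I = "C")
hcp_occupations <- c("MD", "PH", "OT", "HP")

bin_age <- function(age) {
  age <- suppressWarnings(as.numeric(age))
  out <- rep("UNK", length(age))
  out[!is.na(age) & age >= 12 & age < 18] <- "12-17"
  out[!is.na(age) & age >= 18 & age < 65] <- "18-64"
  out[!is.na(age) & age >= 65 & age <= 85] <- "65-85"
  # ages outside the tabulated bands (<12 or >85) carry no band and are UNK
  out
}

bin_weight <- function(wt) {
  wt <- suppressWarnings(as.numeric(wt))
  out <- rep("UNK", length(wt))
  out[!is.na(wt) & wt > 0 & wt < 50] <- "LT50"
  out[!is.na(wt) & wt >= 50 & wt <= 100] <- "50TO100"
  out[!is.na(wt) & wt > 100] <- "GT100"
  out
}

map_reporter <- function(occp) {
  occp <- toupper(trimws(occp))
  out <- ifelse(occp %in% hcp_occupations, "HCP",
                ifelse(nzchar(occp), "NONHCP", "UNK"))
  out[is.na(occp)] <- "UNK"
  out
}

read_dollar <- function(path, required) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop(sprintf("%s: empty file", basename(path)), call. = FALSE)
  header <- strsplit(lines[1], "$", fixed = TRUE)[[1]]
  nf <- length(header)
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "$", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != nf &
                 vapply(parts, length, 1L) != nf - 1L)
  if (length(bad)) {
    stop(sprintf("%s: cannot delimit line %d into %d fields",
                 basename(path), bad[1] + 1L, nf), call. = FALSE)
  }
  # a trailing empty field is dropped by strsplit; pad it back
  parts <- lapply(parts, function(p) c(p, rep("", nf - length(p))))
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  if (!nrow(df)) df <- as.data.frame(matrix(character(), 0, nf))
  names(df) <- header
  miss <- setdiff(required, header)
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 basename(path), paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read FAERS-quarterly-style "$"-delimited files
#'
#' Parses the minimal DEMO/DRUG/REAC/INDI dialect of the FAERS quarterly
#' ASCII distribution: `$`-delimited files with one header row. DEMO carries
#' `caseid`, `caseversion`, `sex`, `age` (years), `wt` (kg) and `occp_cod`;
#' DRUG carries `caseid`, `drugname`, `prod_ai`, `role_cod`; REAC carries
#' `caseid`, `pt`; INDI carries `caseid`, `indi_pt`. Ages and weights are
#' binned into the report-set category bands, occupation codes
#' `MD`/`PH`/`OT`/`HP` map to `HCP`, and drug role codes other than
#' `PS`/`SS`/`C` (e.g. `I`, interacting) map to concomitant `C`. Fields the
#' dialect does not carry (seriousness, history text) are `UNK`/empty.
#'
#' @param demo_path,drug_path,reac_path,indi_path File paths.
#' @param database Database code recorded on the returned set.
#' @return A [report_set()] (pre-deduplication).
#' @export
read_faers_ascii <- function(demo_path, drug_path, reac_path, indi_path,
                             database = "FAERS") {
  demo <- read_dollar(demo_path, c("caseid", "caseversion", "sex", "age",
                                   "wt", "occp_cod"))
  drug <- read_dollar(drug_path, c("caseid", "caseversion", "drugname",
                                   "prod_ai", "role_cod"))
  reac <- read_dollar(reac_path, c("caseid", "caseversion", "pt"))
  indi <- read_dollar(indi_path, c("caseid", "caseversion", "indi_pt"))

  reports <- tibble::tibble(
    report_id = demo$caseid,
    version = as.integer(demo$caseversion),
    sex = norm_category(demo$sex, c("M", "F", "UNK")),
    age_group = bin_age(demo$age),
    weight_band = bin_weight(demo$wt),
    reporter = map_reporter(demo$occp_cod),
    serious = "UNK",
    history_text = ""
  )
  role <- toupper(trimws(drug$role_cod))
  drugs <- tibble::tibble(
    report_id = drug$caseid,
    version = as.integer(drug$caseversion),
    drug_seq = stats::ave(seq_len(nrow(drug)),
                          paste(drug$caseid, drug$caseversion),
                          FUN = seq_along),
    verbatim_name = drug$drugname,
    generic_name = toupper(trimws(drug$prod_ai)),
    role = ifelse(role %in% names(faers_role_map),
                  unname(faers_role_map[role]), "C")
  )
  if (nrow(drugs)) {
    blank <- !nzchar(drugs$generic_name)
    drugs$generic_name[blank] <- toupper(trimws(drugs$verbatim_name[blank]))
  }
  reactions <- tibble::tibble(report_id = reac$caseid,
                              version = as.integer(reac$caseversion),
                              pt = reac$pt)
  indications <- tibble::tibble(report_id = indi$caseid,
                                version = as.integer(indi$caseversion),
                                indication_text = indi$indi_pt)
  report_set(database, reports, drugs, reactions, indications)
}

#' Write a report set as FAERS-quarterly-style "$"-delimited files
#'
#' Emits `DEMO.txt`, `DRUG.txt`, `REAC.txt` and `INDI.txt` readable by
#' [read_faers_ascii()]. Category bands are serialized as representative
#' numeric values (band midpoints) so that the round trip through the
#' dialect reproduces the in-band fields exactly; seriousness and history
#' text are not part of this dialect and are dropped.
#'
#' @param set A [report_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the four file paths.
#' @export
write_faers_ascii <- function(set, dir) {
  stopifnot(inherits(set, "report_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rep <- set$reports
  age_out <- c("12-17" = "15", "18-64" = "40", "65-85" = "70", UNK = "")
  wt_out <- c(LT50 = "45", `50TO100` = "75", GT100 = "110", UNK = "")
  occ_out <- c(HCP = "MD", NONHCP = "CN", UNK = "")
  demo <- data.frame(
    caseid = rep$report_id, caseversion = rep$version,
    sex = ifelse(rep$sex == "UNK", "", rep$sex),
    age = unname(age_out[rep$age_group]),
    wt = unname(wt_out[rep$weight_band]),
    occp_cod = unname(occ_out[rep$reporter]),
    stringsAsFactors = FALSE
  )
  drug <- data.frame(
    caseid = set$drugs$report_id, caseversion = set$drugs$version,
    drugname = set$drugs$verbatim_name, prod_ai = set$drugs$generic_name,
    role_cod = set$drugs$role, stringsAsFactors = FALSE
  )
  reac <- data.frame(caseid = set$reactions$report_id,
                     caseversion = set$reactions$version,
                     pt = set$reactions$pt, stringsAsFactors = FALSE)
  indi <- data.frame(caseid = set$indications$report_id,
                     caseversion = set$indications$version,
                     indi_pt = set$indications$indication_text,
                     stringsAsFactors = FALSE)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    lines <- c(paste(names(df), collapse = "$"),
               if (nrow(df)) do.call(paste, c(lapply(df, as.character), sep = "$")))
    writeLines(lines, path, useBytes = TRUE)
    path
  }
  invisible(c(wr(demo, "DEMO.txt"), wr(drug, "DRUG.txt"),
              wr(reac, "REAC.txt"), wr(indi, "INDI.txt")))
}
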