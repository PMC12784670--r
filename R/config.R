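# Plain-text block config: "[name]" headers, one entry per line, "#"
# comments. This is the on-disk form of the cohort term lists and the
# endpoint PT lists so that both stay editable data, not code.
read_block_config <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  heads <- grepl("^\\[.+\\]$", lines)
  if (!any(heads)) stop("config file has no [block] headers: ", path, call. = FALSE)
  block <- cumsum(heads)
  names <- sub("^\\[(.+)\\]$", "\\1", lines[heads])
  out <- lapply(split(lines[!heads], block[!heads]), toupper)
  stats::setNames(out, names)
}

pv_extdata <- function(name) {
  path <- system.file("extdata", name, package = "pvsignal")
  if (!nzchar(path)) stop("missing installed data file: ", name, call. = FALSE)
  path
}

#' Shipped brand-to-generic drug name map
#'
#' A minimal editable map covering the brand names of the four glioma study
#' drugs (e.g. Avastin, Temodar/Temodal, Gleostine/CeeNU, BiCNU/Gliadel).
#'
#' @param path Optional path to a two-column TSV (`brand`, `generic`);
#'   defaults to the map shipped with the package.
#' @return Named character vector mapping uppercase brand tokens to
#'   uppercase generic tokens.
#' @export
default_brand_map <- function(path = pv_extdata("brand_map.tsv")) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character")
  stats::setNames(toupper(trimws(df$generic)), toupper(trimws(df$brand)))
}

#' Shipped glioma cohort definitions
#'
#' `glioma_broad()` is the sensitive free-text case definition (glioma,
#' malignant glioma, glioblastoma (multiforme), (anaplastic) astrocytoma,
#' (anaplastic) oligodendroglioma); `glioma_strict()` restricts to the
#' higher-certainty malignant terms and its term set is a subset of the
#' broad set, so the strict cohort is always contained in the broad cohort.
#'
#' @param path Optional path to a block config file with `[broad]` and
#'   `[strict]` blocks.
#' @return A [cohort_definition()].
#' @export
glioma_broad <- function(path = pv_extdata("cohort_terms.cfg")) {
  cohort_definition("broad", read_block_config(path)$broad)
}

#' @rdname glioma_broad
#' @export
glioma_strict <- function(path = pv_extdata("cohort_terms.cfg")) {
  cfg <- read_block_config(path)
  if (!all(cfg$strict %in% cfg$broad)) {
    stop("strict cohort terms must be a subset of the broad terms", call. = FALSE)
  }
  cohort_definition("strict", cfg$strict)
}

#' Shipped composite endpoint definitions
#'
#' The three outcome endpoints as MedDRA preferred-term sets: venous
#' thromboembolism (`VTE`), central nervous system bleeding (`CNS_BLEED`)
#' and gastrointestinal bleeding (`GI_BLEED`). The shipped sets are seeded
#' from the PTs named for each composite outcome (deep vein thrombosis,
#' pulmonary embolism and related venous events; intracranial/cerebral
#' haemorrhage and haematoma terms; GI haemorrhage, haematemesis, melaena)
#' and are user-extensible via the config file; they are pairwise disjoint.
#'
#' @param path Optional path to a block config file, one `[ENDPOINT]` block
#'   per endpoint, one PT per line.
#' @return Named list of [endpoint_definition()] objects.
#' @export
default_endpoints <- function(path = pv_extdata("endpoints.cfg")) {
  cfg <- read_block_config(path)
  defs <- lapply(names(cfg), function(n) endpoint_definition(n, cfg[[n]]))
  stats::setNames(defs, names(cfg))
  }

#' Default study drugs
#'
#' The four prespecified systemic glioma therapies, in presentation order.
#' @return Character vector of generic names.
#' @export
default_study_drugs <- function() {
  c("TEMOZOLOMIDE", "BEVACIZUMAB", "LOMUSTINE", "CARMUSTINE")
}
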