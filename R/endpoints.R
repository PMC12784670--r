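#' Composite endpoint definition
#'
#' An endpoint is a set of MedDRA preferred terms (PTs); a report has the
#' endpoint if it lists at least one of them. Comparison is exact string
#' equality after case/whitespace normalization -- no MedDRA hierarchy or
#' SMQ expansion is performed, the configured list *is* the endpoint.
#'
#' @param name Endpoint name (e.g. `"VTE"`, `"CNS_BLEED"`, `"GI_BLEED"`).
#' @param pts Nonempty character vector of preferred terms.
#' @return An object of class `endpoint_definition`.
#' @export
endpoint_definition <- function(name, pts) {
  pts <- toupper(trimws(as.character(pts)))
  pts <- unique(pts[nzchar(pts)])
  if (!length(pts)) stop("endpoint definition needs at least one PT", call. = FALSE)
  structure(list(name = name, pts = pts), class = "endpoint_definition")
}

#' Flag reports carrying a composite endpoint
#'
#' A report is flagged once per endpoint regardless of how many of the
#' endpoint's PTs it lists, and regardless of whether the event is a first
#' occurrence or a recurrence (report versions do not distinguish these).
#'
#' @param set A [report_set()].
#' @param def An [endpoint_definition()].
#' @return Logical vector, one element per row of `set$reports`.
#' @export
has_endpoint <- function(set, def) {
  stopifnot(inherits(set, "report_set"), inherits(def, "endpoint_definition"))
  rx <- set$reactions
  hit <- rx$pt %in% def$pts
  uni <- unique(set$reports$report_id)
  keys <- pair_key(rx$report_id[hit], rx$version[hit], uni)
  pair_key(set$reports$report_id, set$reports$version, uni) %in% keys
}

#' Count reports per composite endpoint
#'
#' Each count is the number of distinct reports with at least one matching
#' PT; a report may count toward several endpoints but never twice toward
#' the same one.
#'
#' @param set A deduplicated [report_set()].
#' @param defs List of [endpoint_definition()] objects
#'   (default [default_endpoints()]).
#' @return Named integer vector of report counts.
#' @export
endpoint_counts <- function(set, defs = default_endpoints()) {
  vapply(defs, function(d) sum(has_endpoint(set, d)), integer(1))
}
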