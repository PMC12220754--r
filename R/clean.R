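#' Deduplicate a report set to one record per case
#'
#' FAERS cases accumulate versions as follow-up information arrives; analyses
#' use only the latest. Keeps, per `caseid`, the row with the highest
#' `caseversion`, breaking ties by latest receipt date (`fda_dt`) and then by
#' lexicographically largest `primaryid` — a total order, so the result is
#' deterministic and idempotent. Repeated drug/event/outcome rows within the
#' kept version are collapsed (the counting unit downstream is the report,
#' not the row). Cases with no event rows are dropped and counted
#' (`dropped_no_events`), since a spontaneous report must list at least one
#' reaction.
#'
#' @param reports a raw [report_set()].
#' @return a [report_set()] with one row per `caseid`.
#' @export
deduplicate_reports <- function(reports) {
  d <- reports$demo
  ord <- order(d$caseid, d$caseversion, d$fda_dt, d$primaryid,
               decreasing = c(FALSE, TRUE, TRUE, TRUE), method = "radix")
  d <- d[ord, , drop = FALSE]
  d <- d[!duplicated(d$caseid), , drop = FALSE]

  keep <- d$primaryid
  ev <- unique(reports$events[reports$events$primaryid %in% keep, , drop = FALSE])
  has_event <- d$primaryid %in% ev$primaryid
  dropped <- sum(!has_event)
  if (dropped)
    warning(sprintf("dropped %d case(s) with no reported event", dropped),
            call. = FALSE)
  d <- d[has_event, , drop = FALSE]
  keep <- d$primaryid

  counters <- reports$counters
  counters$dropped_no_events <- (counters$dropped_no_events %||% 0L) + dropped
  report_set(d,
             unique(reports$drugs[reports$drugs$primaryid %in% keep, , drop = FALSE]),
             ev[ev$primaryid %in% keep, , drop = FALSE],
             unique(reports$outcomes[reports$outcomes$primaryid %in% keep, , drop = FALSE]),
             counters = counters)
}

#' Normalize verbatim drug names to canonical ingredients
#'
#' Replaces each drug name by its canonical ingredient per the dictionary,
#' matching case- and whitespace-insensitively. Names absent from the
#' dictionary are kept verbatim; the number of distinct unmapped names is
#' recorded in counter `unmapped_drugs`. Canonical names map to themselves,
#' so the operation is idempotent.
#'
#' @param reports a [report_set()].
#' @param dictionary data.frame with columns `verbatim`, `canonical`; default
#'   the shipped toy dictionary ([read_drug_dictionary()]).
#' @return the report set with normalized drug names.
#' @export
normalize_drug_names <- function(reports, dictionary = read_drug_dictionary()) {
  lut <- stats::setNames(dictionary$canonical, .norm_key(dictionary$verbatim))
  key <- .norm_key(reports$drugs$drug)
  hit <- key %in% names(lut)
  mapped <- reports$drugs$drug
  mapped[hit] <- unname(lut[key[hit]])
  n_unmapped <- length(unique(reports$drugs$drug[!hit]))
  reports$drugs$drug <- mapped
  reports$counters$unmapped_drugs <- n_unmapped
  canonicalize(reports)
}

#' Restrict to reports naming a drug as primary suspect
#'
#' Keeps the reports in which `drug` appears with role code `PS` on at least
#' one drug entry; reports where it appears only as secondary suspect,
#' concomitant or interacting (`SS`/`C`/`I`) are excluded. This defines the
#' descriptive cohort; the screening universe for 2x2 tables keeps all
#' reports (see [build_table()]).
#'
#' @param reports a [report_set()].
#' @param drug canonical drug name.
#' @return the subset [report_set()].
#' @export
filter_primary_suspect <- function(reports, drug) {
  ps <- reports$drugs$primaryid[reports$drugs$drug == drug &
                                  reports$drugs$role == "PS"]
  keep <- reports$demo$primaryid %in% ps
  subset_rs <- function(tab) tab[tab$primaryid %in% reports$demo$primaryid[keep], , drop = FALSE]
  report_set(reports$demo[keep, , drop = FALSE], subset_rs(reports$drugs),
             subset_rs(reports$events), subset_rs(reports$outcomes),
             counters = reports$counters)
}

#' Attach System Organ Class labels to events
#'
#' Maps every event PT to its primary SOC via the supplied vocabulary. PTs
#' absent from the map are routed to the sentinel SOC `"UNMAPPED"` rather
#' than dropped (preserving the marginal total N) and the number of distinct
#' unmapped PTs is recorded in counter `unmapped_pts`.
#'
#' @param reports a [report_set()].
#' @param map data.frame with columns `pt`, `soc` (see [read_pt_soc_map()]).
#' @return the report set with `events$soc` populated.
#' @export
attach_soc <- function(reports, map = read_pt_soc_map()) {
  .assert(nrow(map) > 0, "PT-to-SOC map must be non-empty")
  lut <- stats::setNames(map$soc, map$pt)
  soc <- unname(lut[reports$events$pt])
  n_unmapped <- length(unique(reports$events$pt[is.na(soc)]))
  soc[is.na(soc)] <- "UNMAPPED"
  reports$events$soc <- soc
  reports$counters$unmapped_pts <- n_unmapped
  canonicalize(reports)
}
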