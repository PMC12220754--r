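#' Construct a spontaneous-report set
#'
#' The package's central container: a normalized, relational view of a set of
#' spontaneous adverse-event case reports, mirroring the quarterly FAERS
#' table layout. One demographic row per case *version* (`primaryid` =
#' `caseid` + zero-padded `caseversion`); drugs, events and serious outcomes
#' are long tables keyed by `primaryid`. After [deduplicate_reports()] there
#' is exactly one row (the latest version) per `caseid`.
#'
#' @param demo data.frame with columns `primaryid`, `caseid`, `caseversion`,
#'   `fda_dt` (integer yyyymmdd receipt date), `sex`, `age`, `age_group`,
#'   `country`, `reporter`, and optionally `latest` (generator ground truth).
#' @param drugs data.frame with columns `primaryid`, `drug`, `role`
#'   (role codes `PS`, `SS`, `C`, `I`).
#' @param events data.frame with columns `primaryid`, `pt`, and optionally
#'   `soc` (attached later by [attach_soc()]).
#' @param outcomes data.frame with columns `primaryid`, `outc_cod`
#'   (codes `DE`, `DS`, `HO`, `LT`).
#' @param counters named list of data-cleaning counters accumulated by the
#'   ingest operations.
#' @return an object of class `report_set`.
#' @export
report_set <- function(demo, drugs, events, outcomes,
                       counters = list()) {
  demo <- as.data.frame(demo)
  drugs <- as.data.frame(drugs)
  events <- as.data.frame(events)
  outcomes <- as.data.frame(outcomes)
  .assert(!anyDuplicated(demo$primaryid),
          "(caseid, caseversion) must be unique within a report set")
  if (is.null(events$soc)) events$soc <- NA_character_
  if (is.null(demo$latest)) demo$latest <- NA
  x <- structure(list(demo = demo, drugs = drugs, events = events,
                      outcomes = outcomes, counters = counters),
                 class = "report_set")
  canonicalize(x)
}

# Deterministic row order so that structurally equal sets compare identical
# regardless of input row order.
canonicalize <- function(x) {
  ord <- order(x$demo$caseid, x$demo$caseversion)
  x$demo <- x$demo[ord, , drop = FALSE]
  x$drugs <- x$drugs[order(x$drugs$primaryid, x$drugs$drug, x$drugs$role), , drop = FALSE]
  x$events <- x$events[order(x$events$primaryid, x$events$pt), , drop = FALSE]
  x$outcomes <- x$outcomes[order(x$outcomes$primaryid, x$outcomes$outc_cod), , drop = FALSE]
  for (nm in c("demo", "drugs", "events", "outcomes"))
    rownames(x[[nm]]) <- NULL
  x
}

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf("<report_set> %d case versions (%d distinct cases)\n",
              nrow(x$demo), length(unique(x$demo$caseid))))
  cat(sprintf("  drug rows: %d | event rows: %d | outcome rows: %d\n",
              nrow(x$drugs), nrow(x$events), nrow(x$outcomes)))
  if (length(x$counters))
    cat("  counters:", paste(names(x$counters), unlist(x$counters),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of case versions in a report set
#' @param x a `report_set`.
#' @return integer count of demographic rows.
#' @export
n_reports <- function(x) nrow(x$demo)

# strip ground-truth and bookkeeping fields before structural comparison
.comparable <- function(x) {
  x$demo$latest <- NULL
  x$counters <- NULL
  unclass(x)
}

#' Structural equality of two report sets
#'
#' Compares the relational payload (demographics, drugs, events, outcomes)
#' after canonical ordering, ignoring cleaning counters and generator
#' ground-truth flags. Used by the generator-to-file round-trip checks.
#'
#' @param x,y `report_set` objects.
#' @return `TRUE` or `FALSE`.
#' @export
report_sets_equal <- function(x, y) {
  isTRUE(all.equal(.comparable(canonicalize(x)), .comparable(canonicalize(y)),
                   check.attributes = FALSE))
}
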