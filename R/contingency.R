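#' Build the 2x2 contingency table for one drug-event pair
#'
#' Cells follow the standard disproportionality layout: with the target drug
#' defined by primary-suspect (PS) role,
#' \describe{
#'   \item{a}{reports with the drug (PS) and the event,}
#'   \item{b}{reports with the drug (PS) and other events,}
#'   \item{c}{reports without the drug (PS) but with the event,}
#'   \item{d}{all remaining reports,}
#' }
#' so `N = a+b+c+d` is the size of the deduplicated analysis universe,
#' identical for every pair. Reports carrying the drug in a non-PS role fall
#' in the `c`/`d` rows, because the query is defined by the PS role. At SOC
#' level a report counts once even if it lists several PTs of that SOC.
#'
#' @param reports the full cleaned, deduplicated universe (a [report_set()]).
#' @param drug canonical target drug name.
#' @param event PT name (`level = "PT"`) or SOC name (`level = "SOC"`).
#' @param level `"PT"` or `"SOC"` (SOC labels must be attached first).
#' @return an object of class `contingency_table`: a list with `a`, `b`,
#'   `c`, `d`, `N`, `drug`, `event`, `level` and a logical `flagged` set when
#'   the event never occurs in the universe (`a = c = 0`).
#' @export
build_table <- function(reports, drug, event, level = c("PT", "SOC")) {
  level <- match.arg(level)
  N <- n_reports(reports)
  ps_ids <- unique(reports$drugs$primaryid[reports$drugs$drug == drug &
                                             reports$drugs$role == "PS"])
  col <- if (level == "PT") reports$events$pt else reports$events$soc
  if (level == "SOC")
    .assert(!anyNA(reports$events$soc), "attach SOC labels before SOC-level tables")
  ev_ids <- unique(reports$events$primaryid[col == event])
  a <- sum(ev_ids %in% ps_ids)
  b <- length(ps_ids) - a
  c_ <- length(ev_ids) - a
  d <- N - a - b - c_
  flagged <- (a + c_) == 0
  if (flagged)
    warning(sprintf("event '%s' absent from the universe", event), call. = FALSE)
  structure(list(a = a, b = b, c = c_, d = d, N = N, drug = drug,
                 event = event, level = level, flagged = flagged),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s vs %s [%s]\n", x$drug, x$event, x$level))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("drug (PS)", "other"), c("event", "other")))
  print(m)
  cat("N =", x$N, "\n")
  invisible(x)
}

#' Build every PT- and SOC-level table for a drug
#'
#' Sweeps all PTs and SOCs observed in the drug's primary-suspect reports and
#' returns one 2x2 table per event, all sharing the same universe size `N`.
#'
#' @param reports the cleaned, deduplicated universe with SOCs attached.
#' @param drug canonical target drug name.
#' @return a `data.frame` with columns `drug`, `event`, `level`, `a`, `b`,
#'   `c`, `d`, `N`.
#' @export
build_all_tables <- function(reports, drug) {
  .assert(!anyNA(reports$events$soc), "attach SOC labels before screening")
  N <- n_reports(reports)
  ps_ids <- unique(reports$drugs$primaryid[reports$drugs$drug == drug &
                                             reports$drugs$role == "PS"])
  n_ps <- length(ps_ids)
  ev <- data.table::as.data.table(reports$events)

  pt_soc <- unique(reports$events[, c("pt", "soc")])
  level_tables <- function(colname, level) {
    pairs <- unique(ev[, .(primaryid, event = get(colname))])
    tot <- pairs[, .(n_tot = .N), by = event]
    tgt <- pairs[primaryid %in% ps_ids, .(a = .N), by = event]
    out <- merge(tgt, tot, by = "event")
    soc <- if (level == "PT") pt_soc$soc[match(out$event, pt_soc$pt)] else out$event
    data.frame(drug = drug, event = out$event, level = level, soc = soc,
               a = out$a, b = n_ps - out$a, c = out$n_tot - out$a,
               d = N - n_ps - (out$n_tot - out$a), N = N)
  }
  res <- rbind(level_tables("pt", "PT"), level_tables("soc", "SOC"))
  res[order(res$level, res$event), , drop = FALSE]
}

#' Export contingency tables as tab-separated text
#'
#' @param tables a data.frame from [build_all_tables()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_tables <- function(tables, path) {
  data.table::fwrite(tables, path, sep = "\t", quote = FALSE, eol = "\n")
  invisible(path)
}
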