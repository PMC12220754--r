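#' Summarize cohort characteristics
#'
#' Counts and percentages per demographic category for a deduplicated,
#' primary-suspect-filtered cohort: sex, age bins (`<18`, `18-44`, `45-64`,
#' `65-74`, `>=75`, `unspecified`), the top-`k` reporting countries, serious
#' outcomes (`LT`/`HO`/`DS`/`DE`, non-exclusive: a report with several
#' outcome codes counts once in each row, so these percentages need not sum
#' to 100), reporter occupations, and annual report counts. Percentages are
#' `100 * count / n_events` rounded half-up to 2 decimals, matching the
#' convention of published report tables.
#'
#' @param reports a [report_set()] (deduplicated cohort).
#' @param top_countries number of countries to report, ranked by count.
#' @return an object of class `cohort_summary`: a list with `n_events` and
#'   data.frames `sex`, `age`, `country`, `outcomes`, `reporter`, `years`,
#'   each with columns `category`, `count`, `pct`.
#' @export
summarize_cohort <- function(reports, top_countries = 5) {
  n <- n_reports(reports)
  .assert(n > 0, "cannot summarize an empty report set")
  d <- reports$demo
  pct <- function(k) round_half_up(100 * k / n, 2)
  cat_table <- function(x, levels = NULL) {
    tab <- table(if (is.null(levels)) x else factor(x, levels = levels))
    data.frame(category = names(tab), count = as.integer(tab),
               pct = pct(as.integer(tab)))
  }
  sex <- cat_table(d$sex, c("male", "female", "unspecified"))
  age <- cat_table(d$age_group, c(.age_labels, "unspecified"))
  # the ranking lists named countries; the pooled "other" label is not one
  ctry <- cat_table(d$country[d$country != "other"])
  ctry <- ctry[order(-ctry$count, ctry$category), , drop = FALSE]
  rownames(ctry) <- NULL
  ctry <- utils::head(ctry, top_countries)
  # outcomes are per-report with multiplicity across codes
  oc <- unique(reports$outcomes[, c("primaryid", "outc_cod")])
  oc_counts <- vapply(.outcome_codes, function(cd)
    sum(oc$outc_cod == cd), integer(1))
  outcomes <- data.frame(category = .outcome_codes,
                         count = unname(oc_counts), pct = pct(unname(oc_counts)))
  reporter <- cat_table(d$reporter,
                        c("consumer", "lawyer", "physician",
                          "other health-professional", "pharmacist",
                          "unspecified"))
  yr <- annual_trend(reports)
  structure(list(n_events = n, sex = sex, age = age, country = ctry,
                 outcomes = outcomes, reporter = reporter, years = yr),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d reports\n", x$n_events))
  for (nm in c("sex", "age", "country", "outcomes", "reporter")) {
    cat("--", nm, "--\n")
    print(x[[nm]], row.names = FALSE)
  }
  peak <- x$years[which.max(x$years$n), ]
  cat(sprintf("peak year: %d (n = %d, %.2f%%)\n", peak$year, peak$n,
              round_half_up(100 * peak$n / x$n_events, 2)))
  invisible(x)
}

#' Annual reporting trend
#'
#' Report counts per receipt year over (at least) the 2004-2023 span, zeros
#' filled, with the peak year as attributes `argmax` and `argmax_share`
#' (percentage of all reports, rounded half-up to 2 decimals).
#'
#' @param reports a [report_set()].
#' @return a `data.frame` with columns `year`, `n`.
#' @export
annual_trend <- function(reports) {
  yr <- reports$demo$fda_dt %/% 10000L
  span <- min(2004L, yr):max(2023L, yr)
  tab <- table(factor(yr, levels = span))
  out <- data.frame(year = span, n = as.integer(tab))
  peak <- out$year[which.max(out$n)]
  attr(out, "argmax") <- peak
  attr(out, "argmax_share") <-
    round_half_up(100 * max(out$n) / nrow(reports$demo), 2)
  out
}

#' Export a cohort summary as tab-separated text
#'
#' One block per characteristic, shaped like a published descriptive table
#' (`section`, `category`, `count`, `pct`), followed by the annual counts.
#'
#' @param summary a [summarize_cohort()] result.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_cohort_summary <- function(summary, path) {
  blocks <- lapply(c("sex", "age", "country", "outcomes", "reporter"),
                   function(nm) cbind(section = nm, summary[[nm]]))
  flat <- do.call(rbind, blocks)
  flat <- rbind(data.frame(section = "total", category = "n_events",
                           count = summary$n_events, pct = 100),
                flat,
                data.frame(section = "year",
                           category = as.character(summary$years$year),
                           count = summary$years$n,
                           pct = round_half_up(100 * summary$years$n /
                                                 summary$n_events, 2)))
  data.table::fwrite(flat, path, sep = "\t", quote = FALSE, eol = "\n")
  invisible(path)
}
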