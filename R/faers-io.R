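## FAERS quarterly ASCII dialect
##
## Four "$"-delimited text files with a header row, one per table:
##   DEMO.txt  primaryid$caseid$caseversion$fda_dt$sex$age$occr_country$occp_cod
##   DRUG.txt  primaryid$drugname$role_cod
##   REAC.txt  primaryid$pt
##   OUTC.txt  primaryid$outc_cod
## Fields are unquoted; a field containing the "$" delimiter is invalid and
## the writer refuses it (FAERS itself never escapes the delimiter).

.faers_files <- c(DEMO = "DEMO.txt", DRUG = "DRUG.txt",
                  REAC = "REAC.txt", OUTC = "OUTC.txt")

.check_no_dollar <- function(df, table) {
  for (nm in names(df)) {
    bad <- grepl("$", as.character(df[[nm]]), fixed = TRUE)
    .assert(!any(bad), sprintf(
      "%s column '%s' contains the '$' delimiter (%d row(s)); the FAERS dialect has no escape for it",
      table, nm, sum(bad)))
  }
  df
}

#' Write a report set as FAERS-style quarterly ASCII tables
#'
#' Emits `DEMO.txt`, `DRUG.txt`, `REAC.txt` and `OUTC.txt` in the
#' "$"-delimited dialect described above: one DEMO row per case version,
#' DRUG rows carrying role codes, REAC rows carrying PT names, OUTC rows
#' carrying serious-outcome codes. Internal demographic labels are written as
#' FAERS field codes (`M`/`F`/`UNK` for sex, `CN`/`LW`/`MD`/`OT`/`PH`/`UNK`
#' for reporter occupation). The mapping is bijective, so
#' [read_faers_quarter()] round-trips losslessly.
#'
#' @param reports a [report_set()].
#' @param directory output directory, created if absent.
#' @return invisibly, the four file paths.
#' @export
write_faers_quarter <- function(reports, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  d <- reports$demo
  demo <- data.frame(primaryid = d$primaryid, caseid = d$caseid,
                     caseversion = d$caseversion, fda_dt = d$fda_dt,
                     sex = .sex_to_code[d$sex],
                     age = ifelse(is.na(d$age), "", format(d$age, trim = TRUE)),
                     occr_country = d$country,
                     occp_cod = .rep_to_code[d$reporter])
  drug <- data.frame(primaryid = reports$drugs$primaryid,
                     drugname = reports$drugs$drug,
                     role_cod = reports$drugs$role)
  reac <- data.frame(primaryid = reports$events$primaryid,
                     pt = reports$events$pt)
  outc <- data.frame(primaryid = reports$outcomes$primaryid,
                     outc_cod = reports$outcomes$outc_cod)
  tabs <- list(DEMO = demo, DRUG = drug, REAC = reac, OUTC = outc)
  paths <- file.path(directory, .faers_files)
  for (i in seq_along(tabs))
    data.table::fwrite(.check_no_dollar(tabs[[i]], names(tabs)[i]), paths[i],
                       sep = "$", quote = FALSE, eol = "\n")
  invisible(stats::setNames(paths, names(tabs)))
}

.read_faers_table <- function(directory, table, required) {
  path <- file.path(directory, .faers_files[[table]])
  .assert(file.exists(path), sprintf("missing FAERS table file: %s", path))
  dt <- data.table::fread(path, sep = "$", quote = "", colClasses = "character",
                          header = TRUE, fill = TRUE)
  missing_cols <- setdiff(required, names(dt))
  .assert(length(missing_cols) == 0, sprintf(
    "%s is missing required column(s): %s", path,
    paste(missing_cols, collapse = ", ")))
  as.data.frame(dt)
}

#' Read a FAERS-style quarterly directory
#'
#' Joins the four "$"-delimited tables into one raw [report_set()], one
#' record per `(caseid, caseversion)`. Unknown columns are ignored. Rows
#' whose `primaryid` is empty (malformed) or has no DEMO row (orphans) are
#' dropped with a warning, and counted in the returned set's `counters`
#' (`malformed_rows`, `orphan_rows`). Demographic field codes are mapped
#' back to the internal labels; unrecognized codes become `"unspecified"`,
#' and ages outside `[0, 120]` are treated as missing.
#'
#' The result is *raw*: it may still contain duplicate case versions (see
#' [deduplicate_reports()]) and events lack SOC labels until
#' [attach_soc()].
#'
#' @param directory path containing `DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#'   `OUTC.txt`.
#' @return a [report_set()] with cleaning counters.
#' @export
read_faers_quarter <- function(directory) {
  demo <- .read_faers_table(directory, "DEMO",
                            c("primaryid", "caseid", "caseversion", "fda_dt",
                              "sex", "age", "occr_country", "occp_cod"))
  drug <- .read_faers_table(directory, "DRUG",
                            c("primaryid", "drugname", "role_cod"))
  reac <- .read_faers_table(directory, "REAC", c("primaryid", "pt"))
  outc <- .read_faers_table(directory, "OUTC", c("primaryid", "outc_cod"))

  malformed <- sum(!nzchar(demo$primaryid)) + sum(!nzchar(drug$primaryid)) +
    sum(!nzchar(reac$primaryid)) + sum(!nzchar(outc$primaryid))
  demo <- demo[nzchar(demo$primaryid), , drop = FALSE]
  keep_known <- function(tab, label) {
    orphan <- nzchar(tab$primaryid) & !(tab$primaryid %in% demo$primaryid)
    if (any(orphan))
      warning(sprintf("%s: dropped %d row(s) with no matching DEMO record",
                      label, sum(orphan)), call. = FALSE)
    list(tab = tab[nzchar(tab$primaryid) & !orphan, , drop = FALSE],
         n_orphan = sum(orphan))
  }
  kd <- keep_known(drug, "DRUG")
  kr <- keep_known(reac, "REAC")
  ko <- keep_known(outc, "OUTC")

  age <- suppressWarnings(as.numeric(demo$age))
  age[!is.na(age) & (age < 0 | age > 120)] <- NA_real_
  sex <- unname(.code_to_sex[demo$sex])
  sex[is.na(sex)] <- "unspecified"
  reporter <- unname(.code_to_rep[demo$occp_cod])
  reporter[is.na(reporter)] <- "unspecified"
  country <- demo$occr_country
  country[!nzchar(country)] <- "other"

  demo_out <- data.frame(primaryid = demo$primaryid, caseid = demo$caseid,
                         caseversion = as.integer(demo$caseversion),
                         fda_dt = as.integer(demo$fda_dt),
                         sex, age, age_group = .age_to_group(age),
                         country, reporter, latest = NA)
  report_set(demo_out,
             data.frame(primaryid = kd$tab$primaryid, drug = kd$tab$drugname,
                        role = kd$tab$role_cod),
             data.frame(primaryid = kr$tab$primaryid, pt = kr$tab$pt,
                        soc = rep(NA_character_, nrow(kr$tab))),
             data.frame(primaryid = ko$tab$primaryid,
                        outc_cod = ko$tab$outc_cod),
             counters = list(malformed_rows = malformed,
                             orphan_rows = kd$n_orphan + kr$n_orphan + ko$n_orphan))
}
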