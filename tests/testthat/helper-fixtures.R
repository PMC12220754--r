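# Shared fixtures and the high-precision arithmetic referee.

toy_vocab <- function(n_pts = 56) utils::head(read_pt_soc_map(), n_pts)

toy_config <- function(n = 500, seed = 1, ...) {
  generator_config(n_reports = n, seed = seed, ...)
}

# hand-built report set: `cases` is a list of lists with fields
# drugs = list(c(name, role), ...), pts = character(), and optional demo fields
hand_reports <- function(cases) {
  n <- length(cases)
  caseid <- sprintf("%08d", 90000000L + seq_len(n))
  pid <- paste0(caseid, "01")
  demo <- data.frame(
    primaryid = pid, caseid = caseid, caseversion = 1L,
    fda_dt = vapply(cases, function(x) x$fda_dt %||% 20130601L, integer(1)),
    sex = vapply(cases, function(x) x$sex %||% "male", character(1)),
    age = vapply(cases, function(x) x$age %||% NA_real_, numeric(1)),
    age_group = NA_character_, country = "US", reporter = "physician")
  demo$age_group <- faersignal:::.age_to_group(demo$age)
  drugs <- do.call(rbind, lapply(seq_len(n), function(i) {
    dr <- cases[[i]]$drugs
    data.frame(primaryid = pid[i],
               drug = vapply(dr, `[`, "", 1), role = vapply(dr, `[`, "", 2))
  }))
  events <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(primaryid = pid[i], pt = cases[[i]]$pts, soc = NA_character_)))
  oc <- lapply(seq_len(n), function(i) {
    out <- cases[[i]]$outcomes
    if (is.null(out)) NULL else data.frame(primaryid = pid[i], outc_cod = out)
  })
  oc <- Filter(Negate(is.null), oc)
  outcomes <- if (length(oc)) do.call(rbind, oc) else
    data.frame(primaryid = character(), outc_cod = character())
  report_set(demo, drugs, events, outcomes)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# mpmath referee: evaluates every statistic from the published closed forms
# at 50 significant digits, independently of the R implementation
oracle_stats <- function(tables) {
  src <- system.file("oracle", "signal_oracle.py", package = "faersignal")
  stopifnot(nzchar(src))
  f_in <- tempfile(fileext = ".csv")
  utils::write.csv(tables[, c("a", "b", "c", "d")], f_in, row.names = FALSE)
  out <- system2("python", c(src, f_in), stdout = TRUE)
  utils::read.csv(text = paste(out, collapse = "\n"), na.strings = "NA")
}

rel_err <- function(x, y) {
  ifelse(is.na(x) & is.na(y), 0, abs(x - y) / pmax(abs(y), 1e-300))
}

# random 2x2 tables with all cells in [lo, hi]
random_tables <- function(n, lo = 1, hi = 1e4, seed = 1) {
  set.seed(seed)
  data.frame(a = sample(lo:hi, n, TRUE), b = sample(lo:hi, n, TRUE),
             c = sample(lo:hi, n, TRUE), d = sample(lo:hi, n, TRUE))
}

# printed montelukast cohort margins used by the descriptive fixtures
published_cohort_counts <- function() {
  list(
    n = 19630L,
    sex = c(male = 10405L, female = 7327L, unspecified = 1898L),
    age_group = c("<18" = 6088L, "18-44" = 3104L, "45-64" = 3180L,
                  "65-74" = 1259L, ">=75" = 699L, unspecified = 5300L),
    country = c(US = 10228L, GB = 3560L, CA = 1707L, FR = 486L, JP = 384L),
    outcomes = c(LT = 1378L, HO = 3987L, DS = 2207L, DE = 497L),
    reporter = c(consumer = 7702L, lawyer = 286L, physician = 4565L,
                 "other health-professional" = 3540L, pharmacist = 2316L,
                 unspecified = 1221L),
    years = c("2013" = 2132L))
}

published_cohort <- function() {
  k <- published_cohort_counts()
  cohort_from_counts(k$n, sex = k$sex, age_group = k$age_group,
                     country = k$country, reporter = k$reporter,
                     outcomes = k$outcomes, years = k$years)
}
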