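#' Configuration for the synthetic spontaneous-report generator
#'
#' Describes a FAERS-like reporting universe with known ground truth: a drug
#' vocabulary, an event (PT) vocabulary with SOC labels, per-report drug
#' exposure and baseline event probabilities, planted drug-event signals
#' expressed as relative-reporting-rate multipliers, a duplicate-version
#' rate, and categorical demographic distributions.
#'
#' The event model is per-PT independent Bernoulli: each PT occurs with
#' probability `baseline_event_prob`, multiplied by the planted relative rate
#' (capped at 1) when the paired drug is the report's primary suspect. Under
#' this model the 2x2 odds ratio of a planted pair in the primary-suspect
#' screening universe is exactly `odds(min(1, p*m)) / odds(p)`; see
#' [planted_odds_ratio()].
#'
#' @param n_reports number of distinct cases to generate (before duplicate
#'   injection).
#' @param drug_vocab character vector of canonical drug names.
#' @param event_vocab data.frame with columns `pt` and `soc` (defaults to the
#'   shipped toy vocabulary, see [read_pt_soc_map()]).
#' @param baseline_event_prob per-(report, PT) background occurrence
#'   probability in `[0, 1]`.
#' @param planted_signals data.frame with columns `drug`, `pt`, `multiplier`
#'   (relative reporting rate, `>= 0`); may have zero rows.
#' @param drug_exposure_prob per-(report, drug) independent exposure
#'   probability in `[0, 1]`.
#' @param duplicate_rate fraction in `[0, 1)` of cases re-emitted as extra
#'   case versions by [inject_duplicates()] (applied by [run_pipeline()]).
#' @param demographic_mix named list of categorical distributions for `sex`,
#'   `age_group`, `country`, `reporter`, `year`, plus independent Bernoulli
#'   rates for `outcomes`; defaults to the proportions of a large published
#'   montelukast cohort.
#' @param background_pt a designated filler PT given to any report whose
#'   Bernoulli draws produce no event, since a spontaneous report always
#'   lists at least one reaction. Must be in `event_vocab` and must not be a
#'   planted PT. Default `"Drug ineffective"`.
#' @param seed integer seed; all generator randomness flows from it.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_reports = 10000,
                             drug_vocab = .default_drug_vocab(),
                             event_vocab = read_pt_soc_map(),
                             baseline_event_prob = 0.02,
                             planted_signals = data.frame(drug = character(),
                                                          pt = character(),
                                                          multiplier = numeric()),
                             drug_exposure_prob = 0.3,
                             duplicate_rate = 0,
                             demographic_mix = default_demographic_mix(),
                             background_pt = "Drug ineffective",
                             seed = 1L) {
  .assert(is.numeric(n_reports) && n_reports >= 1, "n_reports must be >= 1")
  .assert(length(drug_vocab) > 0, "drug vocabulary must be non-empty")
  .assert(!anyDuplicated(drug_vocab), "drug vocabulary entries must be unique")
  event_vocab <- as.data.frame(event_vocab)
  .assert(nrow(event_vocab) > 0, "event vocabulary must be non-empty")
  .assert(all(c("pt", "soc") %in% names(event_vocab)),
          "event_vocab needs columns 'pt' and 'soc'")
  .assert(!anyDuplicated(event_vocab$pt), "event vocabulary PTs must be unique")
  .assert(.is_prob(baseline_event_prob) && length(baseline_event_prob) == 1,
          "baseline_event_prob must be a probability in [0, 1]")
  .assert(.is_prob(drug_exposure_prob) && length(drug_exposure_prob) == 1,
          "drug_exposure_prob must be a probability in [0, 1]")
  .assert(is.numeric(duplicate_rate) && duplicate_rate >= 0 && duplicate_rate < 1,
          "duplicate_rate must be in [0, 1)")
  planted_signals <- as.data.frame(planted_signals)
  if (nrow(planted_signals)) {
    .assert(all(c("drug", "pt", "multiplier") %in% names(planted_signals)),
            "planted_signals needs columns 'drug', 'pt', 'multiplier'")
    .assert(all(planted_signals$multiplier >= 0), "multipliers must be >= 0")
    .assert(all(planted_signals$drug %in% drug_vocab),
            "every planted drug must be in drug_vocab")
    .assert(all(planted_signals$pt %in% event_vocab$pt),
            "every planted PT must be in event_vocab")
    .assert(!background_pt %in% planted_signals$pt,
            "the background filler PT cannot carry a planted signal")
  }
  .assert(background_pt %in% event_vocab$pt,
          "background_pt must be in event_vocab")
  for (nm in c("sex", "age_group", "country", "reporter", "year", "outcomes"))
    .assert(.is_prob(demographic_mix[[nm]]) && length(demographic_mix[[nm]]) > 0,
            sprintf("demographic_mix$%s must be probabilities", nm))
  .assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
          "seed must be a single integer")
  structure(list(n_reports = as.integer(n_reports), drug_vocab = drug_vocab,
                 event_vocab = event_vocab,
                 baseline_event_prob = baseline_event_prob,
                 planted_signals = planted_signals,
                 drug_exposure_prob = drug_exposure_prob,
                 duplicate_rate = duplicate_rate,
                 demographic_mix = demographic_mix,
                 background_pt = background_pt, seed = as.integer(seed)),
            class = "generator_config")
}

#' Odds ratio implied by a planted signal
#'
#' Closed form of the 2x2 odds ratio a planted `(drug, pt, multiplier)`
#' signal induces in the primary-suspect screening universe:
#' with baseline probability `p` and multiplier `m`, the target-row event
#' probability is `p1 = min(1, p*m)` and the comparator rows keep `p`, so
#' `OR = (p1/(1-p1)) / (p/(1-p))`.
#'
#' @param config a [generator_config()].
#' @param multiplier relative reporting rate (vectorized).
#' @return numeric odds ratio(s).
#' @export
planted_odds_ratio <- function(config, multiplier) {
  p0 <- config$baseline_event_prob
  p1 <- pmin(1, p0 * multiplier)
  (p1 / (1 - p1)) / (p0 / (1 - p0))
}

.make_primaryid <- function(caseid, caseversion) {
  paste0(caseid, sprintf("%02d", caseversion))
}

.sample_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic FAERS-like report set
#'
#' Draws `n_reports` distinct cases from the generative model described in
#' [generator_config()]: independent per-drug exposure (a report with no
#' sampled exposure is assigned one drug uniformly at random, since FAERS
#' reports always name a drug), one primary-suspect (PS) drug chosen
#' uniformly among the report's drugs with the others given roles SS/C/I,
#' per-PT Bernoulli events with planted multipliers applied through the PS
#' drug, the background filler PT for event-less draws, and demographics from
#' the configured categorical mix. Fully reproducible from `config$seed`.
#'
#' Duplicate case versions are *not* injected here; see
#' [inject_duplicates()].
#'
#' @param config a [generator_config()].
#' @return a [report_set()] with `n_reports` rows, all `caseversion = 1` and
#'   ground-truth `latest = TRUE`.
#' @export
generate_reports <- function(config) {
  .assert(inherits(config, "generator_config"), "config must be a generator_config")
  set.seed(config$seed)
  n <- config$n_reports
  nd <- length(config$drug_vocab)
  pts <- config$event_vocab$pt
  np <- length(pts)
  mix <- config$demographic_mix

  caseid <- sprintf("%08d", 10000000L + seq_len(n))
  caseversion <- rep(1L, n)
  primaryid <- .make_primaryid(caseid, caseversion)

  sex <- .sample_cat(n, mix$sex)
  age_group <- .sample_cat(n, mix$age_group)
  country <- .sample_cat(n, mix$country)
  reporter <- .sample_cat(n, mix$reporter)
  year <- as.integer(.sample_cat(n, mix$year))
  fda_dt <- year * 10000L + sample(1:12, n, replace = TRUE) * 100L +
    sample(1:28, n, replace = TRUE)

  # numeric age drawn uniformly within the sampled bin
  lo <- c("<18" = 0, "18-44" = 18, "45-64" = 45, "65-74" = 65, ">=75" = 75)
  hi <- c("<18" = 18, "18-44" = 45, "45-64" = 65, "65-74" = 75, ">=75" = 95)
  age <- rep(NA_real_, n)
  spec <- age_group != "unspecified"
  age[spec] <- floor(lo[age_group[spec]] +
                       runif(sum(spec)) * (hi[age_group[spec]] - lo[age_group[spec]]))

  # drug exposure: independent Bernoulli per drug; empty rows get one drug
  expo <- matrix(runif(n * nd) < config$drug_exposure_prob, n, nd)
  none <- !rowSums(expo)
  if (any(none))
    expo[cbind(which(none), sample.int(nd, sum(none), replace = TRUE))] <- TRUE
  # primary suspect: uniform among the report's drugs
  u <- matrix(runif(n * nd), n, nd)
  u[!expo] <- -1
  ps_idx <- max.col(u, ties.method = "first")
  ps_drug <- config$drug_vocab[ps_idx]

  # events: baseline probability, planted multiplier through the PS drug
  pmat <- matrix(config$baseline_event_prob, n, np)
  if (nrow(config$planted_signals)) {
    for (k in seq_len(nrow(config$planted_signals))) {
      sig <- config$planted_signals[k, ]
      rows <- ps_drug == sig$drug
      pmat[rows, match(sig$pt, pts)] <- min(1, config$baseline_event_prob * sig$multiplier)
    }
  }
  ev <- matrix(runif(n * np), n, np) < pmat
  no_ev <- !rowSums(ev)
  if (any(no_ev)) ev[no_ev, match(config$background_pt, pts)] <- TRUE

  # roles for non-PS drugs
  idx <- which(expo, arr.ind = TRUE)
  role <- sample(c("SS", "C", "I"), nrow(idx), replace = TRUE)
  role[ps_idx[idx[, 1]] == idx[, 2]] <- "PS"
  drugs <- data.frame(primaryid = primaryid[idx[, 1]],
                      drug = config$drug_vocab[idx[, 2]], role = role)

  # SOC labels are vocabulary-derived, not part of the report payload (REAC
  # files carry only the PT); attach_soc() adds them during cleaning
  eidx <- which(ev, arr.ind = TRUE)
  events <- data.frame(primaryid = primaryid[eidx[, 1]], pt = pts[eidx[, 2]],
                       soc = NA_character_)

  oc <- names(mix$outcomes)
  om <- matrix(runif(n * length(oc)), n) <
    matrix(mix$outcomes, n, length(oc), byrow = TRUE)
  oidx <- which(om, arr.ind = TRUE)
  outcomes <- data.frame(primaryid = primaryid[oidx[, 1]], outc_cod = oc[oidx[, 2]])

  demo <- data.frame(primaryid, caseid, caseversion, fda_dt, sex, age,
                     age_group, country, reporter, latest = TRUE)
  report_set(demo, drugs, events, outcomes)
}

#' Inject duplicate case versions
#'
#' Re-emits `floor(duplicate_rate * n_cases)` deterministically selected
#' cases as an additional case version: `caseversion` incremented, receipt
#' date advanced by 1-90 days, and (with probability `perturb_prob`) the sex
#' field resampled, emulating the follow-up amendments that deduplication
#' must resolve. Ground truth is recorded in `demo$latest`: the new version
#' is flagged latest and its source unflagged.
#'
#' @param reports a [report_set()].
#' @param duplicate_rate fraction in `[0, 1)` of cases to duplicate.
#' @param seed integer seed for the selection and perturbation draws.
#' @param perturb_prob probability that a duplicate's sex field differs from
#'   its source.
#' @return a [report_set()] with the extra versions appended.
#' @export
inject_duplicates <- function(reports, duplicate_rate, seed,
                              perturb_prob = 0.3) {
  .assert(duplicate_rate >= 0 && duplicate_rate < 1,
          "duplicate_rate must be in [0, 1)")
  if (duplicate_rate == 0) return(reports)
  force(reports)  # lazy argument must not be generated after the re-seed
  set.seed(seed)
  demo <- reports$demo
  ncase <- length(unique(demo$caseid))
  k <- floor(duplicate_rate * ncase)
  if (k == 0) return(reports)
  # duplicate the current latest version of each selected case
  latest_rows <- demo[order(demo$caseid, -demo$caseversion), ]
  latest_rows <- latest_rows[!duplicated(latest_rows$caseid), ]
  pick <- latest_rows[sort(sample.int(nrow(latest_rows), k)), ]

  dup <- pick
  dup$caseversion <- pick$caseversion + 1L
  dup$primaryid <- .make_primaryid(dup$caseid, dup$caseversion)
  d <- as.Date(as.character(pick$fda_dt), "%Y%m%d") + sample(1:90, k, replace = TRUE)
  dup$fda_dt <- as.integer(format(d, "%Y%m%d"))
  flip <- runif(k) < perturb_prob
  if (any(flip))
    dup$sex[flip] <- sample(c("male", "female", "unspecified"), sum(flip),
                            replace = TRUE)
  dup$latest <- TRUE

  copy_rows <- function(tab) {
    sel <- tab[tab$primaryid %in% pick$primaryid, , drop = FALSE]
    sel$primaryid <- dup$primaryid[match(sel$primaryid, pick$primaryid)]
    rbind(tab, sel)
  }
  demo$latest[demo$primaryid %in% pick$primaryid] <- FALSE
  report_set(rbind(demo, dup), copy_rows(reports$drugs),
             copy_rows(reports$events), copy_rows(reports$outcomes),
             counters = reports$counters)
}

#' Build a deterministic report set from marginal counts
#'
#' Constructs a cohort whose categorical margins match the supplied counts
#' exactly, assigning each demographic column independently in blocks. Serious
#' outcomes are non-exclusive: each code is given to the first `k` cases, so
#' codes overlap just as they do in real report sets. Every case receives one
#' filler event and one primary-suspect drug so the set passes downstream
#' invariants. Useful for reproducing published descriptive tables from their
#' printed counts.
#'
#' @param n total number of cases.
#' @param sex,age_group,country,reporter named count vectors; shortfalls
#'   against `n` are absorbed by `unspecified` (or `other` for countries).
#' @param outcomes named count vector (codes `DE`, `DS`, `HO`, `LT`),
#'   non-exclusive.
#' @param years named count vector of receipt years; any shortfall is spread
#'   evenly over the remaining years of 2004-2023.
#' @param drug primary-suspect drug name given to every case.
#' @param filler_pt event PT given to every case.
#' @return a [report_set()] of `n` deduplicated cases.
#' @export
cohort_from_counts <- function(n, sex = NULL, age_group = NULL, country = NULL,
                               reporter = NULL, outcomes = NULL, years = NULL,
                               drug = "MONTELUKAST",
                               filler_pt = "Drug ineffective") {
  fill_col <- function(counts, absorb) {
    if (is.null(counts)) return(rep(absorb, n))
    .assert(sum(counts) <= n, "category counts exceed n")
    rest <- n - sum(counts)
    rep(c(names(counts), absorb), c(counts, rest))
  }
  year_col <- function(counts) {
    if (is.null(counts)) return(rep(2013L, n))
    .assert(sum(counts) <= n, "year counts exceed n")
    rest <- n - sum(counts)
    pool <- setdiff(2004:2023, as.integer(names(counts)))
    if (rest > 0 && length(pool)) {
      per <- rest %/% length(pool)
      extra <- rest %% length(pool)
      filler <- rep(pool, per + (seq_along(pool) <= extra))
    } else filler <- integer(0)
    c(rep(as.integer(names(counts)), counts), filler)[seq_len(n)]
  }
  caseid <- sprintf("%08d", 10000000L + seq_len(n))
  primaryid <- .make_primaryid(caseid, rep(1L, n))
  demo <- data.frame(
    primaryid, caseid, caseversion = 1L,
    fda_dt = year_col(years) * 10000L + 601L,
    sex = fill_col(sex, "unspecified"), age = NA_real_,
    age_group = fill_col(age_group, "unspecified"),
    country = fill_col(country, "other"),
    reporter = fill_col(reporter, "unspecified"), latest = TRUE)
  out <- lapply(names(outcomes %||% integer(0)), function(cd)
    data.frame(primaryid = primaryid[seq_len(outcomes[[cd]])], outc_cod = cd))
  outcomes_df <- if (length(out)) do.call(rbind, out) else
    data.frame(primaryid = character(), outc_cod = character())
  report_set(demo,
             data.frame(primaryid, drug = drug, role = "PS"),
             data.frame(primaryid, pt = filler_pt, soc = NA_character_),
             outcomes_df)
}
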