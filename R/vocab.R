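#' Toy PT-to-SOC vocabulary shipped with the package
#'
#' MedDRA itself is licensed and cannot be redistributed, so the package ships
#' a small synthetic vocabulary of 56 Preferred Terms (PTs) mapped to nine
#' System Organ Classes (SOCs), flavoured after the leukotriene-antagonist
#' safety literature (sleep disturbance, neuropsychiatric and respiratory
#' terms). Each PT maps to exactly one primary SOC.
#'
#' @param path optional path to a user-supplied tab-separated mapping with
#'   columns `pt`, `pt_code`, `soc`, `soc_code` (codes may be omitted).
#' @return a `data.frame` with columns `pt`, `pt_code`, `soc`, `soc_code`.
#' @export
read_pt_soc_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "pt_soc_map.tsv",
                                package = "faersignal", mustWork = TRUE)
  map <- as.data.frame(data.table::fread(path, sep = "\t", colClasses = "character"))
  .assert(all(c("pt", "soc") %in% names(map)),
          "PT-to-SOC map needs at least columns 'pt' and 'soc'")
  if (is.null(map$pt_code)) map$pt_code <- NA_character_
  if (is.null(map$soc_code)) map$soc_code <- NA_character_
  .assert(!anyDuplicated(map$pt), "each PT must map to exactly one primary SOC")
  map[, c("pt", "pt_code", "soc", "soc_code")]
}

#' Toy drug-name normalization dictionary
#'
#' Maps verbatim drug strings (trade names, salt forms, spelling variants) to
#' canonical ingredient names. Matching is case- and whitespace-insensitive.
#'
#' @param path optional path to a two-column tab-separated file with columns
#'   `verbatim` and `canonical`.
#' @return a `data.frame` with columns `verbatim` and `canonical`.
#' @export
read_drug_dictionary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "drug_dictionary.tsv",
                                package = "faersignal", mustWork = TRUE)
  dict <- as.data.frame(data.table::fread(path, sep = "\t", colClasses = "character"))
  .assert(all(c("verbatim", "canonical") %in% names(dict)),
          "drug dictionary needs columns 'verbatim' and 'canonical'")
  dict
}

.default_drug_vocab <- function() {
  c("MONTELUKAST", "ASPIRIN", "PARACETAMOL", "IBUPROFEN",
    "CETIRIZINE", "PREDNISONE", "SALBUTAMOL", "FLUTICASONE")
}

# Default demographic mix: the marginal proportions of a large published
# montelukast report cohort (sex, age bins, top-5 countries plus an "other"
# pool, non-exclusive serious-outcome rates, reporter occupations) and a
# unimodal year distribution peaking in 2013. Probabilities are normalized at
# use; outcome entries are independent per-report Bernoulli rates.
default_demographic_mix <- function() {
  years <- 2004:2023
  wy <- stats::dnorm(years, mean = 2013, sd = 5)
  list(
    sex = c(male = 0.5301, female = 0.3733, unspecified = 0.0967),
    age_group = c("<18" = 0.3101, "18-44" = 0.1581, "45-64" = 0.1620,
                  "65-74" = 0.0641, ">=75" = 0.0356, unspecified = 0.2700),
    country = c(US = 0.5210, GB = 0.1814, CA = 0.0870, FR = 0.0248,
                JP = 0.0196, other = 0.1662),
    reporter = c(consumer = 0.3924, lawyer = 0.0146, physician = 0.2326,
                 "other health-professional" = 0.1803, pharmacist = 0.1180,
                 unspecified = 0.0622),
    outcomes = c(LT = 0.0702, HO = 0.2031, DS = 0.1124, DE = 0.0253),
    year = stats::setNames(wy / sum(wy), years)
  )
}

# age-bin boundaries: [0,18), [18,45), [45,65), [65,75), [75,inf)
.age_breaks <- c(0, 18, 45, 65, 75, Inf)
.age_labels <- c("<18", "18-44", "45-64", "65-74", ">=75")

.age_to_group <- function(age) {
  grp <- rep("unspecified", length(age))
  ok <- !is.na(age) & age >= 0 & age <= 120
  grp[ok] <- as.character(cut(age[ok], breaks = .age_breaks,
                              labels = .age_labels, right = FALSE))
  grp
}

# FAERS field codes <-> internal labels (bijective so files round-trip)
.sex_to_code <- c(male = "M", female = "F", unspecified = "UNK")
.code_to_sex <- stats::setNames(names(.sex_to_code), .sex_to_code)
.rep_to_code <- c(consumer = "CN", lawyer = "LW", physician = "MD",
                  "other health-professional" = "OT", pharmacist = "PH",
                  unspecified = "UNK")
.code_to_rep <- stats::setNames(names(.rep_to_code), .rep_to_code)
.outcome_codes <- c("DE", "DS", "HO", "LT")
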