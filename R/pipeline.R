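#' Configuration for the end-to-end screening pipeline
#'
#' @param mode `"synthetic"` (generate a report universe) or `"faers-dir"`
#'   (read an existing quarterly directory).
#' @param drug canonical target drug name.
#' @param input_dir FAERS-style quarterly directory (`mode = "faers-dir"`).
#' @param generator a [generator_config()] for `mode = "synthetic"`; its seed
#'   and duplicate rate are overridden by `seed` and itself respectively. By
#'   default a 10,000-report universe with one planted montelukast signal
#'   (Nightmare, relative rate 10) and a 10% duplicate rate.
#' @param pt_soc_map,drug_dictionary optional paths to user vocabularies;
#'   defaults to the shipped toy files.
#' @param thresholds a [signal_thresholds()] list.
#' @param rank_by `"ror"` or `"a"` for the top-PT table.
#' @param top_n row limit of the top-PT table.
#' @param output_dir directory for the five output files.
#' @param seed integer; every source of randomness in the run flows from it.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "faers-dir"),
                            drug = "MONTELUKAST",
                            input_dir = NULL,
                            generator = NULL,
                            pt_soc_map = NULL,
                            drug_dictionary = NULL,
                            thresholds = signal_thresholds(),
                            rank_by = "ror",
                            top_n = 50,
                            output_dir = tempfile("faersignal-run-"),
                            seed = 1L) {
  mode <- match.arg(mode)
  .assert(mode != "faers-dir" || !is.null(input_dir),
          "mode 'faers-dir' needs input_dir")
  .assert(is.numeric(top_n) && top_n >= 1, "top_n must be >= 1")
  if (mode == "synthetic" && is.null(generator))
    generator <- generator_config(
      n_reports = 10000,
      planted_signals = data.frame(drug = "MONTELUKAST", pt = "Nightmare",
                                   multiplier = 10),
      duplicate_rate = 0.1, seed = seed)
  if (!is.null(generator)) generator$seed <- as.integer(seed)
  structure(list(mode = mode, drug = drug, input_dir = input_dir,
                 generator = generator, pt_soc_map = pt_soc_map,
                 drug_dictionary = drug_dictionary, thresholds = thresholds,
                 rank_by = rank_by, top_n = as.integer(top_n),
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Executes the stage order of a spontaneous-report disproportionality
#' study: acquire reports (generate-write-read in synthetic mode, so the
#' file dialect is exercised end to end), normalize drug names, deduplicate
#' to the latest case version, attach SOC labels, summarize the
#' primary-suspect cohort, and screen every PT/SOC pair with the four
#' statistics and the conjunctive criteria. Writes five tab-separated
#' outputs to `config$output_dir`:
#' \describe{
#'   \item{stage_log.tsv}{case counts at each pipeline stage,}
#'   \item{cohort_summary.tsv}{descriptive characteristics of the cohort,}
#'   \item{soc_table.tsv}{SOC-level signal values ranked by case count,}
#'   \item{top_pt_table.tsv}{the top-N PT-level signals (default by ROR),}
#'   \item{signal_list.tsv}{the complete screen with every statistic and
#'     verdict.}
#' }
#' Identical config and seed yield byte-identical files.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the cleaned universe, cohort summary,
#'   screen, stage log and output paths.
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- list()

  if (config$mode == "synthetic") {
    gen <- generate_reports(config$generator)
    gen <- inject_duplicates(gen, config$generator$duplicate_rate,
                             seed = config$seed + 1L)
    qdir <- file.path(config$output_dir, "faers_quarter")
    write_faers_quarter(gen, qdir)
    raw <- read_faers_quarter(qdir)
  } else {
    raw <- read_faers_quarter(config$input_dir)
  }
  stage$raw_case_versions <- n_reports(raw)
  stage$distinct_cases <- length(unique(raw$demo$caseid))

  dict <- read_drug_dictionary(config$drug_dictionary)
  map <- read_pt_soc_map(config$pt_soc_map)
  clean <- normalize_drug_names(raw, dict)
  clean <- deduplicate_reports(clean)
  stage$after_dedup <- n_reports(clean)
  clean <- attach_soc(clean, map)

  cohort <- filter_primary_suspect(clean, config$drug)
  stage$primary_suspect_cohort <- n_reports(cohort)
  summary <- summarize_cohort(cohort)

  screen <- screen_signals(clean, config$drug, rank_by = config$rank_by,
                           thresholds = config$thresholds)
  soc_screen <- screen[screen$level == "SOC", , drop = FALSE]
  soc_screen <- soc_screen[order(-soc_screen$a, soc_screen$event), , drop = FALSE]
  pt_screen <- screen[screen$level == "PT", , drop = FALSE]

  paths <- file.path(config$output_dir,
                     c("stage_log.tsv", "cohort_summary.tsv", "soc_table.tsv",
                       "top_pt_table.tsv", "signal_list.tsv"))
  names(paths) <- c("stage_log", "cohort_summary", "soc_table",
                    "top_pt_table", "signal_list")
  log_df <- data.frame(stage = names(stage), cases = unlist(stage))
  data.table::fwrite(log_df, paths["stage_log"], sep = "\t", quote = FALSE,
                     eol = "\n")
  write_cohort_summary(summary, paths["cohort_summary"])
  data.table::fwrite(format_signal_table(soc_screen), paths["soc_table"],
                     sep = "\t", quote = FALSE, eol = "\n")
  data.table::fwrite(format_signal_table(pt_screen, top_n = config$top_n),
                     paths["top_pt_table"], sep = "\t", quote = FALSE,
                     eol = "\n")
  data.table::fwrite(
    cbind(screen[, c("drug", "event", "level", "soc", "a", "b", "c", "d", "N")],
          round(screen[, c("ror", "ror_ci_low", "ror_ci_high", "prr",
                           "prr_ci_low", "prr_ci_high", "chi2", "ic", "e_ic",
                           "v_ic", "ic_minus_2sd", "ebgm", "ebgm05",
                           "ebgm95")], 10),
          screen[, c("tier", "ror_pass", "prr_pass", "bcpnn_pass",
                     "ebgm_pass", "overall")]),
    paths["signal_list"], sep = "\t", quote = FALSE, eol = "\n")
  message(sprintf(
    "pipeline: %d case versions -> %d cases -> %d after dedup -> %d in PS cohort; %d overall signal(s)",
    stage$raw_case_versions, stage$distinct_cases, stage$after_dedup,
    stage$primary_suspect_cohort, sum(screen$overall)))
  invisible(list(universe = clean, cohort = cohort, summary = summary,
                 screen = screen, stages = stage, paths = paths))
}
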