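test_that("the quarterly files round-trip losslessly through write and read", {
  cfg <- toy_config(n = 300, seed = 51, duplicate_rate = 0.2)
  g <- inject_duplicates(generate_reports(cfg), 0.2, seed = 52)
  d <- withr::local_tempdir()
  paths <- write_faers_quarter(g, d)
  expect_setequal(basename(paths), c("DEMO.txt", "DRUG.txt", "REAC.txt", "OUTC.txt"))
  r <- read_faers_quarter(d)
  expect_true(report_sets_equal(g, r))
})

test_that("one report fans out to one DRUG row per drug and one REAC row per PT", {
  rs <- hand_reports(list(list(drugs = list(c("MONTELUKAST", "PS"),
                                            c("ASPIRIN", "C")),
                               pts = c("Nightmare", "Headache", "Cough"))))
  d <- withr::local_tempdir()
  write_faers_quarter(rs, d)
  expect_identical(nrow(read.delim(file.path(d, "DRUG.txt"), sep = "$")), 2L)
  expect_identical(nrow(read.delim(file.path(d, "REAC.txt"), sep = "$")), 3L)
})

test_that("a field containing the dollar delimiter is rejected", {
  rs <- hand_reports(list(list(drugs = list(c("BAD$NAME", "PS")),
                               pts = "Nightmare")))
  expect_error(write_faers_quarter(rs, withr::local_tempdir()), "delimiter")
})

test_that("orphan and malformed rows are dropped, warned about and counted", {
  rs <- hand_reports(list(list(drugs = list(c("MONTELUKAST", "PS")),
                               pts = "Nightmare")))
  d <- withr::local_tempdir()
  write_faers_quarter(rs, d)
  cat("9999999901$ASPIRIN$SS\n", file = file.path(d, "DRUG.txt"), append = TRUE)
  expect_warning(r <- read_faers_quarter(d), "no matching DEMO")
  expect_identical(r$counters$orphan_rows, 1L)
  expect_identical(nrow(r$drugs), 1L)
})

test_that("an empty REAC table leads to every case being rejected downstream", {
  rs <- hand_reports(list(list(drugs = list(c("MONTELUKAST", "PS")),
                               pts = "Nightmare")))
  d <- withr::local_tempdir()
  write_faers_quarter(rs, d)
  writeLines("primaryid$pt", file.path(d, "REAC.txt"))
  r <- read_faers_quarter(d)
  expect_warning(out <- deduplicate_reports(r), "no reported event")
  expect_identical(n_reports(out), 0L)
  expect_identical(out$counters$dropped_no_events, 1L)
})

test_that("deduplication keeps the highest version with documented tie-breaks", {
  demo <- data.frame(
    primaryid = c("C00101", "C00102", "C00103", "C00201", "C00202"),
    caseid = c("C001", "C001", "C001", "C002", "C002"),
    caseversion = c(1L, 2L, 3L, 1L, 1L),
    fda_dt = c(20100101L, 20110101L, 20120101L, 20100101L, 20110101L),
    sex = "male", age = NA_real_, age_group = "unspecified",
    country = "US", reporter = "physician")
  ev <- data.frame(primaryid = demo$primaryid, pt = "Nightmare",
                   soc = NA_character_)
  dr <- data.frame(primaryid = demo$primaryid, drug = "MONTELUKAST", role = "PS")
  oc <- data.frame(primaryid = character(), outc_cod = character())
  rs <- report_set(demo, dr, ev, oc)
  out <- deduplicate_reports(rs)
  # version beats date; equal versions fall back to the later date
  expect_setequal(out$demo$primaryid, c("C00103", "C00202"))
  expect_identical(deduplicate_reports(out)$demo, out$demo)  # idempotent
  expect_setequal(out$demo$caseid, unique(demo$caseid))
})

test_that("deduplication recovers the generator's ground-truth latest versions", {
  cfg <- toy_config(n = 100, seed = 61)
  gd <- inject_duplicates(generate_reports(cfg), 0.25, seed = 62)
  out <- deduplicate_reports(gd)
  expect_setequal(out$demo$primaryid, gd$demo$primaryid[gd$demo$latest])
  expect_identical(n_reports(out), 100L)
})

test_that("cleaning is insensitive to input row order", {
  cfg <- toy_config(n = 150, seed = 71, duplicate_rate = 0.2)
  gd <- inject_duplicates(generate_reports(cfg), 0.2, seed = 72)
  set.seed(73)
  shuffled <- report_set(gd$demo[sample(nrow(gd$demo)), ],
                         gd$drugs[sample(nrow(gd$drugs)), ],
                         gd$events[sample(nrow(gd$events)), ],
                         gd$outcomes[sample(nrow(gd$outcomes)), ])
  a <- attach_soc(deduplicate_reports(normalize_drug_names(gd)))
  b <- attach_soc(deduplicate_reports(normalize_drug_names(shuffled)))
  expect_true(report_sets_equal(a, b))
})

test_that("drug names normalize case/whitespace-insensitively with counters", {
  rs <- hand_reports(list(
    list(drugs = list(c("SINGULAIR", "PS")), pts = "Nightmare"),
    list(drugs = list(c("montelukast  sodium", "PS")), pts = "Nightmare"),
    list(drugs = list(c("Montelukast", "PS")), pts = "Nightmare"),
    list(drugs = list(c("XYZZY", "C"), c("ASPIRIN", "PS")), pts = "Headache")))
  out <- normalize_drug_names(rs)
  expect_setequal(out$drugs$drug[out$drugs$role == "PS"],
                  c("MONTELUKAST", "ASPIRIN"))
  expect_identical(sum(out$drugs$drug == "MONTELUKAST"), 3L)
  expect_identical(out$drugs$drug[out$drugs$drug == "XYZZY"], "XYZZY")
  expect_identical(out$counters$unmapped_drugs, 1L)
  expect_identical(normalize_drug_names(out)$drugs, out$drugs)  # fixed point
})

test_that("primary-suspect filtering keeps PS reports and drops others", {
  rs <- hand_reports(list(
    list(drugs = list(c("MONTELUKAST", "PS")), pts = "Nightmare"),
    list(drugs = list(c("MONTELUKAST", "C")), pts = "Nightmare"),
    list(drugs = list(c("MONTELUKAST", "SS"), c("MONTELUKAST", "PS")),
         pts = "Cough"),
    list(drugs = list(c("ASPIRIN", "PS"), c("MONTELUKAST", "I")),
         pts = "Headache")))
  out <- filter_primary_suspect(rs, "MONTELUKAST")
  expect_setequal(out$demo$primaryid, rs$demo$primaryid[c(1, 3)])
})

test_that("SOC attachment maps PTs and routes unknown PTs to the sentinel", {
  rs <- hand_reports(list(
    list(drugs = list(c("MONTELUKAST", "PS")),
         pts = c("Nightmare", "Aggression", "Mystery term"))))
  out <- attach_soc(rs)
  soc <- setNames(out$events$soc, out$events$pt)
  expect_identical(unname(soc["Nightmare"]), "Psychiatric disorders")
  expect_identical(soc[["Nightmare"]], soc[["Aggression"]])
  expect_identical(unname(soc["Mystery term"]), "UNMAPPED")
  expect_identical(out$counters$unmapped_pts, 1L)
})
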