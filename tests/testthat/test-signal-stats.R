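# Frozen expected values were computed with the mpmath referee
# (inst/oracle/signal_oracle.py) at 50 significant digits.

test_that("statistics match frozen high-precision values on reference tables", {
  t1 <- c(10, 20, 30, 40)
  r <- compute_ror(t1)
  expect_equal(r$ror, 2 / 3, tolerance = 1e-12)
  expect_equal(r$ci_low, 0.27251036778097693, tolerance = 1e-12)
  expect_equal(r$ci_high, 1.6309267352413359, tolerance = 1e-12)
  p <- compute_prr(t1)
  expect_equal(p$prr, 7 / 9, tolerance = 1e-12)
  expect_equal(p$chi2, 0.79365079365079365, tolerance = 1e-12)
  bc <- compute_bcpnn(t1)
  expect_equal(bc$ic, -0.26303440583379383, tolerance = 1e-12)
  expect_equal(bc$e_ic, -0.26483175919365011, tolerance = 1e-12)
  expect_equal(bc$v_ic, 0.24476611960101319, tolerance = 1e-12)
  expect_equal(bc$ic_minus_2sd, -1.2543086302745525, tolerance = 1e-12)
  e <- compute_ebgm(t1)
  expect_equal(e$ebgm, 5 / 6, tolerance = 1e-12)
  expect_equal(e$ebgm05, 0.34063795972622116, tolerance = 1e-12)

  expect_equal(compute_ror(c(3, 1, 1, 3))$ror, 9, tolerance = 1e-12)

  # b = 0: PRR finite, the 1/a - 1/(a+b) SE term vanishes
  p0 <- compute_prr(c(3, 0, 10, 100))
  expect_equal(p0$prr, 11, tolerance = 1e-12)
  expect_equal(p0$ci_low, 6.0917356275149984, tolerance = 1e-12)
  expect_equal(p0$ci_high, 19.862976235125871, tolerance = 1e-12)
  expect_equal(p0$chi2, 23.706293706293706, tolerance = 1e-12)
})

test_that("balanced and degenerate tables behave as the formulas dictate", {
  bal <- c(5, 5, 5, 5)
  expect_equal(compute_ror(bal)$ror, 1)
  expect_lt(compute_ror(bal)$ci_low, 1)
  expect_gt(compute_ror(bal)$ci_high, 1)
  expect_equal(compute_prr(bal)$prr, 1)
  expect_equal(compute_prr(bal)$chi2, 0)
  expect_equal(compute_ebgm(bal)$ebgm, 1)
  v <- evaluate_criteria(compute_ror(bal), compute_prr(bal),
                         compute_bcpnn(bal), compute_ebgm(bal), a = 5)
  expect_false(v$overall)

  # zero cell: frequentist statistics undefined, priors keep BCPNN finite
  z <- c(0, 10, 5, 100)
  expect_false(compute_ror(z)$defined)
  expect_true(is.na(compute_ror(z)$ror))
  bz <- compute_bcpnn(z)
  expect_true(is.finite(bz$e_ic))
  expect_lte(bz$ic_minus_2sd, 0)
  expect_identical(bz$tier, "none")
  # Haldane-Anscombe correction recovers a defined estimate when asked
  expect_true(compute_ror(z, haldane = TRUE)$defined)
})

test_that("EBGM equals 2^IC and chi-square vanishes exactly when ad = bc", {
  tabs <- random_tables(200, seed = 91)
  s <- signal_stats_frame(tabs)
  expect_equal(s$ebgm, 2^s$ic, tolerance = 1e-12)
  expect_equal(s$chi2 == 0, with(tabs, a * d - b * c) == 0)
  prop <- data.frame(a = 6, b = 10, c = 3, d = 5)  # ad = bc
  expect_identical(signal_stats_frame(prop)$chi2, 0)
  expect_equal(signal_stats_frame(prop)$prr, 1)
})

test_that("ROR is monotone increasing in a with the other cells fixed", {
  ror <- vapply(1:30, function(a) compute_ror(c(a, 20, 30, 40))$ror, 0)
  expect_true(all(diff(ror) > 0))
})

test_that("shrinkage washes out as all cells scale up", {
  base <- c(10, 20, 30, 40)
  gap <- vapply(c(1, 10, 100, 1000), function(k) {
    b <- compute_bcpnn(base * k)
    abs(b$e_ic - b$ic)
  }, 0)
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[4], 1e-3)
  vic <- vapply(c(1, 10, 100, 1000),
                function(k) compute_bcpnn(base * k)$v_ic, 0)
  expect_true(all(diff(vic) < 0))
  b <- compute_bcpnn(base * 1000)
  expect_lt(abs(b$ic_minus_2sd - b$e_ic), 0.05)
})

test_that("IC-2SD tiers follow the published thresholds", {
  expect_identical(faersignal:::.ic_tier(c(-1, 0, 0.2, 1.5, 2, 3, 3.1)),
                   c("none", "none", "weak", "weak", "medium", "medium",
                     "strong"))
})

test_that("the four-method criteria gate exactly as specified", {
  mk <- function(a, ror_lo = 1.2, prr = 2.5, chi2 = 5, ic2sd = 0.1,
                 ebgm05 = 2.1) {
    evaluate_criteria(list(ror = 2, ci_low = ror_lo, ci_high = 9),
                      list(prr = prr, ci_low = ror_lo, ci_high = 9,
                           chi2 = chi2),
                      list(ic_minus_2sd = ic2sd),
                      list(ebgm = 3, ebgm05 = ebgm05), a = a)
  }
  expect_true(mk(3)$overall)            # all thresholds crossed
  expect_false(mk(2)$overall)           # a >= 3 gates ROR and PRR
  expect_false(mk(2)$ror_pass)
  expect_false(mk(3, ror_lo = 1)$overall)     # CI lower limit must exceed 1
  expect_false(mk(3, prr = 1.9)$prr_pass)
  expect_false(mk(3, chi2 = 3.9)$prr_pass)
  expect_false(mk(3, ic2sd = 0)$bcpnn_pass)
  expect_false(mk(3, ebgm05 = 2)$ebgm_pass)
  # undefined statistics fail their criterion
  na <- mk(3, ror_lo = NA)
  expect_false(na$ror_pass)
})

test_that("all statistics agree with the mpmath referee on random tables", {
  tabs <- random_tables(250, seed = 101)
  mine <- signal_stats_frame(tabs)
  ref <- oracle_stats(tabs)
  for (col in names(ref))
    expect_lt(max(rel_err(mine[[col]], ref[[col]])), 1e-10)
})

test_that("the null 95% ROR interval excludes 1 at close to the nominal rate", {
  set.seed(111)
  n1 <- 500; n0 <- 2000; p <- 0.1
  excl <- replicate(1000, {
    a <- rbinom(1, n1, p); cc <- rbinom(1, n0, p)
    r <- compute_ror(c(a, n1 - a, cc, n0 - cc))
    !is.na(r$ci_low) && (r$ci_low > 1 || r$ci_high < 1)
  })
  expect_gt(mean(excl), 0.03)
  expect_lt(mean(excl), 0.07)
})

test_that("screening ranks a strong planted signal first and keeps full schema", {
  cfg <- toy_config(n = 4000, seed = 121,
                    planted_signals = data.frame(drug = "MONTELUKAST",
                                                 pt = "Nightmare",
                                                 multiplier = 20))
  rs <- attach_soc(deduplicate_reports(generate_reports(cfg)))
  sc <- screen_signals(rs, "MONTELUKAST")
  pt <- sc[sc$level == "PT", ]
  expect_identical(pt$event[1], "Nightmare")
  expect_true(pt$overall[1])
  expect_true(all(c("a", "ror", "ror_ci_low", "prr", "chi2", "e_ic",
                    "ic_minus_2sd", "ebgm", "ebgm05", "overall") %in%
                    names(sc)))
  # conjunction is never more permissive than any single criterion
  for (flag in c("ror_pass", "prr_pass", "bcpnn_pass", "ebgm_pass"))
    expect_true(all(sc[[flag]][sc$overall]))
  expect_true(all(diff(pt$ror) <= 0 | is.na(diff(pt$ror))))
})
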