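## Disproportionality statistics for 2x2 report tables.
##
## All four statistics are frequentist or shrinkage functions of the cells
## (a, b, c, d) with N = a+b+c+d:
##   ROR  = ad/bc, CI on the log scale with SE sqrt(1/a+1/b+1/c+1/d)
##   PRR  = [a/(a+b)] / [c/(c+d)], CI with SE sqrt(1/a-1/(a+b)+1/c-1/(c+d)),
##          plus the uncorrected chi-square (ad-bc)^2 N / ((a+b)(a+c)(c+d)(b+d))
##   BCPNN information component with conjugate shrinkage priors
##          alpha1 = beta1 = 1, alpha = beta = 2, gamma11 = 1
##   EBGM = aN/((a+c)(a+b)), the unshrunk relative reporting ratio, with a
##          log-scale CI using the ROR standard error
## The EBGM here is deliberately the plain observed/expected ratio (so
## EBGM = 2^IC holds exactly); a gamma-mixture empirical-Bayes shrinkage
## backend is a possible future extension, not implemented.

.z95 <- 1.96

.ror_vec <- function(a, b, c, d) {
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- ifelse(ok, a * d / (b * c), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  data.frame(ror = ror, ror_ci_low = exp(log(ror) - .z95 * se),
             ror_ci_high = exp(log(ror) + .z95 * se))
}

.prr_vec <- function(a, b, c, d, yates = FALSE) {
  N <- a + b + c + d
  ok <- (a + b) > 0 & c > 0
  prr <- ifelse(ok, (a / (a + b)) / (c / (c + d)), NA_real_)
  # the SE term 1/a - 1/(a+b) vanishes when b = 0; a = 0 leaves the CI undefined
  se <- ifelse(ok & a > 0, sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d)),
               NA_real_)
  mok <- (a + b) > 0 & (a + c) > 0 & (c + d) > 0 & (b + d) > 0
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(0, dev - N / 2)
  chi2 <- ifelse(mok, dev^2 * N / ((a + b) * (a + c) * (c + d) * (b + d)),
                 NA_real_)
  data.frame(prr = prr, prr_ci_low = exp(log(prr) - .z95 * se),
             prr_ci_high = exp(log(prr) + .z95 * se), chi2 = chi2)
}

.bcpnn_priors <- c(alpha1 = 1, beta1 = 1, alpha = 2, beta = 2, gamma11 = 1)

.bcpnn_vec <- function(a, b, c, d) {
  N <- a + b + c + d
  p <- .bcpnn_priors
  ic <- log2(a * N / ((a + b) * (a + c)))
  g <- p["gamma11"] * (N + p["alpha"]) * (N + p["beta"]) /
    ((a + b + p["alpha1"]) * (a + c + p["beta1"]))
  e_ic <- log2((a + p["gamma11"]) * (N + p["alpha"]) * (N + p["beta"]) /
                 ((N + g) * (a + b + p["alpha1"]) * (a + c + p["beta1"])))
  v_ic <- (1 / log(2)^2) * (
    (N - a + g - p["gamma11"]) / ((a + p["gamma11"]) * (1 + N + g)) +
      (N - (a + b) + p["alpha"] - p["alpha1"]) /
      ((a + b + p["alpha1"]) * (1 + N + p["alpha"])) +
      (N - (a + c) + p["beta"] - p["beta1"]) /
      ((a + c + p["beta1"]) * (1 + N + p["beta"])))
  ic2sd <- e_ic - 2 * sqrt(v_ic)
  data.frame(ic = ic, e_ic = unname(e_ic), v_ic = unname(v_ic),
             ic_minus_2sd = unname(ic2sd), tier = .ic_tier(ic2sd))
}

# signal tiers on the IC-2SD scale
.ic_tier <- function(ic2sd) {
  unname(c("none", "weak", "medium", "strong")[
    findInterval(ic2sd, c(-Inf, 0, 1.5, 3), left.open = TRUE)])
}

.ebgm_vec <- function(a, b, c, d) {
  N <- a + b + c + d
  ok <- (a + b) > 0 & (a + c) > 0
  ebgm <- ifelse(ok, a * N / ((a + c) * (a + b)), NA_real_)
  ci_ok <- a > 0 & b > 0 & c > 0 & d > 0
  se <- ifelse(ci_ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  data.frame(ebgm = ebgm, ebgm05 = exp(log(ebgm) - .z95 * se),
             ebgm95 = exp(log(ebgm) + .z95 * se))
}

.cells <- function(t) {
  if (inherits(t, "contingency_table")) c(t$a, t$b, t$c, t$d)
  else {
    .assert(is.numeric(t) && length(t) == 4 && all(t >= 0),
            "expected a contingency_table or a numeric vector c(a, b, c, d)")
    t
  }
}

#' Reporting odds ratio
#'
#' Point estimate `ad/bc` with a 95% CI on the log scale,
#' `exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. With any zero cell the
#' statistic is flagged undefined (`NA`); no continuity correction is applied
#' unless `haldane = TRUE` (Haldane-Anscombe +0.5 on every cell).
#'
#' @param t a [build_table()] result or numeric `c(a, b, c, d)`.
#' @param haldane apply the +0.5 continuity correction first.
#' @return list with `ror`, `ci_low`, `ci_high`, `defined`.
#' @export
compute_ror <- function(t, haldane = FALSE) {
  x <- .cells(t) + if (haldane) 0.5 else 0
  r <- .ror_vec(x[1], x[2], x[3], x[4])
  list(ror = r$ror, ci_low = r$ror_ci_low, ci_high = r$ror_ci_high,
       defined = !is.na(r$ror))
}

#' Proportional reporting ratio and chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]` with a log-scale 95% CI using
#' `SE = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`, and the uncorrected
#' chi-square `(ad-bc)^2 N / ((a+b)(a+c)(c+d)(b+d))`. `c = 0` leaves the
#' statistic undefined; `b = 0` is fine (the first SE term vanishes).
#'
#' @inheritParams compute_ror
#' @param yates apply the Yates continuity correction to the chi-square.
#' @return list with `prr`, `ci_low`, `ci_high`, `chi2`, `defined`.
#' @export
compute_prr <- function(t, haldane = FALSE, yates = FALSE) {
  x <- .cells(t) + if (haldane) 0.5 else 0
  r <- .prr_vec(x[1], x[2], x[3], x[4], yates = yates)
  list(prr = r$prr, ci_low = r$prr_ci_low, ci_high = r$prr_ci_high,
       chi2 = r$chi2, defined = !is.na(r$prr))
}

#' BCPNN information component with shrinkage priors
#'
#' The naive information component `IC = log2(aN / ((a+b)(a+c)))` and its
#' Bayesian posterior summaries under the standard conjugate priors
#' `alpha1 = beta1 = 1`, `alpha = beta = 2`, `gamma11 = 1` with
#' `gamma = gamma11 (N+alpha)(N+beta) / ((a+b+alpha1)(a+c+beta1))`:
#' `E(IC)`, `V(IC)`, and the lower signal bound `IC-2SD = E(IC) - 2 sqrt(V(IC))`.
#' The priors regularize zero cells, so every output is finite for `N > 0`
#' (the naive IC itself is `-Inf` at `a = 0`). Signal tiers on IC-2SD:
#' none `<= 0` < weak `<= 1.5` < medium `<= 3` < strong.
#'
#' @inheritParams compute_ror
#' @return list with `ic`, `e_ic`, `v_ic`, `ic_minus_2sd`, `tier`.
#' @export
compute_bcpnn <- function(t) {
  x <- .cells(t)
  .assert(sum(x) > 0, "BCPNN needs N > 0")
  r <- .bcpnn_vec(x[1], x[2], x[3], x[4])
  as.list(r)
}

#' Unshrunk empirical Bayes geometric mean
#'
#' `EBGM = aN / ((a+c)(a+b))`, the observed-to-expected relative reporting
#' ratio (identically `2^IC`), with 95% bounds
#' `exp(ln EBGM +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. The CI requires all
#' cells positive; the point estimate only needs both margins positive.
#'
#' @inheritParams compute_ror
#' @return list with `ebgm`, `ebgm05`, `ebgm95`, `defined` (CI defined).
#' @export
compute_ebgm <- function(t, haldane = FALSE) {
  x <- .cells(t) + if (haldane) 0.5 else 0
  r <- .ebgm_vec(x[1], x[2], x[3], x[4])
  list(ebgm = r$ebgm, ebgm05 = r$ebgm05, ebgm95 = r$ebgm95,
       defined = !is.na(r$ebgm05))
}

#' Default positive-signal thresholds
#'
#' The conjunctive screening rule: ROR requires `a >= 3` and CI lower limit
#' `> 1`; PRR additionally requires `PRR >= 2` and `chi2 >= 4`; BCPNN
#' requires `IC-2SD > 0`; MGPS requires `EBGM05 > 2`. A pair is a signal only
#' if all four methods pass at once.
#'
#' @param min_a minimum co-report count for ROR and PRR.
#' @param ror_ci_low,prr_ci_low exclusive lower-CI thresholds.
#' @param prr_min,chi2_min inclusive PRR and chi-square thresholds.
#' @param ic2sd_min exclusive IC-2SD threshold.
#' @param ebgm05_min exclusive EBGM05 threshold.
#' @return a named list of thresholds.
#' @export
signal_thresholds <- function(min_a = 3, ror_ci_low = 1, prr_ci_low = 1,
                              prr_min = 2, chi2_min = 4, ic2sd_min = 0,
                              ebgm05_min = 2) {
  th <- list(min_a = min_a, ror_ci_low = ror_ci_low, prr_ci_low = prr_ci_low,
             prr_min = prr_min, chi2_min = chi2_min, ic2sd_min = ic2sd_min,
             ebgm05_min = ebgm05_min)
  .assert(all(unlist(th) >= 0), "thresholds must be non-negative")
  th
}

.verdict_vec <- function(a, ror_ci_low, prr, prr_ci_low, chi2, ic_minus_2sd,
                         ebgm05, th = signal_thresholds()) {
  pass <- function(x) !is.na(x) & x
  ror_pass <- pass(a >= th$min_a & ror_ci_low > th$ror_ci_low)
  prr_pass <- pass(a >= th$min_a & prr_ci_low > th$prr_ci_low &
                     prr >= th$prr_min & chi2 >= th$chi2_min)
  bcpnn_pass <- pass(ic_minus_2sd > th$ic2sd_min)
  ebgm_pass <- pass(ebgm05 > th$ebgm05_min)
  data.frame(ror_pass, prr_pass, bcpnn_pass, ebgm_pass,
             overall = ror_pass & prr_pass & bcpnn_pass & ebgm_pass)
}

#' Evaluate the four-method signal criteria
#'
#' Applies the thresholds of [signal_thresholds()] to the four statistic
#' results for one table. An undefined statistic fails its criterion. The
#' overall verdict is the conjunction of all four methods, so it can never be
#' more permissive than any single one.
#'
#' @param ror,prr,bcpnn,ebgm results of the four `compute_*` functions.
#' @param a the co-report count of the table.
#' @param thresholds a [signal_thresholds()] list.
#' @return list of class `signal_verdict` with per-method logicals and
#'   `overall`.
#' @export
evaluate_criteria <- function(ror, prr, bcpnn, ebgm, a,
                              thresholds = signal_thresholds()) {
  v <- .verdict_vec(a, ror$ci_low, prr$prr, prr$ci_low, prr$chi2,
                    bcpnn$ic_minus_2sd, ebgm$ebgm05, thresholds)
  structure(as.list(v), class = "signal_verdict")
}

#' Screen every drug-event pair for signals
#'
#' Runs the full disproportionality screen for one target drug: builds all
#' PT- and SOC-level 2x2 tables ([build_all_tables()]), computes the four
#' statistics for each, applies the conjunctive criteria, and ranks the
#' result (descending ROR by default, matching published top-PT tables;
#' `"a"` ranks by case count as SOC-level tables usually are).
#'
#' @param reports the cleaned, deduplicated universe with SOCs attached.
#' @param drug canonical target drug name.
#' @param rank_by `"ror"` or `"a"`.
#' @param thresholds a [signal_thresholds()] list.
#' @param haldane apply the +0.5 continuity correction to ROR/PRR/EBGM.
#' @return a `data.frame` of class `signal_screen`: one row per pair with
#'   the table cells, every statistic with its interval, the per-method
#'   pass flags and the overall verdict.
#' @export
screen_signals <- function(reports, drug, rank_by = c("ror", "a"),
                           thresholds = signal_thresholds(), haldane = FALSE) {
  rank_by <- match.arg(rank_by)
  tab <- build_all_tables(reports, drug)
  res <- cbind(tab, signal_stats_frame(tab, haldane = haldane,
                                       thresholds = thresholds))
  ord <- if (rank_by == "ror")
    order(-ifelse(is.na(res$ror), -Inf, res$ror), -res$a, res$event)
  else order(-res$a, res$event)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("signal_screen", "data.frame")
  res
}

#' Vectorized statistics for a frame of 2x2 tables
#'
#' The computational core behind [screen_signals()]: takes a data.frame with
#' columns `a`, `b`, `c`, `d` and returns all statistic, interval, tier and
#' verdict columns, row for row.
#'
#' @param tab data.frame with integer columns `a`, `b`, `c`, `d`.
#' @param haldane apply the +0.5 continuity correction to ROR/PRR/EBGM.
#' @param thresholds a [signal_thresholds()] list.
#' @return a `data.frame` of statistic columns.
#' @export
signal_stats_frame <- function(tab, haldane = FALSE,
                               thresholds = signal_thresholds()) {
  h <- if (haldane) 0.5 else 0
  a <- tab$a + h; b <- tab$b + h; c <- tab$c + h; d <- tab$d + h
  out <- cbind(.ror_vec(a, b, c, d), .prr_vec(a, b, c, d),
               .bcpnn_vec(a, b, c, d), .ebgm_vec(a, b, c, d))
  cbind(out, .verdict_vec(tab$a, out$ror_ci_low, out$prr, out$prr_ci_low,
                          out$chi2, out$ic_minus_2sd, out$ebgm05, thresholds))
}

#' Format a screen in the style of published signal tables
#'
#' Collapses estimate and interval into `"est(lo, hi)"` text columns --
#' `ROR(95% CI)`, `PRR(chi2)`, `IC(IC-2SD)`, `EBGM(EBGM05)` -- rounded to
#' 2 decimals, with SOC, PT and case-report count up front.
#'
#' @param screen a [screen_signals()] result.
#' @param top_n optional row limit after ranking.
#' @return a character-column `data.frame` ready for [write_tables()].
#' @export
format_signal_table <- function(screen, top_n = NULL) {
  if (!is.null(top_n)) screen <- utils::head(screen, top_n)
  f <- function(x) sprintf("%.2f", round_half_up(x, 2))
  data.frame(
    soc = screen$soc, event = screen$event, level = screen$level,
    case_reports = screen$a,
    ror_ci = sprintf("%s(%s, %s)", f(screen$ror), f(screen$ror_ci_low),
                     f(screen$ror_ci_high)),
    prr_chi2 = sprintf("%s(%s)", f(screen$prr), f(screen$chi2)),
    ic_ic2sd = sprintf("%s(%s)", f(screen$e_ic), f(screen$ic_minus_2sd)),
    ebgm_ebgm05 = sprintf("%s(%s)", f(screen$ebgm), f(screen$ebgm05)),
    signal = ifelse(screen$overall, "yes", "no"))
}
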