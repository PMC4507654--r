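#' Bland-Altman statistics of paired differences
#'
#' Differences are taken as `reference - estimate`; the SD uses the n-1
#' sample convention.
#'
#' @param est,ref equal-length numeric vectors, mmHg.
#' @return list with `mean_diff` and `sd_diff`, mmHg.
#' @export
bland_altman <- function(est, ref) {
  if (length(est) != length(ref)) stop("length mismatch")
  if (length(est) < 2L) stop("need at least 2 pairs")
  d <- ref - est
  list(mean_diff = mean(d), sd_diff = stats::sd(d))
}

#' Cumulative percentages of absolute differences within 5/10/15 mmHg
#'
#' Boundaries are inclusive: a difference of exactly 5 mmHg counts toward
#' the 5 mmHg percentage.
#'
#' @inheritParams bland_altman
#' @return named numeric vector `c(pct5, pct10, pct15)`, percentages.
#' @export
cumulative_percentages <- function(est, ref) {
  if (length(est) != length(ref)) stop("length mismatch")
  if (length(est) < 1L) stop("need at least 1 pair")
  d <- abs(ref - est)
  c(pct5 = 100 * mean(d <= 5), pct10 = 100 * mean(d <= 10),
    pct15 = 100 * mean(d <= 15))
}

## BHS grading thresholds: all three cumulative percentages must reach the
## row's values.
bhs_table <- data.frame(grade = c("A", "B", "C"),
                        p5 = c(60, 50, 40),
                        p10 = c(85, 75, 65),
                        p15 = c(95, 90, 85))

#' BHS grade from cumulative percentages
#'
#' Grade A requires (>= 60, >= 85, >= 95) within 5/10/15 mmHg, grade B
#' (>= 50, >= 75, >= 90), grade C (>= 40, >= 65, >= 85); anything worse is
#' grade D. All three percentages must meet the row.
#'
#' @param pct5,pct10,pct15 cumulative percentages in \[0, 100\].
#' @return a single character grade, `"A"`-`"D"`.
#' @export
bhs_grade <- function(pct5, pct10, pct15) {
  p <- c(pct5, pct10, pct15)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 100))
    stop("percentages must lie in [0, 100]")
  for (i in seq_len(nrow(bhs_table))) {
    if (pct5 >= bhs_table$p5[i] && pct10 >= bhs_table$p10[i] &&
        pct15 >= bhs_table$p15[i])
      return(bhs_table$grade[i])
  }
  "D"
}

## AAMI: upper SD limit of paired differences by |mean difference|,
## tabulated in 0.5 mmHg steps.
aami_table <- data.frame(mean_abs = seq(0, 5, by = 0.5),
                         sd_limit = c(6.95, 6.93, 6.87, 6.78, 6.65, 6.47,
                                      6.25, 5.97, 5.64, 5.24, 4.81))

#' AAMI mean/SD criterion
#'
#' Fails outright when `|mean_diff| > 5` mmHg. Otherwise the SD limit is
#' read from the tabulated 0.5 mmHg steps with `|mean_diff|` rounded up to
#' the next step (conservative), and the device passes when
#' `sd_diff <= limit`.
#'
#' @param mean_diff,sd_diff mean and SD of paired differences, mmHg.
#' @return list with `pass` (logical) and `sd_limit` (mmHg, `NA` when the
#'   mean alone fails).
#' @export
aami_check <- function(mean_diff, sd_diff) {
  stopifnot(is.finite(mean_diff), is.finite(sd_diff))
  m <- abs(mean_diff)
  if (m > 5) return(list(pass = FALSE, sd_limit = NA_real_))
  lim <- aami_table$sd_limit[ceiling(m / 0.5 - 1e-12) + 1L]
  list(pass = sd_diff <= lim, sd_limit = lim)
}

#' Full device-grading report
#'
#' Combines Bland-Altman statistics, BHS cumulative percentages and grade,
#' and the AAMI verdict for one set of paired estimates.
#'
#' @inheritParams bland_altman
#' @return object of class `bp_eval_report` with fields `n`, `mean_diff`,
#'   `sd_diff`, `cum_pct`, `bhs_grade`, `aami_pass`, `aami_sd_limit`.
#' @export
eval_report <- function(est, ref) {
  keep <- is.finite(est) & is.finite(ref)
  est <- est[keep]; ref <- ref[keep]
  ba <- bland_altman(est, ref)
  cp <- cumulative_percentages(est, ref)
  aami <- aami_check(ba$mean_diff, ba$sd_diff)
  structure(list(n = length(est), mean_diff = ba$mean_diff,
                 sd_diff = ba$sd_diff, cum_pct = cp,
                 bhs_grade = bhs_grade(cp[1L], cp[2L], cp[3L]),
                 aami_pass = aami$pass, aami_sd_limit = aami$sd_limit),
            class = "bp_eval_report")
}

#' @export
print.bp_eval_report <- function(x, ...) {
  cat(sprintf(paste0("<bp_eval_report: n = %d, diff %.1f +/- %.1f mmHg, ",
                     "within 5/10/15 mmHg: %.0f/%.0f/%.0f%%, BHS %s, ",
                     "AAMI %s>\n"),
              x$n, x$mean_diff, x$sd_diff, x$cum_pct[1L], x$cum_pct[2L],
              x$cum_pct[3L], x$bhs_grade,
              if (isTRUE(x$aami_pass)) "pass" else "fail"))
  invisible(x)
}
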