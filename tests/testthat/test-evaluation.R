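test_that("Bland-Altman statistics use reference minus estimate and n-1 SD", {
  expect_equal(bland_altman(c(1, 2, 3), c(1, 2, 3)),
               list(mean_diff = 0, sd_diff = 0))
  ba <- bland_altman(est = c(0, 1), ref = c(1, 0))  # d = (1, -1)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2))

  set.seed(8)
  est <- rnorm(100, 100, 10); ref <- est + rnorm(100, 0, 5)
  ba <- bland_altman(est, ref)
  oracle <- two_pass_stats(ref - est)
  expect_equal(ba$mean_diff, oracle$mean, tolerance = 1e-12)
  expect_equal(ba$sd_diff, oracle$sd, tolerance = 1e-12)

  expect_error(bland_altman(1:3, 1:4), "length mismatch")
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("cumulative percentages count inclusive boundaries", {
  ref <- c(0, 6, 12, 20)
  expect_equal(unname(cumulative_percentages(rep(0, 4), ref)),
               c(25, 50, 75))
  expect_equal(unname(cumulative_percentages(rep(0, 3), c(5, 10, 15))),
               c(100 / 3, 200 / 3, 100))
  expect_equal(unname(cumulative_percentages(rep(0, 3), c(16, 20, 30))),
               c(0, 0, 0))
})

test_that("BHS grade boundaries are reproduced exactly", {
  expect_equal(bhs_grade(60, 85, 95), "A")
  expect_equal(bhs_grade(50, 75, 90), "B")
  expect_equal(bhs_grade(40, 65, 85), "C")
  expect_equal(bhs_grade(39, 65, 85), "D")
  expect_equal(bhs_grade(59.9, 85, 95), "B")
  expect_equal(bhs_grade(100, 100, 94.9), "B")
  expect_error(bhs_grade(101, 50, 50), "0, 100")
})

test_that("published percentage triples map to their reported grades", {
  rows <- list(
    list(c(30, 61, 74), "D"), list(c(43, 61, 79), "D"),
    list(c(55, 84, 90), "B"), list(c(70, 89, 95), "A"),
    list(c(53, 84, 93), "B"), list(c(58, 86, 95), "B"),
    list(c(54, 79, 91), "B"), list(c(63, 87, 94), "B"),
    list(c(50, 84, 93), "B"), list(c(61, 86, 94), "B"),
    list(c(50, 79, 86), "C"), list(c(73, 89, 95), "A"),
    list(c(55, 80, 93), "B"), list(c(55, 85, 96), "B"),
    list(c(55, 89, 98), "B"), list(c(71, 92, 95), "A"),
    list(c(60, 86, 94), "B"), list(c(60, 88, 94), "B"),
    list(c(65, 89, 94), "B"), list(c(55, 83, 91), "B"),
    list(c(69, 89, 94), "B"), list(c(58, 87, 93), "B"),
    list(c(64, 89, 94), "B"), list(c(53, 81, 91), "B"),
    list(c(58, 84, 94), "B"), list(c(59, 89, 98), "B"),
    list(c(58, 88, 98), "B"), list(c(58, 85, 95), "B"),
    list(c(63, 91, 98), "A"), list(c(66, 94, 98), "A"),
    list(c(68, 90, 95), "A"), list(c(98, 100, 100), "A"),
    list(c(100, 100, 100), "A"))
  for (r in rows)
    expect_equal(bhs_grade(r[[1]][1], r[[1]][2], r[[1]][3]), r[[2]])
})

test_that("the AAMI SD limit table and verdicts are reproduced", {
  expect_equal(aami_check(0, 6.95), list(pass = TRUE, sd_limit = 6.95))
  expect_equal(aami_check(0, 6.96)$pass, FALSE)
  # tabulated rows at the 0.5 mmHg steps
  steps <- seq(0, 5, by = 0.5)
  limits <- c(6.95, 6.93, 6.87, 6.78, 6.65, 6.47, 6.25, 5.97, 5.64, 5.24,
              4.81)
  for (i in seq_along(steps)) {
    expect_equal(aami_check(steps[i], 1)$sd_limit, limits[i])
    expect_equal(aami_check(-steps[i], 1)$sd_limit, limits[i])
  }
  # between-step means round the limit down to the next (conservative) row
  expect_equal(aami_check(0.3, 1)$sd_limit, 6.93)
  expect_equal(aami_check(1.6, 8.6)$pass, FALSE)
  expect_equal(aami_check(-1.6, 8.6)$pass, FALSE)
  expect_equal(aami_check(0.3, 6.7)$pass, TRUE)
  expect_equal(aami_check(6, 1)$pass, FALSE)
  expect_true(is.na(aami_check(6, 1)$sd_limit))
})

test_that("grading is monotone in its inputs", {
  grades <- c(A = 1, B = 2, C = 3, D = 4)
  set.seed(11)
  for (i in 1:50) {
    p <- sort(runif(3, 0, 100))
    g0 <- grades[bhs_grade(p[1], p[2], p[3])]
    bump <- pmin(p + c(5, 0, 0), 100)
    expect_lte(grades[bhs_grade(bump[1], bump[2], bump[3])], g0)
  }
  # AAMI: the SD limit never increases with |mean|, and passing SD stays
  # passing when decreased
  lims <- vapply(seq(0, 5, 0.25), function(m) aami_check(m, 1)$sd_limit,
                 numeric(1))
  expect_true(all(diff(lims) <= 0))
  expect_true(aami_check(2, 5)$pass)
  expect_true(aami_check(2, 4)$pass)
})

test_that("the full report is internally consistent", {
  set.seed(12)
  ref <- rnorm(60, 110, 12)
  est <- ref + rnorm(60, -1, 6)
  rep <- eval_report(est, ref)
  expect_equal(rep$n, 60)
  expect_true(all(diff(rep$cum_pct) >= 0))
  expect_equal(rep$bhs_grade,
               bhs_grade(rep$cum_pct[1], rep$cum_pct[2], rep$cum_pct[3]))
  expect_equal(rep$aami_pass,
               aami_check(rep$mean_diff, rep$sd_diff)$pass)
})
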