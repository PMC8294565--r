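test_that("suppression timing uses strict first crossings", {
  s <- fake_series(v = c(1, 1, 1e-3, 1e-8, 1e-9, 1e-4),
                   q = c(0.01, 0.2, 0.9, 0.3, 1e-6, 1e-9))
  rep <- time_to_suppression(s)
  expect_equal(rep$year_q_exceeds, 2)
  expect_equal(rep$year_v_below, 4)
  expect_equal(rep$gap_seasons, 2)
  expect_equal(rep$min_v, 1e-9)
  expect_equal(rep$year_min_v, 5)

  # parasitoid never establishes: gap undefined
  s2 <- fake_series(v = rep(1, 5), q = rep(0.05, 5))
  rep2 <- time_to_suppression(s2)
  expect_true(is.na(rep2$year_q_exceeds))
  expect_true(is.na(rep2$gap_seasons))
  expect_false(rep2$defined[["gap"]])

  # pest already below threshold at the trigger season: zero gap
  s3 <- fake_series(v = c(1e-9, 1e-9), q = c(0.5, 0.6))
  expect_equal(time_to_suppression(s3)$gap_seasons, 0)
  expect_error(time_to_suppression(fake_series(numeric(0))), "empty")
})

test_that("extrema respect the requested window", {
  s <- fake_series(v = c(1, 0.5, 0.1, 0.7), q = c(0.4, 0.3, 0.2, 0.1))
  full <- series_extrema(s)
  expect_equal(full$min_v, 0.1)
  expect_equal(full$year_min_v, 3)
  expect_equal(full$min_q, 0.1)
  win <- series_extrema(s, c(1, 2))
  expect_equal(win$min_v, 0.5)
  # strictly decreasing series: minimum at the last year
  dec <- fake_series(v = 2^-(1:6))
  expect_equal(series_extrema(dec)$year_min_v, 6)
  expect_error(series_extrema(s, c(10, 20)), "window")
})

test_that("implantation runs count post-suppression saturation stretches", {
  # never suppressed: full-length run, flagged
  all_high <- implantation_runs(fake_series(rep(1, 8)))
  expect_false(all_high$suppressed)
  expect_equal(all_high$longest_run, 8)
  # never implanted
  expect_equal(implantation_runs(fake_series(rep(0.1, 8)))$longest_run, 0)
  # suppression at year 3, then runs of 2 and 4 saturated seasons
  v <- c(1, 1, 0.01, 1, 1, 0.05, 1, 1, 1, 1, 0.02)
  r <- implantation_runs(fake_series(v))
  expect_true(r$suppressed)
  expect_equal(r$longest_run, 4)
  expect_error(implantation_runs(fake_series(rep(1, 3)), level = 1.2),
               "level")
})

test_that("cycle periods recover a constructed periodicity", {
  v <- 10^(-3 + 2 * sin(2 * pi * (1:36) / 12))  # peaks at years 3, 15, 27
  per <- cycle_periods(fake_series(v))
  expect_equal(per, c(12, 12))
  # monotone series has no interior peaks
  expect_length(cycle_periods(fake_series(10^-(1:10))), 0)
  expect_error(cycle_periods(fake_series(c(1, 2))), "3 seasons")
})

test_that("diagnostics are pure: identical inputs give identical reports", {
  ss <- homog_run(0.75, 60)
  a <- time_to_suppression(ss)
  b <- time_to_suppression(ss)
  expect_identical(a, b)
  expect_identical(cycle_periods(ss), cycle_periods(ss))
  # year-label invariance: only gaps matter
  shifted <- ss
  shifted$year <- ss$year + 100
  expect_equal(time_to_suppression(shifted)$gap_seasons, a$gap_seasons)
})

test_that("slower pest overwintering lengthens the predator-prey cycles", {
  p65 <- cycle_periods(homog_run(0.65))
  p85 <- cycle_periods(homog_run(0.85))
  expect_gt(mean(p65), mean(p85))
})
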