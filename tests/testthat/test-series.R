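test_that("response-time observations mirror the answered presentations", {
  ses <- make_session(
    onset_s = c(0, 1.7, 3.4, 5.1),
    kind = rep("regular", 4),
    responded = c(TRUE, FALSE, TRUE, FALSE),
    rt_ms = c(300, NA, 500, NA)
  )
  obs <- extract_rt_observations(ses)
  expect_equal(obs$onset_s, c(0, 3.4))
  expect_equal(obs$rt_ms, c(300, 500))

  none <- make_session(1:3, rep("regular", 3), rep(FALSE, 3))
  expect_equal(nrow(extract_rt_observations(none)), 0)
  all_resp <- make_session(1:5, rep("regular", 5), rep(TRUE, 5))
  expect_equal(nrow(extract_rt_observations(all_resp)), 5)
})

test_that("interpolation is linear between observations and flat outside", {
  obs <- tibble::tibble(onset_s = c(10, 20), rt_ms = c(300, 400))
  s <- interpolate_rt(obs, grid = c(0, 10, 15, 20, 30))
  expect_equal(s$value, c(300, 300, 350, 400, 400))

  one <- interpolate_rt(tibble::tibble(onset_s = 5, rt_ms = 321), grid = 0:10)
  expect_true(all(one$value == 321))

  expect_error(interpolate_rt(tibble::tibble(onset_s = numeric(),
                                             rt_ms = numeric()), 0:10),
               "zero observations")
})

test_that("interpolation matches a brute-force oracle at random grid points", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- sample(2:15, 1)
      obs_t <- sort(stats::runif(n, 0, 100))
      obs_v <- stats::runif(n, 200, 800)
      grid <- stats::runif(50, -10, 110)
    })
    got <- interpolate_rt(tibble::tibble(onset_s = obs_t, rt_ms = obs_v), grid)
    expect_equal(got$value, bf_interp(obs_t, obs_v, grid), tolerance = 1e-12)
    # exact at observation times, bounded by neighbours in between
    at_obs <- interpolate_rt(tibble::tibble(onset_s = obs_t, rt_ms = obs_v),
                             obs_t)
    expect_equal(at_obs$value, obs_v)
    expect_true(all(got$value >= min(obs_v) - 1e-9 &
                      got$value <= max(obs_v) + 1e-9))
  }
})

test_that("unit-interval normalization spans [0, 1] and degrades safely", {
  expect_equal(normalize_unit_interval(c(100, 200, 300)), c(0, 0.5, 1))
  expect_equal(normalize_unit_interval(rep(7, 5)), rep(0, 5))
  for (seed in 1:10) {
    x <- withr::with_seed(seed, stats::rnorm(50))
    z <- normalize_unit_interval(x)
    expect_equal(min(z), 0)
    expect_equal(max(z), 1)
  }
  expect_error(normalize_unit_interval(numeric()), "empty")
})

test_that("sliding RTV reproduces hand-computable windows", {
  grid <- 0:120
  const <- tibble::tibble(t_s = grid, value = rep(400, length(grid)))
  expect_true(all(sliding_rtv(const, 60)$value == 0))

  alt <- tibble::tibble(t_s = grid, value = rep(c(300, 400), length.out = 121))
  v <- sliding_rtv(alt, 60)$value
  expect_equal(v[grid >= 59], rep(50^2, sum(grid >= 59)))

  expect_error(sliding_rtv(const[1:10, ], 60), "span")
})

test_that("sliding RTV equals the brute-force window variance", {
  for (seed in 1:20) {
    x <- withr::with_seed(seed, stats::rnorm(150, 400, 50))
    s <- tibble::tibble(t_s = 0:149, value = x)
    expect_equal(sliding_rtv(s, 60)$value, bf_window_var(s$t_s, x, 60),
                 tolerance = 1e-12)
  }
})

test_that("RTV is shift-invariant and scales quadratically", {
  x <- withr::with_seed(5, stats::rnorm(150, 400, 50))
  s <- tibble::tibble(t_s = 0:149, value = x)
  base <- sliding_rtv(s, 60)$value
  shifted <- sliding_rtv(dplyr::mutate(s, value = value + 123), 60)$value
  scaled <- sliding_rtv(dplyr::mutate(s, value = value * 3), 60)$value
  expect_equal(shifted, base, tolerance = 1e-9)
  expect_equal(scaled, 9 * base, tolerance = 1e-9)
})

test_that("error rate counts trailing-window catch errors per minute", {
  ses <- make_session(
    onset_s = c(10, 30, 100),
    kind = c("catch_supra", "catch_infra", "catch_supra"),
    responded = c(FALSE, TRUE, TRUE),   # two errors, at 10 s and 30 s
    rt_ms = c(NA, 350, 420)
  )
  err <- error_rate_per_minute(ses, grid = 0:120)
  expect_equal(err$value[err$t_s == 60], 2)
  expect_equal(err$value[err$t_s == 9], 0)
  expect_equal(err$value[err$t_s == 10], 1)
  expect_equal(err$value[err$t_s == 95], 0)

  clean <- make_session(1:10 * 1.7, rep("regular", 10), rep(TRUE, 10))
  expect_true(all(error_rate_per_minute(clean, grid = 0:20)$value == 0))
})

test_that("error-rate series over disjoint windows recovers the total count", {
  for (seed in 1:10) {
    n_err <- withr::with_seed(seed, sample(3:25, 1))
    onsets <- withr::with_seed(seed + 100, sort(stats::runif(n_err, 0.01, 299)))
    ses <- make_session(onsets, rep("catch_supra", n_err), rep(FALSE, n_err))
    err <- error_rate_per_minute(ses, grid = 0:300)
    parts <- err$value[err$t_s %in% c(60, 120, 180, 240, 300)]
    expect_equal(sum(parts), n_err)
    # pigeonhole: some window must hold at least the average error density
    expect_gte(max(err$value), ceiling(n_err * 60 / 300))
  }
})

test_that("increased-error flags use a strict threshold", {
  flat2 <- tibble::tibble(t_s = 0:10, value = rep(2, 11))
  expect_false(any(flag_increased_error_periods(flat2, 2)$flag))
  flat25 <- tibble::tibble(t_s = 0:10, value = rep(2.5, 11))
  expect_true(all(flag_increased_error_periods(flat25, 2)$flag))
})

test_that("flags from a pooled-percentile threshold match an independent computation", {
  cohort <- simulate_cohort(n_subjects = 6, config = small_protocol(),
                            seed = 21)
  series <- cohort_series(cohort)
  thr <- stats::quantile(series$error_rate, 0.95, names = FALSE)
  per_subject <- lapply(split(series, series$subject_id), function(d) {
    flag_increased_error_periods(
      tibble::tibble(t_s = d$t_s, value = d$error_rate), threshold = thr
    )$flag
  })
  expect_equal(unlist(per_subject, use.names = FALSE),
               series$error_rate > thr)
})

test_that("session series share one grid and normalized columns stay in [0,1]", {
  sched <- build_schedule(small_protocol(), seed = 3)
  ses <- simulate_session(sched, observer_params(seed = 8))
  s <- session_series(ses)
  expect_equal(s$t_s, 0:floor(nrow(sched) * 1.7))
  expect_true(all(s$rt >= 0 & s$rt <= 1))
  expect_true(all(s$rtv >= 0 & s$rtv <= 1))
  expect_true(all(s$error_rate >= 0))
  expect_type(s$err_mask, "logical")

  raw <- session_series(ses, normalize = FALSE)
  expect_equal(raw$rt, raw$rt_raw_ms)
  expect_equal(normalize_unit_interval(raw$rt), s$rt)
})
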