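#' Extract response-time observations from a session
#'
#' One `(onset_s, rt_ms)` pair per answered presentation, ordered by onset;
#' presentations without a response are omitted (response times are undefined
#' there and are later filled in by interpolation).
#'
#' @param session A `perim_session` tibble (one subject).
#' @return A tibble with columns `onset_s`, `rt_ms`.
#' @export
extract_rt_observations <- function(session) {
  obs <- dplyr::filter(tibble::as_tibble(session), .data$responded)
  obs <- dplyr::arrange(obs, .data$onset_s)
  tibble::tibble(onset_s = obs$onset_s, rt_ms = obs$rt_ms)
}

#' Interpolate response times onto a uniform grid
#'
#' Linear interpolation between consecutive observations, evaluated at the
#' grid times; before the first and after the last observation the nearest
#' observed value is held constant. Grid samples lying within half a grid
#' step of an observation are flagged `observed`.
#'
#' @param observations A tibble with `onset_s` and `rt_ms`
#'   (from [extract_rt_observations()]); at least one row.
#' @param grid Numeric vector of evaluation times in seconds.
#' @return A tibble with `t_s`, `value` (ms) and logical `observed`.
#' @examples
#' obs <- tibble::tibble(onset_s = c(10, 20), rt_ms = c(300, 400))
#' interpolate_rt(obs, grid = 0:30)
#' @export
interpolate_rt <- function(observations, grid) {
  if (nrow(observations) == 0) {
    stop("cannot interpolate from zero observations", call. = FALSE)
  }
  step <- if (length(grid) > 1) min(diff(sort(grid))) else 1
  if (nrow(observations) == 1) {
    value <- rep(observations$rt_ms[1], length(grid))
  } else {
    value <- stats::approx(observations$onset_s, observations$rt_ms,
                           xout = grid, method = "linear", rule = 2,
                           ties = "ordered")$y
  }
  observed <- vapply(grid, function(t) {
    any(abs(observations$onset_s - t) <= step / 2)
  }, logical(1))
  tibble::tibble(t_s = grid, value = value, observed = observed)
}

#' Rescale values to the unit interval
#'
#' Min-max normalization `(x - min) / (max - min)`. A constant input maps to
#' 0 everywhere (the degenerate case where the range is empty). `NA`s are
#' ignored for the range and propagated.
#'
#' @param x Numeric vector.
#' @return Numeric vector in \[0, 1\].
#' @examples
#' normalize_unit_interval(c(100, 200, 300))
#' @export
normalize_unit_interval <- function(x) {
  if (length(x) == 0) stop("cannot normalize an empty series", call. = FALSE)
  rng <- range(x, na.rm = TRUE)
  if (rng[1] == rng[2]) return(rep(0, length(x)) + x * 0)
  (x - rng[1]) / (rng[2] - rng[1])
}

# index bounds of the trailing window (t - window, t] for each grid point;
# grid must be sorted
trailing_window_bounds <- function(t_s, window) {
  lo <- findInterval(t_s - window, t_s) + 1L
  list(lo = lo, hi = seq_along(t_s))
}

#' Sliding-window response-time variability
#'
#' The response-time variability (RTV) at time `t` is the variance of the
#' interpolated response-time samples in the trailing window `(t - window_s,
#' t]`. The window slides over the session in 1-s steps; windows reaching
#' before the session start use the partial window. Population variance
#' (divisor `n`) is used; set `population = FALSE` for the `n - 1` divisor.
#'
#' @param rt_series A tibble with `t_s` and `value` on a uniform 1-s grid
#'   (from [interpolate_rt()]).
#' @param window_s Window length in seconds (default 60; must not exceed the
#'   series span).
#' @param population Use the population variance divisor `n` (default).
#' @return A tibble with `t_s` and `value` (variance, in squared input
#'   units).
#' @examples
#' rt <- interpolate_rt(
#'   tibble::tibble(onset_s = c(0, 100), rt_ms = c(300, 500)), grid = 0:100
#' )
#' sliding_rtv(rt, window_s = 60)
#' @export
sliding_rtv <- function(rt_series, window_s = 60, population = TRUE) {
  t_s <- rt_series$t_s
  x <- rt_series$value
  n <- length(x)
  span <- t_s[n] - t_s[1]
  if (window_s > span) {
    stop("`window_s` exceeds the series span", call. = FALSE)
  }
  b <- trailing_window_bounds(t_s, window_s)
  value <- vapply(seq_len(n), function(i) {
    w <- x[b$lo[i]:b$hi[i]]
    m <- length(w)
    if (m < 2 && !population) return(NA_real_)
    mu <- sum(w) / m
    ss <- sum((w - mu)^2)
    if (population) ss / m else ss / (m - 1)
  }, numeric(1))
  tibble::tibble(t_s = t_s, value = value)
}

#' Catch-trial error rate on a uniform grid
#'
#' Pools both catch-trial error kinds (missed 0 dB suprathreshold catches and
#' answered 40 dB infrathreshold catches) and converts them into a
#' pseudo-continuous error rate: the rate at time `t` is the number of error
#' events in the trailing window `(t - window_s, t]`, expressed per minute.
#' Early windows reaching before the session start use the partial window
#' with the full-window denominator, so a session's rate samples on disjoint
#' window-length partitions sum to the total error count (for the default
#' 60-s window).
#'
#' @param session A `perim_session` tibble (one subject).
#' @param grid Evaluation times in seconds; defaults to a 1-s grid over the
#'   session.
#' @param window_s Trailing window length in seconds.
#' @return A tibble with `t_s` and `value` (errors per minute).
#' @export
error_rate_per_minute <- function(session, grid = NULL, window_s = 60) {
  session <- tibble::as_tibble(session)
  if (is.null(grid)) {
    config <- attr(session, "protocol")
    duration <- if (!is.null(config)) {
      nrow(session) * cycle_length_s(config)
    } else {
      max(session$onset_s)
    }
    grid <- seq(0, floor(duration))
  }
  err_onsets <- sort(session$onset_s[catch_error_flags(session)])
  count <- findInterval(grid, err_onsets) -
    findInterval(grid - window_s, err_onsets)
  tibble::tibble(t_s = grid, value = count * 60 / window_s)
}

#' Flag periods with an increased catch-trial error rate
#'
#' A period counts as having an increased number of false responses to catch
#' trials when the error rate exceeds the threshold — strictly more than two
#' errors per minute by default (the 95th percentile of the error rate in the
#' reference cohort).
#'
#' @param err_series A tibble with `t_s` and `value` from
#'   [error_rate_per_minute()].
#' @param threshold Errors per minute; samples with `value > threshold` are
#'   flagged (strict inequality).
#' @return A tibble with `t_s` and logical `flag`.
#' @export
flag_increased_error_periods <- function(err_series, threshold = 2) {
  tibble::tibble(t_s = err_series$t_s, flag = err_series$value > threshold)
}

#' Per-second quality series for one session
#'
#' Composes the full per-subject preprocessing: extract response times,
#' interpolate them onto a 1-s grid, compute the sliding-window RTV and the
#' catch-trial error rate, normalize RT and RTV to \[0, 1\] (per subject),
#' and flag increased-error periods.
#'
#' @param session A `perim_session` tibble (one subject).
#' @param window_s Sliding-window length in seconds.
#' @param error_threshold Errors per minute above which a second is flagged.
#' @param normalize Normalize `rt` and `rtv` to \[0, 1\] (the raw series are
#'   kept in `rt_raw_ms` / `rtv_raw_ms2`).
#' @param config The protocol (defaults to the session's `protocol`
#'   attribute); needed for the session duration.
#' @return A tibble of class `perim_series` with one row per second:
#'   `subject_id`, `t_s`, `rt_raw_ms`, `rtv_raw_ms2`, `rt`, `rtv`,
#'   `error_rate`, `err_mask`, `rt_observed`.
#' @examples
#' ses <- simulate_session(build_schedule(seed = 1), observer_params(seed = 2))
#' head(session_series(ses))
#' @export
session_series <- function(session, window_s = 60, error_threshold = 2,
                           normalize = TRUE, config = NULL) {
  session <- if (is.null(config)) {
    stopifnot(!is.null(attr(session, "protocol")))
    session
  } else {
    `attr<-`(session, "protocol", config)
  }
  cfg <- attr(session, "protocol")
  duration <- nrow(session) * cycle_length_s(cfg)
  grid <- seq(0, floor(duration))

  obs <- extract_rt_observations(session)
  rt <- interpolate_rt(obs, grid)
  rtv <- sliding_rtv(rt, window_s = window_s)
  err <- error_rate_per_minute(session, grid = grid, window_s = window_s)
  mask <- flag_increased_error_periods(err, threshold = error_threshold)

  rt_norm <- if (normalize) normalize_unit_interval(rt$value) else rt$value
  rtv_norm <- if (normalize) normalize_unit_interval(rtv$value) else rtv$value
  rt_raw <- rt$value
  rtv_raw <- rtv$value
  observed_flag <- rt$observed
  out <- tibble::tibble(
    subject_id = session$subject_id[1] %||% "S001",
    t_s = grid,
    rt_raw_ms = rt_raw,
    rtv_raw_ms2 = rtv_raw,
    rt = rt_norm,
    rtv = rtv_norm,
    error_rate = err$value,
    err_mask = mask$flag,
    rt_observed = observed_flag
  )
  attr(out, "window_s") <- window_s
  attr(out, "error_threshold") <- error_threshold
  class(out) <- c("perim_series", class(out))
  out
}

#' Per-second quality series for a whole cohort
#'
#' Applies [session_series()] to every subject of a simulated or loaded
#' cohort and row-binds the results. Normalization is per subject.
#'
#' @param cohort A `perim_cohort` tibble (or list of `perim_session`s).
#' @inheritParams session_series
#' @return A `perim_series` tibble covering all subjects.
#' @export
cohort_series <- function(cohort, window_s = 60, error_threshold = 2,
                          normalize = TRUE) {
  if (inherits(cohort, "perim_cohort") || is.data.frame(cohort)) {
    config <- attr(cohort, "protocol")
    stopifnot(!is.null(config))
    sessions <- split(tibble::as_tibble(cohort), cohort$subject_id)
  } else {
    sessions <- cohort
    config <- NULL
  }
  out <- dplyr::bind_rows(lapply(sessions, function(s) {
    session_series(s, window_s = window_s, error_threshold = error_threshold,
                   normalize = normalize,
                   config = config %||% attr(s, "protocol"))
  }))
  attr(out, "window_s") <- window_s
  attr(out, "error_threshold") <- error_threshold
  class(out) <- c("perim_series", class(out))
  out
}
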