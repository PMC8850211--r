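#' Latent vigilance process parameters
#'
#' The simulator models lapses of sustained attention as a two-state latent
#' vigilance process: vigilance is 1 outside episodes and `1 - episode_depth`
#' inside. Episode onsets follow a Poisson process with `episode_rate`
#' expected episodes per session; episode durations are exponential with mean
#' `episode_duration_mean` seconds; overlapping episodes are merged. During an
#' episode detection reliability is scaled by the vigilance level, responses
#' slow down by `rt_slowdown` ms, response-time noise is inflated by
#' `rtv_inflation`, and the probability of responding to an undetectable
#' stimulus rises by `episode_fp_boost` times the vigilance deficit.
#'
#' @param episode_rate Expected number of low-vigilance episodes per session
#'   (>= 0).
#' @param episode_duration_mean Mean episode duration in seconds (> 0).
#' @param episode_depth Vigilance deficit during an episode, in \[0, 1\];
#'   1 means complete non-detection.
#' @param rt_slowdown Additive response-time slowdown during an episode, ms.
#' @param rtv_inflation Multiplier (>= 1) on the response-time noise standard
#'   deviation during an episode.
#' @param episode_fp_boost Increment (per unit vigilance deficit) to the
#'   probability of responding to an undetected stimulus during an episode.
#' @return A list of class `perim_vigilance_params`.
#' @export
vigilance_params <- function(episode_rate = 3,
                             episode_duration_mean = 60,
                             episode_depth = 0.7,
                             rt_slowdown = 80,
                             rtv_inflation = 3,
                             episode_fp_boost = 0.25) {
  stopifnot(
    episode_rate >= 0,
    episode_duration_mean > 0,
    episode_depth >= 0, episode_depth <= 1,
    rt_slowdown >= 0,
    rtv_inflation >= 1,
    episode_fp_boost >= 0, episode_fp_boost <= 1
  )
  structure(
    list(
      episode_rate = episode_rate,
      episode_duration_mean = episode_duration_mean,
      episode_depth = episode_depth,
      rt_slowdown = rt_slowdown,
      rtv_inflation = rtv_inflation,
      episode_fp_boost = episode_fp_boost
    ),
    class = "perim_vigilance_params"
  )
}

#' Observer behavioural parameters
#'
#' A stochastic observer with a frequency-of-seeing curve, a luminance-
#' dependent response time and a latent vigilance process. Detection follows
#' `p = v * pnorm((threshold_db - db) / slope_db)` where `v` is the current
#' vigilance level, so bright (low-dB) stimuli are detected almost surely when
#' vigilant and detection collapses as vigilance drops. A detected stimulus is
#' answered with response time
#' `rt_intercept + rt_luminance_coeff * db (+ rt_slowdown in an episode)`
#' plus Gaussian noise of sd `rt_sd` (inflated during episodes), truncated to
#' the response window; an undetected stimulus is answered ("guessed") with
#' probability `base_fp_rate` plus the episode boost.
#'
#' The defaults put the psychometric threshold mid-range of the default
#' protocol's 3-39 dB levels and give a pooled median response time of about
#' 355 ms over a vigilant session under the default protocol's attenuation
#' mix.
#'
#' @param threshold_db Psychometric threshold in dB attenuation.
#' @param slope_db Psychometric spread in dB (> 0).
#' @param base_fp_rate Probability of responding to an undetected presentation
#'   when fully vigilant, in \[0, 1\].
#' @param rt_intercept Response-time intercept in ms (> 0).
#' @param rt_luminance_coeff Response-time slope in ms per dB of attenuation
#'   (responses are slower for dimmer stimuli).
#' @param rt_sd Response-time noise sd in ms when fully vigilant (>= 0).
#' @param response_window_ms Responses later than this (from stimulus onset)
#'   count as non-responses.
#' @param vigilance A [vigilance_params()].
#' @param seed Integer seed making the simulated session deterministic.
#' @return A list of class `perim_observer_params`.
#' @export
observer_params <- function(threshold_db = 24,
                            slope_db = 2,
                            base_fp_rate = 0.01,
                            rt_intercept = 322,
                            rt_luminance_coeff = 5,
                            rt_sd = 40,
                            response_window_ms = 1700,
                            vigilance = vigilance_params(),
                            seed = 1L) {
  stopifnot(
    slope_db > 0,
    base_fp_rate >= 0, base_fp_rate <= 1,
    rt_intercept > 0, rt_sd >= 0,
    response_window_ms > 0,
    inherits(vigilance, "perim_vigilance_params")
  )
  structure(
    list(
      threshold_db = threshold_db,
      slope_db = slope_db,
      base_fp_rate = base_fp_rate,
      rt_intercept = rt_intercept,
      rt_luminance_coeff = rt_luminance_coeff,
      rt_sd = rt_sd,
      response_window_ms = response_window_ms,
      vigilance = vigilance,
      seed = as.integer(seed)
    ),
    class = "perim_observer_params"
  )
}

#' Simulate a latent vigilance trace
#'
#' Draws episode onsets from a Poisson process (expected `episode_rate`
#' episodes over `duration_s`), episode durations from an exponential with
#' mean `episode_duration_mean`, merges overlaps, clips to the session, and
#' evaluates the two-state vigilance level on a 1-s grid.
#'
#' @param params A [vigilance_params()].
#' @param duration_s Session duration in seconds (> 0).
#' @param seed Integer seed.
#' @return A tibble of class `perim_vigilance_trace` with columns `t_s` and
#'   `v` (vigilance in \[0, 1\]), and the merged episode intervals in
#'   attribute `episodes` (tibble with `start_s`, `end_s`).
#' @examples
#' tr <- simulate_vigilance(vigilance_params(episode_rate = 2), 600, seed = 7)
#' attr(tr, "episodes")
#' @export
simulate_vigilance <- function(params, duration_s, seed = 1L) {
  stopifnot(inherits(params, "perim_vigilance_params"), duration_s > 0)
  episodes <- withr::with_seed(seed, {
    n <- stats::rpois(1, params$episode_rate)
    if (n > 0) {
      start <- sort(stats::runif(n, 0, duration_s))
      len <- stats::rexp(n, rate = 1 / params$episode_duration_mean)
      tibble::tibble(start_s = start, end_s = pmin(start + len, duration_s))
    } else {
      tibble::tibble(start_s = numeric(), end_s = numeric())
    }
  })
  episodes <- merge_intervals(episodes)
  grid <- seq(0, floor(duration_s))
  in_ep <- in_intervals(grid, episodes)
  out <- tibble::tibble(t_s = grid,
                        v = ifelse(in_ep, 1 - params$episode_depth, 1))
  attr(out, "episodes") <- episodes
  attr(out, "params") <- params
  class(out) <- c("perim_vigilance_trace", class(out))
  out
}

# merge overlapping/touching [start, end] intervals; returns sorted tibble
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) return(intervals)
  o <- order(intervals$start_s)
  s <- intervals$start_s[o]
  e <- intervals$end_s[o]
  ms <- s[1]; me <- e[1]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) {
      me <- max(me, e[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- s[i]; me <- e[i]
    }
  }
  tibble::tibble(start_s = c(out_s, ms), end_s = c(out_e, me))
}

# is each time point inside any [start, end) interval?
in_intervals <- function(t, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(t)))
  vapply(t, function(tt) {
    any(tt >= intervals$start_s & tt < intervals$end_s)
  }, logical(1))
}

#' Frequency-of-seeing detection probability
#'
#' Probability that a stimulus of the given attenuation is detected:
#' `v * pnorm((threshold_db - db) / slope_db)`. Monotonically decreasing in
#' attenuation, 0.5 at threshold when fully vigilant, and scaled linearly by
#' the vigilance level.
#'
#' @param db Stimulus attenuation in dB. Vectorized.
#' @param threshold_db Psychometric threshold in dB.
#' @param slope_db Psychometric spread in dB (> 0).
#' @param v Vigilance level in \[0, 1\]. Vectorized.
#' @return Detection probability in \[0, 1\].
#' @examples
#' detection_probability(24, threshold_db = 24)  # 0.5 at threshold
#' detection_probability(0, threshold_db = 24)   # ~1 for a maximal stimulus
#' @export
detection_probability <- function(db, threshold_db = 24, slope_db = 2, v = 1) {
  stopifnot(slope_db > 0, all(v >= 0), all(v <= 1))
  v * stats::pnorm((threshold_db - db) / slope_db)
}

#' Sample observer responses to scheduled stimuli
#'
#' Vectorized response model used by [simulate_session()]: detection is
#' Bernoulli with [detection_probability()]; undetected presentations are
#' answered with probability `base_fp_rate` plus the episode false-response
#' boost; answered presentations get a response time from the linear-in-dB
#' model with episode slowdown and inflated noise, and responses falling
#' outside `(0, response_window_ms]` are recorded as non-responses. Draws use
#' the current RNG state; seed externally (e.g. `withr::with_seed()`) for
#' reproducibility.
#'
#' @param db Stimulus attenuations in dB.
#' @param v Vigilance level at each presentation, in \[0, 1\].
#' @param params An [observer_params()].
#' @return A tibble with logical `responded` and numeric `rt_ms` (`NA` when
#'   not responded).
#' @export
sample_response <- function(db, v, params) {
  stopifnot(inherits(params, "perim_observer_params"),
            length(db) == length(v))
  n <- length(db)
  vp <- params$vigilance
  p_detect <- detection_probability(db, params$threshold_db, params$slope_db, v)
  detected <- stats::runif(n) < p_detect
  p_guess <- pmin(1, params$base_fp_rate + vp$episode_fp_boost * (1 - v))
  guessed <- !detected & stats::runif(n) < p_guess
  responded <- detected | guessed
  in_episode <- v < 1
  mu <- params$rt_intercept + params$rt_luminance_coeff * db +
    ifelse(in_episode, vp$rt_slowdown, 0)
  sd <- params$rt_sd * ifelse(in_episode, vp$rtv_inflation, 1)
  rt <- mu + stats::rnorm(n, 0, sd)
  # responses outside the response window count as non-responses
  valid <- rt > 0 & rt <= params$response_window_ms
  responded <- responded & valid
  tibble::tibble(responded = responded,
                 rt_ms = ifelse(responded, rt, NA_real_))
}

#' Simulate a full perimetric session
#'
#' Draws a vigilance trace over the schedule's duration, evaluates vigilance
#' at each stimulus onset and samples a response for every presentation. The
#' result is deterministic given the schedule and `params$seed`.
#'
#' @param schedule A `perim_schedule` from [build_schedule()].
#' @param params An [observer_params()].
#' @param subject_id Subject identifier stored with each row.
#' @return A tibble of class `perim_session`: the schedule columns plus
#'   `responded`, `rt_ms`, `v` and `subject_id`. Attributes: `protocol`,
#'   `observer` (the parameters), `episodes` (ground-truth vigilance
#'   episodes), `seed`.
#' @examples
#' sched <- build_schedule(seed = 1)
#' ses <- simulate_session(sched, observer_params(seed = 42))
#' mean(ses$responded)
#' @export
simulate_session <- function(schedule, params = observer_params(),
                             subject_id = "S001") {
  stopifnot(inherits(schedule, "perim_schedule"),
            inherits(params, "perim_observer_params"))
  config <- attr(schedule, "protocol")
  duration <- nrow(schedule) * cycle_length_s(config)
  trace <- simulate_vigilance(params$vigilance, duration, seed = params$seed)
  episodes <- attr(trace, "episodes")
  v <- ifelse(in_intervals(schedule$onset_s, episodes),
              1 - params$vigilance$episode_depth, 1)
  resp <- withr::with_seed(params$seed + 1L,
                           sample_response(schedule$db, v, params))
  out <- tibble::as_tibble(schedule)
  out$responded <- resp$responded
  out$rt_ms <- resp$rt_ms
  out$v <- v
  out$subject_id <- subject_id
  attr(out, "protocol") <- config
  attr(out, "observer") <- params
  attr(out, "episodes") <- episodes
  attr(out, "seed") <- params$seed
  class(out) <- c("perim_session", class(out))
  out
}

#' Simulate a cohort of perimetric sessions
#'
#' Simulates `n_subjects` independent sessions of the same protocol. By
#' default subjects differ only in their vigilance-episode rate, graded
#' linearly from `episode_rate_range[1]` to `episode_rate_range[2]` across
#' the cohort — a cohort in which vigilance problems range from absent to
#' frequent, as the quality analysis assumes. Supply `params_fn` to override
#' subject-level parameters entirely.
#'
#' Per-subject seeds are derived from `seed`, so the whole cohort is
#' reproducible from one master seed.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param config A [perim_protocol()].
#' @param seed Master seed.
#' @param episode_rate_range Length-2 numeric; subjects' episode rates are
#'   graded linearly over this range.
#' @param params_fn Optional `function(subject_index, subject_seed)` returning
#'   an [observer_params()].
#' @param schedule_seed Seed for the (shared) stimulus schedule; defaults to
#'   the master seed.
#' @return A tibble of class `perim_cohort`: all sessions row-bound, with
#'   `subject_id` distinguishing them. Attributes: `protocol`, `episodes`
#'   (per-subject ground-truth episode intervals), `observers` (named list of
#'   parameters), `seed`.
#' @export
simulate_cohort <- function(n_subjects = 48,
                            config = perim_protocol(),
                            seed = 1L,
                            episode_rate_range = c(0, 8),
                            params_fn = NULL,
                            schedule_seed = seed) {
  stopifnot(n_subjects >= 1)
  schedule <- build_schedule(config, seed = schedule_seed)
  rates <- if (n_subjects == 1) episode_rate_range[1] else {
    seq(episode_rate_range[1], episode_rate_range[2], length.out = n_subjects)
  }
  if (is.null(params_fn)) {
    params_fn <- function(i, subject_seed) {
      observer_params(
        vigilance = vigilance_params(episode_rate = rates[i]),
        seed = subject_seed
      )
    }
  }
  ids <- sprintf("S%03d", seq_len(n_subjects))
  subject_seeds <- as.integer((as.integer(seed) * 1000L + seq_len(n_subjects)) %%
                                .Machine$integer.max)
  sessions <- purrr::map(seq_len(n_subjects), function(i) {
    simulate_session(schedule, params_fn(i, subject_seeds[i]), ids[i])
  })
  out <- dplyr::bind_rows(lapply(sessions, tibble::as_tibble))
  attr(out, "protocol") <- config
  attr(out, "episodes") <- stats::setNames(
    lapply(sessions, attr, "episodes"), ids
  )
  attr(out, "observers") <- stats::setNames(
    lapply(sessions, attr, "observer"), ids
  )
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("perim_cohort", class(out))
  out
}

#' Count catch-trial errors in a session
#'
#' An error is a missed suprathreshold catch trial (0 dB stimulus not
#' responded to) or a response to an infrathreshold catch trial (40 dB
#' stimulus that cannot be seen). The two kinds are pooled.
#'
#' @param session A `perim_session` tibble (or any tibble with `kind` and
#'   `responded` columns; grouped input is summarized per group).
#' @return For a single session, the total error count; for a cohort tibble,
#'   a tibble with `subject_id` and `total_errors`.
#' @export
catch_trial_errors <- function(session) {
  if ("subject_id" %in% names(session) &&
      length(unique(session$subject_id)) > 1) {
    tbl <- tibble::as_tibble(session)
    tbl$.err <- catch_error_flags(tbl)
    dplyr::summarise(dplyr::group_by(tbl, .data$subject_id),
                     total_errors = sum(.data$.err), .groups = "drop")
  } else {
    sum(catch_error_flags(session))
  }
}

# logical flag per row: is this presentation a catch-trial error?
catch_error_flags <- function(session) {
  (session$kind == "catch_supra" & !session$responded) |
    (session$kind == "catch_infra" & session$responded)
}
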