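#' Perimetric protocol configuration
#'
#' Defines a method-of-constant-stimuli (MoCS) perimetric protocol: the set of
#' stimulus attenuations on the perimeter's decibel scale, the tested visual
#' field locations, the number of repetitions, the presentation timing and the
#' enrichment rates for the two catch-trial kinds.
#'
#' The decibel scale is anchored so that 0 dB corresponds to
#' `db_anchor_luminance` (the maximal stimulus luminance) and every 10 dB is a
#' tenfold attenuation. The defaults describe a session with 13 luminance
#' levels in equal 3-dB steps from 3 dB (160 cd/m2) to 39 dB (0.04 cd/m2) on a
#' 10 cd/m2 background, Goldmann size III stimuli (25.7 arcmin) shown 20 times
#' per level at each of three peripheral locations and twice per level at a
#' central reference location, 200 ms presentations with a 1500 ms
#' interstimulus interval, and 25% + 25% catch-trial enrichment: suprathreshold
#' catches at 0 dB (an error is *not* responding) and infrathreshold catches at
#' 40 dB (an error is responding).
#'
#' @param db_anchor_luminance Luminance in cd/m2 corresponding to 0 dB.
#' @param background_luminance Background luminance in cd/m2.
#' @param stimulus_levels_db Strictly increasing vector of stimulus
#'   attenuations in dB.
#' @param peripheral_locations Two-column matrix (or data frame) of peripheral
#'   (x, y) eccentricities in degrees.
#' @param reference_location Length-2 numeric, the reference (fixation)
#'   location in degrees.
#' @param reps_peripheral Presentations per level per peripheral location.
#' @param reps_reference Presentations per level at the reference location.
#' @param stimulus_duration_ms Stimulus presentation duration in ms.
#' @param interstimulus_interval_ms Pause between presentations in ms.
#' @param fp_catch_rate,fn_catch_rate Fractions of *all* presentations devoted
#'   to the suprathreshold (`catch_supra`, 0 dB) and infrathreshold
#'   (`catch_infra`, 40 dB) catch kinds. Their sum must be < 1.
#' @param fp_catch_db,fn_catch_db Attenuations of the two catch kinds in dB.
#' @param stimulus_size_arcmin Stimulus diameter in arcmin (Goldmann III).
#'
#' @return A list of class `perim_protocol`.
#' @examples
#' cfg <- perim_protocol()
#' cfg$stimulus_levels_db
#' expected_catch_interval(cfg)
#' @export
perim_protocol <- function(db_anchor_luminance = 320,
                           background_luminance = 10,
                           stimulus_levels_db = seq(3, 39, by = 3),
                           peripheral_locations = rbind(
                             c(-6.1, -3.5), c(0, 7), c(6.1, -3.5)
                           ),
                           reference_location = c(0, 0),
                           reps_peripheral = 20,
                           reps_reference = 2,
                           stimulus_duration_ms = 200,
                           interstimulus_interval_ms = 1500,
                           fp_catch_rate = 0.25,
                           fn_catch_rate = 0.25,
                           fp_catch_db = 0,
                           fn_catch_db = 40,
                           stimulus_size_arcmin = 25.7) {
  peripheral_locations <- as.matrix(peripheral_locations)
  stopifnot(
    is.numeric(db_anchor_luminance), db_anchor_luminance > 0,
    is.numeric(background_luminance), background_luminance > 0,
    ncol(peripheral_locations) == 2,
    length(reference_location) == 2,
    reps_peripheral >= 0, reps_reference >= 0,
    stimulus_duration_ms > 0, interstimulus_interval_ms > 0
  )
  if (length(stimulus_levels_db) > 1 && any(diff(stimulus_levels_db) <= 0)) {
    stop("`stimulus_levels_db` must be strictly increasing", call. = FALSE)
  }
  if (fp_catch_rate < 0 || fn_catch_rate < 0 ||
      fp_catch_rate + fn_catch_rate >= 1) {
    stop("catch-trial rates must satisfy 0 <= fp + fn < 1", call. = FALSE)
  }
  structure(
    list(
      db_anchor_luminance = db_anchor_luminance,
      background_luminance = background_luminance,
      stimulus_levels_db = as.numeric(stimulus_levels_db),
      peripheral_locations = peripheral_locations,
      reference_location = as.numeric(reference_location),
      reps_peripheral = as.integer(reps_peripheral),
      reps_reference = as.integer(reps_reference),
      stimulus_duration_ms = stimulus_duration_ms,
      interstimulus_interval_ms = interstimulus_interval_ms,
      fp_catch_rate = fp_catch_rate,
      fn_catch_rate = fn_catch_rate,
      fp_catch_db = fp_catch_db,
      fn_catch_db = fn_catch_db,
      stimulus_size_arcmin = stimulus_size_arcmin
    ),
    class = "perim_protocol"
  )
}

#' @export
print.perim_protocol <- function(x, ...) {
  cat("<perim_protocol>\n")
  cat(sprintf(
    "  %d levels: %s dB (anchor %g cd/m2, background %g cd/m2)\n",
    length(x$stimulus_levels_db),
    paste(range(x$stimulus_levels_db), collapse = "-"),
    x$db_anchor_luminance, x$background_luminance
  ))
  cat(sprintf(
    "  %d peripheral locations x %d reps, reference x %d reps\n",
    nrow(x$peripheral_locations), x$reps_peripheral, x$reps_reference
  ))
  cat(sprintf(
    "  timing: %g ms stimulus + %g ms ISI; catch rates %g + %g\n",
    x$stimulus_duration_ms, x$interstimulus_interval_ms,
    x$fp_catch_rate, x$fn_catch_rate
  ))
  invisible(x)
}

# presentation cycle length in seconds
cycle_length_s <- function(config) {
  (config$stimulus_duration_ms + config$interstimulus_interval_ms) / 1000
}

#' Convert between luminance and decibel attenuation
#'
#' Perimeters express stimulus intensity as an attenuation in decibels below
#' the instrument's maximal luminance: `dB = 10 * log10(anchor / luminance)`,
#' so 0 dB is the anchor itself and each 10 dB is a tenfold attenuation.
#' Values are stored exactly; rounding to integer dB (as printed on perimeter
#' charts) is left to the caller.
#'
#' @param luminance Stimulus luminance in cd/m2 (> 0). Vectorized.
#' @param db Attenuation in dB. Vectorized.
#' @param anchor Luminance in cd/m2 corresponding to 0 dB.
#' @return `luminance_to_db()`: attenuation in dB; `db_to_luminance()`:
#'   luminance in cd/m2.
#' @examples
#' luminance_to_db(320)          # 0 dB
#' luminance_to_db(0.032)        # 40 dB
#' round(luminance_to_db(160))   # 3 dB
#' db_to_luminance(40)           # 0.032 cd/m2
#' @export
luminance_to_db <- function(luminance, anchor = 320) {
  stopifnot(is.numeric(luminance), is.numeric(anchor), anchor > 0)
  if (any(luminance <= 0)) {
    stop("`luminance` must be positive", call. = FALSE)
  }
  10 * log10(anchor / luminance)
}

#' @rdname luminance_to_db
#' @export
db_to_luminance <- function(db, anchor = 320) {
  stopifnot(is.numeric(db), is.numeric(anchor), anchor > 0)
  anchor * 10^(-db / 10)
}

#' Build a randomized stimulus schedule with enriched catch trials
#'
#' Enumerates every (level x location x repetition) regular presentation of
#' the protocol exactly once, adds catch trials of both kinds so that each
#' constitutes its configured fraction of the total, permutes all
#' presentations with a seeded generator, and assigns onsets on the fixed
#' presentation cycle (stimulus duration + interstimulus interval).
#'
#' The total count is `N = ceiling(n_regular / (1 - fp - fn))`; each catch
#' kind gets `round(rate * N)` presentations, adjusted so the counts sum to
#' `N`. Under the default protocol this doubles 806 regular presentations to
#' 1612 in total.
#'
#' @param config A [perim_protocol()].
#' @param seed Integer randomization seed, stored in the result.
#' @return A tibble of class `perim_schedule` with one row per presentation:
#'   `index`, `onset_s`, `x_deg`, `y_deg`, `kind` (`regular`, `catch_supra`,
#'   `catch_infra`), `db`, `luminance_cdm2`. The protocol and seed are kept in
#'   attributes `protocol` and `seed`.
#' @examples
#' sched <- build_schedule(seed = 1)
#' nrow(sched)        # 1612
#' table(sched$kind)
#' @export
build_schedule <- function(config = perim_protocol(), seed = 1L) {
  stopifnot(inherits(config, "perim_protocol"))
  locs <- rbind(config$peripheral_locations,
                matrix(config$reference_location, nrow = 1))
  reps <- c(rep(config$reps_peripheral, nrow(config$peripheral_locations)),
            config$reps_reference)

  regular <- tidyr::expand_grid(
    db = config$stimulus_levels_db,
    loc = seq_len(nrow(locs))
  )
  regular <- regular[rep(seq_len(nrow(regular)), times = reps[regular$loc]), ]
  n_regular <- nrow(regular)

  combined <- config$fp_catch_rate + config$fn_catch_rate
  n_total <- if (combined > 0) ceiling(n_regular / (1 - combined)) else n_regular
  n_supra <- round(config$fp_catch_rate * n_total)
  n_infra <- round(config$fn_catch_rate * n_total)
  # rounding can leave the three counts off n_total by one; absorb in n_infra
  n_infra <- n_total - n_regular - n_supra

  events <- tibble::tibble(
    x_deg = c(locs[regular$loc, 1],
              rep(config$reference_location[1], n_supra + n_infra)),
    y_deg = c(locs[regular$loc, 2],
              rep(config$reference_location[2], n_supra + n_infra)),
    kind = c(rep("regular", n_regular),
             rep("catch_supra", n_supra),
             rep("catch_infra", n_infra)),
    db = c(regular$db,
           rep(config$fp_catch_db, n_supra),
           rep(config$fn_catch_db, n_infra))
  )

  perm <- withr::with_seed(seed, sample.int(nrow(events)))
  events <- events[perm, ]
  out <- tibble::tibble(
    index = seq_len(nrow(events)),
    onset_s = (seq_len(nrow(events)) - 1) * cycle_length_s(config),
    x_deg = events$x_deg,
    y_deg = events$y_deg,
    kind = events$kind,
    db = events$db,
    luminance_cdm2 = db_to_luminance(events$db, config$db_anchor_luminance)
  )
  attr(out, "protocol") <- config
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("perim_schedule", class(out))
  out
}

#' Expected time between consecutive catch trials
#'
#' With catch trials making up a fraction `fp + fn` of all presentations and a
#' fixed presentation cycle, a catch trial occurs on average every
#' `cycle_s / (fp + fn)` seconds. At conventional clinical rates (4% + 4%)
#' with a 200 ms stimulus and 1500 ms interval this is about 21 s; at the
#' enriched 25% + 25% rates it is 3.4 s, i.e. about every three seconds.
#'
#' @inheritParams build_schedule
#' @return Expected catch-trial interval in seconds.
#' @examples
#' expected_catch_interval(perim_protocol())                      # 3.4 s
#' expected_catch_interval(
#'   perim_protocol(fp_catch_rate = 0.04, fn_catch_rate = 0.04)
#' )                                                              # 21.25 s
#' @export
expected_catch_interval <- function(config = perim_protocol()) {
  stopifnot(inherits(config, "perim_protocol"))
  combined <- config$fp_catch_rate + config$fn_catch_rate
  if (combined <= 0) {
    stop("combined catch-trial rate must be positive", call. = FALSE)
  }
  cycle_length_s(config) / combined
}

#' Summarize a stimulus schedule
#'
#' Counts presentations per kind, attenuation level and location, and reports
#' the total session duration.
#'
#' @param schedule A `perim_schedule` from [build_schedule()].
#' @return A tibble with columns `kind`, `db`, `x_deg`, `y_deg`, `n`, with the
#'   total duration in seconds in attribute `duration_s`. Use
#'   [glance.perim_schedule()] for a one-row overview.
#' @export
schedule_summary <- function(schedule) {
  counts <- dplyr::count(tibble::as_tibble(schedule),
                         .data$kind, .data$db, .data$x_deg, .data$y_deg)
  config <- attr(schedule, "protocol")
  attr(counts, "duration_s") <-
    if (nrow(schedule)) nrow(schedule) * cycle_length_s(config) else 0
  counts
}

#' @importFrom generics glance
#' @export
generics::glance

#' One-row overview of a schedule
#'
#' @param x A `perim_schedule`.
#' @param ... Unused.
#' @return A one-row tibble with event counts per kind, the total event count
#'   and the session duration in seconds and minutes.
#' @export
glance.perim_schedule <- function(x, ...) {
  config <- attr(x, "protocol")
  duration <- if (nrow(x)) nrow(x) * cycle_length_s(config) else 0
  tibble::tibble(
    n_events = nrow(x),
    n_regular = sum(x$kind == "regular"),
    n_catch_supra = sum(x$kind == "catch_supra"),
    n_catch_infra = sum(x$kind == "catch_infra"),
    duration_s = duration,
    duration_min = duration / 60
  )
}

#' Write / read a schedule as CSV with a JSON sidecar
#'
#' The CSV holds one row per presentation; the sidecar (same path with
#' `.json` appended) records the protocol and the randomization seed so a
#' schedule round-trips exactly.
#'
#' @param schedule A `perim_schedule`.
#' @param path CSV file path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns a `perim_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  readr::write_csv(tibble::as_tibble(schedule), path)
  config <- attr(schedule, "protocol")
  sidecar <- list(
    protocol = protocol_to_list(config),
    seed = attr(schedule, "seed")
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  events <- readr::read_csv(path, show_col_types = FALSE)
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- tibble::as_tibble(events)
  attr(out, "protocol") <- protocol_from_list(sidecar$protocol)
  attr(out, "seed") <- as.integer(sidecar$seed)
  class(out) <- c("perim_schedule", class(out))
  out
}

protocol_to_list <- function(config) {
  out <- unclass(config)
  out$peripheral_locations <- unname(as.matrix(out$peripheral_locations))
  out
}

protocol_from_list <- function(x) {
  if (!is.matrix(x$peripheral_locations)) {
    x$peripheral_locations <- matrix(unlist(x$peripheral_locations),
                                     ncol = 2, byrow = TRUE)
  }
  do.call(perim_protocol, x[names(formals(perim_protocol))[
    names(formals(perim_protocol)) %in% names(x)
  ]])
}
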