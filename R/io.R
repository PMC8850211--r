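#' Write a session record to CSV with a JSON sidecar
#'
#' The CSV holds one row per presentation (`index`, `onset_s`, `x_deg`,
#' `y_deg`, `kind`, `db`, `luminance_cdm2`, `responded`, `rt_ms`,
#' `subject_id`); the sidecar (`<path>.json`) records the protocol, the
#' observer parameters, the ground-truth vigilance episodes and the seeds, so
#' a session round-trips exactly.
#'
#' @param session A `perim_session` tibble.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  cols <- c("index", "onset_s", "x_deg", "y_deg", "kind", "db",
            "luminance_cdm2", "responded", "rt_ms", "subject_id")
  readr::write_csv(tibble::as_tibble(session)[, cols], path)
  params <- attr(session, "observer")
  sidecar <- list(
    protocol = protocol_to_list(attr(session, "protocol")),
    observer = observer_to_list(params),
    episodes = as.list(attr(session, "episodes")),
    seed = attr(session, "seed")
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

observer_to_list <- function(params) {
  if (is.null(params)) return(NULL)
  out <- unclass(params)
  out$vigilance <- unclass(out$vigilance)
  out
}

observer_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  x$vigilance <- do.call(vigilance_params, x$vigilance)
  do.call(observer_params, x[names(formals(observer_params))[
    names(formals(observer_params)) %in% names(x)
  ]])
}

#' Read session records from CSV files
#'
#' Reads one session CSV (as written by [write_session()]) or every `*.csv`
#' in a directory (in stable, sorted order), validating the schema: required
#' columns present, non-negative onsets and response times, and `rt_ms`
#' present exactly when `responded` is true. Violations are reported with row
#' numbers.
#'
#' @param path A session CSV file, or a directory of them.
#' @return For a single file, a `perim_session` tibble; for a directory, a
#'   `perim_cohort` tibble with all sessions row-bound.
#' @export
read_sessions <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0) stop("no session CSVs in ", path, call. = FALSE)
    sessions <- lapply(files, read_one_session)
    out <- dplyr::bind_rows(lapply(sessions, tibble::as_tibble))
    attr(out, "protocol") <- attr(sessions[[1]], "protocol")
    attr(out, "episodes") <- stats::setNames(
      lapply(sessions, attr, "episodes"),
      vapply(sessions, function(s) s$subject_id[1], character(1))
    )
    class(out) <- c("perim_cohort", class(out))
    out
  } else {
    read_one_session(path)
  }
}

read_one_session <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("index", "onset_s", "kind", "db", "responded", "rt_ms",
                "subject_id")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("session file ", path, " lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_rt <- which(!is.na(d$rt_ms) & !d$responded)
  if (length(bad_rt)) {
    stop("session file ", path, ": rt_ms present on non-response rows ",
         paste(utils::head(bad_rt, 5), collapse = ", "), call. = FALSE)
  }
  missing_rt <- which(d$responded & is.na(d$rt_ms))
  if (length(missing_rt)) {
    stop("session file ", path, ": rt_ms missing on response rows ",
         paste(utils::head(missing_rt, 5), collapse = ", "), call. = FALSE)
  }
  neg <- which(d$rt_ms <= 0 | d$onset_s < 0)
  if (length(neg)) {
    stop("session file ", path, ": non-positive rt_ms or negative onset_s ",
         "at rows ", paste(utils::head(neg, 5), collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(d)
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    attr(out, "protocol") <- protocol_from_list(sidecar$protocol)
    attr(out, "observer") <- observer_from_list(sidecar$observer)
    if (!is.null(sidecar$episodes)) {
      attr(out, "episodes") <- tibble::as_tibble(sidecar$episodes)
    }
    attr(out, "seed") <- sidecar$seed
  }
  class(out) <- c("perim_session", class(out))
  out
}

#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run (simulate, series, analyze,
#' report) with a master seed, so a run is fully described by one object.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; drives schedule randomization and every subject's
#'   simulation.
#' @param n_subjects Number of simulated subjects.
#' @param protocol A [perim_protocol()].
#' @param episode_rate_range Graded vigilance-episode rates across the
#'   cohort, passed to [simulate_cohort()].
#' @param window_s Sliding-window length in seconds.
#' @param error_threshold Errors per minute defining the gold-standard mask.
#' @param cutoff_mode `"youden"` or `"fixed"`.
#' @param fixed_cutoff Cut-off when `cutoff_mode = "fixed"`.
#' @param input_dir Optional directory of existing session CSVs; when given,
#'   simulation is skipped and sessions are read from disk.
#' @return A list of class `perim_run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, n_subjects = 48,
                       protocol = perim_protocol(),
                       episode_rate_range = c(0, 8),
                       window_s = 60, error_threshold = 2,
                       cutoff_mode = "youden", fixed_cutoff = NULL,
                       input_dir = NULL) {
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir, call. = FALSE)
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         n_subjects = n_subjects, protocol = protocol,
         episode_rate_range = episode_rate_range, window_s = window_s,
         error_threshold = error_threshold, cutoff_mode = cutoff_mode,
         fixed_cutoff = fixed_cutoff, input_dir = input_dir),
    class = "perim_run_config"
  )
}

#' Run the full quality-control pipeline
#'
#' Simulates (or loads) a cohort, writes the per-subject session files,
#' computes the per-second series and the full quality analysis, and writes a
#' tidy series CSV, a JSON report and a manifest listing every produced file
#' with the package version, a configuration hash and the master seed.
#' Outputs are deterministic given the configuration.
#'
#' @param config A [run_config()].
#' @return The `perim_qc` analysis, invisibly, with the manifest in attribute
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "perim_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sessions_dir <- file.path(config$out_dir, "sessions")
  dir.create(sessions_dir, showWarnings = FALSE)

  cohort <- if (is.null(config$input_dir)) {
    simulate_cohort(
      n_subjects = config$n_subjects, config = config$protocol,
      seed = config$seed, episode_rate_range = config$episode_rate_range
    )
  } else {
    read_sessions(config$input_dir)
  }
  if (nrow(cohort) == 0) stop("empty cohort; nothing to analyze", call. = FALSE)

  files <- character()
  if (is.null(config$input_dir)) {
    protocol <- attr(cohort, "protocol")
    episodes <- attr(cohort, "episodes")
    observers <- attr(cohort, "observers")
    for (id in unique(cohort$subject_id)) {
      ses <- dplyr::filter(tibble::as_tibble(cohort), .data$subject_id == id)
      attr(ses, "protocol") <- protocol
      attr(ses, "observer") <- observers[[id]]
      attr(ses, "episodes") <- episodes[[id]]
      attr(ses, "seed") <- observers[[id]]$seed
      class(ses) <- c("perim_session", class(ses))
      f <- file.path(sessions_dir, paste0(id, ".csv"))
      write_session(ses, f)
      files <- c(files, f, paste0(f, ".json"))
    }
  }

  qc <- analyze_cohort(cohort, window_s = config$window_s,
                       error_threshold = config$error_threshold,
                       cutoff_mode = config$cutoff_mode,
                       fixed_cutoff = config$fixed_cutoff)

  series_file <- file.path(config$out_dir, "series.csv")
  long <- tidyr::pivot_longer(
    tibble::as_tibble(qc$series)[, c("subject_id", "t_s", "rt", "rtv",
                                     "error_rate", "err_mask")],
    cols = c("rt", "rtv", "error_rate", "err_mask"),
    names_to = "variable", values_to = "value",
    values_transform = as.numeric
  )
  readr::write_csv(long, series_file)
  files <- c(files, series_file)

  report_file <- file.path(config$out_dir, "report.json")
  report <- list(
    glance = as.list(glance(qc)),
    cutoff_rt = as.list(qc$cutoff_rt),
    cutoff_rtv = as.list(qc$cutoff_rtv),
    subjects = tidy(qc),
    seed = config$seed
  )
  jsonlite::write_json(report, report_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  files <- c(files, report_file)

  manifest_file <- file.path(config$out_dir, "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("perimqc")),
    config_hash = rlang::hash(unclass(config)[
      setdiff(names(config), "out_dir")
    ]),
    master_seed = config$seed,
    files = sort(basename(files))
  )
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       pretty = TRUE)
  attr(qc, "manifest") <- manifest
  invisible(qc)
}
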