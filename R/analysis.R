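#' Pooled ROC curve for a quality predictor
#'
#' Pools the per-second predictor samples (normalized RT or RTV) of all
#' subjects and treats the increased-error-period mask — the catch-trial gold
#' standard — as the truth label. For every candidate cut-off `c` (every
#' distinct pooled value, plus `-Inf`), sensitivity is the fraction of
#' positive seconds with predictor `> c` and specificity the fraction of
#' negative seconds with predictor `<= c`.
#'
#' @param series A `perim_series` tibble (typically from [cohort_series()])
#'   with the predictor column and the logical `err_mask` truth column.
#' @param predictor Which predictor column to evaluate, `"rtv"` or `"rt"`
#'   (any numeric column name is accepted).
#' @param truth Name of the logical truth column.
#' @return A tibble of class `perim_roc` with `cutoff`, `sensitivity`,
#'   `specificity`, ordered by increasing cut-off. Attributes: `predictor`,
#'   `values` (the pooled predictor samples), `n_pos`, `n_neg`.
#' @export
pooled_roc <- function(series, predictor = c("rtv", "rt"),
                       truth = "err_mask") {
  predictor <- if (is.character(predictor)) predictor[1] else predictor
  x <- series[[predictor]]
  y <- series[[truth]]
  stopifnot(is.numeric(x), is.logical(y), length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC undefined: need at least one positive and one negative sample",
         call. = FALSE)
  }
  u <- sort(unique(x))
  # counts of samples <= each candidate cut-off, split by label
  pos_le <- cumsum(tabulate(match(sort(x[y]), u), nbins = length(u)))
  neg_le <- cumsum(tabulate(match(sort(x[!y]), u), nbins = length(u)))
  out <- tibble::tibble(
    cutoff = c(-Inf, u),
    sensitivity = c(1, (n_pos - pos_le) / n_pos),
    specificity = c(0, neg_le / n_neg)
  )
  attr(out, "predictor") <- predictor
  attr(out, "values") <- x
  attr(out, "n_pos") <- n_pos
  attr(out, "n_neg") <- n_neg
  class(out) <- c("perim_roc", class(out))
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal area over (1 - specificity, sensitivity). Equals the
#' probability that a random positive sample outranks a random negative one,
#' with ties counted half.
#'
#' @param curve A `perim_roc` from [pooled_roc()].
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(curve) {
  stopifnot(nrow(curve) >= 2)
  fpr <- 1 - curve$specificity
  tpr <- curve$sensitivity
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Youden-optimal cut-off selection
#'
#' Selects the cut-off maximizing the Youden index `J = sensitivity +
#' specificity - 1`; ties are broken toward the larger cut-off (fewer flagged
#' seconds). The percentile of the cut-off within the pooled predictor values
#' uses the inclusive empirical distribution function (fraction of values
#' `<=` cut-off).
#'
#' @param curve A `perim_roc` from [pooled_roc()].
#' @param values Pooled predictor values for the percentile; defaults to the
#'   samples stored in the curve.
#' @return A one-row tibble of class `perim_cutoff`: `predictor`, `auroc`,
#'   `cutoff`, `sensitivity`, `specificity`, `youden_j`, `percentile`.
#' @export
youden_cutoff <- function(curve, values = attr(curve, "values")) {
  j <- curve$sensitivity + curve$specificity - 1
  best <- max(j)
  idx <- which(j >= best - 1e-12)
  idx <- idx[which.max(curve$cutoff[idx])]
  cutoff <- curve$cutoff[idx]
  percentile <- if (is.null(values)) NA_real_ else 100 * mean(values <= cutoff)
  out <- tibble::tibble(
    predictor = attr(curve, "predictor") %||% NA_character_,
    auroc = auroc(curve),
    cutoff = cutoff,
    sensitivity = curve$sensitivity[idx],
    specificity = curve$specificity[idx],
    youden_j = j[idx],
    percentile = percentile
  )
  class(out) <- c("perim_cutoff", class(out))
  out
}

#' Flag deviant predictor values
#'
#' Seconds with a normalized predictor value strictly above the cut-off count
#' as deviant.
#'
#' @param values Numeric vector (normalized predictor samples).
#' @param cutoff Cut-off value.
#' @return Logical vector, `values > cutoff`.
#' @export
deviant_value_mask <- function(values, cutoff) {
  values > cutoff
}

#' Agreement index between two binary time masks
#'
#' The agreement index (AI) is the Jaccard index of the two masks: time with
#' both an increased catch-trial error rate and deviant predictor values,
#' over time with either, counted in grid samples. When the union is empty
#' the AI is undefined and returned as `NA` (such subjects are excluded from
#' cohort medians).
#'
#' @param error_mask,deviant_mask Logical vectors on the same grid.
#' @return A one-row tibble: `ai`, `seconds_intersection`, `seconds_union`.
#' @examples
#' agreement_index(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
agreement_index <- function(error_mask, deviant_mask) {
  if (length(error_mask) != length(deviant_mask)) {
    stop("masks must share one grid", call. = FALSE)
  }
  inter <- sum(error_mask & deviant_mask, na.rm = TRUE)
  union <- sum(error_mask | deviant_mask, na.rm = TRUE)
  tibble::tibble(
    ai = if (union > 0) inter / union else NA_real_,
    seconds_intersection = inter,
    seconds_union = union
  )
}

#' Spearman rank correlation with a large-sample p-value
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with the
#' two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' When either input has zero rank variance the coefficient is undefined and
#' returned as `NA`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return A one-row tibble: `rho`, `p_value`, `n`.
#' @examples
#' spearman_rho(1:10, (1:10)^2)  # rho = 1, monotone
#' @export
spearman_rho <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(x, y, method = "spearman")
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(rho = rho, p_value = p, n = n)
}

#' Per-subject Spearman analysis of RT and RTV against the error rate
#'
#' For every subject, correlates the per-second error rate with the
#' normalized RT and RTV series using Spearman rank correlation. Subjects
#' whose error-rate series is constant (e.g. zero errors) get an undefined,
#' `NA`-flagged coefficient.
#'
#' @param series A `perim_series` tibble covering one or more subjects, with
#'   columns `rt`, `rtv`, `error_rate`.
#' @return A tibble of class `perim_correlations`: one row per subject with
#'   `subject_id`, `rho_rt`, `p_rt`, `rho_rtv`, `p_rtv`, `n`.
#' @export
individual_analysis <- function(series) {
  out <- dplyr::group_modify(
    dplyr::group_by(tibble::as_tibble(series), .data$subject_id),
    function(d, key) {
      crt <- spearman_rho(d$error_rate, d$rt)
      crtv <- spearman_rho(d$error_rate, d$rtv)
      tibble::tibble(rho_rt = crt$rho, p_rt = crt$p_value,
                     rho_rtv = crtv$rho, p_rtv = crtv$p_value,
                     n = crt$n)
    }
  )
  out <- dplyr::ungroup(out)
  class(out) <- c("perim_correlations", class(out))
  out
}

#' Per-subject agreement indices
#'
#' Applies a deviant-value cut-off (typically the Youden optimum from the
#' pooled analysis) to every subject's normalized predictor series and
#' computes the agreement index against the subject's increased-error mask.
#'
#' @param series A `perim_series` tibble covering one or more subjects.
#' @param cutoff Deviant-value cut-off on the normalized predictor scale.
#' @param predictor Predictor column, `"rtv"` (default) or `"rt"`.
#' @return A tibble of class `perim_agreement`: one row per subject with
#'   `subject_id`, `ai`, `seconds_intersection`, `seconds_union`.
#' @export
agreement_analysis <- function(series, cutoff, predictor = "rtv") {
  out <- dplyr::group_modify(
    dplyr::group_by(tibble::as_tibble(series), .data$subject_id),
    function(d, key) {
      agreement_index(d$err_mask, deviant_value_mask(d[[predictor]], cutoff))
    }
  )
  out <- dplyr::ungroup(out)
  attr(out, "cutoff") <- cutoff
  attr(out, "predictor") <- predictor
  class(out) <- c("perim_agreement", class(out))
  out
}

#' Meta-correlation of a per-subject statistic with total errors
#'
#' Spearman correlation between a per-subject quality statistic (agreement
#' index or individual correlation coefficient) and the subjects' total
#' catch-trial error counts. Pairs with an undefined statistic are dropped.
#'
#' @param stat Numeric vector, one value per subject (`NA` allowed).
#' @param total_errors Integer vector of total error counts, same length.
#' @return A one-row tibble: `rho`, `p_value`, `n`.
#' @export
meta_correlation <- function(stat, total_errors) {
  stopifnot(length(stat) == length(total_errors))
  spearman_rho(stat, total_errors)
}

#' End-to-end quality analysis of a cohort
#'
#' Runs the full analysis on a cohort of sessions: per-subject series
#' ([cohort_series()]), pooled ROC + AUROC + Youden cut-off for both RT and
#' RTV, per-subject agreement indices at the RTV cut-off, per-subject
#' Spearman correlations, and the two meta-correlations (AI vs total errors;
#' individual RTV coefficient vs total errors).
#'
#' @param cohort A `perim_cohort` tibble from [simulate_cohort()] or
#'   [read_sessions()].
#' @param window_s Sliding-window length in seconds.
#' @param error_threshold Errors per minute defining the gold-standard mask.
#' @param cutoff_mode `"youden"` (select the cut-off from the pooled ROC) or
#'   `"fixed"` (use `fixed_cutoff`).
#' @param fixed_cutoff Cut-off on the normalized predictor scale when
#'   `cutoff_mode = "fixed"`.
#' @return A list of class `perim_qc` with elements `series`, `roc_rt`,
#'   `roc_rtv`, `cutoff_rt`, `cutoff_rtv`, `agreement`, `correlations`,
#'   `errors` (per-subject totals), `meta_ai`, `meta_rho_rtv`, and the
#'   analysis options. Use [glance()] / [tidy()] for flat summaries.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(n_subjects = 8, seed = 1)
#' qc <- analyze_cohort(cohort)
#' glance(qc)
#' }
#' @export
analyze_cohort <- function(cohort, window_s = 60, error_threshold = 2,
                           cutoff_mode = c("youden", "fixed"),
                           fixed_cutoff = NULL) {
  cutoff_mode <- match.arg(cutoff_mode)
  series <- if (inherits(cohort, "perim_series")) cohort else {
    cohort_series(cohort, window_s = window_s,
                  error_threshold = error_threshold)
  }
  errors <- catch_trial_errors(cohort)
  if (!is.data.frame(errors)) {
    errors <- tibble::tibble(subject_id = cohort$subject_id[1] %||% "S001",
                             total_errors = errors)
  }

  roc_rt <- pooled_roc(series, "rt")
  roc_rtv <- pooled_roc(series, "rtv")
  cutoff_rt <- youden_cutoff(roc_rt)
  cutoff_rtv <- youden_cutoff(roc_rtv)
  rtv_cut <- if (cutoff_mode == "fixed") {
    stopifnot(!is.null(fixed_cutoff))
    fixed_cutoff
  } else {
    cutoff_rtv$cutoff
  }

  agreement <- agreement_analysis(series, cutoff = rtv_cut, predictor = "rtv")
  agreement <- dplyr::left_join(agreement, errors, by = "subject_id")
  correlations <- individual_analysis(series)
  correlations <- dplyr::left_join(correlations, errors, by = "subject_id")

  structure(
    list(
      series = series,
      roc_rt = roc_rt,
      roc_rtv = roc_rtv,
      cutoff_rt = cutoff_rt,
      cutoff_rtv = cutoff_rtv,
      agreement = agreement,
      correlations = correlations,
      errors = errors,
      meta_ai = safe_meta(agreement$ai, agreement$total_errors),
      meta_rho_rtv = safe_meta(correlations$rho_rtv,
                               correlations$total_errors),
      window_s = window_s,
      error_threshold = error_threshold,
      cutoff_mode = cutoff_mode,
      rtv_cutoff_used = rtv_cut
    ),
    class = "perim_qc"
  )
}

# meta-correlation degrading to NA when fewer than 3 defined pairs remain
safe_meta <- function(stat, total_errors) {
  n_ok <- sum(!is.na(stat) & !is.na(total_errors))
  if (n_ok < 3) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n_ok))
  }
  meta_correlation(stat, total_errors)
}

#' @export
print.perim_qc <- function(x, ...) {
  cat("<perim_qc> cohort quality analysis\n")
  cat(sprintf("  subjects: %d, grid seconds: %d\n",
              nrow(x$errors), nrow(x$series)))
  cat(sprintf("  AUROC: RT %.4f, RTV %.4f\n",
              x$cutoff_rt$auroc, x$cutoff_rtv$auroc))
  cat(sprintf(
    "  RTV cut-off %.4f (sens %.2f, spec %.2f, %.0fth percentile)\n",
    x$cutoff_rtv$cutoff, x$cutoff_rtv$sensitivity,
    x$cutoff_rtv$specificity, x$cutoff_rtv$percentile
  ))
  cat(sprintf("  AI median/max: %.2f/%.2f; meta rho(AI, errors) %.2f\n",
              stats::median(x$agreement$ai, na.rm = TRUE),
              suppressWarnings(max(x$agreement$ai, na.rm = TRUE)),
              x$meta_ai$rho))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Per-subject results of a cohort quality analysis
#'
#' @param x A `perim_qc` from [analyze_cohort()].
#' @param ... Unused.
#' @return A tibble with one row per subject: total errors, agreement index,
#'   and the individual Spearman coefficients for RT and RTV.
#' @export
tidy.perim_qc <- function(x, ...) {
  dplyr::left_join(
    x$agreement[, c("subject_id", "ai", "total_errors")],
    x$correlations[, c("subject_id", "rho_rt", "p_rt", "rho_rtv", "p_rtv")],
    by = "subject_id"
  )
}

#' Cohort-level summary of a quality analysis
#'
#' @param x A `perim_qc` from [analyze_cohort()].
#' @param ... Unused.
#' @return A one-row tibble with the pooled AUROCs, the Youden cut-off
#'   operating point for RTV, AI and individual-coefficient medians/maxima,
#'   and the two meta-correlations.
#' @export
glance.perim_qc <- function(x, ...) {
  ai <- x$agreement$ai
  tibble::tibble(
    n_subjects = nrow(x$errors),
    auroc_rt = x$cutoff_rt$auroc,
    auroc_rtv = x$cutoff_rtv$auroc,
    rtv_cutoff = x$cutoff_rtv$cutoff,
    rtv_sensitivity = x$cutoff_rtv$sensitivity,
    rtv_specificity = x$cutoff_rtv$specificity,
    rtv_cutoff_percentile = x$cutoff_rtv$percentile,
    ai_median = stats::median(ai, na.rm = TRUE),
    ai_max = if (all(is.na(ai))) NA_real_ else max(ai, na.rm = TRUE),
    rho_rt_median = stats::median(x$correlations$rho_rt, na.rm = TRUE),
    rho_rtv_median = stats::median(x$correlations$rho_rtv, na.rm = TRUE),
    rho_rtv_max = if (all(is.na(x$correlations$rho_rtv))) NA_real_ else {
      max(x$correlations$rho_rtv, na.rm = TRUE)
    },
    errors_median = stats::median(x$errors$total_errors),
    errors_max = max(x$errors$total_errors),
    meta_rho_ai = x$meta_ai$rho,
    meta_rho_ai_p = x$meta_ai$p_value,
    meta_rho_individual = x$meta_rho_rtv$rho,
    meta_rho_individual_p = x$meta_rho_rtv$p_value
  )
}
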