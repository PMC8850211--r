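# Independent brute-force oracles and small fixtures used across tests.

# a small, fast protocol: 4 levels x (3 peripheral x 5 + 1 reference) = 64
# regular presentations, 128 total at the default 25% + 25% catch rates
small_protocol <- function(...) {
  perim_protocol(
    stimulus_levels_db = c(3, 15, 27, 39),
    reps_peripheral = 5,
    reps_reference = 1,
    ...
  )
}

# bare-bones session tibble for series tests: regular events plus catch
# trials at given onsets, with explicit error flags
make_session <- function(onset_s, kind, responded, rt_ms = NULL,
                         subject_id = "T01") {
  n <- length(onset_s)
  tibble::tibble(
    index = seq_len(n),
    onset_s = onset_s,
    kind = kind,
    db = ifelse(kind == "catch_supra", 0,
                ifelse(kind == "catch_infra", 40, 20)),
    responded = responded,
    rt_ms = if (is.null(rt_ms)) ifelse(responded, 400, NA_real_) else rt_ms,
    subject_id = subject_id
  )
}

# random small labelled instance for ROC-family oracle checks
random_instance <- function(seed, n_max = 20, discrete = FALSE) {
  withr::with_seed(seed, {
    n <- sample(4:n_max, 1)
    y <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    x <- if (discrete) {
      sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    } else {
      stats::runif(n)
    }
    list(x = x, y = y)
  })
}

# run the pooled ROC machinery on bare vectors
roc_from_vectors <- function(x, y) {
  pooled_roc(tibble::tibble(value = x, err_mask = y), predictor = "value")
}

# two-point linear interpolation with flat extension, evaluated pointwise
bf_interp <- function(obs_t, obs_v, t) {
  vapply(t, function(tt) {
    if (tt <= obs_t[1]) return(obs_v[1])
    n <- length(obs_t)
    if (tt >= obs_t[n]) return(obs_v[n])
    i <- max(which(obs_t <= tt))
    if (obs_t[i] == tt) return(obs_v[i])
    w <- (tt - obs_t[i]) / (obs_t[i + 1] - obs_t[i])
    (1 - w) * obs_v[i] + w * obs_v[i + 1]
  }, numeric(1))
}

# population variance over the trailing window (t - window, t]
bf_window_var <- function(t_s, x, window) {
  vapply(seq_along(t_s), function(i) {
    w <- x[t_s > t_s[i] - window & t_s <= t_s[i]]
    mean((w - mean(w))^2)
  }, numeric(1))
}

# exhaustive ROC over every distinct threshold plus -Inf
bf_roc <- function(x, y) {
  cuts <- c(-Inf, sort(unique(x)))
  tibble::tibble(
    cutoff = cuts,
    sensitivity = vapply(cuts, function(c) mean(x[y] > c), numeric(1)),
    specificity = vapply(cuts, function(c) mean(x[!y] <= c), numeric(1))
  )
}

# P(random positive outranks random negative), ties half-counted
bf_auroc_pairs <- function(x, y) {
  pos <- x[y]; neg <- x[!y]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# brute-force Youden optimum: max J over all thresholds, ties -> larger cutoff
bf_youden <- function(x, y) {
  r <- bf_roc(x, y)
  j <- r$sensitivity + r$specificity - 1
  best <- max(j)
  idx <- which(abs(j - best) < 1e-12)
  idx <- idx[which.max(r$cutoff[idx])]
  list(cutoff = r$cutoff[idx], j = best,
       sensitivity = r$sensitivity[idx], specificity = r$specificity[idx])
}

# Jaccard index by explicit set operations on flagged indices
bf_jaccard <- function(a, b) {
  ia <- which(a); ib <- which(b)
  u <- union(ia, ib)
  if (length(u) == 0) return(NA_real_)
  length(intersect(ia, ib)) / length(u)
}

# Spearman via explicit mid-ranks and the Pearson formula
bf_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
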