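#' Specification for event-related BOLD epochs
#'
#' Epochs run from 2 volumes before to 8 volumes after outcome onset at
#' TR = 2 s (11 volumes, times -4 to +16 s), are normalized to the
#' pre-outcome baseline window (-4 to 0 s, i.e. the two pre-onset volumes),
#' and expressed as percent signal change. The synthetic generator injects a
#' double-gamma hemodynamic response scaled so its 6 s sample equals 1, with
#' trial amplitude `amp_baseline + history_gain * history_level` (levels 0,
#' 1, 2 for no / one / two-or-more prior punishments) plus Gaussian noise.
#'
#' @param tr Repetition time in seconds.
#' @param pre_volumes,post_volumes Epoch extent around onset, in volumes.
#' @param baseline_window Baseline window in seconds relative to onset
#'   (volumes with `baseline_window[1] <= t < baseline_window[2]`).
#' @param baseline_level Raw signal baseline (so 1 raw unit = 1% change).
#' @param amp_baseline Response amplitude at history level 0, in percent.
#' @param history_gain Amplitude increase per history level, in percent.
#' @param noise_sd Per-volume Gaussian noise SD, in percent.
#' @export
bold_spec <- function(tr = 2, pre_volumes = 2, post_volumes = 8,
                      baseline_window = c(-4, 0), baseline_level = 100,
                      amp_baseline = 0.5, history_gain = 0.1,
                      noise_sd = 0.1) {
  structure(list(tr = tr, pre_volumes = pre_volumes,
                 post_volumes = post_volumes,
                 baseline_window = baseline_window,
                 baseline_level = baseline_level,
                 amp_baseline = amp_baseline, history_gain = history_gain,
                 noise_sd = noise_sd),
            class = "bold_spec")
}

# Canonical double-gamma HRF, rescaled so h(6) = 1. Support is windowed to
# (0, 32) s -- the response is numerically ~0 there anyway -- so that widely
# spaced synthetic trials are exactly non-overlapping.
hrf_double_gamma <- function(t) {
  h <- function(x) {
    ifelse(x <= 0 | x >= 32, 0,
           dgamma(x, shape = 6, rate = 1) -
             dgamma(x, shape = 16, rate = 1) / 6)
  }
  h(t) / h(6)
}

#' Punishment-history labels for reward trials in mixed blocks
#'
#' Walks each subject's mixed blocks chronologically. For every valid
#' reward trial it records (a) the number of punishment deliveries
#' (outcome -1 on punishment pairs) since the previous reward trial in the
#' block (counter starts at 0 at block start and resets after every reward
#' trial), binned as 0 / 1 / 2-or-more (`count_level` 1-3), and (b) the
#' recency of the most recent punishment delivery in trials (also reset
#' after each reward; `NA` when none occurred). Recency is split into three
#' equal-sized per-subject tertiles (`recency_level` 1 = least recent to
#' 3 = most recent; sizes differ by at most 1, ties broken by trial order).
#'
#' @param data A `choice_data` data frame.
#' @return Data frame with one row per valid mixed-block reward trial:
#'   `subject`, `block`, `trial`, `outcome`, `pun_count`, `count_level`,
#'   `recency`, `recency_level`.
#' @export
punishment_history <- function(data) {
  out <- list()
  for (sj in unique(data$subject)) {
    ds <- data[data$subject == sj & data$context == "mixed", , drop = FALSE]
    for (b in unique(ds$block)) {
      db <- ds[ds$block == b, , drop = FALSE]
      db <- db[order(db$trial), , drop = FALSE]
      count <- 0L
      last_pun <- NA_integer_
      for (i in seq_len(nrow(db))) {
        row <- db[i, ]
        if (!row$valid) next
        if (row$valence == "reward") {
          out[[length(out) + 1L]] <- data.frame(
            subject = sj, block = b, trial = row$trial,
            outcome = row$outcome, pun_count = count,
            recency = if (is.na(last_pun)) NA_real_
                      else row$trial - last_pun)
          count <- 0L
          last_pun <- NA_integer_
        } else if (row$outcome == -1) {
          count <- count + 1L
          last_pun <- row$trial
        }
      }
    }
  }
  h <- do.call(rbind, out)
  h$count_level <- pmin(h$pun_count, 2L) + 1L
  h$recency_level <- NA_integer_
  for (sj in unique(h$subject)) {
    i <- which(h$subject == sj & !is.na(h$recency))
    if (!length(i)) next
    # least recent (largest recency) first; ties by trial order
    ord <- i[order(-h$recency[i], seq_along(i))]
    h$recency_level[ord] <- tertile_sizes(length(ord))
  }
  h
}

# Level labels 1,2,3 with group sizes differing by at most one (earlier
# groups take the remainder).
tertile_sizes <- function(n) {
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- base + (seq_len(3L) <= rem)
  rep(1:3, times = sizes)
}

#' Epoch a raw ROI series and convert to percent signal change
#'
#' Cuts per-trial epochs from `pre_volumes` before to `post_volumes` after
#' each onset, subtracts the baseline-window mean, and scales to percent
#' change relative to that mean. Trials whose epoch exceeds the series are
#' dropped (recorded in `dropped`).
#'
#' @param raw_series Numeric vector, one value per volume.
#' @param onsets Integer volume indices (1-based) of outcome onsets.
#' @param spec A [bold_spec()].
#' @return List with `epochs` (trial x 11 matrix of percent change),
#'   `times` (seconds relative to onset), `kept`, `dropped`.
#' @export
epoch_and_normalize <- function(raw_series, onsets, spec = bold_spec()) {
  nv <- spec$pre_volumes + spec$post_volumes + 1L
  times <- seq(-spec$pre_volumes, spec$post_volumes) * spec$tr
  base_idx <- which(times >= spec$baseline_window[1] &
                    times < spec$baseline_window[2])
  keep <- onsets - spec$pre_volumes >= 1 &
    onsets + spec$post_volumes <= length(raw_series)
  kept <- which(keep)
  epochs <- matrix(NA_real_, length(kept), nv)
  for (j in seq_along(kept)) {
    idx <- (onsets[kept[j]] - spec$pre_volumes):(onsets[kept[j]] + spec$post_volumes)
    x <- raw_series[idx]
    bmean <- mean(x[base_idx])
    epochs[j, ] <- 100 * (x - bmean) / bmean
  }
  list(epochs = epochs, times = times, kept = kept,
       dropped = which(!keep))
}

#' Simulate ROI time series for mixed-block reward trials
#'
#' Ground-truth generator for the punishment-history analyses: for every
#' valid reward trial in a mixed block it injects a double-gamma response
#' into a flat raw series (one widely spaced onset per trial), with
#' amplitude `amp_baseline + history_gain * (count_level - 1)` percent plus
#' Gaussian noise, then epochs and normalizes the series with
#' [epoch_and_normalize()].
#'
#' @param data A `choice_data` data frame (needs mixed-block reward trials).
#' @param spec A [bold_spec()].
#' @param seed Integer seed.
#' @param roi ROI label stored in the output.
#' @return An object of class `roi_timeseries`: `epochs` (trial x 11 matrix
#'   of percent signal change), `times`, `meta` (one row per trial with the
#'   [punishment_history()] labels), `roi`, `spec`.
#' @export
simulate_bold <- function(data, spec = bold_spec(), seed = 1,
                          roi = "caudate") {
  hist <- punishment_history(data)
  if (is.null(hist) || nrow(hist) == 0) stop("no mixed-block reward trials")
  spacing <- 20L  # 40 s between onsets: beyond the HRF window, no overlap
  epochs_all <- NULL
  meta_all <- list()
  with_seed(seed, {
    for (sj in unique(hist$subject)) {
      hs <- hist[hist$subject == sj, , drop = FALSE]
      n <- nrow(hs)
      len <- n * spacing + spacing
      onsets <- spec$pre_volumes + 1L + spacing * (seq_len(n) - 1L)
      raw <- rep(spec$baseline_level, len)
      tgrid <- seq_len(len)
      for (i in seq_len(n)) {
        amp <- spec$amp_baseline + spec$history_gain * (hs$count_level[i] - 1)
        t_rel <- (tgrid - onsets[i]) * spec$tr
        raw <- raw + amp * hrf_double_gamma(t_rel)
      }
      if (spec$noise_sd > 0)
        raw <- raw + rnorm(len, sd = spec$noise_sd)
      ep <- epoch_and_normalize(raw, onsets, spec)
      epochs_all <- rbind(epochs_all, ep$epochs)
      meta_all[[length(meta_all) + 1L]] <- hs
    }
  })
  structure(list(epochs = epochs_all,
                 times = seq(-spec$pre_volumes, spec$post_volumes) * spec$tr,
                 meta = do.call(rbind, meta_all), roi = roi, spec = spec),
            class = "roi_timeseries")
}

#' Tertile binning of signed prediction errors
#'
#' Splits each subject x condition's signed PEs into three equal-sized bins
#' (low, medium, high; sizes differ by at most 1, ties at bin boundaries
#' assigned deterministically by trial order) and reports the per-bin mean
#' PE for context-equivalence checks.
#'
#' @param pe_table Data frame with columns `subject`, `condition`, `pe`,
#'   chronological within subject x condition.
#' @return List with `labels` (bin 1-3 per row of `pe_table`) and
#'   `bin_means` (per subject x condition x bin mean PE).
#' @export
bin_pe_tertiles <- function(pe_table) {
  stopifnot(all(c("subject", "condition", "pe") %in% names(pe_table)))
  labels <- integer(nrow(pe_table))
  means <- list()
  for (sj in unique(pe_table$subject)) {
    for (cond in unique(pe_table$condition)) {
      i <- which(pe_table$subject == sj & pe_table$condition == cond)
      if (!length(i)) next
      if (length(i) < 3) stop("fewer than 3 trials for subject ", sj,
                              " in ", cond)
      ord <- i[order(pe_table$pe[i], seq_along(i))]
      labels[ord] <- tertile_sizes(length(ord))
      for (bin in 1:3) {
        means[[length(means) + 1L]] <- data.frame(
          subject = sj, condition = cond, bin = bin,
          mean_pe = mean(pe_table$pe[ord][tertile_sizes(length(ord)) == bin]))
      }
    }
  }
  list(labels = labels, bin_means = do.call(rbind, means))
}

#' Per-subject slope of BOLD measures over punishment-history levels
#'
#' For each subject, averages the chosen measure -- the 6 s post-outcome
#' sample (`"peak6s"`) or the 0-to-6 s ramp (`"ramp0to6"`) -- within each
#' history level (count or recency, coded 1-3), fits an OLS slope across
#' the occupied levels, and tests the group of slopes against zero with a
#' one-tailed one-sample t test (positive slope = stronger reward response
#' with more/ more recent punishment). Subjects with fewer than two
#' occupied levels are excluded (listed in `excluded`).
#'
#' @param roi_ts A [simulate_bold()] / `roi_timeseries` object.
#' @param bins `"count"` or `"recency"` history coding.
#' @param measure `"peak6s"` or `"ramp0to6"`.
#' @return List with `slopes` (per subject), `t`, `df`, `p` (one-tailed),
#'   `cohens_d`, `excluded`.
#' @export
history_slope_test <- function(roi_ts, bins = c("count", "recency"),
                               measure = c("peak6s", "ramp0to6")) {
  bins <- match.arg(bins)
  measure <- match.arg(measure)
  level <- switch(bins, count = roi_ts$meta$count_level,
                  recency = roi_ts$meta$recency_level)
  i6 <- which(roi_ts$times == 6)
  i0 <- which(roi_ts$times == 0)
  m <- switch(measure,
              peak6s = roi_ts$epochs[, i6],
              ramp0to6 = roi_ts$epochs[, i6] - roi_ts$epochs[, i0])
  subjects <- unique(roi_ts$meta$subject)
  slopes <- c()
  excluded <- c()
  for (sj in subjects) {
    i <- which(roi_ts$meta$subject == sj & !is.na(level))
    if (!length(i)) { excluded <- c(excluded, sj); next }
    lv <- level[i]
    bin_mean <- tapply(m[i], lv, mean)
    lvls <- as.numeric(names(bin_mean))
    if (length(lvls) < 2) { excluded <- c(excluded, sj); next }
    slopes[as.character(sj)] <- unname(coef(lm(bin_mean ~ lvls))[2])
  }
  if (length(slopes) < 2) stop("fewer than 2 subjects with usable slopes")
  if (sd(slopes) < 1e-14) {
    # degenerate noise-free case: all slopes identical
    m <- mean(slopes)
    return(list(slopes = slopes, t = if (m > 0) Inf else if (m < 0) -Inf else 0,
                df = length(slopes) - 1,
                p = if (m > 0) 0 else 1,
                cohens_d = if (m == 0) 0 else sign(m) * Inf,
                excluded = excluded))
  }
  tt <- t.test(slopes, alternative = "greater")
  list(slopes = slopes, t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value,
       cohens_d = mean(slopes) / sd(slopes), excluded = excluded)
}
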