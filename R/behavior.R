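#' Per-subject condition summaries
#'
#' Computes, for every subject x condition (reward-mixed, reward-only,
#' punishment-mixed, punishment-only) over valid trials only:
#' * `accuracy` -- proportion of "good" choices (high-probability reward /
#'   low-probability punishment option);
#' * `stay_after_positive` -- proportion of repeated choices on a pair's
#'   next presentation after positive feedback (a win, or an avoided loss on
#'   punishment pairs);
#' * `switch_after_negative` -- proportion of switches after negative
#'   feedback (reward omission or a loss);
#' * `stay_switch_index` -- mean of the two proportions (a single index; the
#'   raw proportions are kept alongside);
#' * `mean_rt` -- mean response time in seconds;
#' * `learning_slope` -- per-subject regression slope of correct (0/1) on
#'   trial-in-pair (1-20), linear by default, logistic on request.
#'
#' @param data A `choice_data` data frame.
#' @param slope_method `"linear"` (OLS) or `"logistic"` (GLM) learning
#'   slope.
#' @return Data frame with one row per subject x condition.
#' @export
summarize_conditions <- function(data, slope_method = c("linear", "logistic")) {
  slope_method <- match.arg(slope_method)
  d <- data[data$valid, , drop = FALSE]
  out <- list()
  for (sj in unique(d$subject)) {
    for (cond in CONDITIONS) {
      dc <- d[d$subject == sj & d$condition == cond, , drop = FALSE]
      if (nrow(dc) == 0)
        stop("subject ", sj, " has no valid trials in ", cond)
      correct <- as.integer(dc$choice == "good")
      ss <- stay_switch(dc)
      slope <- if (length(unique(dc$trial_in_pair)) < 2) NA_real_
        else if (slope_method == "linear")
          unname(coef(lm(correct ~ dc$trial_in_pair))[2])
        else
          unname(coef(stats::glm(correct ~ dc$trial_in_pair,
                                 family = stats::binomial()))[2])
      out[[paste(sj, cond)]] <- data.frame(
        subject = sj, condition = cond,
        accuracy = mean(correct),
        stay_after_positive = ss$stay_after_positive,
        switch_after_negative = ss$switch_after_negative,
        stay_switch_index = mean(c(ss$stay_after_positive,
                                   ss$switch_after_negative)),
        mean_rt = mean(dc$rt),
        learning_slope = slope,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Stay/switch proportions over consecutive valid presentations of the same
# pair. Positive feedback = win or avoided loss; negative = omission or loss.
stay_switch <- function(dc) {
  stay_pos <- stay_neg <- c()
  for (p in unique(dc$pair)) {
    dp <- dc[dc$pair == p, , drop = FALSE]
    if (nrow(dp) < 2) next
    prev <- dp[-nrow(dp), ]
    nxt <- dp[-1, ]
    stayed <- nxt$choice == prev$choice
    positive <- prev$outcome == 1 |
      (prev$valence == "punishment" & prev$outcome == 0)
    stay_pos <- c(stay_pos, stayed[positive])
    stay_neg <- c(stay_neg, stayed[!positive])
  }
  list(stay_after_positive = if (length(stay_pos)) mean(stay_pos) else NA_real_,
       switch_after_negative = if (length(stay_neg)) mean(!stay_neg) else NA_real_)
}

#' Two-by-two repeated-measures ANOVA
#'
#' Within-subject ANOVA with factors context (mixed vs only) and valence
#' (reward vs punishment), computed by the standard sum-of-squares
#' decomposition with subject-by-effect error terms (each effect has df 1,
#' n - 1). Effect sizes are classical eta-squared (`SS_effect / SS_total`);
#' partial eta-squared is reported alongside. A zero-variance error term
#' yields `F = Inf`, `p = 0`, flagged in the output.
#'
#' @param values Data frame or matrix with columns `reward_mixed`,
#'   `reward_only`, `punishment_mixed`, `punishment_only`, one row per
#'   subject (complete cases required, n >= 3).
#' @return Data frame with one row per effect (`context`, `valence`,
#'   `interaction`): `F`, `df1`, `df2`, `p`, `eta_sq`, `eta_sq_partial`,
#'   `zero_variance`.
#' @export
rm_anova_2x2 <- function(values) {
  values <- as.data.frame(values)
  stopifnot(all(CONDITIONS %in% names(values)))
  y <- as.matrix(values[, CONDITIONS])
  if (any(!complete.cases(y))) stop("complete cases required")
  n <- nrow(y)
  if (n < 3) stop("need at least 3 subjects")

  # cell layout: context in {mixed, only}, valence in {reward, punishment}
  cells <- list(mixed_reward = y[, "reward_mixed"],
                only_reward = y[, "reward_only"],
                mixed_punishment = y[, "punishment_mixed"],
                only_punishment = y[, "punishment_only"])
  grand <- mean(y)
  subj_m <- rowMeans(y)
  ctx_m <- c(mixed = mean(c(y[, "reward_mixed"], y[, "punishment_mixed"])),
             only = mean(c(y[, "reward_only"], y[, "punishment_only"])))
  val_m <- c(reward = mean(c(y[, "reward_mixed"], y[, "reward_only"])),
             punishment = mean(c(y[, "punishment_mixed"], y[, "punishment_only"])))
  cell_m <- c(mean(cells$mixed_reward), mean(cells$only_reward),
              mean(cells$mixed_punishment), mean(cells$only_punishment))
  cell_ctx <- c("mixed", "only", "mixed", "only")
  cell_val <- c("reward", "reward", "punishment", "punishment")

  ss_total <- sum((y - grand)^2)
  ss_subj <- 4 * sum((subj_m - grand)^2)
  ss_ctx <- 2 * n * sum((ctx_m - grand)^2)
  ss_val <- 2 * n * sum((val_m - grand)^2)
  ss_int <- n * sum((cell_m - ctx_m[cell_ctx] - val_m[cell_val] + grand)^2)

  ctx_s <- cbind(mixed = (y[, "reward_mixed"] + y[, "punishment_mixed"]) / 2,
                 only = (y[, "reward_only"] + y[, "punishment_only"]) / 2)
  val_s <- cbind(reward = (y[, "reward_mixed"] + y[, "reward_only"]) / 2,
                 punishment = (y[, "punishment_mixed"] + y[, "punishment_only"]) / 2)
  ss_ctx_err <- 2 * sum(sweep(sweep(ctx_s, 2L, ctx_m), 1L, subj_m - grand)^2)
  ss_val_err <- 2 * sum(sweep(sweep(val_s, 2L, val_m), 1L, subj_m - grand)^2)
  ss_int_err <- ss_total - ss_subj - ss_ctx - ss_val - ss_int -
    ss_ctx_err - ss_val_err
  ss_int_err <- max(ss_int_err, 0)

  effect_row <- function(name, ss_eff, ss_err) {
    ms_err <- ss_err / (n - 1)
    zero_var <- ms_err < 1e-14
    f <- if (zero_var) {
      if (ss_eff < 1e-14) 0 else Inf
    } else (ss_eff / 1) / ms_err
    p <- if (is.infinite(f)) 0 else if (zero_var && f == 0) 1
         else pf(f, 1, n - 1, lower.tail = FALSE)
    data.frame(effect = name, F = f, df1 = 1, df2 = n - 1, p = p,
               eta_sq = if (ss_total > 0) ss_eff / ss_total else 0,
               eta_sq_partial = if (ss_eff + ss_err > 0)
                 ss_eff / (ss_eff + ss_err) else 0,
               zero_variance = zero_var,
               stringsAsFactors = FALSE)
  }
  rbind(effect_row("context", ss_ctx, ss_ctx_err),
        effect_row("valence", ss_val, ss_val_err),
        effect_row("interaction", ss_int, ss_int_err))
}

#' Paired contrast with Bonferroni adjustment and Cohen's d
#'
#' Paired t test between two within-subject measures, with Bonferroni
#' family size `m` supplied by the caller (`p_adj = min(1, m * p)`, never
#' smaller than the raw p) and `d = mean(diff) / sd(diff)`.
#'
#' @param x,y Paired vectors.
#' @param m Bonferroni family size.
#' @param alternative Passed to [t.test()] (`"greater"` gives the one-tailed
#'   replication test of `x > y`).
#' @export
paired_contrast <- function(x, y, m = 1, alternative = "two.sided") {
  stopifnot(length(x) == length(y), m >= 1)
  tt <- t.test(x, y, paired = TRUE, alternative = alternative)
  dif <- x - y
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, p_bonferroni = min(1, m * tt$p.value),
             cohens_d = mean(dif) / sd(dif))
}

#' Composite learning index
#'
#' Adds the products `alpha_pos * beta` and `alpha_neg * beta` to a fitted
#' parameter table; the product is more stably estimated than either factor
#' when learning rate and inverse temperature trade off.
#'
#' @param fit_table A [fit_cohort()] data frame from a dual-learning-rate
#'   fit.
#' @export
composite_index <- function(fit_table) {
  stopifnot(all(c("alpha_pos", "alpha_neg", "beta") %in% names(fit_table)))
  fit_table$composite_pos <- fit_table$alpha_pos * fit_table$beta
  fit_table$composite_neg <- fit_table$alpha_neg * fit_table$beta
  fit_table
}

#' Regress accuracy on fitted parameters
#'
#' Ordinary least squares of per-subject mean accuracy in one condition on
#' the fitted `alpha_pos`, `alpha_neg`, and `beta` for that condition, with
#' intercept. Near-collinear design matrices are flagged via the condition
#' number.
#'
#' @param summary_table A [summarize_conditions()] table.
#' @param fit_table A [fit_cohort()] table (dual model).
#' @param condition Condition label to analyze.
#' @param kappa_limit Condition-number threshold for the collinearity flag.
#' @return List with `coefficients` (estimate, se, t, p per term),
#'   `condition_number`, `collinear`.
#' @export
accuracy_on_params_regression <- function(summary_table, fit_table, condition,
                                          kappa_limit = 1e8) {
  a <- summary_table[summary_table$condition == condition,
                     c("subject", "accuracy")]
  b <- fit_table[fit_table$condition == condition,
                 c("subject", "alpha_pos", "alpha_neg", "beta")]
  d <- merge(a, b, by = "subject")
  fit <- lm(accuracy ~ alpha_pos + alpha_neg + beta, data = d)
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "t", "p")
  kap <- kappa(stats::model.matrix(fit), exact = TRUE)
  aliased <- any(is.na(coef(fit)))
  list(coefficients = co, condition_number = kap,
       collinear = aliased || kap > kappa_limit, n = nrow(d))
}

#' Exclude poor learners
#'
#' Applies the prespecified screening filters: a subject is excluded if
#' accuracy is below chance in every block, or below 40% in the first 10
#' trials of every block.
#'
#' @param data A `choice_data` data frame.
#' @return List with `data` (retained rows) and `excluded` (subject ids).
#' @export
filter_poor_learners <- function(data) {
  d <- data[data$valid, , drop = FALSE]
  excluded <- c()
  for (sj in unique(d$subject)) {
    ds <- d[d$subject == sj, , drop = FALSE]
    blocks <- split(ds, ds$block)
    acc_block <- vapply(blocks, function(b) mean(b$choice == "good"), 0)
    acc_first10 <- vapply(blocks, function(b)
      mean(head(b, 10)$choice == "good"), 0)
    if (all(acc_block < 0.5) || all(acc_first10 < 0.4))
      excluded <- c(excluded, sj)
  }
  list(data = data[!data$subject %in% excluded, , drop = FALSE],
       excluded = excluded)
}

#' Export a trial-level table for mixed-effects modelling
#'
#' Long-format table with the variables used by trial-level generalized
#' mixed models of choice accuracy (correct 0/1, context, valence, block
#' repetition, trial number, subject); the estimation itself is left to
#' dedicated mixed-model software.
#'
#' @param data A `choice_data` data frame.
#' @export
export_glme_table <- function(data) {
  d <- data[data$valid, , drop = FALSE]
  rep_idx <- stats::ave(d$block, d$subject, d$context,
                        FUN = function(b) match(b, sort(unique(b))))
  data.frame(subject = d$subject,
             correct = as.integer(d$choice == "good"),
             context = ifelse(d$context == "mixed", "mixed", "only"),
             valence = d$valence,
             block = rep_idx,
             trial = d$trial_in_pair,
             block_id = d$block)
}
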