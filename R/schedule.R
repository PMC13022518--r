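#' Build a task schedule for the probabilistic reward/punishment task
#'
#' The task has six blocks of 40 trials (240 trials total) over three block
#' types -- reward-only, punishment-only, and mixed -- each presented twice in
#' an alternating, counterbalanced order. Every block holds two stimulus
#' pairs with 20 trials each, pseudorandomized so that the same pair is never
#' shown more than four times in a row. In single-valence blocks both pairs
#' share the block's valence; in mixed blocks one pair is a reward pair and
#' the other a punishment pair. The high-probability ("good") option delivers
#' its salient outcome with probability 0.75 in the behavioral version and
#' 0.70 in the fMRI version (wins for reward pairs; for punishment pairs the
#' good option is the one with the *low* loss probability).
#'
#' @param study_version `"behavioral"` (0.75/0.25 outcome probabilities) or
#'   `"fmri"` (0.70/0.30).
#' @param counterbalance_index Integer 0-5 selecting which permutation of the
#'   three block types is alternated (`perm, perm`).
#' @param seed Integer seed controlling the within-block pair order.
#' @return An object of class `task_schedule`: a list with `study_version`,
#'   `outcome_prob_good`, `counterbalance_index`, and `trials`, a data frame
#'   with one row per trial (`block`, `context`, `trial`, `pair`, `valence`,
#'   `trial_in_pair`, `condition`, `p_good`).
#' @examples
#' sch <- make_schedule("behavioral", counterbalance_index = 0, seed = 1)
#' table(sch$trials$condition)
#' @export
make_schedule <- function(study_version = c("behavioral", "fmri"),
                          counterbalance_index = 0, seed = 1) {
  study_version <- match.arg(study_version)
  p_good <- switch(study_version, behavioral = 0.75, fmri = 0.70)
  contexts <- c("reward_only", "punishment_only", "mixed")
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  idx <- as.integer(counterbalance_index) %% 6L
  block_contexts <- contexts[rep(perms[[idx + 1L]], 2L)]

  trials <- with_seed(seed, {
    out <- vector("list", 6L)
    for (b in seq_len(6L)) {
      ctx <- block_contexts[b]
      pair_ids <- c(2L * b - 1L, 2L * b)
      pair_valence <- switch(ctx,
        reward_only     = c("reward", "reward"),
        punishment_only = c("punishment", "punishment"),
        mixed           = c("reward", "punishment"))
      order_ids <- shuffle_pairs(pair_ids, n_each = 20L, max_run = 4L)
      valence <- pair_valence[match(order_ids, pair_ids)]
      out[[b]] <- data.frame(
        block = b, context = ctx, trial = seq_len(40L),
        pair = order_ids, valence = valence,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  trials$trial_in_pair <- stats::ave(trials$trial, trials$pair,
                                     FUN = seq_along)
  trials$condition <- condition_label(trials$context, trials$valence)
  trials$p_good <- p_good
  structure(list(study_version = study_version,
                 outcome_prob_good = p_good,
                 counterbalance_index = idx,
                 trials = trials),
            class = "task_schedule")
}

# Interleave two pair ids, 20 trials each, rejecting draws with more than
# `max_run` consecutive repeats of the same pair.
shuffle_pairs <- function(pair_ids, n_each = 20L, max_run = 4L) {
  base <- rep(pair_ids, each = n_each)
  repeat {
    ord <- sample(base)
    if (max(rle(ord)$lengths) <= max_run) return(ord)
  }
}

#' @export
print.task_schedule <- function(x, ...) {
  cat("<task_schedule> ", x$study_version,
      " (P[good outcome] = ", x$outcome_prob_good, ")\n", sep = "")
  cat("  blocks: ", paste(unique(x$trials$context[!duplicated(x$trials$block)]),
                          collapse = " -> "), "\n", sep = "")
  cat("  ", nrow(x$trials), " trials, ", length(unique(x$trials$pair)),
      " pairs\n", sep = "")
  invisible(x)
}
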