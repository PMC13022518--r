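#' Prior specification for model parameters
#'
#' Weakly informative priors used for MAP fitting and for drawing synthetic
#' populations: `Beta(1.1, 1.1)` on both learning rates and
#' `Gamma(shape = 15, scale = 0.75)` on the inverse temperature (mean 11.25,
#' mode 10.5, close to the fixed-beta = 10 robustness check). Users who think
#' in shape/rate terms can pass `beta_rate` instead of `beta_scale`.
#'
#' @param alpha_shape1,alpha_shape2 Beta hyperparameters for the learning
#'   rates.
#' @param beta_shape,beta_scale Gamma hyperparameters (shape/scale) for the
#'   inverse temperature.
#' @param beta_rate Optional rate parameterization (`scale = 1/rate`).
#' @export
prior_spec <- function(alpha_shape1 = 1.1, alpha_shape2 = 1.1,
                       beta_shape = 15, beta_scale = 0.75, beta_rate = NULL) {
  if (!is.null(beta_rate)) beta_scale <- 1 / beta_rate
  structure(list(alpha_shape1 = alpha_shape1, alpha_shape2 = alpha_shape2,
                 beta_shape = beta_shape, beta_scale = beta_scale),
            class = "prior_spec")
}

# Draw n parameter sets from the prior (current RNG stream).
draw_prior_params <- function(n, prior = prior_spec()) {
  data.frame(
    subject = seq_len(n),
    alpha_pos = rbeta(n, prior$alpha_shape1, prior$alpha_shape2),
    alpha_neg = rbeta(n, prior$alpha_shape1, prior$alpha_shape2),
    beta = rgamma(n, shape = prior$beta_shape, scale = prior$beta_scale))
}

#' Simulate one agent on a task schedule
#'
#' Plays the full 240-trial schedule with softmax choices and value updates
#' under `params`; outcomes are drawn from the schedule's probabilities
#' ("good" reward options win with `outcome_prob_good`; "good" punishment
#' options lose with `1 - outcome_prob_good`). Response times are a constant
#' placeholder since no latency model is specified.
#'
#' @param schedule A [make_schedule()] object.
#' @param params An [agent_params()] object.
#' @param seed Integer seed; the simulation is bitwise reproducible.
#' @param subject Subject id stored in the output.
#' @param miss_rate Probability that a trial times out (no choice, no
#'   update); such trials are marked invalid.
#' @return A `choice_data` data frame with one row per trial: `subject`,
#'   `block`, `context`, `valence`, `pair`, `trial`, `trial_in_pair`,
#'   `condition`, `choice` (`"good"`/`"bad"`), `outcome` (-1/0/+1), `rt`,
#'   `valid`.
#' @export
simulate_agent <- function(schedule, params, seed = 1, subject = 1L,
                           miss_rate = 0) {
  stopifnot(inherits(schedule, "task_schedule"),
            inherits(params, "agent_params"),
            miss_rate >= 0, miss_rate < 1)
  tr <- schedule$trials
  pair_ids <- unique(tr$pair)
  pair_valence <- tr$valence[match(pair_ids, tr$pair)]
  q0 <- q0_for_pairs(pair_valence, params$q0_scheme, params$q0_free)
  sim <- with_seed(seed,
    cpp_simulate(match(tr$pair, pair_ids) - 1L,
                 as.integer(tr$valence == "reward"),
                 tr$p_good, q0, q0,
                 params$alpha_pos, params$alpha_neg, params$beta,
                 params$rho, miss_rate))
  valid <- as.logical(sim$valid)
  data.frame(
    subject = subject,
    block = tr$block, context = tr$context, valence = tr$valence,
    pair = tr$pair, trial = tr$trial, trial_in_pair = tr$trial_in_pair,
    condition = tr$condition,
    choice = ifelse(valid, ifelse(sim$chosen_good == 1L, "good", "bad"),
                    NA_character_),
    outcome = sim$outcome,
    rt = ifelse(valid, 0.6, NA_real_),
    valid = valid,
    stringsAsFactors = FALSE)
}

#' Simulate a multi-subject cohort
#'
#' Simulates `n_subjects` agents on the same schedule, with parameters either
#' supplied explicitly (`params_list`) or drawn from the MAP priors. Subject
#' `i` is simulated with seed `seed + i`, so a one-subject cohort reproduces
#' [simulate_agent()] exactly for that seed.
#'
#' @param schedule A [make_schedule()] object.
#' @param n_subjects Number of subjects (>= 1).
#' @param params_list Optional list of [agent_params()] (length
#'   `n_subjects`) or a data frame with columns `alpha_pos`, `alpha_neg`,
#'   `beta`.
#' @param prior A [prior_spec()] used when `params_list` is `NULL`.
#' @param seed Integer seed.
#' @param miss_rate Per-trial timeout probability.
#' @return A list of class `cohort`: `data` (stacked `choice_data` rows) and
#'   `params` (one row per subject with the generating parameters).
#' @export
simulate_population <- function(schedule, n_subjects,
                                params_list = NULL, prior = prior_spec(),
                                seed = 1, miss_rate = 0) {
  stopifnot(n_subjects >= 1)
  if (is.null(params_list)) {
    ptab <- with_seed(seed, draw_prior_params(n_subjects, prior))
  } else if (is.data.frame(params_list)) {
    stopifnot(nrow(params_list) == n_subjects)
    ptab <- data.frame(subject = seq_len(n_subjects),
                       alpha_pos = params_list$alpha_pos,
                       alpha_neg = params_list$alpha_neg,
                       beta = params_list$beta)
  } else {
    stopifnot(length(params_list) == n_subjects)
    ptab <- data.frame(
      subject = seq_len(n_subjects),
      alpha_pos = vapply(params_list, `[[`, 0, "alpha_pos"),
      alpha_neg = vapply(params_list, `[[`, 0, "alpha_neg"),
      beta = vapply(params_list, `[[`, 0, "beta"))
  }
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    par_i <- agent_params(alpha_pos = ptab$alpha_pos[i],
                          alpha_neg = ptab$alpha_neg[i],
                          beta = ptab$beta[i])
    rows[[i]] <- simulate_agent(schedule, par_i, seed = seed + i,
                                subject = i, miss_rate = miss_rate)
  }
  structure(list(data = do.call(rbind, rows), params = ptab),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$params), " subjects, ", nrow(x$data), " trials (",
      sum(x$data$valid), " valid)\n", sep = "")
  invisible(x)
}

#' Read/write trial-level choice data
#'
#' Plain CSV with the fixed header `subject, block, context, valence, pair,
#' trial, trial_in_pair, condition, choice, outcome, rt, valid`.
#'
#' @param data A `choice_data` data frame.
#' @param path File path.
#' @export
write_choice_data <- function(data, path) {
  cols <- c("subject", "block", "context", "valence", "pair", "trial",
            "trial_in_pair", "condition", "choice", "outcome", "rt", "valid")
  stopifnot(all(cols %in% names(data)))
  write.csv(data[, cols], path, row.names = FALSE)
}

#' @rdname write_choice_data
#' @export
read_choice_data <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$valid <- as.logical(d$valid)
  d
}
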