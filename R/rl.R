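#' Agent parameters for the Q-learning model
#'
#' The model updates the value of the chosen option by `Q <- Q + alpha * delta`
#' with prediction error `delta = rho * r - Q`, where the learning rate is
#' `alpha_pos` when `delta > 0` and `alpha_neg` when `delta < 0` (no change at
#' `delta = 0`). Choices follow a two-option softmax with inverse temperature
#' `beta`. Initial Q values follow `q0_scheme`: `"signed_half"` starts reward
#' pairs at +0.5 and punishment pairs at -0.5, `"zero"` starts all pairs at 0,
#' and `"free"` uses the supplied `q0_free` (one value per valence, named
#' `reward` and `punishment`, or a single shared value).
#'
#' @param alpha_pos,alpha_neg Learning rates in \[0, 1\] for positive and
#'   negative prediction errors.
#' @param beta Softmax inverse temperature, >= 0.
#' @param rho Outcome-sensitivity scalar >= 0 multiplying `r` before the
#'   prediction error; 1 recovers the base model.
#' @param q0_scheme Initial-value scheme (see Details).
#' @param q0_free Initial value(s) when `q0_scheme = "free"`.
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(alpha_pos, alpha_neg = alpha_pos, beta,
                         rho = 1, q0_scheme = c("signed_half", "zero", "free"),
                         q0_free = NULL) {
  q0_scheme <- match.arg(q0_scheme)
  stopifnot(alpha_pos >= 0, alpha_pos <= 1,
            alpha_neg >= 0, alpha_neg <= 1,
            beta >= 0, rho >= 0)
  if (q0_scheme == "free" && is.null(q0_free))
    stop("q0_scheme = 'free' requires q0_free")
  structure(list(alpha_pos = alpha_pos, alpha_neg = alpha_neg, beta = beta,
                 rho = rho, q0_scheme = q0_scheme, q0_free = q0_free),
            class = "agent_params")
}

#' Prediction error
#'
#' `delta = rho * r - q_chosen`, the difference between the (sensitivity
#' scaled) outcome and the current value of the chosen option.
#'
#' @param q_chosen Current value of the chosen option.
#' @param r Outcome, one of -1, 0, +1.
#' @param rho Sensitivity scalar (default 1).
#' @export
prediction_error <- function(q_chosen, r, rho = 1) {
  stopifnot(all(r %in% c(-1, 0, 1)), rho >= 0)
  rho * r - q_chosen
}

#' Valence-specific value update
#'
#' Applies `alpha_pos` to positive and `alpha_neg` to negative prediction
#' errors; a zero prediction error leaves the value unchanged.
#'
#' @param q_chosen Current value of the chosen option.
#' @param delta Prediction error.
#' @param alpha_pos,alpha_neg Learning rates in \[0, 1\].
#' @export
update_value <- function(q_chosen, delta, alpha_pos, alpha_neg) {
  stopifnot(alpha_pos >= 0, alpha_pos <= 1, alpha_neg >= 0, alpha_neg <= 1)
  alpha <- ifelse(delta > 0, alpha_pos, ifelse(delta < 0, alpha_neg, 0))
  q_chosen + alpha * delta
}

#' Softmax choice probability for a two-option pair
#'
#' `P(A) = 1 / (1 + exp(-beta * (q_A - q_B)))`, the two-option logistic form
#' of the softmax; the exponent is clipped at +/-700 so the computation never
#' overflows.
#'
#' @param q_a,q_b Option values.
#' @param beta Inverse temperature >= 0.
#' @return `P(choose A)`.
#' @export
choice_prob <- function(q_a, q_b, beta) {
  stopifnot(beta >= 0)
  z <- pmin(pmax(beta * (q_a - q_b), -700), 700)
  1 / (1 + exp(-z))
}

#' Model variants
#'
#' Defines the model family:
#' * `"dual"` -- the main model: separate learning rates for positive and
#'   negative prediction errors plus `beta`, fit separately per condition
#'   (k = 3).
#' * `"single"` -- one shared learning rate plus `beta` (k = 2).
#' * `"sensitivity"` -- the dual model plus an outcome-sensitivity scalar
#'   `rho` (k = 4).
#' * `"null"`, `"alpha_only"`, `"beta_only"`, `"full"` -- single-learning-rate
#'   variants fit jointly on a valence's mixed + single-context stream, with
#'   `alpha` and/or `beta` shared or varying by context (k = 2, 3, 3, 4).
#'
#' @param variant Variant name.
#' @param q0_scheme Initial-value scheme passed through to the replay.
#' @param q0_free Initial values when `q0_scheme = "free"`.
#' @return A list of class `model_spec` with the number of free parameters
#'   `k`, parameter names, and context structure.
#' @export
model_spec <- function(variant = c("dual", "single", "sensitivity",
                                   "null", "alpha_only", "beta_only", "full"),
                       q0_scheme = "signed_half", q0_free = NULL) {
  variant <- match.arg(variant)
  info <- switch(variant,
    dual        = list(names = c("alpha_pos", "alpha_neg", "beta"),
                       joint = FALSE),
    single      = list(names = c("alpha", "beta"), joint = FALSE),
    sensitivity = list(names = c("alpha_pos", "alpha_neg", "beta", "rho"),
                       joint = FALSE),
    null        = list(names = c("alpha", "beta"), joint = TRUE),
    alpha_only  = list(names = c("alpha_mixed", "alpha_only", "beta"),
                       joint = TRUE),
    beta_only   = list(names = c("alpha", "beta_mixed", "beta_only"),
                       joint = TRUE),
    full        = list(names = c("alpha_mixed", "alpha_only",
                                 "beta_mixed", "beta_only"), joint = TRUE))
  structure(list(variant = variant, par_names = info$names,
                 k = length(info$names), joint = info$joint,
                 q0_scheme = q0_scheme, q0_free = q0_free),
            class = "model_spec")
}

# Initial Q values per pair given each pair's valence.
q0_for_pairs <- function(pair_valence, q0_scheme, q0_free = NULL) {
  switch(q0_scheme,
    signed_half = ifelse(pair_valence == "reward", 0.5, -0.5),
    zero = rep(0, length(pair_valence)),
    free = {
      if (length(q0_free) == 1L && is.null(names(q0_free)))
        rep(q0_free, length(pair_valence))
      else {
        if (!all(c("reward", "punishment") %in% names(q0_free)))
          stop("q0_free must be a single value or named for both valences")
        unname(q0_free[pair_valence])
      }
    },
    stop("unknown q0_scheme: ", q0_scheme))
}

# Validate a condition stream and convert it to the integer form consumed by
# the C++ replay. Streams must be chronologically ordered within subject;
# invalid trials are dropped before the replay.
prepare_stream <- function(stream) {
  stopifnot(is.data.frame(stream))
  req <- c("block", "trial", "context", "pair", "valence", "choice",
           "outcome", "valid")
  miss <- setdiff(req, names(stream))
  if (length(miss)) stop("stream lacks columns: ", paste(miss, collapse = ", "))
  if (length(unique(stream$subject %||% 1L)) > 1L)
    stop("stream must contain a single subject")
  key <- stream$block * 1000 + stream$trial
  if (is.unsorted(key)) stop("stream trials are not in chronological order")
  stream <- stream[as.logical(stream$valid), , drop = FALSE]
  pair_ids <- unique(stream$pair)
  pair_idx <- match(stream$pair, pair_ids)
  pair_valence <- stream$valence[match(pair_ids, stream$pair)]
  if (!all(stream$choice %in% c("good", "bad")))
    stop("choice must be 'good' or 'bad' on valid trials")
  list(stream = stream,
       pair = pair_idx - 1L,
       chosen_good = as.integer(stream$choice == "good"),
       outcome = as.numeric(stream$outcome),
       group = as.integer(stream$context != "mixed"),  # 0 = mixed, 1 = only
       pair_ids = pair_ids,
       pair_valence = pair_valence,
       n = nrow(stream))
}

#' Replay negative log-likelihood of a condition stream
#'
#' Replays the Q-value trajectories implied by `params` over one subject's
#' chronologically ordered condition stream (invalid trials excluded) and
#' returns the summed negative log-likelihood of the observed choices along
#' with the signed prediction error of every valid trial.
#'
#' @param stream Data frame of one subject's trials for one condition (or a
#'   valence's joint mixed + single-context stream), in chronological order,
#'   with the `choice_data` columns.
#' @param params An [agent_params()] object.
#' @return A list with `nll`, `pe` (signed prediction error per valid trial),
#'   `p_chosen` (model probability of each observed choice), and `n` (number
#'   of valid trials).
#' @export
replay_negloglik <- function(stream, params) {
  stopifnot(inherits(params, "agent_params"))
  ps <- prepare_stream(stream)
  q0 <- q0_for_pairs(ps$pair_valence, params$q0_scheme, params$q0_free)
  res <- cpp_replay(ps$pair, ps$chosen_good, ps$outcome,
                    rep(0L, ps$n), q0, q0,
                    params$alpha_pos, params$alpha_neg, params$beta,
                    params$rho)
  list(nll = res$nll, pe = res$pe, p_chosen = res$p_chosen, n = ps$n)
}

# Negative log-likelihood for a free-parameter vector under a model_spec;
# the workhorse behind fitting. `ps` is a prepared stream.
spec_nll <- function(theta, ps, spec, return_pe = FALSE) {
  q0 <- q0_for_pairs(ps$pair_valence, spec$q0_scheme, spec$q0_free)
  v <- spec$variant
  # per-group parameter vectors; group 0 = mixed, 1 = only (joint variants)
  if (v %in% c("dual", "sensitivity")) {
    ap <- theta[1]; an <- theta[2]; b <- theta[3]
    rho <- if (v == "sensitivity") theta[4] else 1
    pars <- list(ap = ap, an = an, b = b, rho = rho)
    grp <- rep(0L, ps$n)
    res <- cpp_replay(ps$pair, ps$chosen_good, ps$outcome, grp, q0, q0,
                      pars$ap, pars$an, pars$b, pars$rho)
  } else if (v == "single") {
    res <- cpp_replay(ps$pair, ps$chosen_good, ps$outcome, rep(0L, ps$n),
                      q0, q0, theta[1], theta[1], theta[2], 1)
  } else {
    grp <- ps$group
    a <- switch(v,
      null = c(theta[1], theta[1]),
      alpha_only = c(theta[1], theta[2]),
      beta_only = c(theta[1], theta[1]),
      full = c(theta[1], theta[2]))
    b <- switch(v,
      null = c(theta[2], theta[2]),
      alpha_only = c(theta[3], theta[3]),
      beta_only = c(theta[2], theta[3]),
      full = c(theta[3], theta[4]))
    res <- cpp_replay(ps$pair, ps$chosen_good, ps$outcome, grp, q0, q0,
                      a, a, b, 1)
  }
  if (return_pe) res else res$nll
}
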