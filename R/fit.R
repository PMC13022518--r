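#' Configuration for model fitting
#'
#' Fits are bounded optimizations on the natural parameter scale (learning
#' rates in \[0, 1\], inverse temperature in `beta_bounds`, sensitivity in
#' `rho_bounds`) from `n_starts` random starting points drawn from the MAP
#' priors. The estimator is either maximum likelihood (`"mle"`) or maximum a
#' posteriori (`"map"`, adding the log prior of [prior_spec()] to the
#' objective; the sensitivity parameter carries no prior and is intended for
#' MLE fits). Parameters named in `fixed` (for example `list(beta = 10)`) are
#' held at the given value and excluded from the free-parameter count.
#'
#' @param estimator `"mle"` or `"map"`.
#' @param n_starts Number of random optimizer starts (>= 1).
#' @param beta_bounds,rho_bounds Lower/upper bounds for `beta` and `rho`.
#' @param prior A [prior_spec()]; used for MAP penalties and start sampling.
#' @param fixed Named list of parameters to hold fixed.
#' @param min_trials Minimum number of valid trials per fit.
#' @param seed Seed for the start sampler.
#' @param rel_tol Relative convergence tolerance passed to the optimizer.
#' @export
fit_config <- function(estimator = c("mle", "map"), n_starts = 10,
                       beta_bounds = c(0, 50), rho_bounds = c(0, 3),
                       prior = prior_spec(), fixed = list(),
                       min_trials = 10, seed = 1, rel_tol = 1e-8) {
  estimator <- match.arg(estimator)
  stopifnot(n_starts >= 1, all(is.finite(beta_bounds)), all(is.finite(rho_bounds)))
  structure(list(estimator = estimator, n_starts = n_starts,
                 beta_bounds = beta_bounds, rho_bounds = rho_bounds,
                 prior = prior, fixed = fixed, min_trials = min_trials,
                 seed = seed, rel_tol = rel_tol),
            class = "fit_config")
}

# Bounds per parameter name.
par_bounds <- function(par_names, config) {
  lo <- hi <- numeric(length(par_names))
  for (i in seq_along(par_names)) {
    nm <- par_names[i]
    if (grepl("^alpha", nm)) { lo[i] <- 0; hi[i] <- 1 }
    else if (grepl("^beta", nm)) { lo[i] <- config$beta_bounds[1]; hi[i] <- config$beta_bounds[2] }
    else if (nm == "rho") { lo[i] <- config$rho_bounds[1]; hi[i] <- config$rho_bounds[2] }
    else stop("unknown parameter: ", nm)
  }
  list(lower = lo, upper = hi)
}

# Log prior over a named parameter vector (alpha and beta components only;
# floored so boundary values stay finite for the optimizer).
log_prior <- function(theta, par_names, prior) {
  lp <- 0
  for (i in seq_along(par_names)) {
    nm <- par_names[i]
    if (grepl("^alpha", nm))
      lp <- lp + dbeta(theta[i], prior$alpha_shape1, prior$alpha_shape2, log = TRUE)
    else if (grepl("^beta", nm))
      lp <- lp + dgamma(theta[i], shape = prior$beta_shape,
                        scale = prior$beta_scale, log = TRUE)
  }
  max(lp, -1e10)
}

# Random starts drawn from the priors, clipped into bounds.
draw_starts <- function(n, par_names, config) {
  prior <- config$prior
  m <- matrix(0, n, length(par_names), dimnames = list(NULL, par_names))
  for (i in seq_along(par_names)) {
    nm <- par_names[i]
    if (grepl("^alpha", nm))
      m[, i] <- rbeta(n, prior$alpha_shape1, prior$alpha_shape2)
    else if (grepl("^beta", nm))
      m[, i] <- pmin(rgamma(n, shape = prior$beta_shape,
                            scale = prior$beta_scale),
                     config$beta_bounds[2])
    else
      m[, i] <- runif(n, config$rho_bounds[1], config$rho_bounds[2])
  }
  m
}

# Build a lean objective closure for the optimizer: stream arrays, initial
# values, and the theta -> per-group parameter mapping are all resolved
# once, so each evaluation is a single C++ call (plus the prior under MAP).
fast_objective <- function(ps, spec, config, free_names, fixed, build_theta) {
  q0 <- q0_for_pairs(ps$pair_valence, spec$q0_scheme, spec$q0_free)
  grp <- if (spec$joint) ps$group else rep(0L, ps$n)
  v <- spec$variant
  map_par <- switch(v,
    dual        = function(th) list(a1 = th[1], a2 = th[2], b = th[3], rho = 1),
    single      = function(th) list(a1 = th[1], a2 = th[1], b = th[2], rho = 1),
    sensitivity = function(th) list(a1 = th[1], a2 = th[2], b = th[3], rho = th[4]),
    null        = function(th) list(a1 = c(th[1], th[1]), a2 = NULL,
                                    b = c(th[2], th[2]), rho = 1),
    alpha_only  = function(th) list(a1 = c(th[1], th[2]), a2 = NULL,
                                    b = c(th[3], th[3]), rho = 1),
    beta_only   = function(th) list(a1 = c(th[1], th[1]), a2 = NULL,
                                    b = c(th[2], th[3]), rho = 1),
    full        = function(th) list(a1 = c(th[1], th[2]), a2 = NULL,
                                    b = c(th[3], th[4]), rho = 1))
  is_map <- config$estimator == "map"
  ai <- grep("^alpha", free_names)
  bi <- grep("^beta", free_names)
  prior <- config$prior
  has_fixed <- length(fixed) > 0
  function(free) {
    th <- if (has_fixed) unname(build_theta(free)) else free
    m <- map_par(th)
    a2 <- m$a2 %||% m$a1
    val <- cpp_nll(ps$pair, ps$chosen_good, ps$outcome, grp, q0, q0,
                   m$a1, a2, m$b, m$rho)
    if (is_map) {
      lp <- sum(dbeta(free[ai], prior$alpha_shape1, prior$alpha_shape2,
                      log = TRUE)) +
        sum(dgamma(free[bi], shape = prior$beta_shape,
                   scale = prior$beta_scale, log = TRUE))
      val <- val - max(lp, -1e10)
    }
    val
  }
}

# Best point of a small full-factorial lattice over the bounds (three
# levels per parameter), used as one additional deterministic start.
lattice_start <- function(free_names, b, obj) {
  if (!length(free_names)) return(NULL)
  levels <- lapply(seq_along(free_names), function(i)
    b$lower[i] + c(0.15, 0.5, 0.85) * (b$upper[i] - b$lower[i]))
  pts <- as.matrix(expand.grid(levels, KEEP.OUT.ATTRS = FALSE))
  vals <- apply(pts, 1L, obj)
  unname(pts[which.min(vals), ])
}

# Prior modes, used as the MAP estimate for an empty stream:
# Beta(1.1, 1.1) mode = 0.5, Gamma(15, scale 0.75) mode = (15 - 1) * 0.75.
prior_modes <- function(par_names, prior) {
  vapply(par_names, function(nm) {
    if (grepl("^alpha", nm))
      (prior$alpha_shape1 - 1) / (prior$alpha_shape1 + prior$alpha_shape2 - 2)
    else if (grepl("^beta", nm))
      (prior$beta_shape - 1) * prior$beta_scale
    else 1
  }, 0)
}

#' Fit a model to one condition stream
#'
#' Minimizes the negative log-likelihood (MLE) or the negative log-posterior
#' (MAP) over bounded parameters, restarting from `n_starts` prior-drawn
#' points and keeping the best optimum. An empty stream under MAP returns
#' the prior modes. A best fit with `beta` on a bound, or no converged
#' start, is flagged via `converged = FALSE` rather than raised as an error.
#'
#' @param stream One subject's chronologically ordered condition stream (see
#'   [replay_negloglik()]).
#' @param spec A [model_spec()].
#' @param config A [fit_config()].
#' @return A list of class `fit_result`: `params` (named vector), `nll`
#'   (likelihood-only, also for MAP fits), `logpost` (MAP only), `n_valid`,
#'   `k` (free parameters), `converged`, `best_start`, `estimator`.
#' @export
fit_condition <- function(stream, spec = model_spec("dual"),
                          config = fit_config()) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "fit_config"))
  ps <- prepare_stream(stream)
  free_names <- setdiff(spec$par_names, names(config$fixed))
  fixed <- unlist(config$fixed[intersect(names(config$fixed), spec$par_names)])
  k <- length(free_names)

  build_theta <- function(free) {
    full <- numeric(spec$k)
    names(full) <- spec$par_names
    full[free_names] <- free
    if (length(fixed)) full[names(fixed)] <- fixed
    full
  }

  if (ps$n == 0) {
    if (config$estimator == "map") {
      est <- prior_modes(spec$par_names, config$prior)
      if (length(fixed)) est[names(fixed)] <- fixed
      return(structure(list(params = est, nll = 0,
                            logpost = log_prior(est, spec$par_names, config$prior),
                            n_valid = 0L, k = k, converged = TRUE,
                            best_start = NA_integer_,
                            estimator = "map", spec = spec),
                       class = "fit_result"))
    }
    stop("no valid trials to fit under MLE")
  }

  b <- par_bounds(free_names, config)
  obj <- fast_objective(ps, spec, config, free_names, fixed, build_theta)
  starts <- with_seed(config$seed, draw_starts(config$n_starts, free_names, config))
  # deterministic extra start: best point of a coarse lattice scan, guarding
  # against all random starts landing in one basin of a multimodal surface
  lattice <- lattice_start(free_names, b, obj)
  if (!is.null(lattice)) starts <- rbind(starts, lattice)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      nlminb(pmin(pmax(starts[s, ], b$lower), b$upper), obj,
             lower = b$lower, upper = b$upper,
             control = list(rel.tol = config$rel_tol,
                            eval.max = 500, iter.max = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) {
      best <- fit
      best$start <- s
    }
  }
  if (is.null(best)) {
    return(structure(list(params = setNames(rep(NA_real_, spec$k), spec$par_names),
                          nll = NA_real_, logpost = NA_real_,
                          n_valid = ps$n, k = k, converged = FALSE,
                          best_start = NA_integer_,
                          estimator = config$estimator, spec = spec),
                     class = "fit_result"))
  }
  est <- build_theta(best$par)
  nll <- spec_nll(unname(est), ps, spec)
  beta_idx <- grep("^beta", free_names)
  at_bound <- length(beta_idx) > 0 &&
    any(abs(best$par[beta_idx] - b$upper[beta_idx]) < 1e-8)
  structure(list(params = est, nll = nll,
                 logpost = if (config$estimator == "map")
                   -best$objective else NA_real_,
                 n_valid = ps$n, k = k,
                 converged = best$convergence == 0 && !at_bound,
                 best_start = best$start,
                 estimator = config$estimator, spec = spec),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$estimator, ", nll = ", format(x$nll, digits = 6),
      ", n = ", x$n_valid, ", k = ", x$k,
      if (!x$converged) " [flagged]", "\n", sep = "")
  print(round(x$params, 4))
  invisible(x)
}

#' Per-trial prediction errors implied by a fit
#'
#' Replays the stream under the fitted parameters and returns the signed
#' prediction error of every valid trial.
#'
#' @param fit A [fit_condition()] result.
#' @param stream The stream the model was fit to.
#' @export
fit_pes <- function(fit, stream) {
  ps <- prepare_stream(stream)
  spec_nll(unname(fit$params), ps, fit$spec, return_pe = TRUE)$pe
}

#' Fit every subject x condition of a dataset
#'
#' For per-condition variants (`dual`, `single`, `sensitivity`) each of the
#' four condition streams is fit separately; for the context variants
#' (`null`, `alpha_only`, `beta_only`, `full`) each valence's mixed + single
#' context trials form one joint stream.
#'
#' @param data A `choice_data` data frame (one or many subjects).
#' @param spec A [model_spec()].
#' @param config A [fit_config()]; per-fit start seeds are derived from
#'   `config$seed` and the subject id so cohort fits are reproducible.
#' @return Data frame with one row per subject x stream: fitted parameters,
#'   `nll`, `n_valid`, `k`, `bic`, `converged`.
#' @export
fit_cohort <- function(data, spec = model_spec("dual"), config = fit_config()) {
  subjects <- unique(data$subject)
  units <- if (spec$joint) c("reward", "punishment") else CONDITIONS
  rows <- list()
  for (sj in subjects) {
    d_s <- data[data$subject == sj, , drop = FALSE]
    for (u in seq_along(units)) {
      stream <- if (spec$joint) d_s[d_s$valence == units[u], , drop = FALSE]
                else d_s[d_s$condition == units[u], , drop = FALSE]
      cfg <- config
      cfg$seed <- config$seed + 7L * match(sj, subjects) + u
      fit <- fit_condition(stream, spec, cfg)
      row <- data.frame(subject = sj, condition = units[u],
                        t(fit$params), nll = fit$nll,
                        n_valid = fit$n_valid, k = fit$k,
                        bic = bic(fit$nll, fit$k, fit$n_valid),
                        converged = fit$converged,
                        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exhaustive grid-search reference optimizer
#'
#' Evaluates the (negative log-) likelihood on a full factorial grid and
#' returns the grid minimum. Intended as an independent check on the
#' gradient-based optimizer, not for routine fitting.
#'
#' @param stream Condition stream.
#' @param spec A [model_spec()].
#' @param grid_spec Named list of candidate values, one entry per model
#'   parameter (total evaluations capped at 1e6).
#' @return List with `best_params` (named vector) and `best_nll`.
#' @export
grid_oracle <- function(stream, spec, grid_spec) {
  stopifnot(setequal(names(grid_spec), spec$par_names))
  sizes <- vapply(grid_spec, length, 0L)
  if (any(sizes == 0L)) stop("empty grid")
  if (prod(sizes) > 1e6) stop("grid too large (> 1e6 evaluations)")
  ps <- prepare_stream(stream)
  grid <- as.matrix(expand.grid(grid_spec[spec$par_names],
                                KEEP.OUT.ATTRS = FALSE))
  vals <- apply(grid, 1L, function(th) spec_nll(unname(th), ps, spec))
  i <- which.min(vals)
  list(best_params = setNames(grid[i, ], spec$par_names), best_nll = vals[i])
}

#' Correlate MLE- and MAP-derived prediction errors
#'
#' Fits every subject x condition with both estimators, replays the fitted
#' models to obtain trialwise signed prediction errors, and reports the
#' Pearson correlation between the two PE vectors per condition (pooled
#' across subjects).
#'
#' @param data A `choice_data` data frame.
#' @param spec A [model_spec()] (per-condition variants).
#' @param config A [fit_config()]; the estimator field is overridden.
#' @param mle_fit Optional precomputed MLE fit list (as returned in
#'   `$fits` of this function) to avoid refitting.
#' @return List with `r` (named correlation per condition), `n_trials`, and
#'   the two fit tables.
#' @export
compare_mle_map_pes <- function(data, spec = model_spec("dual"),
                                config = fit_config(), mle_fit = NULL) {
  stopifnot(!spec$joint)
  pe_table <- function(estimator, reuse = NULL) {
    cfg <- config
    cfg$estimator <- estimator
    subjects <- unique(data$subject)
    out <- list()
    for (sj in subjects) {
      d_s <- data[data$subject == sj, , drop = FALSE]
      for (u in seq_along(CONDITIONS)) {
        cond <- CONDITIONS[u]
        stream <- d_s[d_s$condition == cond, , drop = FALSE]
        if (sum(stream$valid) < 3) next
        cfg$seed <- config$seed + 7L * match(sj, subjects) + u
        fit <- fit_condition(stream, spec, cfg)
        out[[paste(sj, cond)]] <- data.frame(
          subject = sj, condition = cond, pe = fit_pes(fit, stream))
      }
    }
    do.call(rbind, out)
  }
  pe_mle <- if (is.null(mle_fit)) pe_table("mle") else mle_fit
  pe_map <- pe_table("map")
  stopifnot(nrow(pe_mle) == nrow(pe_map))
  r <- sapply(CONDITIONS, function(cond) {
    i <- pe_mle$condition == cond
    cor(pe_mle$pe[i], pe_map$pe[i])
  })
  list(r = r,
       n_trials = sapply(CONDITIONS, function(cond) sum(pe_mle$condition == cond)),
       pe_mle = pe_mle, pe_map = pe_map)
}
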