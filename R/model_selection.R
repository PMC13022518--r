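#' Bayesian Information Criterion
#'
#' `BIC = 2 * nll + k * log(n)` with `n` the number of valid trials; lower
#' is better. `-BIC / 2` approximates the log model evidence used by
#' [rfx_bms()].
#'
#' @param nll Negative log-likelihood at the optimum.
#' @param k Number of free parameters.
#' @param n Number of valid trials (>= 1).
#' @export
bic <- function(nll, k, n) {
  if (any(n < 1)) stop("n must be >= 1")
  2 * nll + k * log(n)
}

#' Likelihood-ratio test for nested models
#'
#' `statistic = 2 * (nll_nested - nll_full)`, referred to a chi-square
#' distribution with `df` degrees of freedom. A slightly negative statistic
#' (full model marginally worse, from optimizer noise) is clamped to zero
#' within `tol`.
#'
#' @param nll_nested,nll_full Negative log-likelihoods of the nested and
#'   full models.
#' @param df Difference in free-parameter count.
#' @param tol Numerical tolerance for a negative statistic.
#' @return List with `statistic` and `p`.
#' @export
likelihood_ratio_test <- function(nll_nested, nll_full, df, tol = 1e-6) {
  stat <- 2 * (nll_nested - nll_full)
  if (stat < -tol) stop("nested model fits better than full model")
  stat <- max(stat, 0)
  list(statistic = stat, p = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet-multinomial scheme for group-level model
#' comparison: subjects are treated as random effects over models, with a
#' `Dirichlet(alpha0)` prior on model frequencies. Iterates the standard
#' update (posterior model assignments from evidence plus the expected log
#' frequency, then Dirichlet counts) to convergence, estimates exceedance
#' probabilities by Monte Carlo sampling of the posterior Dirichlet, and
#' computes the Bayes omnibus risk (BOR) -- the posterior probability that
#' model frequencies are exactly equal -- from the free energy of the
#' random-effects model against the equal-frequency null. Protected
#' exceedance probabilities shrink the exceedance probabilities toward
#' uniform: `pEP = EP * (1 - BOR) + BOR / K`.
#'
#' @param evidence Subjects x models matrix of log model evidence
#'   (typically `-BIC / 2`); at least two model columns.
#' @param alpha0 Dirichlet prior count per model.
#' @param n_samples Monte Carlo draws for the exceedance probabilities.
#' @param tol,max_iter Convergence tolerance on the Dirichlet counts and
#'   iteration cap (non-convergence is flagged, not an error).
#' @param seed Seed for the Monte Carlo step.
#' @return A list of class `bms_result`: `dirichlet_alpha`, `expected_freq`,
#'   `exceedance_prob`, `protected_ep`, `bor`, `converged`, `n_iter`.
#' @export
rfx_bms <- function(evidence, alpha0 = 1, n_samples = 1e5,
                    tol = 1e-6, max_iter = 500, seed = 1) {
  evidence <- as.matrix(evidence)
  n <- nrow(evidence)
  K <- ncol(evidence)
  if (K < 2) stop("need at least two models")
  if (!all(is.finite(evidence))) stop("evidence must be finite")
  labels <- colnames(evidence) %||% paste0("model", seq_len(K))

  alpha <- rep(alpha0, K)
  z <- matrix(1 / K, n, K)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    elogr <- digamma(alpha) - digamma(sum(alpha))
    u <- sweep(evidence, 2L, elogr, "+")
    u <- u - apply(u, 1L, max)
    z <- exp(u)
    z <- z / rowSums(z)
    alpha_new <- alpha0 + colSums(z)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
    if (iter >= max_iter) break
  }

  freq <- alpha / sum(alpha)
  ep <- with_seed(seed, {
    g <- matrix(rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                n_samples, K)
    tabulate(max.col(g, ties.method = "first"), K) / n_samples
  })

  # free energy of the random-effects model (ELBO at the optimum)
  elogr <- digamma(alpha) - digamma(sum(alpha))
  zl <- z * log(pmax(z, 1e-300))
  f1 <- sum(z * evidence) + sum(sweep(z, 2L, elogr, "*")) -
    sum(zl) +
    lgamma(K * alpha0) - K * lgamma(alpha0) -
    lgamma(sum(alpha)) + sum(lgamma(alpha)) +
    sum((alpha0 - alpha) * elogr)
  # null model: all subjects share equal model frequencies 1/K
  f0 <- sum(apply(evidence, 1L, function(l) {
    m <- max(l)
    m + log(mean(exp(l - m)))
  }))
  bor <- 1 / (1 + exp(f1 - f0))
  pep <- ep * (1 - bor) + bor / K

  structure(list(dirichlet_alpha = setNames(alpha, labels),
                 expected_freq = setNames(freq, labels),
                 exceedance_prob = setNames(ep, labels),
                 protected_ep = setNames(pep, labels),
                 bor = bor, converged = converged, n_iter = iter),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result> BOR = ", format(x$bor, digits = 4),
      if (!x$converged) " [not converged]", "\n", sep = "")
  print(round(rbind(freq = x$expected_freq, ep = x$exceedance_prob,
                    pep = x$protected_ep), 4))
  invisible(x)
}

#' Model comparison summary over a cohort
#'
#' Aggregates [fit_cohort()] tables for several model variants: summed BIC
#' per model, per-subject best-model counts, and optionally [rfx_bms()] on
#' the `-BIC / 2` evidence. Evidence can be taken per condition stream or
#' summed per subject across streams.
#'
#' @param fit_tables Named list of [fit_cohort()] data frames (same subjects
#'   and streams).
#' @param condition Optional stream label to restrict to; `NULL` sums
#'   evidence per subject across streams.
#' @param bms Run [rfx_bms()] on the evidence matrix?
#' @param seed Seed forwarded to [rfx_bms()].
#' @export
compare_models <- function(fit_tables, condition = NULL, bms = TRUE, seed = 1) {
  stopifnot(length(fit_tables) >= 2, !is.null(names(fit_tables)))
  per_subject <- lapply(fit_tables, function(tab) {
    if (!is.null(condition)) tab <- tab[tab$condition == condition, , drop = FALSE]
    agg <- stats::aggregate(bic ~ subject, data = tab, FUN = sum)
    agg[order(agg$subject), ]
  })
  subjects <- per_subject[[1]]$subject
  bic_mat <- sapply(per_subject, function(a) a$bic)
  rownames(bic_mat) <- subjects
  best <- apply(bic_mat, 1L, which.min)
  out <- list(bic_sum = colSums(bic_mat),
              best_counts = table(factor(names(fit_tables)[best],
                                         levels = names(fit_tables))),
              evidence = -bic_mat / 2)
  if (bms) out$bms <- rfx_bms(-bic_mat / 2, seed = seed)
  out
}
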