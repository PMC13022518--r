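#' @useDynLib rewpun, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor dbeta dgamma lm optimize nlminb pchisq pf pt
#'   quantile rbeta rbinom rgamma rnorm runif sd t.test var complete.cases
#'   setNames
#' @importFrom utils read.csv write.csv head
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards, so seeded helpers never
# perturb each other.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# Map block context + trial valence to the four analysis conditions.
condition_label <- function(context, valence) {
  ifelse(context == "mixed",
         ifelse(valence == "reward", "reward_mixed", "punishment_mixed"),
         ifelse(valence == "reward", "reward_only", "punishment_only"))
}

CONDITIONS <- c("reward_mixed", "reward_only", "punishment_mixed", "punishment_only")

`%||%` <- function(a, b) if (is.null(a)) b else a
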