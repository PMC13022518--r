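# Shared fixtures and independent oracles, all built in code.

# A tiny hand-built condition stream: one pair, explicit choices/outcomes.
# choices: character vector of "good"/"bad"; outcomes: -1/0/1.
make_stream <- function(choices, outcomes, valence = "reward",
                        context = "reward_only", pair = 1L, subject = 1L) {
  n <- length(choices)
  if (n == 0)
    return(make_stream("good", 1, valence, context, pair, subject)[0, ])
  data.frame(subject = subject, block = 1L, context = context,
             valence = valence, pair = pair, trial = seq_len(n),
             trial_in_pair = seq_len(n),
             condition = rewpun:::condition_label(context, valence),
             choice = choices, outcome = outcomes, rt = 0.6, valid = TRUE,
             stringsAsFactors = FALSE)
}

# Independent pure-R replay oracle: literal step-by-step transcription of
# the update and softmax rules, no shared code with the package internals.
oracle_replay <- function(stream, alpha_pos, alpha_neg, beta, rho = 1,
                          q0_scheme = "signed_half") {
  stream <- stream[stream$valid, ]
  q <- list()
  nll <- 0
  pes <- numeric(nrow(stream))
  for (i in seq_len(nrow(stream))) {
    row <- stream[i, ]
    key <- as.character(row$pair)
    if (is.null(q[[key]])) {
      q0 <- switch(q0_scheme,
                   signed_half = if (row$valence == "reward") 0.5 else -0.5,
                   zero = 0)
      q[[key]] <- c(good = q0, bad = q0)
    }
    qg <- q[[key]]["good"]; qb <- q[[key]]["bad"]
    p_good <- exp(qg * beta) / (exp(qg * beta) + exp(qb * beta))
    p <- if (row$choice == "good") p_good else 1 - p_good
    nll <- nll - log(max(p, 1e-12))
    qc <- if (row$choice == "good") qg else qb
    delta <- rho * row$outcome - qc
    pes[i] <- delta
    a <- if (delta > 0) alpha_pos else if (delta < 0) alpha_neg else 0
    q[[key]][row$choice] <- qc + a * delta
  }
  list(nll = unname(nll), pe = unname(pes))
}

# Default schedule reused across tests.
test_schedule <- function(version = "behavioral", seed = 1) {
  make_schedule(version, counterbalance_index = 0, seed = seed)
}

# Accuracy per subject x condition straight from the trial table.
accuracy_table <- function(data) {
  d <- data[data$valid, ]
  stats::aggregate(correct ~ subject + condition,
                   data = transform(d, correct = as.integer(choice == "good")),
                   FUN = mean)
}

# Wide accuracy matrix (subject x 4 conditions) for the ANOVA.
accuracy_wide <- function(data) {
  a <- accuracy_table(data)
  out <- data.frame(subject = sort(unique(a$subject)))
  for (cond in unique(a$condition)) {
    ac <- a[a$condition == cond, ]
    out[[cond]] <- ac$correct[match(out$subject, ac$subject)]
  }
  out
}
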