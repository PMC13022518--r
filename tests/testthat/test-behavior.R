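test_that("condition summaries match an independent one-pass recount", {
  sch <- test_schedule()
  for (k in 1:5) {
    co <- simulate_population(sch, 3, seed = 100 + k)
    s <- summarize_conditions(co$data)
    ind <- accuracy_table(co$data)
    for (i in seq_len(nrow(s))) {
      want <- ind$correct[ind$subject == s$subject[i] &
                          ind$condition == s$condition[i]]
      expect_equal(s$accuracy[i], want)
    }
    expect_true(all(s$accuracy >= 0 & s$accuracy <= 1))
    expect_true(all(s$stay_after_positive >= 0 & s$stay_after_positive <= 1,
                    na.rm = TRUE))
  }
})

test_that("an always-correct subject scores accuracy 1 everywhere", {
  sch <- test_schedule()
  d <- simulate_agent(sch, agent_params(0, 0, 0), seed = 1)
  d$choice <- "good"
  s <- summarize_conditions(d)
  expect_true(all(s$accuracy == 1))
})

test_that("a strict win-stay/lose-shift agent maxes both stay/switch rates", {
  sch <- test_schedule()
  tr <- sch$trials
  # hand-built WSLS trajectory per pair: stay after +1 / avoided loss,
  # switch after 0 (reward) / -1
  choice <- character(nrow(tr))
  outcome <- numeric(nrow(tr))
  set.seed(3)
  last <- list()
  for (i in seq_len(nrow(tr))) {
    key <- as.character(tr$pair[i])
    choice[i] <- if (is.null(last[[key]])) "good" else last[[key]]
    if (tr$valence[i] == "reward") {
      outcome[i] <- rbinom(1, 1, 0.5)
      positive <- outcome[i] == 1
    } else {
      outcome[i] <- -rbinom(1, 1, 0.5)
      positive <- outcome[i] == 0
    }
    last[[key]] <- if (positive) choice[i]
                   else setdiff(c("good", "bad"), choice[i])
  }
  d <- data.frame(subject = 1L, block = tr$block, context = tr$context,
                  valence = tr$valence, pair = tr$pair, trial = tr$trial,
                  trial_in_pair = tr$trial_in_pair, condition = tr$condition,
                  choice = choice, outcome = outcome, rt = 0.6, valid = TRUE)
  s <- summarize_conditions(d)
  expect_true(all(s$stay_after_positive == 1))
  expect_true(all(s$switch_after_negative == 1))
  expect_true(all(s$stay_switch_index == 1))
})

test_that("zero-beta populations sit at chance accuracy", {
  sch <- test_schedule()
  pl <- data.frame(alpha_pos = rep(0.5, 60), alpha_neg = 0.5, beta = 0)
  co <- simulate_population(sch, 60, params_list = pl, seed = 7)
  acc <- accuracy_table(co$data)$correct
  se <- sd(acc) / sqrt(length(acc))
  expect_lt(abs(mean(acc) - 0.5), 3 * se + 1e-3)
})

test_that("the 2x2 ANOVA agrees with the aov error-strata oracle", {
  set.seed(11)
  for (k in 1:4) {
    n <- 8
    vals <- data.frame(subject = 1:n,
                       reward_mixed = runif(n), reward_only = runif(n),
                       punishment_mixed = runif(n), punishment_only = runif(n))
    got <- rm_anova_2x2(vals)
    long <- reshape(vals, direction = "long",
                    varying = list(rewpun:::CONDITIONS),
                    v.names = "y", timevar = "cond",
                    times = rewpun:::CONDITIONS)
    long$context <- factor(ifelse(grepl("mixed", long$cond), "mixed", "only"))
    long$valence <- factor(ifelse(grepl("reward", long$cond),
                                  "reward", "punishment"))
    long$subject <- factor(long$subject)
    fit <- summary(aov(y ~ context * valence +
                         Error(subject / (context * valence)), data = long))
    f_ctx <- fit[["Error: subject:context"]][[1]]["context", "F value"]
    f_val <- fit[["Error: subject:valence"]][[1]]["valence", "F value"]
    f_int <- fit[["Error: subject:context:valence"]][[1]][
      "context:valence", "F value"]
    expect_equal(got$F[got$effect == "context"], f_ctx, tolerance = 1e-8)
    expect_equal(got$F[got$effect == "valence"], f_val, tolerance = 1e-8)
    expect_equal(got$F[got$effect == "interaction"], f_int, tolerance = 1e-8)
    expect_true(all(got$df1 == 1) && all(got$df2 == n - 1))
  }
})

test_that("ANOVA on identical conditions gives F = 0, p = 1", {
  vals <- data.frame(subject = 1:6, reward_mixed = runif(6))
  vals$reward_only <- vals$reward_mixed
  vals$punishment_mixed <- vals$reward_mixed
  vals$punishment_only <- vals$reward_mixed
  res <- rm_anova_2x2(vals)
  expect_true(all(res$F == 0))
  expect_true(all(res$p == 1))
  expect_true(all(res$zero_variance))
})

test_that("a constant nonzero difference gives infinite F with p = 0", {
  vals <- data.frame(subject = 1:5, reward_mixed = runif(5))
  vals$reward_only <- vals$reward_mixed - 0.2   # exact context shift
  vals$punishment_mixed <- vals$reward_mixed
  vals$punishment_only <- vals$reward_mixed - 0.2
  res <- rm_anova_2x2(vals)
  ctx <- res[res$effect == "context", ]
  expect_true(is.infinite(ctx$F))
  expect_equal(ctx$p, 0)
  expect_true(ctx$zero_variance)
  expect_error(rm_anova_2x2(vals[1:2, ]), "at least 3")
})

test_that("a planted pure interaction inflates only the interaction F", {
  set.seed(13)
  n <- 40
  base <- matrix(rnorm(4 * n, sd = 0.05), n, 4)
  vals <- data.frame(subject = 1:n,
                     reward_mixed = 0.7 + 0.1 + base[, 1],
                     reward_only = 0.7 - 0.1 + base[, 2],
                     punishment_mixed = 0.7 - 0.1 + base[, 3],
                     punishment_only = 0.7 + 0.1 + base[, 4])
  res <- rm_anova_2x2(vals)
  expect_lt(res$p[res$effect == "interaction"], 0.001)
  expect_gt(res$p[res$effect == "context"], 0.01)
  expect_gt(res$p[res$effect == "valence"], 0.01)
})

test_that("paired contrasts carry Bonferroni adjustment and Cohen's d", {
  set.seed(14)
  x <- rnorm(30, 0.6, 0.1)
  y <- x - rnorm(30, 0.05, 0.05)
  pc <- paired_contrast(x, y, m = 4)
  expect_equal(pc$p_bonferroni, min(1, 4 * pc$p))
  expect_gte(pc$p_bonferroni, pc$p)
  expect_lte(pc$p_bonferroni, 1)
  expect_equal(pc$cohens_d, mean(x - y) / sd(x - y))
  one <- paired_contrast(x, y, m = 1, alternative = "greater")
  expect_lt(one$p, pc$p)  # one-tailed in the right direction halves p
})

test_that("the composite index multiplies rate by temperature", {
  ft <- data.frame(subject = 1:3, condition = "reward_only",
                   alpha_pos = c(0, 0.5, 1), alpha_neg = c(0.2, 0.4, 0.6),
                   beta = c(10, 10, 2))
  ci <- composite_index(ft)
  expect_equal(ci$composite_pos, c(0, 5, 2))
  expect_equal(ci$composite_neg, c(2, 4, 1.2))
  # invariant to a common scale factor moving between alpha and beta
  c_scaled <- composite_index(transform(ft, alpha_pos = alpha_pos * 2,
                                        beta = beta / 2))
  expect_equal(c_scaled$composite_pos, ci$composite_pos)
})

test_that("accuracy regression recovers an exact linear construction", {
  set.seed(15)
  n <- 40
  ft <- data.frame(subject = 1:n, condition = "reward_mixed",
                   alpha_pos = runif(n), alpha_neg = runif(n),
                   beta = rgamma(n, 15, scale = 0.75))
  st <- data.frame(subject = 1:n, condition = "reward_mixed",
                   accuracy = 0.5 + 0.2 * ft$alpha_pos)
  reg <- suppressWarnings(accuracy_on_params_regression(st, ft, "reward_mixed"))
  expect_equal(reg$coefficients["alpha_pos", "estimate"], 0.2,
               tolerance = 1e-10)
  expect_equal(reg$coefficients["alpha_neg", "estimate"], 0,
               tolerance = 1e-10)
  expect_equal(reg$coefficients["beta", "estimate"], 0, tolerance = 1e-10)
  expect_false(reg$collinear)
  # duplicated predictors are flagged
  ft2 <- transform(ft, alpha_neg = alpha_pos)
  reg2 <- suppressWarnings(accuracy_on_params_regression(st, ft2, "reward_mixed"))
  expect_true(reg2$collinear)
})

test_that("poor-learner screening removes only below-criterion subjects", {
  sch <- test_schedule()
  good <- simulate_agent(sch, agent_params(0.6, 0.6, 10), seed = 16,
                         subject = 1L)
  bad <- simulate_agent(sch, agent_params(0.6, 0.6, 10), seed = 17,
                        subject = 2L)
  bad$choice <- ifelse(bad$choice == "good", "bad", "good")  # anti-learner
  res <- filter_poor_learners(rbind(good, bad))
  expect_equal(res$excluded, 2L)
  expect_setequal(unique(res$data$subject), 1L)
})

test_that("the GLME export is a complete long-format trial table", {
  sch <- test_schedule()
  co <- simulate_population(sch, 2, seed = 18)
  g <- export_glme_table(co$data)
  expect_setequal(names(g), c("subject", "correct", "context", "valence",
                              "block", "trial", "block_id"))
  expect_true(all(g$correct %in% 0:1))
  expect_setequal(unique(g$context), c("mixed", "only"))
  expect_setequal(unique(g$block), 1:2)
  expect_equal(nrow(g), sum(co$data$valid))
})
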