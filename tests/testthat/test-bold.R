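test_that("epoching normalizes to the pre-outcome baseline", {
  spec <- bold_spec()
  # constant raw signal -> identically zero epochs
  flat <- epoch_and_normalize(rep(250, 100), c(10, 40, 70), spec)
  expect_true(all(flat$epochs == 0))
  expect_equal(dim(flat$epochs), c(3L, 11L))
  expect_equal(flat$times, seq(-4, 16, by = 2))
  # baseline 100, post value 101 -> exactly 1 percent signal change
  raw <- rep(100, 60)
  raw[33] <- 101    # 6 s after an onset at volume 30
  ep <- epoch_and_normalize(raw, 30, spec)
  expect_equal(ep$epochs[1, ep$times == 6], 1)
  # epochs beyond the series bounds are dropped and reported
  short <- epoch_and_normalize(rep(100, 20), c(1, 10), spec)
  expect_equal(short$dropped, 1L)
  expect_equal(short$kept, 2L)
})

test_that("an injected HRF peaks at the 6 s sample", {
  spec <- bold_spec()
  onset <- 20L
  tgrid <- (seq_len(60) - onset) * spec$tr
  raw <- 100 + 0.8 * rewpun:::hrf_double_gamma(tgrid)
  ep <- epoch_and_normalize(raw, onset, spec)
  expect_equal(ep$times[which.max(ep$epochs[1, ])], 6)
  expect_equal(ep$epochs[1, ep$times == 6], 0.8, tolerance = 1e-6)
})

test_that("normalized epochs have exactly zero baseline mean", {
  sch <- test_schedule("fmri")
  co <- simulate_population(sch, 4, seed = 44)
  ts <- simulate_bold(co$data, bold_spec(noise_sd = 0.2), seed = 45)
  base <- rowMeans(ts$epochs[, ts$times < 0])
  expect_lt(max(abs(base)), 1e-10)
  expect_equal(ncol(ts$epochs), 11)
})

test_that("punishment-history counts match an independent single-pass scan", {
  sch <- test_schedule("fmri")
  for (k in 1:5) {
    co <- simulate_population(sch, 3, seed = 200 + k)
    h <- punishment_history(co$data)
    # independent recount, structured differently from the implementation
    d <- co$data[co$data$context == "mixed" & co$data$valid, ]
    d <- d[order(d$subject, d$block, d$trial), ]
    idx <- 0
    for (key in unique(paste(d$subject, d$block))) {
      db <- d[paste(d$subject, d$block) == key, ]
      pun_trials <- c()
      for (i in seq_len(nrow(db))) {
        if (db$valence[i] == "reward") {
          idx <- idx + 1
          expect_equal(h$pun_count[idx], length(pun_trials))
          expect_equal(h$recency[idx],
                       if (length(pun_trials) == 0) NA_real_
                       else db$trial[i] - max(pun_trials))
          pun_trials <- c()
        } else if (db$outcome[i] == -1) {
          pun_trials <- c(pun_trials, db$trial[i])
        }
      }
    }
    expect_equal(idx, nrow(h))
  }
})

test_that("recency tertiles are balanced within subject", {
  sch <- test_schedule("fmri")
  co <- simulate_population(sch, 6, seed = 55)
  h <- punishment_history(co$data)
  for (sj in unique(h$subject)) {
    lv <- h$recency_level[h$subject == sj & !is.na(h$recency)]
    if (length(lv) >= 3) {
      counts <- table(factor(lv, levels = 1:3))
      expect_lte(max(counts) - min(counts), 1)
    }
  }
})

test_that("PE tertiles split evenly with deterministic tie-breaking", {
  tab <- data.frame(subject = 1, condition = "reward_mixed", pe = 1:9)
  bt <- bin_pe_tertiles(tab)
  expect_equal(bt$labels, rep(1:3, each = 3))
  expect_equal(bt$bin_means$mean_pe, c(2, 5, 8))
  # exact ties are assigned by trial order
  ties <- data.frame(subject = 1, condition = "reward_mixed",
                     pe = rep(0.5, 6))
  bt2 <- bin_pe_tertiles(ties)
  expect_equal(bt2$labels, rep(1:3, each = 2))
  expect_error(bin_pe_tertiles(tab[1:2, ]), "fewer than 3")
})

test_that("mixed and single-context PE bin means stay comparable", {
  sch <- test_schedule("fmri")
  co <- simulate_population(sch, 20, seed = 66)
  ft <- fit_cohort(co$data, model_spec("dual"), fit_config(n_starts = 6))
  pe_rows <- list()
  for (sj in unique(co$data$subject)) {
    for (cond in c("reward_mixed", "reward_only")) {
      s <- co$data[co$data$subject == sj & co$data$condition == cond, ]
      fr <- ft[ft$subject == sj & ft$condition == cond, ]
      fit <- list(params = c(alpha_pos = fr$alpha_pos,
                             alpha_neg = fr$alpha_neg, beta = fr$beta),
                  spec = model_spec("dual"))
      pe_rows[[paste(sj, cond)]] <- data.frame(
        subject = sj, condition = cond, pe = fit_pes(fit, s))
    }
  }
  bt <- bin_pe_tertiles(do.call(rbind, pe_rows))
  bm <- bt$bin_means
  for (bin in 1:3) {
    mixed <- bm$mean_pe[bm$bin == bin & bm$condition == "reward_mixed"]
    only <- bm$mean_pe[bm$bin == bin & bm$condition == "reward_only"]
    p <- t.test(mixed, only, paired = TRUE)$p.value
    expect_gt(p, 0.01)  # same generative model in both contexts
  }
})

test_that("noise-free generator slopes equal the history gain exactly", {
  sch <- test_schedule("fmri")
  co <- simulate_population(sch, 5, seed = 77)
  for (g in c(0, 0.1)) {
    ts <- simulate_bold(co$data, bold_spec(history_gain = g, noise_sd = 0),
                        seed = 78)
    hs <- history_slope_test(ts, "count", "peak6s")
    expect_equal(unname(hs$slopes), rep(g, length(hs$slopes)),
                 tolerance = 1e-10)
  }
  # flat traces: zero amplitude and zero noise give zero ramp everywhere
  ts0 <- simulate_bold(co$data, bold_spec(amp_baseline = 0, history_gain = 0,
                                          noise_sd = 0), seed = 79)
  hs0 <- history_slope_test(ts0, "count", "ramp0to6")
  expect_true(all(hs0$slopes == 0))
  expect_equal(max(abs(ts0$epochs)), 0)
})

test_that("the slope test has power under gain and holds size under null", {
  sch <- test_schedule("fmri")
  co <- simulate_population(sch, 26, seed = 88)
  # power at the generator's default gain
  ts <- simulate_bold(co$data, bold_spec(history_gain = 0.1, noise_sd = 0.05),
                      seed = 89)
  expect_lt(history_slope_test(ts, "count", "peak6s")$p, 0.05)
  # null: rejection rate near the nominal level over repeated cohorts
  rej <- vapply(1:40, function(k) {
    tsk <- simulate_bold(co$data, bold_spec(history_gain = 0, noise_sd = 0.1),
                         seed = 1000 + k)
    history_slope_test(tsk, "count", "peak6s")$p < 0.05
  }, TRUE)
  expect_lt(mean(rej), 0.175)
})

test_that("recency-based slopes detect recency-coded amplitudes", {
  sch <- test_schedule("fmri")
  co <- simulate_population(sch, 8, seed = 90)
  ts <- simulate_bold(co$data, bold_spec(history_gain = 0.1, noise_sd = 0),
                      seed = 91)
  hs <- history_slope_test(ts, "recency", "ramp0to6")
  expect_true(is.finite(hs$t) || is.infinite(hs$t))
  expect_true(length(hs$slopes) >= 2)
})
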