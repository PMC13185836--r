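test_that("trial sequences have the configured session structure", {
  tr_train <- simulate_trials(sim_config("training"), seed = 1)
  expect_equal(nrow(tr_train), 300)
  expect_equal(unique(stats::na.omit(tr_train$amplitude_um)), 15)

  tr_test <- simulate_trials(sim_config("testing"), seed = 2)
  amps <- sort(unique(stats::na.omit(tr_test$amplitude_um)))
  expect_equal(amps, c(2, 4, 6, 8, 10, 12))
  expect_equal(mean(tr_test$trial_type == "go"), 0.9)

  # amplitude counts balanced within +/- 1 across Go trials
  counts <- table(tr_test$amplitude_um)
  expect_lte(diff(range(counts)), 1)

  # timestamps consistent with the ITI range
  gaps <- diff(tr_test$stim_onset_s)
  cfg <- sim_config("testing")
  lo <- cfg$iti_range_s[1] + cfg$stim_dur_s + cfg$response_window_s
  hi <- cfg$iti_range_s[2] + cfg$stim_dur_s + cfg$response_window_s
  expect_true(all(gaps >= lo - 1e-9 & gaps <= hi + 1e-9))
})

test_that("degenerate go fractions and bad configs are handled", {
  all_go <- simulate_trials(sim_config("testing", go_fraction = 1), seed = 3)
  expect_equal(sum(all_go$trial_type == "nogo"), 0)
  expect_error(sim_config(amplitudes_um = numeric()), "amplitudes")
  expect_error(sim_config(n_trials = 0), "n_trials")
})

test_that("simulated outcomes follow the latent psychometric model", {
  cfg <- sim_config("testing", n_trials = 4000, amplitudes_um = 6,
                    timeout_rate = 0)
  tr <- simulate_trials(cfg, seed = 4)

  # at threshold with no lapse the hit rate sits at the logistic midpoint
  mid <- simulate_behavior(tr, wt_mouse(threshold_um = 6), cfg, seed = 5)
  r <- outcome_rates(mid)
  expect_equal(r$hit_rate, 0.5, tolerance = 0.05)

  # fa_rate = 0 makes every No-Go a correct rejection
  clean <- simulate_behavior(tr, wt_mouse(fa_rate = 0), cfg, seed = 6)
  expect_true(all(clean$outcome[clean$trial_type == "nogo"] == "cr"))

  # a near-step psychometric separates amplitudes around threshold
  cfg2 <- sim_config("testing", n_trials = 600, timeout_rate = 0)
  tr2 <- simulate_trials(cfg2, seed = 7)
  steep <- simulate_behavior(tr2, wt_mouse(threshold_um = 7, slope = 100),
                             cfg2, seed = 8)
  by_amp <- amplitude_hit_rates(steep)
  expect_true(all(by_amp$hit_rate[by_amp$amplitude_um < 7] == 0))
  expect_true(all(by_amp$hit_rate[by_amp$amplitude_um > 7] == 1))
})

test_that("cohort generation is deterministic and validates its inputs", {
  cfg <- sim_config("testing", n_trials = 30, n_neurons_range = c(10, 12))
  a <- simulate_session(cfg, wt_mouse(), seed = 11, n_neurons = 10)
  b <- simulate_session(cfg, wt_mouse(), seed = 11, n_neurons = 10)
  expect_identical(a$trials, b$trials)
  expect_identical(a$traces$F, b$traces$F)
  expect_error(simulate_cohort(cfg, n_per_group = 0), "empty cohort")
  expect_error(
    simulate_traces(a$trials, wt_mouse(), cfg, seed = 1, n_neurons = 99),
    "outside configured range")
})

test_that("silent traces are constant and saturated cells always recruit", {
  cfg <- sim_config("testing", n_trials = 20, n_neurons_range = c(3, 3),
                    timeout_rate = 0)
  tr <- simulate_behavior(simulate_trials(cfg, 1), wt_mouse(), cfg, 2)
  silent <- ground_truth_mouse(evoked_amp_gain = 0, shared_gain_loading = 0,
                               baseline_noise_sd = 0, recruit_floor = 0,
                               recruit_amp_gain = 0, recruit_detect_boost = 0)
  st <- simulate_traces(tr, silent, cfg, seed = 3, n_neurons = 3)
  expect_true(all(apply(st$traces$F, 1, stats::sd) < 1e-9))

  # recruit_prob = 1 with a huge evoked amplitude: the percentile test
  # flags the cell activated on every Go trial
  loud <- ground_truth_mouse(recruit_floor = 1, recruit_amp_gain = 0,
                             recruit_detect_boost = 0, evoked_amp_gain = 10,
                             shared_gain_loading = 0)
  s <- simulate_session(cfg, loud, seed = 4, n_neurons = 3)
  resp <- session_responses(s, seed = 5)
  go <- resp$recruitment$meta$trial_type == "go" & resp$recruitment$meta$included
  expect_true(all(resp$recruitment$labels[go, ] != 0, na.rm = TRUE))
})

test_that("ground-truth recruitment tracks the configured probabilities", {
  cfg <- sim_config("testing", n_trials = 300, timeout_rate = 0,
                    n_neurons_range = c(60, 60))
  # loading 0 isolates the Bernoulli recruitment mechanism
  m <- wt_mouse(shared_gain_loading = 0)
  s <- simulate_session(cfg, m, seed = 21, n_neurons = 60)
  go <- s$trials$trial_type == "go"
  det <- s$trials$outcome == "hit" & go
  rec_frac <- rowMeans(s$ground_truth$recruitment != 0)
  for (amp in cfg$amplitudes_um) {
    for (d in c(TRUE, FALSE)) {
      rows <- which(go & s$trials$amplitude_um == amp & (det == d))
      if (length(rows) < 5) next
      p <- recruit_prob(m, amp, d)
      n_draws <- length(rows) * 60
      se <- sqrt(p * (1 - p) / n_draws)
      expect_lt(abs(mean(rec_frac[rows]) - p), 3 * se + 1e-12)
    }
  }
  # monotonicity: recruitment increases with amplitude
  means <- vapply(cfg$amplitudes_um, function(a)
    mean(rec_frac[go & s$trials$amplitude_um == a]), numeric(1))
  expect_gt(stats::cor(cfg$amplitudes_um, means, method = "spearman"), 0.9)
})
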