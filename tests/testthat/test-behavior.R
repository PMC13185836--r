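make_trials <- function(outcomes, types, amplitudes = NULL, timeout = NULL) {
  n <- length(outcomes)
  tibble::tibble(
    trial_idx = seq_len(n), trial_type = types,
    amplitude_um = amplitudes %||% ifelse(types == "go", 6, NA_real_),
    freq_hz = 10, stim_onset_s = 12 + 10 * seq_len(n),
    stim_offset_s = 12.5 + 10 * seq_len(n), first_lick_s = NA_real_,
    outcome = outcomes, timeout = timeout %||% rep(FALSE, n))
}

test_that("outcome rates match direct tallies and handle timeouts", {
  tr <- make_trials(c(rep("hit", 8), rep("miss", 2), "fa", rep("cr", 4)),
                    c(rep("go", 10), rep("nogo", 5)))
  r <- outcome_rates(tr)
  expect_equal(r$hit_rate, 0.8)
  expect_equal(r$fa_rate, 0.2)
  expect_equal(r$miss_rate, 0.2)
  expect_equal(r$cr_rate, 0.8)

  # randomized table equals an independent brute-force tally
  set.seed(1)
  types <- sample(c("go", "nogo"), 200, replace = TRUE, prob = c(0.8, 0.2))
  outc <- ifelse(types == "go",
                 sample(c("hit", "miss"), 200, replace = TRUE),
                 sample(c("cr", "fa"), 200, replace = TRUE))
  tmo <- types == "go" & runif(200) < 0.05
  outc[tmo] <- NA
  tr2 <- make_trials(outc, types, timeout = tmo)
  r2 <- outcome_rates(tr2)
  go_rows <- which(types == "go" & !tmo)
  expect_equal(r2$hit_rate, sum(outc[go_rows] == "hit") / length(go_rows),
               tolerance = 1e-12)
  expect_equal(r2$prestim_lick_rate, sum(tmo) / sum(types == "go"),
               tolerance = 1e-12)

  # zero No-Go trials: rate flagged undefined, not silently NaN
  r3 <- outcome_rates(make_trials(rep("hit", 4), rep("go", 4)))
  expect_false(r3$nogo_defined)
  expect_true(is.na(r3$fa_rate))
})

test_that("psychometric fit recovers generating parameters", {
  cfg <- sim_config("testing", n_trials = 1200, timeout_rate = 0)
  tr <- simulate_behavior(simulate_trials(cfg, 31),
                          wt_mouse(threshold_um = 6, slope = 1), cfg, 32)
  fit <- fit_psychometric(tr)
  expect_lt(abs(fit$threshold_um - 6), 0.5)
  expect_true(fit$flags$threshold_defined)
  # accuracy is the peak derivative of the logistic: slope / 4
  expect_equal(fit$accuracy_slope, fit$slope / 4)
})

test_that("psychometric edge cases are flagged", {
  flat <- tibble::tibble(amplitude_um = c(2, 4, 6), n = c(50, 50, 50),
                         hits = c(0, 0, 0))
  f1 <- fit_psychometric(flat)
  expect_false(f1$flags$threshold_defined)
  expect_true(is.na(f1$threshold_um))

  # perfect separation triggers the ridge fallback, still near the step
  sep <- tibble::tibble(amplitude_um = c(2, 4, 8, 10), n = rep(60, 4),
                        hits = c(0, 0, 60, 60))
  f2 <- fit_psychometric(sep)
  expect_true(f2$flags$separation)
  expect_true(f2$threshold_um > 4 && f2$threshold_um < 8)
})

test_that("raising all hit rates lowers the fitted threshold", {
  base <- tibble::tibble(amplitude_um = c(2, 4, 6, 8, 10, 12), n = 200,
                         hits = round(200 * plogis(c(2, 4, 6, 8, 10, 12) - 6)))
  up <- dplyr::mutate(base,
                      hits = round(200 * plogis(.data$amplitude_um - 6 + 1)))
  expect_lt(fit_psychometric(up)$threshold_um,
            fit_psychometric(base)$threshold_um)
})

test_that("criterion c' matches quantile arithmetic and is antisymmetric", {
  expect_equal(criterion_c(0.8, 0.2, 100, 100)$c_prime, 0, tolerance = 1e-12)
  expect_false(criterion_c(0.5, 0.5, 100, 100)$defined)
  # frozen value from closed-form normal-quantile arithmetic
  expect_equal(criterion_c(0.9, 0.4, 1e6, 1e6)$c_prime, -0.3349421312,
               tolerance = 1e-9)
  # swapping hit <-> 1-fa and fa <-> 1-hit flips the sign
  for (h in c(0.7, 0.85, 0.95)) {
    for (f in c(0.1, 0.3)) {
      a <- criterion_c(h, f, 1e5, 1e5)$c_prime
      b <- criterion_c(1 - f, 1 - h, 1e5, 1e5)$c_prime
      expect_equal(a, -b, tolerance = 1e-9)
    }
  }
  # extreme rates are clipped, not infinite
  expect_true(is.finite(criterion_c(1, 0, 50, 20)$c_prime))
})

test_that("trial-by-trial variability obeys the Bernoulli bound", {
  types <- rep("go", 40)
  amps <- rep(c(2, 4, 6, 8), each = 10)
  outc <- c(rep("miss", 10),                          # p=0 -> var 0
            rep(c("hit", "miss"), 5),                 # p=.5 -> var .25
            rep("hit", 10),                           # p=1 -> var 0
            c(rep("hit", 7), rep("miss", 3)))         # p=.7
  tv <- trial_variability(make_trials(outc, types, amplitudes = amps),
                          threshold_um = 4)
  pa <- tv$per_amplitude
  expect_equal(pa$variance[pa$amplitude_um == 4], 0.25)
  expect_equal(pa$variance[pa$amplitude_um == 6], 0)
  expect_equal(pa$variance[pa$amplitude_um == 8], 0.21, tolerance = 1e-12)
  expect_true(all(pa$variance <= 0.25 + 1e-12))
  # triplet anchored at threshold -2 / threshold / +2
  expect_equal(tv$triplet$amplitude_um, c(2, 4, 6))
  expect_equal(tv$triplet$normalized, tv$triplet$variance / 0.25)

  # brute-force oracle on a random table
  set.seed(9)
  outc2 <- sample(c("hit", "miss"), 60, replace = TRUE)
  amps2 <- sample(c(2, 6, 10), 60, replace = TRUE)
  tv2 <- trial_variability(make_trials(outc2, rep("go", 60),
                                       amplitudes = amps2))
  for (a in c(2, 6, 10)) {
    x <- as.numeric(outc2[amps2 == a] == "hit")
    expect_equal(tv2$per_amplitude$variance[tv2$per_amplitude$amplitude_um == a],
                 mean((x - mean(x))^2), tolerance = 1e-12)
  }
})

test_that("subgroup clustering recovers separated groups", {
  set.seed(5)
  lo <- matrix(runif(7 * 6, 0.1, 0.3), 7)
  hi <- matrix(runif(7 * 6, 0.6, 0.9), 7)
  m <- rbind(lo, hi)
  rownames(m) <- paste0("m", 1:14)
  cl <- cluster_subgroups(m, seed = 2)
  expect_equal(cl$subgroup[1:7], rep("hyposensitive-like", 7))
  expect_equal(cl$subgroup[8:14], rep("typical", 7))
  # partition is invariant to cluster relabeling: check grouping not ids
  expect_equal(length(unique(cl$cluster[1:7])), 1)
  expect_equal(length(unique(cl$cluster[8:14])), 1)

  ident <- matrix(0.5, 4, 6)
  cl2 <- cluster_subgroups(ident)
  expect_true(attr(cl2, "degenerate"))
  expect_error(cluster_subgroups(m[1, , drop = FALSE]), "at least 2")
})

test_that("session QC applies a strict 40% false-alarm boundary", {
  qc_for <- function(n_fa, n_cr) {
    session_qc(make_trials(c(rep("hit", 10), rep("fa", n_fa), rep("cr", n_cr)),
                           c(rep("go", 10), rep("nogo", n_fa + n_cr))))
  }
  expect_true(qc_for(39, 61)$include)   # 0.39
  expect_false(qc_for(40, 60)$include)  # 0.40 exactly: excluded
  expect_true(qc_for(0, 10)$include)
})

test_that("learning criterion uses 3-day rolling means", {
  d <- tibble::tibble(day = 1:5, hit_rate = c(0.6, 0.85, 0.85, 0.85, 0.9),
                      fa_rate = c(0.4, 0.2, 0.2, 0.2, 0.1))
  lc <- learning_criterion(d)
  # brute-force rolling scan oracle
  roll_ok <- sapply(3:5, function(i)
    mean(d$hit_rate[(i - 2):i]) >= 0.8 && mean(d$fa_rate[(i - 2):i]) < 0.3)
  expect_equal(lc$first_pass_day, (3:5)[which(roll_ok)[1]])

  fail <- learning_criterion(tibble::tibble(
    day = 1:3, hit_rate = rep(0.85, 3), fa_rate = rep(0.35, 3)))
  expect_true(is.na(fail$first_pass_day))
  short <- learning_criterion(tibble::tibble(day = 1:2, hit_rate = 1,
                                             fa_rate = 0))
  expect_false(short$sufficient)
})
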