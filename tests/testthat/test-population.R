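test_that("cosine similarity matches a brute-force double loop", {
  # identical vectors
  v <- rbind(c(1, 1, 0), c(1, 1, 0))
  expect_equal(ensemble_cosine(v)$mean_cosine, 1)
  # anti-aligned
  expect_equal(ensemble_cosine(rbind(c(1, 0), c(-1, 0)))$mean_cosine, -1)

  set.seed(21)
  m <- matrix(sample(c(-1L, 0L, 1L), 15 * 40, replace = TRUE,
                     prob = c(0.15, 0.6, 0.25)), nrow = 15)
  res <- ensemble_cosine(m)
  # O(n^2) oracle
  tot <- 0; np <- 0
  for (i in 1:14) for (j in (i + 1):15) {
    a <- m[i, ]; b <- m[j, ]
    tot <- tot + sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    np <- np + 1
  }
  expect_equal(res$mean_cosine, tot / np, tolerance = 1e-9)

  # symmetry and positive-scale invariance
  expect_equal(ensemble_cosine(m[c(2, 1), ])$mean_cosine,
               ensemble_cosine(m[c(1, 2), ])$mean_cosine)
  m2 <- m; m2[1, ] <- 5 * m2[1, ]
  expect_equal(ensemble_cosine(m2)$mean_cosine, res$mean_cosine,
               tolerance = 1e-9)

  # zero vectors are excluded, not averaged as zeros
  mz <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 0))
  rz <- ensemble_cosine(mz)
  expect_equal(rz$mean_cosine, 1)
  expect_equal(rz$n_zero_excluded, 1)
})

test_that("E/I ratio counts activated cells per trial", {
  lab <- matrix(0L, 3, 40)
  lab[1, 1:30] <- 1L; lab[1, 31:40] <- 1L      # 30 pyr + 10 inh activated
  lab[2, 1:5] <- 1L                            # no inh activated
  ct <- c(rep("pyr", 30), rep("inh", 10))
  rec <- toy_recruitment(lab, celltype = ct,
                         detected = c(TRUE, FALSE, FALSE))
  ei <- ei_ratio(rec)
  expect_equal(ei$per_trial$ei_ratio[1], 3.0)
  expect_false(ei$per_trial$defined[2])
  expect_equal(ei$n_undefined, 2)
  expect_equal(ei$by_condition$mean_ei[ei$by_condition$condition == "all"], 3.0)
})

test_that("single-cell SNR equals the direct computation", {
  at <- toy_tensor(n_hit = 6, n_miss = 4, n_neurons = 3, seed = 22)
  # make two catch trials by relabeling
  at$meta$trial_type[9:10] <- "nogo"
  at$meta$outcome[9:10] <- "cr"
  at$meta$detected[9:10] <- FALSE
  m <- trial_mean_stim_z(at)
  res <- single_cell_snr(at)
  go <- which(at$meta$trial_type == "go")
  for (j in 1:3) {
    oracle <- mean(abs(m[go, j] - mean(m[9:10, j])))
    expect_equal(res$snr_all[j], oracle, tolerance = 1e-9)
  }
  # stim identical to catch -> SNR 0; constant offset -> that offset
  at2 <- at
  at2$z[] <- 0
  expect_equal(single_cell_snr(at2)$snr_all, rep(0, 3))
  at2$z[go, , at2$window$pre + seq_len(at2$window$stim)] <- 2
  expect_equal(single_cell_snr(at2)$snr_all, rep(2, 3), tolerance = 1e-9)
})

test_that("population SNR is the recruited-fraction ratio over catch", {
  lab <- matrix(0L, 12, 10)
  lab[1:10, 1:2] <- 1L            # stimulus trials: 20% recruited
  lab[11:12, 1] <- c(1L, 1L)      # catch trials: 10% recruited
  rec <- toy_recruitment(lab,
                         trial_type = c(rep("go", 10), rep("nogo", 2)),
                         detected = c(rep(TRUE, 10), rep(FALSE, 2)))
  ps <- population_snr(rec)
  expect_equal(ps$catch_mean_fraction, 0.1)
  expect_equal(ps$per_trial$pop_snr, rep(2, 10))
  # recruited fraction equal to catch mean -> ratio 1
  lab2 <- lab; lab2[1:10, ] <- 0L; lab2[1:10, 5] <- 1L
  ps2 <- population_snr(toy_recruitment(
    lab2, trial_type = c(rep("go", 10), rep("nogo", 2))))
  expect_equal(ps2$per_trial$pop_snr, rep(1, 10))
  # catch trials against themselves average exactly 1
  expect_equal(mean(lab[11:12, ] != 0) / ps$catch_mean_fraction, 1)
  # zero catch recruitment: flagged undefined
  lab3 <- lab; lab3[11:12, ] <- 0L
  ps3 <- population_snr(toy_recruitment(
    lab3, trial_type = c(rep("go", 10), rep("nogo", 2))))
  expect_false(ps3$defined)
})

test_that("SNR-recruitment regression returns least-squares statistics", {
  perfect <- tibble::tibble(snr = c(0, 1, 2), recruited_fraction = c(0, 1, 2))
  r <- snr_recruitment_cor(perfect)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$r, 1, tolerance = 1e-9)

  set.seed(23)
  indep <- tibble::tibble(snr = rnorm(500),
                          recruited_fraction = rnorm(500))
  r2 <- snr_recruitment_cor(indep)
  expect_lt(abs(r2$r), 0.1)
  expect_gt(r2$p, 0.01)

  flat <- tibble::tibble(snr = rep(1, 5), recruited_fraction = rnorm(5))
  expect_false(snr_recruitment_cor(flat)$defined)
  expect_error(snr_recruitment_cor(perfect[1:2, ]), "at least 3")
})

test_that("hyposensitive-like sessions show weaker population statistics", {
  cfg <- sim_config("testing", n_trials = 100,
                    n_neurons_range = c(40, 40), timeout_rate = 0)
  stats_for <- function(mouse, seed) {
    s <- simulate_session(cfg, mouse, seed = seed, n_neurons = 40)
    resp <- session_responses(s, seed = seed + 1)
    at <- resp$aligned
    c(cos = ensemble_cosine(resp$recruitment)$mean_cosine,
      snr = mean(single_cell_snr(at)$snr_all, na.rm = TRUE))
  }
  wt <- rowMeans(sapply(1:3, function(i) stats_for(wt_mouse(), 400 + i)))
  hy <- rowMeans(sapply(1:3, function(i) stats_for(hypo_mouse(), 500 + i)))
  expect_gt(wt["snr"], hy["snr"])
  expect_gt(wt["cos"], hy["cos"])
})
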