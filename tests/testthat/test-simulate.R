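test_that("agent samplers respect bounds and structures", {
  flat <- sample_agents(200, "flat", seed = 1)
  expect_true(all(flat$K_self > 0 & flat$K_self < 1.5))
  expect_true(all(flat$beta_other > 0 & flat$beta_other < 4))

  shared <- sample_agents(50, "flat", spec = spec_1k1b, seed = 2)
  expect_identical(shared$K_self, shared$K_other)
  expect_identical(shared$beta_self, shared$beta_other)

  grid <- sample_agents(sampler = "grid", seed = 3)
  expect_equal(nrow(grid), 900)  # 6 x 6 x 5 x 5 crossing
  expect_true(all(grid$K_self > 0 & grid$K_self < 1.5))
  expect_true(all(grid$beta_self >= 0.02 & grid$beta_self < 4))
  # jitter is small: values sit near their grid points
  expect_lt(max(abs(grid$K_other -
                      pmin(pmax(rep(rep(c(0, .3, .6, .9, 1.2, 1.5),
                                       each = 6), 25),
                                1e-3), 1.5 - 1e-3))), 0.35)

  expect_identical(sample_agents(sampler = "grid", seed = 3), grid)
})

test_that("simulated acceptance matches the analytic mean work probability", {
  sched <- build_schedule(n_reps = 200, seed = 4)  # 10,000 trials
  pars <- agent_params(1e-9, 1e-9, 2, 2)           # K ~ 0: flat in effort
  dat <- simulate_choices(pars, sched, spec_2k2b, seed = 5)
  p_cell <- plogis(2 * (seq(2, 10, 2) - 1))
  expect_equal(mean(p_cell), mean(dat$p_work), tolerance = 1e-6)
  se <- sqrt(sum(dat$p_work * (1 - dat$p_work))) / nrow(dat)
  expect_lt(abs(mean(dat$choice) - mean(p_cell)), 3 * se)

  # vanishing beta: acceptance near one half
  p0 <- agent_params(0.5, 0.5, 1e-9, 1e-9)
  d0 <- simulate_choices(p0, sched, spec_2k2b, seed = 6)
  expect_lt(abs(mean(d0$choice) - 0.5), 3 * 0.5 / sqrt(nrow(d0)))

  expect_identical(simulate_choices(pars, sched, spec_2k2b, seed = 5), dat)
})

test_that("per-cell acceptance passes a chi-square calibration check", {
  sched <- build_schedule(n_reps = 200, seed = 7)
  pars <- agent_params(0.15, 0.45, 1.5, 0.8)
  dat <- simulate_choices(pars, sched, spec_2k2b, seed = 8)
  cell <- interaction(dat$recipient, dat$effort_level, dat$reward_credits)
  obs <- tapply(dat$choice, cell, sum)
  n <- tapply(dat$choice, cell, length)
  p <- tapply(dat$p_work, cell, mean)
  stat <- sum((obs - n * p)^2 / (n * p * (1 - p)))
  expect_lt(stat, qchisq(0.99, df = length(obs)))
})

test_that("missed trials appear only when a miss rate is set", {
  sched <- std_schedule()
  pars <- agent_params(0.3, 0.3, 1, 1)
  expect_false(anyNA(simulate_choices(pars, sched, seed = 1)$choice))
  d <- simulate_choices(pars, sched, seed = 1, miss_rate = 0.2)
  expect_gt(sum(is.na(d$choice)), 0)
})

test_that("force traces obey the success criterion limits", {
  # constant squeeze just above threshold always succeeds
  tr_hi <- simulate_force(0.5, gain = 1.1, noise_sd = 0, seed = 1)
  expect_true(evaluate_success(tr_hi))
  # half the required force never succeeds
  tr_lo <- simulate_force(0.5, gain = 0.5, noise_sd = 0, seed = 1)
  expect_false(evaluate_success(tr_lo))
  expect_identical(simulate_force(0.5, seed = 3)$samples,
                   simulate_force(0.5, seed = 3)$samples)
})

test_that("stochastic success rate matches the closed-form binomial oracle", {
  level <- 0.5; gain <- 0.98; sd <- 0.03; reps <- 1000
  succ <- vapply(seq_len(reps), function(i)
    evaluate_success(simulate_force(level, gain, sd, seed = i)), logical(1))
  # each 20 ms sample independently clears the threshold with prob p1;
  # success needs >= 50 of 151 samples above it
  p1 <- pnorm((gain * level - level) / sd)
  p_success <- 1 - pbinom(49, 151, p1)
  se <- sqrt(p_success * (1 - p_success) / reps)
  expect_lt(abs(mean(succ) - p_success), 3 * se)
})

test_that("trial outcomes attach force success and AUC to accepted work", {
  sched <- std_schedule()
  dat <- simulate_choices(agent_params(0.2, 0.2, 1, 1), sched, seed = 55)
  out <- simulate_outcomes(dat, gain_self = 1.1, gain_other = 0.5,
                           noise_sd = 0.01, seed = 56)
  work <- !is.na(out$choice) & out$choice == 1
  expect_true(all(is.na(out$success[!work])))
  # near-noiseless gains: self succeeds, other (half the force) fails
  expect_true(all(out$success[work & out$recipient == "self"]))
  expect_false(any(out$success[work & out$recipient == "other"]))
  # AUC tracks gain x required level
  i <- which(work & out$recipient == "self")[1]
  expect_equal(out$force_auc[i], 1.1 * out$effort_pct_mvc[i] / 100,
               tolerance = 0.02)
  path <- tempfile(fileext = ".csv")
  write_cohort(out, path)
  back <- read_cohort(path)
  expect_equal(back$force_auc, out$force_auc, tolerance = 1e-9)
  unlink(path)
})

test_that("lesion cohorts are binary, reproducible, and plant their effect", {
  coh <- simulate_lesion_cohort(n_patients = 20, grid_shape = c(24, 28, 24),
                                effect_size_d = 2, seed = 9)
  expect_length(coh$masks, 20)
  for (v in coh$masks) {
    expect_true(all(v$mask %in% c(0L, 1L)))
    expect_gt(sum(v$mask), 0)
  }
  coh2 <- simulate_lesion_cohort(n_patients = 20, grid_shape = c(24, 28, 24),
                                 effect_size_d = 2, seed = 9)
  expect_identical(coh$behaviour, coh2$behaviour)

  # group means separated by ~d across seeds (default grid geometry)
  diffs <- vapply(1:12, function(s) {
    cc <- simulate_lesion_cohort(45, effect_size_d = 2, seed = s)
    b <- cc$behaviour
    mean(b$value[b$overlaps]) - mean(b$value[!b$overlaps])
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 2), 3 * sd(diffs) / sqrt(length(diffs)))

  expect_error(simulate_lesion_cohort(20, grid_shape = c(24, 28, 24),
                                      planted_center = c(2, 2, 2),
                                      planted_radius = 4, seed = 1),
               "outside")
})

test_that("null cohorts show no behaviour-lesion association", {
  rs <- vapply(1:60, function(s) {
    cc <- simulate_lesion_cohort(30, effect_size_d = 0, seed = 100 + s)
    b <- cc$behaviour
    if (length(unique(b$overlaps)) < 2) return(0)
    cor(b$value, as.numeric(b$overlaps))
  }, numeric(1))
  # point-biserial r should sit in its null band
  expect_lt(mean(abs(rs) > 2 / sqrt(30 - 1)), 0.2)
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)))
})
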