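test_that("credits follow the payoff rules on the standard schedule", {
  sched <- std_schedule()
  all_rest <- transform(sched, choice = 0, success = FALSE)
  expect_equal(unname(credits_earned(all_rest)["self"]), 75)
  expect_equal(unname(credits_earned(all_rest)["other"]), 75)

  all_work <- transform(sched, choice = 1, success = TRUE)
  # 3 reps x 5 efforts x (2+4+6+8+10) credits per recipient
  expect_equal(unname(credits_earned(all_work)["self"]), 450)
  expect_equal(unname(credits_earned(all_work)["other"]), 450)

  all_missed <- transform(sched, choice = NA, success = NA)
  expect_equal(sum(credits_earned(all_missed)), 0)

  # conservation: total = rest count + successful work rewards
  set.seed(3)
  mixed <- transform(sched, choice = rbinom(150, 1, 0.6))
  mixed$success <- mixed$choice == 1 & runif(150) < 0.8
  expect_equal(sum(credits_earned(mixed)),
               sum(mixed$choice == 0) +
                 sum(mixed$reward_credits[mixed$success]))

  bad <- transform(sched, choice = 0, success = TRUE)
  expect_error(credits_earned(bad), "not accepted")
})

test_that("success requires one cumulative second at or above threshold", {
  rate <- 50
  # exactly at the required level throughout: boundary inclusive
  expect_true(evaluate_success(force_trace(rep(0.5, 151), 0.5, rate = rate)))
  # two disjoint half-second spans accumulate to one second
  samp <- rep(0, 151)
  samp[11:35] <- 0.6; samp[101:125] <- 0.6   # 25 + 25 samples = 1.0 s
  expect_true(evaluate_success(force_trace(samp, 0.5, rate = rate)))
  # 0.9 s total falls short
  samp2 <- rep(0, 151); samp2[1:45] <- 0.7
  expect_false(evaluate_success(force_trace(samp2, 0.5, rate = rate)))
  expect_error(force_trace(numeric(0), 0.5), "empty")
})

test_that("success is monotone in the force trace", {
  set.seed(5)
  base <- pmax(rnorm(151, 0.48, 0.05), 0)
  tr <- force_trace(base, 0.5)
  tr_up <- force_trace(base + 0.05, 0.5)
  if (evaluate_success(tr)) expect_true(evaluate_success(tr_up))
  expect_gte(sum(tr_up$samples >= 0.5), sum(tr$samples >= 0.5))
})

test_that("normalized force AUC anchors at 0, 0.5 and 1", {
  expect_equal(force_auc(force_trace(rep(1, 151), 0.5, mvc = 1)), 1)
  expect_equal(force_auc(force_trace(rep(0, 151), 0.5, mvc = 1)), 0)
  expect_equal(force_auc(force_trace(rep(0.5, 151), 0.5, mvc = 1)), 0.5)
  # linear in trace scaling
  set.seed(6)
  f <- runif(151, 0, 0.5)
  a1 <- force_auc(force_trace(f, 0.5))
  a2 <- force_auc(force_trace(2 * f, 0.5))
  expect_equal(a2, 2 * a1, tolerance = 1e-12)
  expect_error(force_auc(force_trace(rep(0.5, 10), 0.5, mvc = 0)), "mvc")
})

test_that("rank-z transform is monotone-invariant and standardized", {
  x <- c(3.2, -1, 0.5, 10, 2)
  z <- rank_z(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(rank_z(exp(x)), z)              # monotone transform
  # hand-ranked 5-element list with one tie pair
  y <- c(2, 7, 7, 1, 5)                        # ranks 2, 4.5, 4.5, 1, 3
  r <- c(2, 4.5, 4.5, 1, 3)
  expect_equal(rank_z(y), as.numeric(scale(r)))
  expect_warning(z0 <- rank_z(rep(1, 5)), "equal")
  expect_equal(as.numeric(z0), rep(0, 5))
  expect_error(rank_z(c(1, 2)), ">= 3")
})

test_that("subject regressors recover generative structure", {
  sched <- std_schedule()
  # identical behaviour across recipients: recipient effects vanish
  pars_eq <- agent_params(0.4, 0.4, 2, 2)
  dat <- simulate_choices(pars_eq, sched, seed = 71)
  reg <- subject_regressors(dat, pars_eq)
  expect_equal(reg$k_recipient_effect, 0)
  dat_mirror <- dat
  dat_mirror$recipient <- ifelse(dat$recipient == "self", "other", "self")
  both <- rbind(dat, dat_mirror)
  expect_equal(subject_regressors(both, pars_eq)$choice_recipient_effect, 0)

  # planted K difference appears in the regressor after refitting
  agents <- sample_agents(sampler = "fixed", seed = 72, params = data.frame(
    K_self = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3),
    K_other = c(0.6, 0.6, 0.6, 0.6, 0.6, 0.6),
    beta_self = 3, beta_other = 3))
  datc <- simulate_cohort_choices(agents, sched, seed = 73)
  fit <- fit_map_em(datc, spec_2k2b, seed = 74, mc_samples = 0)
  kdiffs <- vapply(fit$subjects, function(s)
    s$params$K_other - s$params$K_self, numeric(1))
  expect_lt(abs(mean(kdiffs) - 0.3), 0.15)

  # zero discounting: flat effort slope, positive reward slope (averaged
  # over agents; single-subject slopes carry sampling noise of ~0.4)
  pars_k0 <- agent_params(1e-6, 1e-6, 1, 1)
  regs0 <- do.call(rbind, lapply(1:6, function(s) subject_regressors(
    simulate_choices(pars_k0, sched, seed = 750 + s), pars_k0)))
  expect_lt(abs(mean(regs0$effort_slope)), 0.6)
  expect_gt(mean(regs0$reward_slope), 1)

  # deterministic all-work subject triggers the penalized fallback
  dat_sep <- transform(sched, choice = 1)
  reg_sep <- subject_regressors(dat_sep, pars_eq)
  expect_true(reg_sep$penalized_slopes)
  expect_true(is.finite(reg_sep$effort_slope))
})

test_that("behaviour summaries aggregate per subject and recipient", {
  sched <- std_schedule()
  agents <- sample_agents(3, "flat", seed = 81)
  dat <- simulate_cohort_choices(agents, sched, seed = 82)
  dat$success <- dat$choice == 1
  s <- behaviour_summary(dat)
  expect_equal(nrow(s), 6)
  expect_true(all(s$acceptance >= 0 & s$acceptance <= 1))
  one <- dat[dat$subject == "s0001" & dat$recipient == "self", ]
  expect_equal(s$acceptance[s$subject == "s0001" & s$recipient == "self"],
               mean(one$choice))
})
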