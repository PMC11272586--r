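test_that("parameter transforms round-trip to high precision", {
  for (tok in c("parabolic-2k2b", "hyperbolic-1k2b", "linear-1k1b")) {
    sp <- parse_model_token(tok)
    x <- c(-1.3, 0.2, 2.5, -0.7)[seq_len(length(transformed_params(
      agent_params(0.3, 0.3, 1, 1), sp)))]
    p <- natural_params(x, sp)
    expect_equal(unname(transformed_params(p, sp)), x, tolerance = 1e-10)
  }
})

test_that("flat-prior MAP matches an independent grid-search MLE", {
  sched <- std_schedule()
  pars <- agent_params(0.6, 0.6, 1.8, 1.8)
  dat <- simulate_choices(pars, sched, spec_1k1b, seed = 21)
  sub <- effortmap:::encode_subject(dat)
  flat_mu <- c(0, 0); flat_s2 <- c(1e6, 1e6)
  opt <- effortmap:::map_estimate(sub, spec_1k1b, flat_mu, flat_s2,
                                  starts = list(c(0, 0), c(1, 1), c(-1, -1)))
  map_pars <- natural_params(opt$par, spec_1k1b)

  # independent 50 x 50 lattice search through the R-level likelihood
  Ks <- seq(0.015, 1.485, length.out = 50)
  Bs <- seq(0.04, 3.96, length.out = 50)
  ll <- outer(seq_along(Ks), seq_along(Bs), Vectorize(function(i, j)
    choice_loglik(dat, agent_params(Ks[i], Ks[i], Bs[j], Bs[j]), spec_1k1b)))
  best <- arrayInd(which.max(ll), dim(ll))
  expect_lt(abs(map_pars$K_self - Ks[best[1]]), diff(Ks[1:2]) + 1e-9)
  expect_lt(abs(map_pars$beta_self - Bs[best[2]]), diff(Bs[1:2]) + 1e-9)
})

test_that("EM improves the summed evidence monotonically and converges", {
  sched <- std_schedule()
  agents <- sample_agents(14, "flat", seed = 31)
  dat <- simulate_cohort_choices(agents, sched, seed = 32)
  fit <- fit_map_em(dat, spec_2k2b, seed = 33, mc_samples = 0)
  expect_true(fit$converged)
  expect_true(all(diff(fit$evidence_trace) > -1e-6))
  expect_true(all(vapply(fit$subjects, function(s)
    s$params$K_self > 0 && s$params$K_self < 1.5 &&
      s$params$beta_other > 0 && s$params$beta_other < 4, logical(1))))
  expect_true(all(is.finite(vapply(fit$subjects, `[[`, numeric(1),
                                   "evidence"))))
})

test_that("fits are bitwise reproducible under a fixed seed", {
  sched <- std_schedule()
  agents <- sample_agents(6, "flat", seed = 41)
  dat <- simulate_cohort_choices(agents, sched, seed = 42)
  f1 <- fit_map_em(dat, spec_2k2b, seed = 43, mc_samples = 100)
  f2 <- fit_map_em(dat, spec_2k2b, seed = 43, mc_samples = 100)
  expect_identical(serialize(f1, NULL), serialize(f2, NULL))
})

test_that("group fits serialize to structured text with provenance", {
  sched <- std_schedule()
  agents <- sample_agents(4, "flat", seed = 44)
  dat <- simulate_cohort_choices(agents, sched, seed = 45)
  fit <- fit_map_em(dat, spec_1k1b, seed = 46, mc_samples = 100)
  path <- tempfile(fileext = ".json")
  write_group_fit(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$model, "parabolic-1k1b")
  expect_equal(back$ibic, fit$ibic)
  expect_equal(back$subjects$K_self,
               vapply(fit$subjects, function(s) s$params$K_self, numeric(1)),
               ignore_attr = TRUE)
  unlink(path)
})

test_that("a homogeneous cohort shrinks the group prior variance", {
  sched <- std_schedule()
  same <- data.frame(K_self = rep(0.5, 10), K_other = 0.5,
                     beta_self = 2, beta_other = 2)
  agents <- sample_agents(sampler = "fixed", params = same, seed = 51)
  dat <- simulate_cohort_choices(agents, sched, seed = 52)
  fit <- fit_map_em(dat, spec_2k2b, seed = 53, mc_samples = 0)
  expect_true(all(fit$prior$var < 4))
})

test_that("recovered parameters track generating values in a flat cohort", {
  sched <- std_schedule()
  agents <- sample_agents(60, "flat", seed = 61)
  dat <- simulate_cohort_choices(agents, sched, seed = 62)
  fit <- fit_map_em(dat, spec_2k2b, seed = 63, mc_samples = 0)
  rec <- coef_table(fit)
  for (p in c("K_self", "K_other", "beta_self", "beta_other"))
    expect_gt(cor(agents[[p]], rec[[p]]), 0.7)
})

test_that("integrated BIC applies the prior-count penalty", {
  sched <- std_schedule()
  pars <- agent_params(0.4, 0.4, 1.5, 1.5)
  dat <- simulate_cohort_choices(
    sample_agents(sampler = "fixed", seed = 71,
                  params = data.frame(K_self = c(0.4, 0.4), K_other = 0.4,
                                      beta_self = 1.5, beta_other = 1.5)),
    sched, seed = 72)
  subs <- effortmap:::split_subjects(dat)
  # near-degenerate prior pins every MC draw at the prior mean, so the
  # integral reduces to the likelihood at that point
  make_fit <- function(sp, x_mu) {
    structure(list(spec = sp, token = model_token(sp),
                   prior = list(mean = x_mu, var = rep(1e-16, length(x_mu))),
                   data = subs, converged = TRUE, seed = 5,
                   n_choices_total = 300), class = "group_fit")
  }
  x2 <- unname(transformed_params(pars, spec_1k1b))        # K, beta
  sp_2k1b <- model_spec("parabolic", "per_recipient", "shared")
  x3 <- c(x2[1], x2[1], x2[2])
  ib2 <- integrated_bic(make_fit(spec_1k1b, x2), n_samples = 50, seed = 1)
  ib3 <- integrated_bic(make_fit(sp_2k1b, x3), n_samples = 50, seed = 1)
  expect_equal(ib3 - ib2, 2 * log(300), tolerance = 1e-6)

  # against direct likelihood arithmetic, and the N = 1 zero-penalty corner
  ll <- sum(vapply(split(dat, dat$subject), function(d)
    choice_loglik(d, pars, spec_1k1b), numeric(1)))
  expect_equal(ib2, -2 * ll + 4 * log(300), tolerance = 1e-6)
  f1 <- make_fit(spec_1k1b, x2); f1$n_choices_total <- 1
  expect_equal(integrated_bic(f1, n_samples = 50, seed = 1), -2 * ll,
               tolerance = 1e-6)
})

test_that("pseudo-R2 spans chance to near-perfect prediction", {
  sched <- std_schedule()
  # nearly deterministic, low-discounting agents: high R2
  det <- data.frame(K_self = rep(0.05, 8), K_other = 0.05,
                    beta_self = 3.9, beta_other = 3.9)
  dat_hi <- simulate_cohort_choices(
    sample_agents(sampler = "fixed", params = det, seed = 81), sched,
    seed = 82)
  fit_hi <- fit_map_em(dat_hi, spec_2k2b, seed = 83, mc_samples = 0)
  expect_gt(choice_r2(fit_hi), 0.8)
  expect_lte(choice_r2(fit_hi), 1)

  # near-random agents: R2 close to zero
  rnd <- data.frame(K_self = rep(0.5, 8), K_other = 0.5,
                    beta_self = 0.02, beta_other = 0.02)
  dat_lo <- simulate_cohort_choices(
    sample_agents(sampler = "fixed", params = rnd, seed = 84), sched,
    seed = 85)
  fit_lo <- fit_map_em(dat_lo, spec_2k2b, seed = 86, mc_samples = 0)
  expect_lt(abs(choice_r2(fit_lo)), 0.1)
})
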