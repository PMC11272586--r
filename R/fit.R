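# ---- transformed parameter space -------------------------------------------
# Fitting works in an unconstrained space; bounds are enforced by scaled
# logistic transforms K = 1.5 * logistic(x), beta = 4 * logistic(y).

par_layout <- function(spec) {
  nk <- if (spec$k_structure == "per_recipient") 2L else 1L
  nb <- if (spec$beta_structure == "per_recipient") 2L else 1L
  nm_k <- if (nk == 2) c("K_self", "K_other") else "K"
  nm_b <- if (nb == 2) c("beta_self", "beta_other") else "beta"
  list(nk = nk, nb = nb, np = nk + nb, names = c(nm_k, nm_b))
}

#' Map parameters between natural and unconstrained scales
#'
#' @param x numeric vector in the unconstrained space (K entries first,
#'   then beta entries, per the model's parameter structure).
#' @param spec a [model_spec()].
#' @return `natural_params()`: an [agent_params()] object (shared entries
#'   duplicated); `transformed_params()`: the unconstrained vector.
#' @export
natural_params <- function(x, spec) {
  lay <- par_layout(spec)
  K <- K_BOUND * plogis(x[seq_len(lay$nk)])
  b <- B_BOUND * plogis(x[lay$nk + seq_len(lay$nb)])
  agent_params(K_self = K[1], K_other = K[min(2, lay$nk)],
               beta_self = b[1], beta_other = b[min(2, lay$nb)])
}

#' @rdname natural_params
#' @param params an [agent_params()] object.
#' @export
transformed_params <- function(params, spec) {
  lay <- par_layout(spec)
  K <- c(params$K_self, params$K_other)[seq_len(lay$nk)]
  b <- c(params$beta_self, params$beta_other)[seq_len(lay$nb)]
  out <- c(qlogis(K / K_BOUND), qlogis(b / B_BOUND))
  names(out) <- lay$names
  out
}

family_code <- function(spec) match(spec$family, FAMILIES)

# Per-subject data in the compact encoding the C++ likelihood uses.
encode_subject <- function(trials) {
  trials <- trials[!is.na(trials$choice), , drop = FALSE]
  if (nrow(trials) == 0) stop("subject has no valid trials")
  list(choice = as.integer(trials$choice),
       E = as.numeric(trials$effort_level),
       R = as.numeric(trials$reward_credits),
       recip = ifelse(trials$recipient == "other", 2L, 1L))
}

split_subjects <- function(data) {
  stopifnot(all(c("subject", "recipient", "effort_level", "reward_credits",
                  "choice") %in% names(data)))
  lapply(split(data, data$subject), encode_subject)
}

subject_nll <- function(x, dat, spec, mu, sigma2, use_prior = TRUE) {
  nll_map_cpp(x, dat$choice, dat$E, dat$R, dat$recip, family_code(spec),
              spec$k_structure == "per_recipient",
              spec$beta_structure == "per_recipient",
              mu, sigma2, use_prior)
}

subject_nll_grad <- function(x, dat, spec, mu, sigma2, use_prior = TRUE) {
  nll_map_grad_cpp(x, dat$choice, dat$E, dat$R, dat$recip, family_code(spec),
                   spec$k_structure == "per_recipient",
                   spec$beta_structure == "per_recipient",
                   mu, sigma2, use_prior)
}

# One subject's MAP optimization with multistart; returns the best optimum.
map_estimate <- function(dat, spec, mu, sigma2, starts) {
  fn <- function(x) subject_nll(x, dat, spec, mu, sigma2)
  gr <- function(x) subject_nll_grad(x, dat, spec, mu, sigma2)
  best <- NULL
  for (x0 in starts) {
    opt <- tryCatch(
      optim(x0, fn, gr, method = "BFGS", control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("MAP optimization failed for a subject (non-finite likelihood?)")
  best
}

# Laplace approximation pieces at a subject's MAP optimum.
laplace_evidence <- function(opt, dat, spec, mu, sigma2) {
  fn <- function(x) subject_nll(x, dat, spec, mu, sigma2)
  gr <- function(x) subject_nll_grad(x, dat, spec, mu, sigma2)
  hess <- tryCatch(optimHess(opt$par, fn, gr), error = function(e) NULL)
  np <- length(opt$par)
  fallback <- FALSE
  var_diag <- rep(0, np)
  ch <- if (!is.null(hess)) tryCatch(chol(hess), error = function(e) NULL) else NULL
  if (is.null(ch)) {
    # Hessian not positive-definite: -BIC/2 evidence fallback
    fallback <- TRUE
    ll <- -subject_nll(opt$par, dat, spec, mu, sigma2, use_prior = FALSE)
    ev <- ll - 0.5 * np * log(length(dat$choice))
  } else {
    logdet <- 2 * sum(log(diag(ch)))
    # subject_nll drops the prior's normalizing constant; restore it here
    ev <- -opt$value - 0.5 * sum(log(sigma2)) - 0.5 * logdet
    var_diag <- diag(chol2inv(ch))
  }
  list(evidence = ev, hessian = hess, var_diag = var_diag, fallback = fallback)
}

#' Hierarchical MAP fit of a discounting model by expectation maximization
#'
#' Fits one model to a multi-subject choice dataset with an iterative
#' maximum a posteriori (MAP) scheme: the E-step finds each subject's MAP
#' parameters under a Gaussian group prior in the unconstrained space
#' (multistart BFGS), and the M-step re-estimates the prior mean and
#' variance from the MAP estimates with a Laplace (inverse-curvature)
#' correction.  Iterations stop when the summed per-subject log model
#' evidence (Laplace approximation) changes by less than `tol`.
#'
#' @param data data frame with columns `subject`, `recipient`,
#'   `effort_level`, `reward_credits`, `choice` (1 = work, 0 = rest,
#'   NA = missed; missed trials are dropped).
#' @param spec a [model_spec()].
#' @param max_iter maximum EM iterations (default 100).
#' @param tol convergence tolerance on the summed log evidence
#'   (default 1e-3).
#' @param n_starts multistart points per subject on the first E-step
#'   (prior mean plus random prior draws; default 5).  Later E-steps are
#'   warm-started from the previous optimum (plus the prior mean and one
#'   fresh draw), which preserves the optimum tracking while keeping
#'   iterations cheap.
#' @param seed integer seed for multistart draws and the Monte-Carlo
#'   integrated BIC.
#' @param prior_mean,prior_var initial group prior in the unconstrained
#'   space (defaults: mean 0, variance 4).
#' @param mc_samples Monte-Carlo draws per subject for the integrated BIC
#'   (default 2000; 0 skips the iBIC).
#' @return an object of class `group_fit`: the converged prior, per-subject
#'   fits (MAP parameters on both scales, log evidence, curvature
#'   diagnostics), the evidence trace, `ibic`, and `pseudo_r2`.
#' @export
#' @examples
#' sched <- build_schedule(seed = 1)
#' pop <- sample_agents(8, sampler = "flat", seed = 2)
#' dat <- simulate_cohort_choices(pop, sched, seed = 3)
#' fit <- fit_map_em(dat, model_spec("parabolic", "per_recipient",
#'                                   "per_recipient"),
#'                   seed = 4, mc_samples = 200)
#' fit$pseudo_r2
fit_map_em <- function(data, spec, max_iter = 100, tol = 1e-3, n_starts = 5,
                       seed = 1, prior_mean = NULL, prior_var = NULL,
                       mc_samples = 2000) {
  subjects <- split_subjects(data)
  if (length(subjects) < 2) stop("hierarchical fitting needs >= 2 subjects")
  lay <- par_layout(spec)
  np <- lay$np
  mu <- if (is.null(prior_mean)) rep(0, np) else rep_len(prior_mean, np)
  sigma2 <- if (is.null(prior_var)) rep(4, np) else rep_len(prior_var, np)

  with_local_seed(seed, function() {
    n_sub <- length(subjects)
    M <- matrix(0, n_sub, np)       # MAP estimates
    first <- TRUE
    ev_trace <- numeric(0)
    converged <- FALSE
    iter <- 0
    lap <- vector("list", n_sub)
    prev <- NULL                    # last accepted state, for revert
    while (iter < max_iter) {
      iter <- iter + 1
      total_ev <- 0
      for (s in seq_len(n_sub)) {
        # full multistart on the first E-step; afterwards the previous
        # optimum is an excellent warm start, so keep it plus the prior
        # mean and one fresh draw
        starts <- list(mu)
        if (!first) starts <- c(starts, list(M[s, ]))
        k_starts <- if (first) n_starts else min(n_starts, 3)
        while (length(starts) < k_starts)
          starts <- c(starts, list(rnorm(np, mu, sqrt(sigma2))))
        opt <- map_estimate(subjects[[s]], spec, mu, sigma2, starts)
        M[s, ] <- opt$par
        lap[[s]] <- laplace_evidence(opt, subjects[[s]], spec, mu, sigma2)
        total_ev <- total_ev + lap[[s]]$evidence
      }
      if (!first && total_ev < prev$ev + tol) {
        # converged, or the Laplace objective dipped: keep the better state
        converged <- TRUE
        if (total_ev < prev$ev) {
          M <- prev$M; lap <- prev$lap; mu <- prev$mu; sigma2 <- prev$sigma2
        } else ev_trace <- c(ev_trace, total_ev)
        break
      }
      ev_trace <- c(ev_trace, total_ev)
      prev <- list(ev = total_ev, M = M, lap = lap, mu = mu, sigma2 = sigma2)
      first <- FALSE
      # M-step: empirical Bayes update of the Gaussian prior
      V <- t(vapply(lap, `[[`, numeric(np), "var_diag"))
      mu <- colMeans(M)
      s2 <- colMeans(M^2 + V) - mu^2
      bad <- !is.finite(s2) | s2 <= 0
      if (any(bad)) s2[bad] <- apply(M, 2, var)[bad]
      sigma2 <- pmax(s2, 1e-4)
    }

    ll_map <- vapply(seq_len(n_sub), function(s)
      -subject_nll(M[s, ], subjects[[s]], spec, mu, sigma2, use_prior = FALSE),
      numeric(1))
    n_choices <- vapply(subjects, function(d) length(d$choice), numeric(1))

    fits <- lapply(seq_len(n_sub), function(s) {
      x <- M[s, ]; names(x) <- lay$names
      list(id = names(subjects)[s], x = x,
           params = natural_params(x, spec),
           loglik = ll_map[s], n_trials = n_choices[s],
           evidence = lap[[s]]$evidence, fallback = lap[[s]]$fallback,
           var_diag = lap[[s]]$var_diag)
    })
    names(fits) <- names(subjects)

    res <- structure(list(
      spec = spec, token = model_token(spec),
      prior = list(mean = mu, var = sigma2, names = lay$names),
      subjects = fits, data = subjects,
      evidence_trace = ev_trace, iterations = iter, converged = converged,
      n_choices_total = sum(n_choices),
      pseudo_r2 = 1 - sum(ll_map) / (sum(n_choices) * log(0.5)),
      seed = seed
    ), class = "group_fit")
    res$ibic <- if (mc_samples > 0)
      integrated_bic(res, n_samples = mc_samples) else NA_real_
    res
  })
}

#' @export
print.group_fit <- function(x, ...) {
  cat("<group_fit ", x$token, ": ", length(x$subjects), " subjects, ",
      x$iterations, " EM iterations",
      if (x$converged) " (converged)" else " (NOT converged)",
      ">\n  iBIC = ", format(x$ibic), ", pseudo-R2 = ",
      round(x$pseudo_r2, 3), "\n", sep = "")
  invisible(x)
}

#' Integrated BIC of a hierarchical fit
#'
#' Group-level model evidence penalized by the number of prior
#' hyperparameters:
#' \deqn{iBIC = -2 \sum_s \log \hat p(D_s | prior) + P \log N,}
#' where \eqn{\hat p} integrates each subject's likelihood over the fitted
#' group prior by Monte Carlo, P counts prior hyperparameters (a mean and a
#' variance per model parameter) and N is the total number of choices.
#'
#' Called inside [fit_map_em()] by default; re-running does not mutate the
#' fit. A warning is raised on non-converged fits.
#'
#' @param fit a `group_fit`.
#' @param n_samples Monte-Carlo draws per subject (default 2000).
#' @param seed seed for the draws; defaults to the fit's own seed + 1.
#' @return scalar iBIC (smaller is better).
#' @export
integrated_bic <- function(fit, n_samples = 2000, seed = NULL) {
  if (!fit$converged)
    warning("integrated_bic called on a non-converged fit")
  if (is.null(seed)) seed <- (fit$seed %% 21474830) + 1L
  np <- length(fit$prior$mean)
  spec <- fit$spec
  with_local_seed(seed, function() {
    tot <- 0
    for (dat in fit$data) {
      X <- matrix(rnorm(n_samples * np, rep(fit$prior$mean, each = n_samples),
                        rep(sqrt(fit$prior$var), each = n_samples)),
                  n_samples, np)
      ll <- loglik_draws_cpp(X, dat$choice, dat$E, dat$R, dat$recip,
                             family_code(spec),
                             spec$k_structure == "per_recipient",
                             spec$beta_structure == "per_recipient")
      m <- max(ll)
      tot <- tot + (m + log(mean(exp(ll - m))))
    }
    -2 * tot + 2 * np * log(fit$n_choices_total)
  })
}

#' Pseudo-R-squared of choice predictions
#'
#' Proportional reduction in log loss of the MAP predictions relative to a
#' coin-flip baseline: \eqn{1 - \sum_s LL_s / (N \log 0.5)}.  1 for perfect
#' prediction, 0 at chance.
#'
#' @param fit a `group_fit`.
#' @return scalar pseudo-R2.
#' @export
choice_r2 <- function(fit) fit$pseudo_r2

#' Per-subject parameter table from a fit
#'
#' @param fit a `group_fit`.
#' @return data frame, one row per subject: the four natural-scale
#'   parameters, log-likelihood, evidence and diagnostics.
#' @export
coef_table <- function(fit) {
  rows <- lapply(fit$subjects, function(s) {
    p <- s$params
    data.frame(subject = s$id, K_self = p$K_self, K_other = p$K_other,
               beta_self = p$beta_self, beta_other = p$beta_other,
               loglik = s$loglik, evidence = s$evidence,
               n_trials = s$n_trials, laplace_fallback = s$fallback,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a group fit to JSON
#'
#' Writes the converged prior, per-subject estimates and evidences, fit
#' metrics and provenance (model token, seed, iterations) as structured
#' text.  Requires the jsonlite package.
#'
#' @param fit a `group_fit`.
#' @param path output file.
#' @export
write_group_fit <- function(fit, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("write_group_fit requires the jsonlite package")
  out <- list(
    model = fit$token,
    prior = list(mean = fit$prior$mean, var = fit$prior$var,
                 names = fit$prior$names),
    subjects = coef_table(fit),
    ibic = fit$ibic, pseudo_r2 = fit$pseudo_r2,
    iterations = fit$iterations, converged = fit$converged,
    evidence_trace = fit$evidence_trace, seed = fit$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Per-subject log evidences from a list of fits
#'
#' Assembles the subjects-by-models evidence matrix consumed by
#' [bms_random_effects()].  Models are ordered as given; subjects must agree
#' across fits.
#'
#' @param fits named list of `group_fit` objects (same subjects).
#' @return numeric matrix, subjects x models, with dimnames.
#' @export
evidence_matrix <- function(fits) {
  ids <- names(fits[[1]]$subjects)
  out <- vapply(fits, function(f) {
    stopifnot(identical(names(f$subjects), ids))
    vapply(f$subjects, `[[`, numeric(1), "evidence")
  }, numeric(length(ids)))
  dimnames(out) <- list(ids, names(fits))
  out
}
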