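# Observable behavioural outcome measures: payoffs, trial success,
# normalized force, and the per-subject regressors used for lesion-symptom
# mapping.

#' Credits earned per recipient
#'
#' Payoff rules: rest earns the fixed 1 credit; accepted work earns the
#' offered credits only if the force criterion was met, else 0; missed
#' trials earn 0.
#'
#' @param trials data frame with `recipient`, `reward_credits`, `choice`
#'   (1 work, 0 rest, NA missed) and `success` (logical; only consulted for
#'   accepted work trials).
#' @return named numeric vector of total credits, one entry per recipient
#'   present.
#' @export
credits_earned <- function(trials) {
  stopifnot(all(c("recipient", "reward_credits", "choice") %in% names(trials)))
  success <- if ("success" %in% names(trials)) trials$success else
    rep(TRUE, nrow(trials))
  if ("success" %in% names(trials)) {
    inconsistent <- !is.na(trials$choice) & trials$choice == 0 &
      !is.na(success) & success
    if (any(inconsistent))
      stop("success flagged on trials where work was not accepted")
  }
  pay <- ifelse(is.na(trials$choice), 0,
                ifelse(trials$choice == 0, REST_CREDITS,
                       ifelse(!is.na(success) & success,
                              trials$reward_credits, 0)))
  tapply(pay, trials$recipient, sum)
}

#' Did a force trace meet the success criterion?
#'
#' A trial succeeds when the cumulative (not necessarily consecutive) time
#' at or above the required force level reaches at least one second within
#' the 3 s window.
#'
#' @param trace a [force_trace()].
#' @return logical.
#' @export
evaluate_success <- function(trace) {
  stopifnot(inherits(trace, "force_trace"))
  if (length(trace$samples) == 0) stop("empty force trace")
  time_at <- sum(trace$samples >= trace$required_level) / trace$rate
  time_at >= 1 - 1e-9
}

#' Normalized force area under the curve
#'
#' Trapezoidal integral of force (as a fraction of MVC) over the response
#' window, divided by the window duration: a dimensionless index that is 1
#' for a constant squeeze at MVC and 0 at rest.
#'
#' @param trace a [force_trace()]; samples are assumed evenly spaced across
#'   the window.
#' @return scalar in `[0, ~1.1]` for physiological traces.
#' @export
force_auc <- function(trace) {
  stopifnot(inherits(trace, "force_trace"))
  if (trace$mvc <= 0) stop("mvc must be positive")
  f <- trace$samples / trace$mvc
  n <- length(f)
  if (n == 1) return(f)
  # evenly spaced over the window: trapezoid = mean of interior + half ends
  integral <- (sum(f) - (f[1] + f[n]) / 2) * trace$duration / (n - 1)
  integral / trace$duration
}

#' Rank-then-z transform of a behavioural regressor
#'
#' Ranks the values across patients (ties averaged) to remove skew, then
#' centres and scales to mean 0, SD 1.  Invariant to any monotone transform
#' of the input.
#'
#' @param values numeric vector (>= 3 patients).
#' @return transformed vector; an all-equal input returns a zero vector
#'   with a warning and attribute `degenerate = TRUE`.
#' @export
rank_z <- function(values) {
  if (length(values) < 3) stop("rank_z needs >= 3 values")
  if (length(unique(values)) == 1) {
    warning("all regressor values equal; returning zeros")
    return(structure(rep(0, length(values)), degenerate = TRUE))
  }
  r <- rank(values, ties.method = "average")
  as.numeric(scale(r))
}

#' Per-subject regressors for lesion-symptom mapping
#'
#' Computes the four behavioural variables mapped against lesion location:
#' * `k_recipient_effect`: K_other - K_self from the fitted
#'   recipient-specific model (larger = steeper devaluation of the other
#'   person's rewards, i.e. less prosocial);
#' * `choice_recipient_effect`: acceptance(self) - acceptance(other)
#'   (larger = less prosocial);
#' * `effort_slope`, `reward_slope`: per-subject logistic-regression slopes
#'   of choice on squared effort level and on reward credits.
#'
#' Separation in the per-subject logistic regression (all-work or all-rest
#' subjects) is handled by a weakly informative ridge penalty on the
#' slopes; such fits are flagged.
#'
#' @param trials one subject's trials (`recipient`, `effort_level`,
#'   `reward_credits`, `choice`).
#' @param params the subject's fitted [agent_params()] (recipient-specific
#'   K).
#' @return one-row data frame with the four regressors and a
#'   `penalized_slopes` flag.
#' @export
subject_regressors <- function(trials, params) {
  trials <- trials[!is.na(trials$choice), , drop = FALSE]
  if (!all(c("self", "other") %in% trials$recipient))
    stop("subject needs trials for both recipients")
  acc <- tapply(trials$choice, trials$recipient, mean)
  X <- cbind(eff2 = as.numeric(scale(trials$effort_level^2)),
             rew = as.numeric(scale(trials$reward_credits)))
  y <- trials$choice
  warned <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ X, family = binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  slopes <- coef(fit)[-1]
  penalized <- warned || !fit$converged || any(!is.finite(slopes)) ||
    any(abs(slopes) > 10)
  if (penalized) slopes <- ridge_logistic(X, y, lambda = 1)
  data.frame(
    k_recipient_effect = params$K_other - params$K_self,
    choice_recipient_effect = unname(acc["self"] - acc["other"]),
    effort_slope = unname(slopes[1]),
    reward_slope = unname(slopes[2]),
    penalized_slopes = penalized
  )
}

# Newton-iterated logistic regression with an L2 penalty on the slopes
# (the intercept gets a weak penalty so separation stays well-posed);
# used when the unpenalized fit separates.
ridge_logistic <- function(X, y, lambda = 1, max_iter = 100) {
  Z <- cbind(1, X)
  b <- rep(0, ncol(Z))
  pen <- diag(c(0.01, rep(lambda, ncol(X))))
  for (i in seq_len(max_iter)) {
    p <- plogis(drop(Z %*% b))
    W <- p * (1 - p)
    g <- crossprod(Z, y - p) - pen %*% b
    H <- crossprod(Z * W, Z) + pen
    step <- solve(H, g)
    b <- b + drop(step)
    if (max(abs(step)) < 1e-8) break
  }
  b[-1]
}

#' Cohort summary of behavioural measures
#'
#' Per subject and recipient: credits earned, acceptance proportion,
#' success proportion among accepted trials, and mean force AUC (when
#' force columns are present).
#'
#' @param data cohort trial data (`subject`, `recipient`,
#'   `reward_credits`, `choice`, optional `success`, `force_auc`).
#' @return data frame, one row per subject x recipient.
#' @export
behaviour_summary <- function(data) {
  out <- do.call(rbind, lapply(split(data, list(data$subject, data$recipient),
                                     drop = TRUE), function(d) {
    ok <- !is.na(d$choice)
    data.frame(
      subject = d$subject[1], recipient = d$recipient[1],
      credits = unname(credits_earned(d)[d$recipient[1]]),
      acceptance = mean(d$choice[ok]),
      success_rate = if ("success" %in% names(d) && any(ok & d$choice == 1))
        mean(d$success[ok & d$choice == 1]) else NA_real_,
      mean_force_auc = if ("force_auc" %in% names(d))
        mean(d$force_auc, na.rm = TRUE) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$subject, out$recipient), ]
}
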