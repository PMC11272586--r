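K_BOUND <- 1.5
B_BOUND <- 4

FAMILIES <- c("linear", "hyperbolic", "parabolic")
STRUCTURES <- c("shared", "per_recipient")

#' Specify an effort-discounting model
#'
#' A model is defined by the shape of its effort cost function and by whether
#' the discount weight K and the inverse-stochasticity (choice consistency)
#' beta are shared across recipients or recipient-specific.  The three cost
#' families are
#' \deqn{V = R - K E \quad (linear),\qquad V = R / (1 + K E) \quad
#'   (hyperbolic),\qquad V = R - K E^2 \quad (parabolic),}
#' with `E` the integer effort level (2--6) and `R` the offered reward in
#' credits.
#'
#' @param family one of `"linear"`, `"hyperbolic"`, `"parabolic"`.
#' @param k_structure,beta_structure `"shared"` (one parameter across
#'   recipients) or `"per_recipient"` (separate self/other parameters).
#' @return a `discount_model` object.
#' @export
#' @examples
#' model_spec("parabolic", "per_recipient", "per_recipient")
model_spec <- function(family, k_structure = "shared", beta_structure = "shared") {
  family <- match.arg(family, FAMILIES)
  k_structure <- match.arg(k_structure, STRUCTURES)
  beta_structure <- match.arg(beta_structure, STRUCTURES)
  structure(
    list(family = family, k_structure = k_structure,
         beta_structure = beta_structure),
    class = "discount_model"
  )
}

n_params <- function(spec) {
  (if (spec$k_structure == "per_recipient") 2L else 1L) +
    (if (spec$beta_structure == "per_recipient") 2L else 1L)
}

#' @export
format.discount_model <- function(x, ...) model_token(x)

#' @export
print.discount_model <- function(x, ...) {
  cat("<discount model ", model_token(x), ": ", n_params(x), " parameters>\n",
      sep = "")
  invisible(x)
}

#' Short string token for a model
#'
#' Tokens look like `"parabolic-2k2b"`: family name, then `1`/`2` for shared
#' vs recipient-specific K and beta.
#'
#' @param spec a `discount_model`.
#' @return character token.
#' @export
model_token <- function(spec) {
  paste0(spec$family, "-",
         if (spec$k_structure == "per_recipient") "2k" else "1k",
         if (spec$beta_structure == "per_recipient") "2b" else "1b")
}

#' @rdname model_token
#' @param token a token such as `"hyperbolic-1k2b"`.
#' @export
parse_model_token <- function(token) {
  m <- regmatches(token, regexec("^(linear|hyperbolic|parabolic)-([12])k([12])b$", token))[[1]]
  if (length(m) != 4) stop("unrecognized model token: ", token)
  model_spec(m[2],
             if (m[3] == "2") "per_recipient" else "shared",
             if (m[4] == "2") "per_recipient" else "shared")
}

#' Enumerate the candidate model space
#'
#' All combinations of three cost families with shared or recipient-specific
#' K and beta: 12 models, in canonical order (family-major, then K
#' structure, then beta structure).
#'
#' @return named list of 12 `discount_model` objects; names are tokens.
#' @export
#' @examples
#' names(model_space())
model_space <- function() {
  out <- list()
  for (fam in FAMILIES)
    for (ks in STRUCTURES)
      for (bs in STRUCTURES) {
        sp <- model_spec(fam, ks, bs)
        out[[model_token(sp)]] <- sp
      }
  out
}

#' Agent parameters
#'
#' Discount weights K (bounded in (0, 1.5)) and inverse-stochasticity beta
#' (bounded in (0, 4)) for the self and other recipient conditions.  Under a
#' shared structure the corresponding self/other entries must be equal.
#'
#' @param K_self,K_other discount weights.
#' @param beta_self,beta_other choice consistency (inverse stochasticity).
#' @param spec optional `discount_model`; when given, shared structures are
#'   checked for exact self/other equality.
#' @return an `agent_params` object (named list).
#' @export
agent_params <- function(K_self, K_other = K_self, beta_self, beta_other = beta_self,
                         spec = NULL) {
  p <- list(K_self = K_self, K_other = K_other,
            beta_self = beta_self, beta_other = beta_other)
  for (k in c("K_self", "K_other")) {
    v <- p[[k]]
    if (!is.finite(v) || v <= 0 || v >= K_BOUND)
      stop(k, " must lie strictly inside (0, ", K_BOUND, ")")
  }
  for (k in c("beta_self", "beta_other")) {
    v <- p[[k]]
    if (!is.finite(v) || v <= 0 || v >= B_BOUND)
      stop(k, " must lie strictly inside (0, ", B_BOUND, ")")
  }
  if (!is.null(spec)) {
    if (spec$k_structure == "shared" && p$K_self != p$K_other)
      stop("shared K structure requires K_self == K_other")
    if (spec$beta_structure == "shared" && p$beta_self != p$beta_other)
      stop("shared beta structure requires beta_self == beta_other")
  }
  structure(p, class = "agent_params")
}

# Pick the recipient-appropriate K / beta for vectors of recipient labels.
param_for <- function(params, recipient, which = c("K", "beta")) {
  which <- match.arg(which)
  a <- params[[paste0(which, "_self")]]
  b <- params[[paste0(which, "_other")]]
  ifelse(recipient == "other", b, a)
}

#' Effort-discounted subjective value of an offer
#'
#' @param effort_level integer effort level(s) in 0..6 (0 codes rest).
#' @param reward_credits reward magnitude(s) in credits.
#' @param recipient `"self"` or `"other"` (vectorized).
#' @param params an [agent_params()] object.
#' @param spec a [model_spec()].
#' @return numeric subjective value(s), in credits.
#' @export
#' @examples
#' p <- agent_params(0.1, 0.1, 1, 1)
#' subjective_value(6, 10, "self", p, model_spec("parabolic"))
subjective_value <- function(effort_level, reward_credits, recipient, params, spec) {
  K <- param_for(params, recipient, "K")
  E <- effort_level
  R <- reward_credits
  switch(spec$family,
    linear     = R - K * E,
    hyperbolic = R / (1 + K * E),
    parabolic  = R - K * E^2
  )
}

#' Probability of choosing work over rest
#'
#' Softmax (logistic) choice rule on the value difference between the work
#' offer and the 1-credit rest option:
#' \deqn{P(work) = 1 / (1 + \exp(-\beta (V_{work} - V_{rest}))).}
#'
#' @inheritParams subjective_value
#' @param rest_credits undiscounted value of resting; default 1 credit.
#' @return probability/ies in (0, 1).
#' @export
p_work <- function(effort_level, reward_credits, recipient, params, spec,
                   rest_credits = REST_CREDITS) {
  v_work <- subjective_value(effort_level, reward_credits, recipient, params, spec)
  beta <- param_for(params, recipient, "beta")
  plogis(beta * (v_work - rest_credits))
}

#' Bernoulli log-likelihood of observed choices
#'
#' Sum over trials of the log probability of the chosen option (work or
#' rest) under the softmax rule.  Missed trials (NA choice) are dropped.
#'
#' @param trials data frame with columns `recipient`, `effort_level`,
#'   `reward_credits`, `choice` (1 = work, 0 = rest, NA = missed).
#' @inheritParams subjective_value
#' @return scalar log-likelihood (<= 0).
#' @export
choice_loglik <- function(trials, params, spec) {
  trials <- trials[!is.na(trials$choice), , drop = FALSE]
  if (nrow(trials) == 0) stop("no valid (non-missed) trials")
  p <- p_work(trials$effort_level, trials$reward_credits, trials$recipient,
              params, spec)
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(trials$choice * log(p) + (1 - trials$choice) * log(1 - p))
}
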