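# Random-effects Bayesian model selection over per-subject log evidences,
# via the variational Dirichlet scheme: subjects' model assignments and the
# population model frequencies are jointly inferred, giving estimated model
# frequencies (EF) and exceedance probabilities (XP).

# Variational updates for the Dirichlet posterior; returns alpha, the
# subject responsibilities g, and the free energy (evidence lower bound).
bms_vb <- function(lme, alpha0, tol = 1e-6, max_iter = 500) {
  n <- nrow(lme); m <- ncol(lme)
  alpha <- alpha0
  g <- matrix(1 / m, n, m)
  for (it in seq_len(max_iter)) {
    elogr <- digamma(alpha) - digamma(sum(alpha))
    u <- lme + matrix(elogr, n, m, byrow = TRUE)
    u <- u - apply(u, 1, max)
    g <- exp(u) / rowSums(exp(u))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  elogr <- digamma(alpha) - digamma(sum(alpha))
  # variational lower bound on log p(evidence matrix)
  fe <- sum(g * (lme + matrix(elogr, n, m, byrow = TRUE))) -
    sum(g[g > 0] * log(g[g > 0])) +
    lgamma(sum(alpha0)) - sum(lgamma(alpha0)) + sum((alpha0 - 1) * elogr) -
    (lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * elogr))
  list(alpha = alpha, g = g, free_energy = fe)
}

dirichlet_xp <- function(alpha, n_draws, seed) {
  m <- length(alpha)
  with_local_seed(seed, function() {
    counts <- integer(m)
    # draw in chunks to bound memory at ~8 MB per chunk
    left <- n_draws
    while (left > 0) {
      chunk <- min(left, 1e5)
      G <- matrix(rgamma(chunk * m, shape = rep(alpha, each = chunk)),
                  chunk, m)
      counts <- counts + tabulate(max.col(G, ties.method = "first"), m)
      left <- left - chunk
    }
    counts / n_draws
  })
}

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across subjects: a
#' Dirichlet prior over population model frequencies is updated
#' variationally from the per-subject log model evidences.  Returns the
#' Dirichlet posterior, estimated model frequencies (EF) and exceedance
#' probabilities (XP) — the posterior probability that each model is the
#' most frequent in the population, estimated by Monte-Carlo sampling of
#' the Dirichlet posterior.
#'
#' @param lme numeric matrix of per-subject log model evidences
#'   (subjects x models, >= 2 models).
#' @param alpha0 Dirichlet prior concentration (scalar or per model;
#'   default 1).
#' @param n_draws Monte-Carlo draws for XP (default 1e6).
#' @param seed integer seed for the draws.
#' @return a `bms_result`: `alpha`, `ef`, `xp`, responsibilities `g`,
#'   `free_energy`, `n_draws`.
#' @export
#' @examples
#' lme <- cbind(m1 = rep(0, 10), m2 = rep(-3, 10))
#' bms_random_effects(lme, seed = 1)$xp
bms_random_effects <- function(lme, alpha0 = 1, n_draws = 1e6, seed = 1) {
  lme <- as.matrix(lme)
  if (ncol(lme) < 2) stop("model selection needs >= 2 models")
  if (!all(is.finite(lme))) stop("log evidences must be finite")
  if (anyDuplicated(t(lme)))
    warning("duplicate model columns: EF/XP mass will be split among them")
  alpha0 <- rep_len(alpha0, ncol(lme))
  vb <- bms_vb(lme, alpha0)
  xp <- dirichlet_xp(vb$alpha, n_draws, seed)
  names(xp) <- colnames(lme)
  ef <- vb$alpha / sum(vb$alpha)
  names(ef) <- colnames(lme)
  structure(list(alpha = vb$alpha, ef = ef, xp = xp, g = vb$g,
                 free_energy = vb$free_energy, n_draws = n_draws),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result over", length(x$ef), "models>\n")
  print(round(rbind(EF = x$ef, XP = x$xp), 3))
  invisible(x)
}

#' Between-group Bayesian model selection
#'
#' Runs random-effects model selection within each group and compares two
#' hypotheses about the population: that all groups share one vector of
#' model frequencies (pooled Dirichlet) versus group-specific frequencies
#' (independent Dirichlets).  The comparison uses the variational free
#' energies as log evidence, with equal prior odds.
#'
#' @param lme_by_group named list of evidence matrices (subjects x models,
#'   same model columns; >= 2 subjects per group).
#' @inheritParams bms_random_effects
#' @return list with `groups` (per-group `bms_result`),
#'   `p_equal_frequencies` (posterior probability the model frequencies
#'   are shared), and the two free energies.
#' @export
between_group_bms <- function(lme_by_group, alpha0 = 1, n_draws = 1e6,
                              seed = 1) {
  if (length(lme_by_group) < 2) stop("need >= 2 groups")
  lme_by_group <- lapply(lme_by_group, as.matrix)
  m <- ncol(lme_by_group[[1]])
  for (g in lme_by_group) {
    if (ncol(g) != m) stop("groups must share the same model set")
    if (nrow(g) < 2) stop("each group needs >= 2 subjects")
  }
  groups <- lapply(seq_along(lme_by_group), function(i)
    bms_random_effects(lme_by_group[[i]], alpha0, n_draws,
                       seed = seed + i))
  names(groups) <- names(lme_by_group)
  a0 <- rep_len(alpha0, m)
  fe_split <- sum(vapply(lme_by_group,
                         function(g) bms_vb(g, a0)$free_energy, numeric(1)))
  fe_pooled <- bms_vb(do.call(rbind, lme_by_group), a0)$free_energy
  p_equal <- 1 / (1 + exp(fe_split - fe_pooled))
  list(groups = groups, p_equal_frequencies = p_equal,
       free_energy_pooled = fe_pooled, free_energy_split = fe_split)
}

#' Model-identifiability confusion matrix
#'
#' Averages exceedance probabilities over datasets simulated from each
#' generator model: entry (g, f) is the mean XP of fitted model f across
#' the datasets generated from model g.  Rows are probability vectors.
#'
#' @param xp_tables named list (one entry per generator model) of matrices
#'   or data frames holding the per-dataset XP vectors (datasets x models);
#'   model columns must match the generator names.
#' @return M x M numeric matrix (generator x fitted) of average XP.
#' @export
confusion_matrix <- function(xp_tables) {
  models <- names(xp_tables)
  if (is.null(models)) stop("xp_tables must be a named list")
  out <- matrix(NA_real_, length(models), length(models),
                dimnames = list(generator = models, fitted = models))
  for (g in models) {
    tab <- as.matrix(xp_tables[[g]])
    if (is.null(tab) || nrow(tab) == 0)
      stop("missing XP table for generator model: ", g)
    if (!all(models %in% colnames(tab)))
      stop("XP table for ", g, " lacks fitted models: ",
           paste(setdiff(models, colnames(tab)), collapse = ", "))
    out[g, ] <- colMeans(tab[, models, drop = FALSE])
  }
  out
}
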