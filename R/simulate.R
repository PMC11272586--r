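# ---- agent populations -----------------------------------------------------

clamp_open <- function(x, lo, hi) pmin(pmax(x, lo), hi)

K_EPS <- 1e-3   # clamp margin keeping noisy grid values strictly inside bounds
B_FLOOR <- 0.02 # beta floor: a hard zero makes choices pure noise

#' Sample a population of discounting agents
#'
#' Three samplers are available:
#' * `"flat"`: each distinct parameter drawn uniformly within its bounds
#'   (K in (0, 1.5), beta in (0, 4)), respecting shared structures.
#' * `"grid"`: the full crossing of `K_values` (self and other) and
#'   `beta_values` (self and other) — with the defaults, 6 x 6 x 5 x 5 = 900
#'   agents — with additive N(0, 1) x `noise_sd` jitter, clamped strictly
#'   inside the bounds (beta floored at 0.02 so likelihoods stay
#'   informative).
#' * `"fixed"`: the rows of `params` taken as-is.
#'
#' @param n number of agents (ignored for `"grid"` and `"fixed"`).
#' @param sampler `"flat"`, `"grid"` or `"fixed"`.
#' @param spec generating model (default parabolic 2K2beta); shared
#'   structures tie the self/other draws.
#' @param seed integer seed.
#' @param K_values,beta_values grid values for the `"grid"` sampler.
#' @param noise_sd jitter standard deviation for the grid sampler.
#' @param params data frame with columns `K_self`, `K_other`, `beta_self`,
#'   `beta_other` for the `"fixed"` sampler.
#' @return data frame with columns `agent`, `K_self`, `K_other`,
#'   `beta_self`, `beta_other`.
#' @export
#' @examples
#' head(sample_agents(5, sampler = "flat", seed = 1))
#' nrow(sample_agents(sampler = "grid", seed = 1))  # 900
sample_agents <- function(n = NULL, sampler = c("flat", "grid", "fixed"),
                          spec = model_spec("parabolic", "per_recipient",
                                            "per_recipient"),
                          seed = 1,
                          K_values = c(0, 0.3, 0.6, 0.9, 1.2, 1.5),
                          beta_values = c(0, 1, 2, 3, 4),
                          noise_sd = 0.05, params = NULL) {
  sampler <- match.arg(sampler)
  with_local_seed(seed, function() {
    if (sampler == "flat") {
      stopifnot(!is.null(n), n >= 1)
      K_self <- runif(n, 0, K_BOUND)
      K_other <- if (spec$k_structure == "per_recipient")
        runif(n, 0, K_BOUND) else K_self
      beta_self <- runif(n, 0, B_BOUND)
      beta_other <- if (spec$beta_structure == "per_recipient")
        runif(n, 0, B_BOUND) else beta_self
      out <- data.frame(K_self, K_other, beta_self, beta_other)
    } else if (sampler == "grid") {
      stopifnot(all(K_values >= 0 & K_values <= K_BOUND),
                all(beta_values >= 0 & beta_values <= B_BOUND))
      out <- expand.grid(K_self = K_values, K_other = K_values,
                         beta_self = beta_values, beta_other = beta_values,
                         KEEP.OUT.ATTRS = FALSE)
      m <- nrow(out)
      for (cn in c("K_self", "K_other"))
        out[[cn]] <- clamp_open(out[[cn]] + rnorm(m) * noise_sd,
                                K_EPS, K_BOUND - K_EPS)
      for (cn in c("beta_self", "beta_other"))
        out[[cn]] <- clamp_open(out[[cn]] + rnorm(m) * noise_sd,
                                B_FLOOR, B_BOUND - K_EPS)
    } else {
      stopifnot(is.data.frame(params),
                all(c("K_self", "K_other", "beta_self", "beta_other") %in%
                      names(params)))
      out <- params[, c("K_self", "K_other", "beta_self", "beta_other")]
    }
    out <- cbind(agent = sprintf("s%04d", seq_len(nrow(out))), out)
    rownames(out) <- NULL
    out
  })
}

# ---- choice simulation -----------------------------------------------------

#' Simulate one agent's choices on a schedule
#'
#' Draws one Bernoulli work/rest choice per trial at the softmax work
#' probability.  With `miss_rate > 0`, trials are independently recorded as
#' missed (`choice = NA`).
#'
#' @param params an [agent_params()] object or a one-row data frame with
#'   the four parameter columns.
#' @param schedule a [build_schedule()] result.
#' @param spec generating model (default parabolic 2K2beta).
#' @param seed integer seed.
#' @param miss_rate probability a trial is missed (default 0).
#' @return the schedule with `choice` (1 work, 0 rest, NA missed) appended.
#' @export
simulate_choices <- function(params, schedule,
                             spec = model_spec("parabolic", "per_recipient",
                                               "per_recipient"),
                             seed = 1, miss_rate = 0) {
  if (is.data.frame(params))
    params <- agent_params(params$K_self[1], params$K_other[1],
                           params$beta_self[1], params$beta_other[1])
  stopifnot(miss_rate >= 0, miss_rate < 1)
  with_local_seed(seed, function() {
    p <- p_work(schedule$effort_level, schedule$reward_credits,
                schedule$recipient, params, spec)
    out <- as.data.frame(schedule)
    out$p_work <- p
    out$choice <- rbinom(nrow(out), 1, p)
    if (miss_rate > 0)
      out$choice[runif(nrow(out)) < miss_rate] <- NA
    out
  })
}

#' Simulate a cohort of agents on a common schedule
#'
#' @param agents data frame from [sample_agents()].
#' @inheritParams simulate_choices
#' @return long data frame with a `subject` column (one block of trials per
#'   agent).
#' @export
simulate_cohort_choices <- function(agents, schedule,
                                    spec = model_spec("parabolic",
                                                      "per_recipient",
                                                      "per_recipient"),
                                    seed = 1, miss_rate = 0) {
  with_local_seed(seed, function() {
    out <- lapply(seq_len(nrow(agents)), function(i) {
      d <- simulate_choices(agents[i, ], schedule, spec,
                            seed = NULL, miss_rate = miss_rate)
      cbind(subject = agents$agent[i], d, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

# ---- force traces ----------------------------------------------------------

#' Construct a grip-force trace
#'
#' @param samples force samples in fraction-of-MVC units, spanning the 3 s
#'   response window at a fixed rate.
#' @param required_level required force threshold, fraction of MVC.
#' @param mvc the subject's maximum voluntary contraction (device units);
#'   only its positivity matters for the normalized metrics.
#' @param rate sampling rate in Hz.
#' @param duration window length in seconds (default 3).
#' @return a `force_trace` object.
#' @export
force_trace <- function(samples, required_level, mvc = 1, rate = 50,
                        duration = 3) {
  if (length(samples) == 0) stop("empty force trace")
  if (any(samples < 0)) stop("force samples must be >= 0")
  structure(list(samples = samples, required_level = required_level,
                 mvc = mvc, rate = rate, duration = duration),
            class = "force_trace")
}

#' Simulate a grip-force trace for an accepted work trial
#'
#' The exerted force is modelled as `gain x required_level` plus Gaussian
#' noise (in fraction-of-MVC units), clipped at zero, sampled at `rate` Hz
#' across the 3 s window.
#'
#' @param required_level required threshold, fraction of MVC (0.3--0.7 for
#'   effort levels 2--6).
#' @param gain multiplier on the required level (1 = just meets it on
#'   average).
#' @param noise_sd noise standard deviation, fraction of MVC.
#' @param rate sampling rate, Hz (default 50).
#' @param duration window seconds (default 3).
#' @param seed integer seed.
#' @return a [force_trace()].
#' @export
simulate_force <- function(required_level, gain = 1, noise_sd = 0.05,
                           rate = 50, duration = 3, seed = 1) {
  stopifnot(gain >= 0, noise_sd >= 0)
  with_local_seed(seed, function() {
    n <- round(rate * duration) + 1
    raw <- gain * required_level + rnorm(n, 0, noise_sd)
    force_trace(pmax(raw, 0), required_level, mvc = 1, rate = rate,
                duration = duration)
  })
}

#' Simulate force outcomes for accepted work trials
#'
#' Adds `success` and `force_auc` columns to simulated choice data by
#' drawing a grip-force trace for every accepted work trial.  Rest and
#' missed trials get `NA` in both columns.
#'
#' @param data trial data with `choice` and `effort_pct_mvc` columns (e.g.
#'   from [simulate_choices()] or [simulate_cohort_choices()]).
#' @param gain_self,gain_other force gain multipliers per recipient (1 =
#'   meets the requirement on average; below 1 emulates under-exertion).
#' @param noise_sd trace noise SD, fraction of MVC.
#' @param rate sampling rate, Hz.
#' @param seed integer seed.
#' @return `data` with `success` (logical) and `force_auc` appended.
#' @export
simulate_outcomes <- function(data, gain_self = 1, gain_other = 1,
                              noise_sd = 0.05, rate = 50, seed = 1) {
  stopifnot(all(c("choice", "effort_pct_mvc", "recipient") %in% names(data)))
  with_local_seed(seed, function() {
    n <- nrow(data)
    data$success <- NA
    data$force_auc <- NA_real_
    work <- which(!is.na(data$choice) & data$choice == 1)
    gains <- ifelse(data$recipient == "other", gain_other, gain_self)
    for (i in work) {
      tr <- simulate_force(data$effort_pct_mvc[i] / 100, gain = gains[i],
                           noise_sd = noise_sd, rate = rate, seed = NULL)
      data$success[i] <- evaluate_success(tr)
      data$force_auc[i] <- force_auc(tr)
    }
    data
  })
}

#' Read and write cohort trial data as delimited text
#'
#' @param data cohort trial data frame.
#' @param path CSV file path.
#' @export
write_cohort <- function(data, path) {
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) read.csv(path, stringsAsFactors = FALSE)

# ---- lesion cohorts --------------------------------------------------------

#' A binary lesion volume
#'
#' @param mask logical/0-1 3D array.
#' @param affine 4x4 voxel-to-world affine.
#' @param id patient identifier.
#' @return a `lesion_volume` object.
#' @export
lesion_volume <- function(mask, affine, id = NA_character_) {
  stopifnot(length(dim(mask)) == 3, all(mask %in% c(0, 1)),
            identical(dim(affine), c(4L, 4L)))
  structure(list(mask = array(as.integer(mask), dim(mask)),
                 affine = affine, id = id),
            class = "lesion_volume")
}

# Affine for a grid centred on the origin; first voxel axis is left-right.
centered_affine <- function(grid_shape, spacing) {
  aff <- diag(c(rep(spacing, 3), 1))
  aff[1:3, 4] <- -spacing * (grid_shape - 1) / 2
  aff
}

#' Simulate a lesion cohort with a planted voxel-behaviour association
#'
#' Each patient's lesion is a random ellipsoid (centre and semi-axes
#' jittered) on a common grid.  Behaviour scores are standard normal, with
#' `effect_size_d` added for patients whose lesion overlaps the planted
#' spherical region — a known ground truth for exercising the
#' lesion-symptom mapping routines.
#'
#' @param n_patients cohort size (>= 10).
#' @param grid_shape 3D grid dimensions (default 40 x 48 x 40).
#' @param spacing voxel size in mm (default 4).
#' @param planted_center,planted_radius centre (voxel coordinates, 1-based)
#'   and radius (voxels) of the planted region; default is the grid centre,
#'   radius 4.
#' @param effect_size_d behaviour shift (in SD units) for patients whose
#'   lesion touches the planted region.
#' @param axes_range semi-axis range (voxels) of the random ellipsoids.
#' @param target_fraction fraction of patients whose lesion centres cluster
#'   tightly around the planted region (emulating a target-territory
#'   subgroup, as in lesion cohorts recruited for damage to one region);
#'   the remainder are scattered widely (lesions elsewhere).
#' @param target_sd,scatter_sd centre spread (SD, voxels) of the
#'   target-territory and scattered subgroups.
#' @param center_margin margin (voxels) keeping lesion centres away from
#'   the grid edge.
#' @param seed integer seed.
#' @return list with `masks` (list of [lesion_volume()]), `behaviour`
#'   (data frame `patient`, `value`, `overlaps`), `planted` (logical 3D
#'   array), and `affine`.
#' @export
simulate_lesion_cohort <- function(n_patients = 45,
                                   grid_shape = c(40, 48, 40), spacing = 4,
                                   planted_center = NULL, planted_radius = 4,
                                   effect_size_d = 0,
                                   axes_range = c(4, 9),
                                   target_fraction = 0.4, target_sd = 2.5,
                                   scatter_sd = 10,
                                   center_margin = 8, seed = 1) {
  stopifnot(n_patients >= 10, length(grid_shape) == 3)
  if (is.null(planted_center)) planted_center <- round(grid_shape / 2)
  if (any(planted_center - planted_radius < 1) ||
      any(planted_center + planted_radius > grid_shape))
    stop("planted region extends outside the grid")
  affine <- centered_affine(grid_shape, spacing)
  coords <- as.matrix(expand.grid(x = seq_len(grid_shape[1]),
                                  y = seq_len(grid_shape[2]),
                                  z = seq_len(grid_shape[3])))
  planted_vec <- rowSums(sweep(coords, 2, planted_center)^2) <=
    planted_radius^2
  planted <- array(planted_vec, grid_shape)
  with_local_seed(seed, function() {
    masks <- vector("list", n_patients)
    overlaps <- logical(n_patients)
    is_target <- runif(n_patients) < target_fraction
    for (i in seq_len(n_patients)) {
      repeat {
        ctr <- if (is_target[i])
          rnorm(3, planted_center, target_sd)
        else rnorm(3, grid_shape / 2, scatter_sd)
        ctr <- pmin(pmax(ctr, center_margin), grid_shape - center_margin)
        ax <- runif(3, axes_range[1], axes_range[2])
        inside <- rowSums(sweep(coords, 2, ctr)^2 /
                            rep(ax^2, each = nrow(coords))) <= 1
        if (any(inside)) break
      }
      masks[[i]] <- lesion_volume(array(inside, grid_shape), affine,
                                  id = sprintf("p%03d", i))
      overlaps[i] <- any(inside & planted_vec)
    }
    behaviour <- data.frame(
      patient = vapply(masks, `[[`, character(1), "id"),
      value = rnorm(n_patients) + effect_size_d * overlaps,
      overlaps = overlaps, stringsAsFactors = FALSE)
    list(masks = masks, behaviour = behaviour, planted = planted,
         affine = affine)
  })
}

#' Read and write lesion masks as NIfTI
#'
#' @param volumes list of [lesion_volume()] objects.
#' @param dir output directory (created if needed); one file per patient,
#'   named `<id>.nii`.
#' @export
write_lesions <- function(volumes, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (v in volumes) {
    img <- RNifti::asNifti(v$mask + 0)
    img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
    RNifti::writeNifti(img, file.path(dir, paste0(v$id, ".nii")))
  }
  invisible(dir)
}

#' @rdname write_lesions
#' @param paths NIfTI file paths.
#' @export
read_lesions <- function(paths) {
  lapply(paths, function(p) {
    img <- RNifti::readNifti(p)
    lesion_volume(array(as.array(img) > 0.5, dim(img)),
                  unclass(RNifti::xform(img)),
                  id = sub("\\.nii(\\.gz)?$", "", basename(p)))
  })
}
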