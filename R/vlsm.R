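# Voxel-based lesion-symptom mapping: voxelwise two-sample tests of a
# behavioural regressor against binary lesion status, with family-wise
# error control by the permutation distribution of the map-wide maximum
# TFCE statistic.

check_cohort <- function(masks) {
  stopifnot(length(masks) >= 1)
  dims <- dim(masks[[1]]$mask)
  aff <- masks[[1]]$affine
  for (v in masks) {
    if (!identical(dim(v$mask), dims)) stop("lesion grids differ in shape")
    if (max(abs(v$affine - aff)) > 1e-6) stop("lesion affines differ")
  }
  invisible(list(dims = dims, affine = aff))
}

#' Voxel inclusion mask for a lesion cohort
#'
#' A voxel enters the analysis only if at least `min_patients` patients
#' have damage there (to any extent).
#'
#' @param masks list of [lesion_volume()] objects on a common grid.
#' @param min_patients minimum lesioned patients per voxel (default 5).
#' @return logical 3D array.
#' @export
voxel_inclusion <- function(masks, min_patients = 5) {
  geom <- check_cohort(masks)
  counts <- Reduce(`+`, lapply(masks, function(v) v$mask))
  array(counts >= min_patients, geom$dims)
}

# Which voxel axis runs left-right in world space, and is the grid centred
# on the midline so that reversing that axis is a world-space mirror?
lr_axis <- function(affine, dims) {
  xrow <- abs(affine[1, 1:3])
  a <- which.max(xrow)
  if (sum(xrow > 0.5 * max(xrow)) > 1)
    stop("left-right axis is oblique/ambiguous in the affine")
  # centre of the axis must map to world x = 0
  xc <- affine[1, a] * (dims[a] - 1) / 2 + affine[1, 4]
  if (abs(xc) > 1e-6 * max(abs(affine[1, ])))
    stop("grid is not centred on the midline; cannot mirror")
  a
}

#' Mirror lesion masks across the midline
#'
#' Replaces each mask by the union of itself and its left-right flip,
#' producing symmetric masks (used to pool power when no laterality
#' hypothesis exists).
#'
#' @param masks list of [lesion_volume()] objects; the affine must encode
#'   an unambiguous left-right axis and the grid must straddle the midline
#'   symmetrically.
#' @return list of symmetrized [lesion_volume()] objects.
#' @export
mirror_masks <- function(masks) {
  geom <- check_cohort(masks)
  a <- lr_axis(geom$affine, geom$dims)
  idx <- rep(list(quote(expr = )), 3)
  idx[[a]] <- rev(seq_len(geom$dims[a]))
  lapply(masks, function(v) {
    flipped <- do.call(`[`, c(list(v$mask), idx))
    lesion_volume((v$mask | flipped) + 0L, v$affine, v$id)
  })
}

# 26-connectivity neighbour lists (CSR, 0-based) for the included voxels.
neighbour_csr <- function(incl) {
  dims <- dim(incl)
  id <- array(0L, dims)
  lin <- which(incl)
  id[lin] <- seq_along(lin)
  co <- arrayInd(lin, dims)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  pairs_from <- integer(0); pairs_to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nid <- integer(length(lin))
    nid[ok] <- id[nb[ok, , drop = FALSE]]
    keep <- ok & nid > 0
    pairs_from <- c(pairs_from, which(keep))
    pairs_to <- c(pairs_to, nid[keep])
  }
  o <- order(pairs_from)
  pairs_from <- pairs_from[o]; pairs_to <- pairs_to[o]
  ptr <- c(0L, cumsum(tabulate(pairs_from, length(lin))))
  list(nbr = as.integer(pairs_to - 1L), ptr = as.integer(ptr),
       lin = lin, n = length(lin))
}

#' TFCE transform of a statistic map
#'
#' Threshold-free cluster enhancement with default parameters H = 2,
#' E = 0.5, 100 integration steps (step = max/100) and 26-connectivity.
#' Only the positive part of the map is enhanced; pass `-stat` for the
#' opposite tail.
#'
#' @param stat numeric 3D array (non-included voxels can be 0 or NA).
#' @param mask optional logical array restricting the support.
#' @param H,E height and extent exponents.
#' @param nsteps integration steps.
#' @return numeric 3D array of TFCE scores (0 outside the mask).
#' @export
tfce <- function(stat, mask = NULL, H = 2, E = 0.5, nsteps = 100) {
  dims <- dim(stat)
  if (is.null(mask)) mask <- array(TRUE, dims)
  csr <- neighbour_csr(mask)
  s <- stat[csr$lin]
  s[is.na(s)] <- 0
  out <- array(0, dims)
  out[csr$lin] <- tfce_cpp(s, csr$nbr, csr$ptr, H, E, as.integer(nsteps))
  out
}

# all permutations of 1..n (n small), as a list
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1))
    for (pos in seq_len(n)) out[[length(out) + 1]] <- append(sub, n, pos - 1)
  out
}

# pooled-variance two-sample t per voxel for each behaviour column.
# D: voxels x patients binary matrix; Y: patients x maps.
voxel_t <- function(D, Y, n1, n0) {
  sy <- colSums(Y); sy2 <- colSums(Y^2)
  S1 <- D %*% Y
  Q1 <- D %*% Y^2
  M1 <- S1 / n1
  M0 <- sweep(-S1, 2, sy, `+`) / n0
  SS1 <- Q1 - n1 * M1^2
  SS0 <- sweep(-Q1, 2, sy2, `+`) - n0 * M0^2
  n <- ncol(D)
  sp2 <- (SS1 + SS0) / (n - 2)
  denom <- sqrt(sp2 * (1 / n1 + 1 / n0))
  t <- (M1 - M0) / denom
  t[!is.finite(t)] <- 0
  t
}

#' Voxel-based lesion-symptom map with permutation TFCE inference
#'
#' At each included voxel, patients with damage there are compared to all
#' other patients on the behavioural regressor with a pooled-variance
#' two-sample t test.  The t map is TFCE-enhanced (both directions:
#' damage-higher and damage-lower behaviour, as two one-sided maps), and
#' family-wise corrected p values are obtained from the permutation
#' distribution of the map-wide maximum TFCE score under random
#' reshuffling of the behaviour vector.
#'
#' @param masks list of [lesion_volume()] (optionally pre-mirrored with
#'   [mirror_masks()]).
#' @param behaviour numeric vector, one value per patient in the order of
#'   `masks` (typically a [rank_z()]-transformed regressor).
#' @param n_perm number of random permutations (default 5000).
#' @param alpha significance level for the corrected maps; default
#'   0.05 / 4 = 0.0125, Bonferroni across the four behavioural regressors.
#' @param min_patients voxel inclusion threshold (default 5).
#' @param seed integer seed for the permutations.
#' @param exhaustive if `TRUE`, enumerate all `n!` permutations instead of
#'   sampling (small cohorts only); p values are then exact.
#' @param tails `"both"` (default) runs the damage-higher and damage-lower
#'   one-sided maps; `"pos"` runs only the damage-higher map (its null
#'   permutation cost halves).
#' @param tfce_h,tfce_e,nsteps TFCE parameters (defaults 2, 0.5, 100).
#' @param chunk permutations processed per block (memory control).
#' @return a `vlsm_result`: arrays `t`, `tfce_pos`, `tfce_neg`, corrected
#'   `p_pos`, `p_neg` (NA outside inclusion), logical `sig` (either
#'   direction below `alpha`), `inclusion`, null maxima, `peak` (world
#'   coordinates of the strongest significant voxel, or best voxel if none
#'   significant), and bookkeeping.
#' @export
vlsm_map <- function(masks, behaviour, n_perm = 5000, alpha = 0.0125,
                     min_patients = 5, seed = 1, exhaustive = FALSE,
                     tails = c("both", "pos"),
                     tfce_h = 2, tfce_e = 0.5, nsteps = 100, chunk = 250) {
  tails <- match.arg(tails)
  both <- tails == "both"
  geom <- check_cohort(masks)
  n <- length(masks)
  if (length(behaviour) != n)
    stop("need one behaviour value per patient")
  if (sd(behaviour) == 0)
    stop("behaviour regressor is constant")
  incl <- voxel_inclusion(masks, min_patients)
  if (!any(incl)) stop("inclusion mask is empty")
  csr <- neighbour_csr(incl)
  D <- vapply(masks, function(v) v$mask[csr$lin] + 0, numeric(csr$n))
  n1 <- rowSums(D)
  n0 <- n - n1
  usable <- n0 >= 1           # voxels lesioned in every patient carry no contrast
  tvec <- voxel_t(D, matrix(behaviour, ncol = 1), n1, n0)[, 1]
  tvec[!usable] <- 0

  tf_pos <- tfce_cpp(tvec, csr$nbr, csr$ptr, tfce_h, tfce_e,
                     as.integer(nsteps))
  tf_neg <- if (both) tfce_cpp(-tvec, csr$nbr, csr$ptr, tfce_h, tfce_e,
                               as.integer(nsteps)) else rep(0, csr$n)

  perm_cols <- if (exhaustive) {
    perms <- all_perms(n)
    vapply(perms, function(p) behaviour[p], numeric(n))
  } else NULL
  n_tot <- if (exhaustive) ncol(perm_cols) else n_perm

  max_pos <- numeric(n_tot); max_neg <- numeric(n_tot)
  with_local_seed(seed, function() {
    done <- 0
    while (done < n_tot) {
      m <- min(chunk, n_tot - done)
      Y <- if (exhaustive) perm_cols[, done + seq_len(m), drop = FALSE]
        else vapply(seq_len(m), function(i) sample(behaviour), numeric(n))
      Tm <- voxel_t(D, Y, n1, n0)
      Tm[!usable, ] <- 0
      max_pos[done + seq_len(m)] <<- tfce_max_cpp(Tm, csr$nbr, csr$ptr,
                                                  tfce_h, tfce_e,
                                                  as.integer(nsteps))
      if (both)
        max_neg[done + seq_len(m)] <<- tfce_max_cpp(-Tm, csr$nbr, csr$ptr,
                                                    tfce_h, tfce_e,
                                                    as.integer(nsteps))
      done <- done + m
    }
  })

  pval <- function(obs, null_max) {
    if (exhaustive) vapply(obs, function(o) mean(null_max >= o), numeric(1))
    else vapply(obs, function(o) (sum(null_max >= o) + 1) / (n_tot + 1),
                numeric(1))
  }
  p_pos <- pval(tf_pos, max_pos)
  p_neg <- if (both) pval(tf_neg, max_neg) else rep(NA_real_, csr$n)

  to_arr <- function(v, fill = 0) {
    a <- array(fill, geom$dims); a[csr$lin] <- v; a
  }
  sig_vec <- if (both) (p_pos < alpha) | (p_neg < alpha) else p_pos < alpha
  sig <- array(FALSE, geom$dims); sig[csr$lin] <- sig_vec

  best <- which.max(pmax(tf_pos, tf_neg))
  best_p <- if (both) min(p_pos[best], p_neg[best]) else p_pos[best]
  vox <- arrayInd(csr$lin[best], geom$dims)
  world <- drop(geom$affine %*% c(vox - 1, 1))[1:3]

  structure(list(
    t = to_arr(tvec), tfce_pos = to_arr(tf_pos), tfce_neg = to_arr(tf_neg),
    p_pos = to_arr(p_pos, NA_real_), p_neg = to_arr(p_neg, NA_real_),
    sig = sig, inclusion = incl, affine = geom$affine,
    null_max_pos = max_pos, null_max_neg = max_neg,
    n_perm = n_tot, alpha = alpha, exhaustive = exhaustive,
    n_excluded_degenerate = sum(!usable),
    peak = list(voxel = drop(vox), world = world,
                t = tvec[best], p = best_p)
  ), class = "vlsm_result")
}

#' @export
print.vlsm_result <- function(x, ...) {
  cat("<vlsm_result: ", sum(x$inclusion), " voxels tested, ",
      x$n_perm, if (x$exhaustive) " exhaustive" else " random",
      " permutations>\n  significant voxels at alpha=", x$alpha, ": ",
      sum(x$sig), "\n  peak t = ", round(x$peak$t, 2), " at world (",
      paste(round(x$peak$world, 1), collapse = ", "), "), corrected p = ",
      signif(x$peak$p, 3), "\n", sep = "")
  invisible(x)
}

#' Write VLSM output maps as NIfTI
#'
#' @param result a `vlsm_result`.
#' @param dir output directory; writes `t.nii`, `tfce_pos.nii`,
#'   `tfce_neg.nii`, `p_pos.nii`, `p_neg.nii`, `sig.nii`.
#' @export
write_vlsm <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  maps <- list(t = result$t, tfce_pos = result$tfce_pos,
               tfce_neg = result$tfce_neg, p_pos = result$p_pos,
               p_neg = result$p_neg, sig = result$sig + 0)
  for (nm in names(maps)) {
    img <- RNifti::asNifti(maps[[nm]])
    img <- RNifti::`sform<-`(img, structure(result$affine, code = 2L))
    RNifti::writeNifti(img, file.path(dir, paste0(nm, ".nii")))
  }
  invisible(dir)
}
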