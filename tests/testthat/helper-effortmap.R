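# Shared fixtures and independent oracles for the test suite.

std_schedule <- function(seed = 11) build_schedule(n_reps = 3, seed = seed)

spec_2k2b <- model_spec("parabolic", "per_recipient", "per_recipient")
spec_1k1b <- model_spec("parabolic", "shared", "shared")

# Brute-force TFCE oracle: direct threshold loop with BFS connected
# components (26-connectivity), independent of the package's union-find.
tfce_oracle <- function(stat, H = 2, E = 0.5, nsteps = 100) {
  dims <- dim(stat)
  mx <- max(stat)
  out <- array(0, dims)
  if (mx <= 0) return(out)
  dh <- mx / nsteps
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (j in seq_len(nsteps)) {
    h <- j * dh
    supra <- stat >= h
    lin <- which(supra)
    if (length(lin) == 0) next
    lab <- array(0L, dims)
    nxt <- 1L
    for (v in lin) {
      if (lab[v] != 0) next
      # BFS flood fill
      queue <- v
      lab[v] <- nxt
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        co <- arrayInd(cur, dims)
        for (r in seq_len(nrow(offs))) {
          nb <- co + offs[r, ]
          if (any(nb < 1) || any(nb > dims)) next
          if (supra[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0) {
            lab[nb[1], nb[2], nb[3]] <- nxt
            queue <- c(queue, (nb[3] - 1) * dims[1] * dims[2] +
                         (nb[2] - 1) * dims[1] + nb[1])
          }
        }
      }
      nxt <- nxt + 1L
    }
    sizes <- tabulate(lab[lin])
    out[lin] <- out[lin] + sizes[lab[lin]]^E * h^H * dh
  }
  out
}

# Pooled-variance two-sample t, computed the plain way.
t_oracle <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  sp2 <- (sum((x1 - mean(x1))^2) + sum((x0 - mean(x0))^2)) / (n1 + n0 - 2)
  (mean(x1) - mean(x0)) / sqrt(sp2 * (1 / n1 + 1 / n0))
}

# All permutations of 1..n, by direct insertion (test-side enumeration).
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  res <- list()
  for (sub in combinat_perms(n - 1))
    for (k in 0:(n - 1)) res[[length(res) + 1]] <- append(sub, n, k)
  res
}

# A tiny hand-made lesion cohort on a small centred grid.
toy_cohort <- function() {
  dims <- c(8, 8, 8)
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- -2 * (dims - 1) / 2
  blk <- function(xr, yr, zr) {
    m <- array(0L, dims); m[xr, yr, zr] <- 1L; m
  }
  list(
    lesion_volume(blk(2:5, 2:5, 2:5), aff, "a"),
    lesion_volume(blk(3:6, 3:6, 3:6), aff, "b"),
    lesion_volume(blk(2:4, 4:6, 3:5), aff, "c"),
    lesion_volume(blk(4:7, 2:4, 4:6), aff, "d")
  )
}
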