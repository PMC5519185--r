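# Shared builders and independent oracles for the test suite.

# Small full-rank harmonic network: elastic network + position tethers.
# The stiffness matrix K is assembled independently (enm_hessian + diag),
# so sampled covariances can be checked against kT * K^-1.
make_harmonic_network <- function(seed = 1L, n = 5L, tether_k = 4,
                                  spring = 6) {
  set.seed(seed)
  # well separated, stiff: thermal fluctuations stay small against the
  # pair distances, so the network is genuinely harmonic at kT = 1
  repeat {
    ref <- matrix(rnorm(3 * n, sd = 3.5), n, 3)
    if (min(dist(ref)) > 3) break
  }
  cutoff <- if (n > 3) as.numeric(quantile(dist(ref), 0.8))
            else max(dist(ref)) * 1.01
  net <- enm_term(ref, cutoff = cutoff, spring = spring)
  teth <- tether_term(seq_len(n) - 1L, ref, tether_k)
  K <- enm_hessian(net, n, ref) + diag(tether_k, 3 * n)
  list(ref = ref, terms = list(net, teth), K = K, n = n)
}

# Independent quaternion (Horn) superposition oracle: the optimal RMSD is
# sqrt((Sx + Sy - 2*lambda_max) / n) with lambda_max the largest
# eigenvalue of the 4x4 key matrix. Never calls the package's Kabsch.
quaternion_rmsd <- function(mobile, reference) {
  n <- nrow(mobile)
  xc <- scale(mobile, scale = FALSE)
  yc <- scale(reference, scale = FALSE)
  M <- t(xc) %*% yc
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  key <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(key, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(xc^2) + sum(yc^2) - 2 * lam) / n
  sqrt(max(msd, 0))
}

# Central-difference gradient check: returns max |analytic - numeric|.
gradient_check <- function(coords, terms, t_now = 0, h = 1e-5,
                           n_probe = NULL) {
  ef <- energy_forces(coords, terms, t_now)
  idx <- seq_along(coords)
  if (!is.null(n_probe)) idx <- sample(idx, n_probe)
  worst <- 0
  for (k in idx) {
    xp <- coords; xp[k] <- xp[k] + h
    xm <- coords; xm[k] <- xm[k] - h
    num <- (energy_forces(xp, terms, t_now)$energy -
              energy_forces(xm, terms, t_now)$energy) / (2 * h)
    worst <- max(worst, abs(-num - ef$forces[k]))
  }
  worst
}

# Small toy spec used where full defaults would be slower than needed.
small_toy_spec <- function(...) toy_transporter_spec(...)

# Benchmark monitor: full-site RMSD to the IF reference.
if_monitor <- function(ref, threshold = 1.5) {
  list(list(name = "rmsd_to_if", metric = "rmsd", selection = NULL,
            reference = ref$if_state$coords, comparator = "<",
            threshold = threshold))
}

# Windowed mean-structure RMSD over consecutive frame blocks: the same
# basin-residence measure the LRPF cycle monitor uses (mean structure of
# an unbiased segment), applied to a plain trajectory.
windowed_mean_rmsd <- function(traj, reference, window) {
  nw <- n_frames(traj) %/% window
  vapply(seq_len(nw), function(w) {
    m <- apply(traj$coords[((w - 1) * window + 1):(w * window), , ,
                           drop = FALSE], c(2, 3), mean)
    kabsch_superpose(m, reference)$rmsd
  }, numeric(1))
}

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
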