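#' Elastic-network force term
#'
#' Pairwise harmonic potential anchored at a reference structure: every
#' site pair within `cutoff` in the reference gets a spring of stiffness
#' `spring` at its reference distance.
#'
#' @param ref N x 3 reference coordinates.
#' @param cutoff pair cutoff distance.
#' @param spring spring constant (energy / length^2).
#' @param indices optional 0-based subset of sites the network spans
#'   (default: all rows of `ref`).
#' @return a `force_term` of type `enm`.
#' @export
enm_term <- function(ref, cutoff, spring, indices = NULL) {
  ref <- as.matrix(ref)
  if (is.null(indices)) indices <- seq_len(nrow(ref)) - 1L
  sub <- ref[indices + 1L, , drop = FALSE]
  d <- as.matrix(stats::dist(sub))
  pair <- which(upper.tri(d) & d < cutoff & d > 1e-9, arr.ind = TRUE)
  if (!nrow(pair)) stop("elastic network has no pairs within cutoff")
  structure(list(type = "enm",
                 i = indices[pair[, 1]], j = indices[pair[, 2]],
                 r0 = d[pair], k = rep(spring, nrow(pair))),
            class = "force_term")
}

#' Double-basin force term
#'
#' Smooth log-sum-exp mixing of two single-basin terms:
#' `E = -log(exp(-b (V_A + dV)) + exp(-b V_B)) / b` with mixing inverse
#' temperature `b = beta_mix` and basin offset `dV`. Large `beta_mix`
#' approaches the pointwise minimum of the two basins.
#'
#' @param basin_a,basin_b `enm` force terms anchoring the two states.
#' @param beta_mix mixing parameter (> 0, units 1/energy).
#' @param dv offset added to basin A's energy.
#' @return a `force_term` of type `double_basin`.
#' @export
double_basin_term <- function(basin_a, basin_b, beta_mix = 1.0, dv = 0.0) {
  if (beta_mix <= 0) stop("beta_mix must be positive")
  structure(list(type = "double_basin", basin_a = unclass(basin_a),
                 basin_b = unclass(basin_b), beta_mix = beta_mix, dv = dv),
            class = "force_term")
}

#' Constant external bias force term
#' @param forces N x 3 matrix of per-site forces (or a `bias_field`).
#' @return a `force_term` of type `bias`.
#' @export
bias_term <- function(forces) {
  if (inherits(forces, "bias_field")) forces <- forces$forces
  structure(list(type = "bias", forces = as.matrix(forces)),
            class = "force_term")
}

#' Harmonic pair restraints
#' @param i,j 0-based site index vectors.
#' @param k spring constants (recycled).
#' @param r0 rest lengths (recycled).
#' @return a `force_term` of type `pair_restraints`.
#' @export
pair_restraint_term <- function(i, j, k, r0) {
  n <- max(length(i), length(j))
  structure(list(type = "pair_restraints", i = as.integer(i),
                 j = as.integer(j), k = rep_len(k, n),
                 r0 = rep_len(r0, n)),
            class = "force_term")
}

#' Harmonic position tether
#' @param idx 0-based site indices.
#' @param ref length(idx) x 3 anchor coordinates.
#' @param k spring constant.
#' @return a `force_term` of type `tether`.
#' @export
tether_term <- function(idx, ref, k) {
  structure(list(type = "tether", idx = as.integer(idx),
                 ref = as.matrix(ref), k = k),
            class = "force_term")
}

#' Moving (steered) harmonic restraint on a scalar coordinate
#'
#' The restraint center moves as `center0 + velocity * t`. The coordinate
#' is either the distance between the centroids of two site groups
#' (`"pair_distance"`) or the projection of one group's centroid on an
#' axis (`"projection"`).
#'
#' @param coordinate `"pair_distance"` or `"projection"`.
#' @param group1 0-based site indices of the pulled group.
#' @param group2 0-based indices of the anchor group (pair_distance only).
#' @param axis projection axis (projection only; normalized internally).
#' @param k_pull restraint stiffness (> 0).
#' @param center0 initial center of the restraint.
#' @param velocity pulling velocity (length / time).
#' @return a `force_term` of type `steered`.
#' @export
steered_term <- function(coordinate = c("pair_distance", "projection"),
                         group1, group2 = NULL, axis = c(0, 0, 1),
                         k_pull, center0, velocity) {
  coordinate <- match.arg(coordinate)
  if (k_pull <= 0) stop("k_pull must be positive")
  if (coordinate == "pair_distance" && is.null(group2))
    stop("pair_distance coordinate needs group2")
  structure(list(type = "steered", coordinate = coordinate,
                 group1 = as.integer(group1),
                 group2 = as.integer(if (is.null(group2)) integer(0)
                                     else group2),
                 axis = as.numeric(axis), k_pull = k_pull,
                 center0 = center0, velocity = velocity),
            class = "force_term")
}

#' Targeted (RMSD) restraint term
#'
#' `V = k_t / 2 * (RMSD(x, target) - rmsd0)^2` with the RMSD taken after
#' optimal superposition; forces follow by the chain rule through the
#' Kabsch fit.
#'
#' @param idx 0-based indices of the restrained sites (>= 3).
#' @param target length(idx) x 3 target coordinates.
#' @param k_t restraint stiffness.
#' @param rmsd0 target RMSD offset (0 drives all the way to the target).
#' @return a `force_term` of type `targeted`.
#' @export
targeted_term <- function(idx, target, k_t, rmsd0 = 0) {
  if (length(idx) < 3L)
    stop("underdetermined-superposition error: targeted restraint needs ",
         ">= 3 sites")
  structure(list(type = "targeted", idx = as.integer(idx),
                 target = as.matrix(target), k_t = k_t, rmsd0 = rmsd0),
            class = "force_term")
}

#' Soft repulsion between tracers and protein beads
#'
#' Purely repulsive truncated quartic core,
#' `E = eps (1 - (r / sigma)^2)^2` at distances below `sigma`, zero
#' beyond; smooth at
#' the cutoff. `sigma` is per protein site so gate beads can carry a wider
#' exclusion core than ordinary beads. Tracer-tracer pairs use
#' `sigma_tt` / `eps_tt`.
#'
#' @param tracer_idx 0-based tracer site indices.
#' @param protein_idx 0-based protein site indices.
#' @param sigma_protein per-protein-site core diameters (recycled).
#' @param eps repulsion strength at full overlap (energy units).
#' @param sigma_tt tracer-tracer core diameter.
#' @param eps_tt tracer-tracer repulsion strength.
#' @return a `force_term` of type `soft_repulsion`.
#' @export
soft_repulsion_term <- function(tracer_idx, protein_idx, sigma_protein,
                                eps = 40, sigma_tt = 1.5, eps_tt = 40) {
  structure(list(type = "soft_repulsion",
                 tracer_idx = as.integer(tracer_idx),
                 protein_idx = as.integer(protein_idx),
                 sigma_protein = rep_len(as.numeric(sigma_protein),
                                         length(protein_idx)),
                 eps = eps, sigma_tt = sigma_tt, eps_tt = eps_tt),
            class = "force_term")
}

#' Flat-bottom cylindrical confinement
#'
#' Harmonic wall beyond `radius` from the z axis and outside
#' `[zlo, zhi]`; zero inside. Used to keep tracer particles near the
#' protein.
#'
#' @param idx 0-based confined site indices.
#' @param radius cylinder radius.
#' @param zlo,zhi axial bounds.
#' @param k wall stiffness.
#' @return a `force_term` of type `cylinder_wall`.
#' @export
cylinder_wall_term <- function(idx, radius, zlo, zhi, k = 10) {
  structure(list(type = "cylinder_wall", idx = as.integer(idx),
                 radius = radius, zlo = zlo, zhi = zhi, k = k),
            class = "force_term")
}

#' Langevin dynamics parameters
#'
#' @param temperature temperature in kT units (>= 0).
#' @param friction Langevin friction (1/time); `dt * friction < 0.5`.
#' @param dt integration time step.
#' @param n_steps number of steps.
#' @param seed integer RNG seed (same seed, same trajectory).
#' @param save_stride save a frame every this many steps (>= 1).
#' @return a `langevin_params` object.
#' @export
langevin_params <- function(temperature = 1.0, friction = 1.0, dt = 0.005,
                            n_steps = 1000L, seed = 1L, save_stride = 10L) {
  if (temperature < 0) stop("temperature must be >= 0")
  if (friction <= 0 || dt <= 0) stop("friction and dt must be positive")
  if (dt * friction >= 0.5)
    stop("stability: dt * friction must be < 0.5")
  if (save_stride < 1) stop("save_stride must be >= 1")
  structure(list(temperature = temperature, friction = friction, dt = dt,
                 n_steps = as.integer(n_steps), seed = as.integer(seed),
                 save_stride = as.integer(save_stride)),
            class = "langevin_params")
}

.unclass_terms <- function(force_terms) {
  if (inherits(force_terms, "force_term")) force_terms <- list(force_terms)
  lapply(force_terms, unclass)
}

#' Total energy and forces of a force-term set
#'
#' Forces are the exact negative analytic gradient of the energy (checked
#' against finite differences in the test suite for every term type).
#'
#' @param coords N x 3 coordinates.
#' @param force_terms a `force_term` or list of them.
#' @param t_now time (moves steered restraint centers).
#' @return list with `energy` (scalar) and `forces` (N x 3).
#' @export
energy_forces <- function(coords, force_terms, t_now = 0) {
  .cpp_energy_forces(as.matrix(coords), .unclass_terms(force_terms), t_now)
}

#' Double-basin mixed energy (closed form)
#'
#' @param va,vb basin energies (basin A's offset `dv` is added to `va`).
#' @param beta_mix mixing parameter (> 0).
#' @param dv basin offset.
#' @return mixed energy, computed with a log-sum-exp guard.
#' @export
double_basin_energy <- function(va, vb, beta_mix, dv = 0) {
  if (beta_mix <= 0) stop("beta_mix must be positive")
  a <- va + dv
  m <- pmin(a, vb)
  m - log(exp(-beta_mix * (a - m)) + exp(-beta_mix * (vb - m))) / beta_mix
}

#' Run Langevin dynamics (BAOAB discretization)
#'
#' @param coords0 initial N x 3 coordinates.
#' @param force_terms list of `force_term`s.
#' @param params a `langevin_params`.
#' @param topology optional `site_model` attached to the returned
#'   trajectory (masses are taken from it when present).
#' @return a `trajectory`; attributes `potential`, `kinetic`, `work`,
#'   `final_coords`, `final_velocities`.
#' @export
run_langevin <- function(coords0, force_terms, params, topology = NULL) {
  coords0 <- as.matrix(coords0)
  mass <- if (!is.null(topology)) topology$mass else rep(1, nrow(coords0))
  res <- .cpp_run_langevin(coords0, .unclass_terms(force_terms),
                           params$temperature, params$friction, params$dt,
                           params$n_steps, params$save_stride, params$seed,
                           mass)
  arr <- aperm(res$coords, c(3, 1, 2))  # frames x N x 3
  tr <- trajectory(topology, arr, times = res$times)
  attr(tr, "potential") <- res$potential
  attr(tr, "kinetic") <- res$kinetic
  attr(tr, "work") <- res$work
  attr(tr, "final_coords") <- res$final_coords
  attr(tr, "final_velocities") <- res$final_velocities
  tr
}

#' Steered-MD segment with work accumulation
#'
#' Adds a moving harmonic restraint to the force terms and integrates;
#' the external work `W = sum k (x0(t) - x) v dt` is accumulated per step
#' and reported at each saved frame.
#'
#' @param coords0 initial coordinates.
#' @param force_terms static force terms (the steered term is added).
#' @param steered a `steered` force term (see [steered_term()]).
#' @param params a `langevin_params`.
#' @param topology optional `site_model`.
#' @return a `trajectory` whose `work` attribute holds the cumulative
#'   work series.
#' @export
steered_segment <- function(coords0, force_terms, steered, params,
                            topology = NULL) {
  if (!identical(steered$type, "steered"))
    stop("'steered' must be a steered force term")
  run_langevin(coords0, c(.as_term_list(force_terms), list(steered)),
               params, topology)
}

.as_term_list <- function(force_terms) {
  if (inherits(force_terms, "force_term")) list(force_terms)
  else force_terms
}

#' Targeted-restraint energy and forces
#'
#' Convenience wrapper evaluating `V = k_t/2 (RMSD(x, target) - rmsd0)^2`
#' and its analytic forces at one configuration.
#'
#' @param coords N x 3 coordinates.
#' @param target N x 3 target coordinates.
#' @param k_t restraint stiffness.
#' @param rmsd0 RMSD offset.
#' @return list with `energy` and `forces`.
#' @export
targeted_restraint_force <- function(coords, target, k_t, rmsd0 = 0) {
  coords <- as.matrix(coords)
  term <- targeted_term(seq_len(nrow(coords)) - 1L, target, k_t, rmsd0)
  energy_forces(coords, term)
}

#' Analytic Hessian of an elastic-network term
#'
#' The 3N x 3N second-derivative matrix at the term's reference structure
#' (where off-diagonal blocks are `-k e e^T` over the pair unit vectors).
#' Useful as an independent linear-algebra route to the stationary
#' covariance `kT H^-1`.
#'
#' @param term an `enm` force term (optionally plus tether terms via
#'   `extra_tether_k` on the same sites).
#' @param n_sites total number of sites (3N rows).
#' @param ref the reference coordinates the pair geometry is taken from.
#' @return 3N x 3N symmetric matrix, coordinate order x1 y1 z1 x2 ...
#' @export
enm_hessian <- function(term, n_sites, ref) {
  ref <- as.matrix(ref)
  H <- matrix(0, 3 * n_sites, 3 * n_sites)
  for (p in seq_along(term$i)) {
    i <- term$i[p] + 1L; j <- term$j[p] + 1L
    e <- ref[i, ] - ref[j, ]
    e <- e / sqrt(sum(e^2))
    blk <- term$k[p] * (e %o% e)
    ii <- (3 * (i - 1) + 1):(3 * i)
    jj <- (3 * (j - 1) + 1):(3 * j)
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
  }
  H
}
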