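#' Specification of the two-state toy transporter
#'
#' A pseudo three-fold-symmetric bundle of six straight bead helices on a
#' ring about z (the membrane normal). Each domain contributes one
#' "even" helix whose cytoplasmic (top) end carries the cytoplasmic gate
#' and one "odd" helix whose matrix (bottom) end carries the matrix gate
#' and the acidic motif sites. The outward-facing (OF) state has the
#' cytoplasmic gate open and the matrix gate closed; the inward-facing
#' (IF) state is the reverse. Default cytoplasmic gate radii (13 and 9
#' model units) follow the channel gyration-radius change reported for
#' the carrier's closure; matrix radii (6 and 10) mirror the opposite
#' gate swinging open.
#'
#' @param n_domains number of domains (default 3).
#' @param sites_per_helix beads per helix (default 8).
#' @param helices_per_domain helices per domain (default 2).
#' @param gate_radius_cyt_OF,gate_radius_cyt_IF cytoplasmic gate ring
#'   radii in the two states (OF > IF).
#' @param gate_radius_mat_OF,gate_radius_mat_IF matrix gate ring radii
#'   (IF > OF).
#' @param r_mid ring radius of the non-gate helix ends.
#' @param helix_length axial extent of a helix (bead spacing follows).
#' @param barrier_height target OF-IF barrier in kT along the linear
#'   interpolation path (default 12).
#' @param temperature temperature in kT units.
#' @param enm_cutoff elastic-network pair cutoff.
#' @param enm_spring elastic-network spring constant before barrier
#'   calibration rescales it.
#' @param beta_mix double-basin mixing parameter.
#' @param n_tracers number of tracer particles [add_tracers()] will add.
#' @param min_separation smallest allowed bead-bead distance in either
#'   reference state.
#' @param seed integer seed for tracer placement.
#' @return a `toy_transporter_spec`.
#' @export
toy_transporter_spec <- function(n_domains = 3L, sites_per_helix = 8L,
                                 helices_per_domain = 2L,
                                 gate_radius_cyt_OF = 13,
                                 gate_radius_cyt_IF = 9,
                                 gate_radius_mat_OF = 6,
                                 gate_radius_mat_IF = 10,
                                 r_mid = 8, helix_length = 16,
                                 barrier_height = 12, temperature = 1,
                                 enm_cutoff = 14, enm_spring = 3,
                                 beta_mix = 0.5, n_tracers = 60L,
                                 min_separation = 1.0, seed = 1L) {
  if (gate_radius_cyt_OF <= gate_radius_cyt_IF)
    stop("cytoplasmic gate must be wider in OF than IF")
  if (gate_radius_mat_IF <= gate_radius_mat_OF)
    stop("matrix gate must be wider in IF than OF")
  radii <- c(gate_radius_cyt_OF, gate_radius_cyt_IF, gate_radius_mat_OF,
             gate_radius_mat_IF)
  if (any(radii <= 0)) stop("gate radii must be positive")
  if (barrier_height <= 0) stop("barrier_height must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(n_domains = as.integer(n_domains),
                 sites_per_helix = as.integer(sites_per_helix),
                 helices_per_domain = as.integer(helices_per_domain),
                 gate_radius_cyt_OF = gate_radius_cyt_OF,
                 gate_radius_cyt_IF = gate_radius_cyt_IF,
                 gate_radius_mat_OF = gate_radius_mat_OF,
                 gate_radius_mat_IF = gate_radius_mat_IF,
                 r_mid = r_mid, helix_length = helix_length,
                 barrier_height = barrier_height,
                 temperature = temperature, enm_cutoff = enm_cutoff,
                 enm_spring = enm_spring, beta_mix = beta_mix,
                 n_tracers = as.integer(n_tracers),
                 min_separation = min_separation, seed = as.integer(seed)),
            class = "toy_transporter_spec")
}

.toy_state_coords <- function(spec, state = c("of", "if")) {
  state <- match.arg(state)
  nh <- spec$n_domains * spec$helices_per_domain
  s <- spec$sites_per_helix
  L <- spec$helix_length
  r_cyt <- if (state == "of") spec$gate_radius_cyt_OF else
    spec$gate_radius_cyt_IF
  r_mat <- if (state == "of") spec$gate_radius_mat_OF else
    spec$gate_radius_mat_IF
  coords <- matrix(0, nh * s, 3)
  for (h in seq_len(nh) - 1L) {
    phi <- 2 * pi * h / nh
    even <- (h %% spec$helices_per_domain) == 0L
    r_bot <- if (even) spec$r_mid else r_mat
    r_top <- if (even) r_cyt else spec$r_mid
    # rigid rod: constant length, so the states are related by a pivot
    dz <- sqrt(L^2 - (r_top - r_bot)^2)
    frac <- (seq_len(s) - 1) / (s - 1)
    r <- r_bot + (r_top - r_bot) * frac
    z <- -dz / 2 + dz * frac
    rows <- h * s + seq_len(s)
    coords[rows, 1] <- r * cos(phi)
    coords[rows, 2] <- r * sin(phi)
    coords[rows, 3] <- z
  }
  coords
}

.toy_topology <- function(spec) {
  nh <- spec$n_domains * spec$helices_per_domain
  s <- spec$sites_per_helix
  roman <- as.character(utils::as.roman(seq_len(spec$n_domains)))
  name <- character(nh * s)
  domain <- character(nh * s)
  helix <- character(nh * s)
  tags <- rep(list(character(0)), nh * s)
  for (h in seq_len(nh) - 1L) {
    dom <- h %/% spec$helices_per_domain
    even <- (h %% spec$helices_per_domain) == 0L
    rows <- h * s + seq_len(s)
    name[rows] <- sprintf("B%d", seq_len(s))
    domain[rows] <- roman[dom + 1L]
    helix[rows] <- sprintf("TM%d", h + 1L)
    if (even) {
      tags[[rows[s]]] <- c("gate_cyt", "basic")
      tags[[rows[s - 1L]]] <- "hydrophobic"
    } else {
      tags[[rows[1L]]] <- c("gate_mat", "acidic")
    }
  }
  site_model(name = name, domain = domain, helix = helix, tags = tags)
}

#' Build the OF/IF reference pair of the toy transporter
#'
#' Constructs the two reference geometries and the shared topology. Both
#' states are exactly three-fold symmetric: rotating either by 120 deg
#' about z reproduces the structure up to a cyclic relabeling of the
#' domains.
#'
#' @param spec a `toy_transporter_spec`.
#' @return a `reference_pair`: `of_state` and `if_state` (`frame`s) plus
#'   `topology` (`site_model`) and the generating `spec`.
#' @export
build_reference_states <- function(spec) {
  of <- .toy_state_coords(spec, "of")
  ifc <- .toy_state_coords(spec, "if")
  for (st in list(of = of, `if` = ifc)) {
    dmin <- min(stats::dist(st))
    if (dmin < spec$min_separation)
      stop("geometry error: reference beads closer than min_separation (",
           signif(dmin, 3), " < ", spec$min_separation, ")")
  }
  topo <- .toy_topology(spec)
  structure(list(of_state = frame(of), if_state = frame(ifc),
                 topology = topo, spec = spec),
            class = "reference_pair")
}

#' @export
print.reference_pair <- function(x, ...) {
  r <- kabsch_superpose(x$of_state$coords, x$if_state$coords)$rmsd
  cat(sprintf("reference_pair: %d sites, RMSD(OF, IF) = %.3f model units\n",
              n_sites(x$topology), r))
  invisible(x)
}

#' Site permutation realized by a 120-degree rotation
#'
#' For the three-fold-symmetric toy, rotating the structure by
#' `2 pi / n_domains` about z maps each helix onto the corresponding
#' helix of the next domain. Returns the 1-based site permutation `p`
#' such that `rotate(coords) == coords[p, ]` up to domain relabeling.
#'
#' @param spec a `toy_transporter_spec`.
#' @return integer permutation vector of length `n_sites`.
#' @export
threefold_permutation <- function(spec) {
  nh <- spec$n_domains * spec$helices_per_domain
  s <- spec$sites_per_helix
  p <- integer(nh * s)
  for (h in seq_len(nh) - 1L) {
    h2 <- (h + spec$helices_per_domain) %% nh
    p[h * s + seq_len(s)] <- h2 * s + seq_len(s)
  }
  p
}

#' Rotation matrix about z
#' @param angle rotation angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_z <- function(angle) {
  c <- cos(angle); s <- sin(angle)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

.split_pair_masks <- function(of, ifc, cutoff, invariant_tol) {
  dof <- as.matrix(stats::dist(of))
  dif <- as.matrix(stats::dist(ifc))
  ut <- upper.tri(dof)
  # invariant pairs are taken at any range: a distance the transition does
  # not change is a constraint of the fold wherever it sits, and the
  # long-range ones (cytoplasmic-gate bead to the diametrically opposite
  # matrix-gate bead) carry the concerted seesaw coupling of alternating
  # access
  inv <- ut & abs(dof - dif) < invariant_tol
  chg <- ut & (dof < cutoff | dif < cutoff) & !inv & dof > 1e-9
  list(invariant = inv, changing = chg, d_of = dof, d_if = dif)
}

.enm_from_mask <- function(mask, r0mat, k) {
  pr <- which(mask, arr.ind = TRUE)
  if (!nrow(pr)) stop("elastic network has no pairs within cutoff")
  structure(list(type = "enm", i = pr[, 1] - 1L, j = pr[, 2] - 1L,
                 r0 = r0mat[pr], k = rep(k, nrow(pr))),
            class = "force_term")
}

# deterministic gradient-descent quench to the nearest local minimum
.quench <- function(x0, terms, step = 0.02, n_iter = 4000L) {
  x <- x0
  for (it in seq_len(n_iter)) {
    f <- energy_forces(x, terms)$forces
    x <- x + step * f
    if (max(abs(f)) < 1e-8) break
  }
  x
}

# harmonic (energy + entropy) free energy of the basin at a minimum:
# E_min + kT/2 * log det' H, internal modes only
.basin_free_energy <- function(xmin, terms, temperature) {
  n <- nrow(xmin)
  h <- 1e-5
  H <- matrix(0, 3 * n, 3 * n)
  for (k in seq_len(3 * n)) {
    i <- (k - 1) %/% 3 + 1; d <- (k - 1) %% 3 + 1
    xp <- xmin; xp[i, d] <- xp[i, d] + h
    xm <- xmin; xm[i, d] <- xm[i, d] - h
    H[, k] <- as.vector(t(-energy_forces(xp, terms)$forces +
                            energy_forces(xm, terms)$forces)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  energy_forces(xmin, terms)$energy +
    0.5 * temperature * sum(log(ev[ev > 1e-6]))
}

#' Calibrate the double-basin potential of the toy transporter
#'
#' Splits all site pairs into a state-invariant scaffold — pairs whose
#' OF and IF distances differ by less than `invariant_tol`, held by a
#' single stiff elastic network anchored at the mean distance — and
#' state-changing pairs within `enm_cutoff`, which enter a
#' [double_basin_term()] with one network anchored at each reference.
#' Two quantities are then calibrated jointly: the changing-pair spring
#' constant is rescaled by bisection until the energy barrier along the
#' 101-point linear OF-IF interpolation path equals
#' `barrier_height * temperature`, and the basin offset `dV` is iterated
#' until the two basins' harmonic free energies (minimum energy plus the
#' entropic log-determinant of the Hessian) agree, so neither state is
#' systematically shallower than the other. The scaffold keeps the fold
#' rigid independently of how soft the calibrated transition springs
#' come out, so basin fluctuations stay small while the barrier stays at
#' its target.
#'
#' @param ref a `reference_pair`.
#' @param spec a `toy_transporter_spec` (defaults to `ref$spec`).
#' @param dv starting basin offset added to the OF basin; refined by the
#'   free-energy balancing unless `balance_basins = FALSE`.
#' @param invariant_tol distance-change threshold separating scaffold
#'   from transition pairs (model units).
#' @param tol relative tolerance of the barrier calibration.
#' @param balance_basins equalize the basins' harmonic free energies by
#'   adjusting `dV` (default `TRUE`).
#' @return a `double_basin_spec`: `term` (the calibrated double-basin
#'   `force_term`), `scaffold` (the invariant-pair `force_term`),
#'   `terms` (both, ready for the engine), `spring_scale`, `barrier`
#'   (achieved, kT), `profile` (data.frame of `lambda`, `energy`),
#'   `beta_mix`, `dv`, `basin_free_energy_gap` (residual, kT).
#' @export
build_double_basin_spec <- function(ref, spec = ref$spec, dv = 0,
                                    invariant_tol = 0.5, tol = 0.01,
                                    balance_basins = TRUE) {
  of <- ref$of_state$coords
  ifc <- ref$if_state$coords
  pm <- .split_pair_masks(of, ifc, spec$enm_cutoff, invariant_tol)
  scaffold <- .enm_from_mask(pm$invariant, (pm$d_of + pm$d_if) / 2,
                             spec$enm_spring)
  lambdas <- seq(0, 1, length.out = 101)
  path <- lapply(lambdas, function(l) (1 - l) * of + l * ifc)
  mk <- function(scale, dv_now) {
    a <- .enm_from_mask(pm$changing, pm$d_of, spec$enm_spring * scale)
    b <- .enm_from_mask(pm$changing, pm$d_if, spec$enm_spring * scale)
    double_basin_term(a, b, beta_mix = spec$beta_mix, dv = dv_now)
  }
  target <- spec$barrier_height * spec$temperature
  calibrate_scale <- function(dv_now) {
    barrier_of <- function(scale) {
      terms <- list(mk(scale, dv_now), scaffold)
      e <- vapply(path, function(x) energy_forces(x, terms)$energy,
                  numeric(1))
      max(e) - e[1]
    }
    lo <- 1e-5; hi <- 1e3
    b_lo <- barrier_of(lo); b_hi <- barrier_of(hi)
    if (!(b_lo < target && b_hi > target))
      stop("calibration error: cannot bracket target barrier ", target,
           " kT (barrier at scale ", lo, " is ", signif(b_lo, 4),
           ", at scale ", hi, " is ", signif(b_hi, 4), ")")
    mid <- sqrt(lo * hi)
    for (it in 1:100) {
      mid <- sqrt(lo * hi)
      b_mid <- barrier_of(mid)
      if (abs(b_mid - target) < tol * target) break
      if (b_mid < target) lo <- mid else hi <- mid
    }
    mid
  }
  scale <- calibrate_scale(dv)
  gap <- NA_real_
  if (balance_basins) {
    for (round in 1:4) {
      terms <- list(mk(scale, dv), scaffold)
      f_of <- .basin_free_energy(.quench(of, terms), terms,
                                 spec$temperature)
      f_if <- .basin_free_energy(.quench(ifc, terms), terms,
                                 spec$temperature)
      gap <- f_if - f_of
      if (abs(gap) < 0.25 * spec$temperature) break
      dv <- dv + gap   # raising the OF basin by the gap closes it
      scale <- calibrate_scale(dv)
    }
  }
  term <- mk(scale, dv)
  prof <- vapply(path, function(x)
    energy_forces(x, list(term, scaffold))$energy, numeric(1))
  structure(list(term = term, scaffold = scaffold,
                 terms = list(term, scaffold), spring_scale = scale,
                 barrier = max(prof) - prof[1],
                 profile = data.frame(lambda = lambdas, energy = prof),
                 beta_mix = spec$beta_mix, dv = dv,
                 basin_free_energy_gap = gap),
            class = "double_basin_spec")
}

#' @export
print.double_basin_spec <- function(x, ...) {
  cat(sprintf(
    "double_basin_spec: spring scale %.4g, barrier %.3f kT at lambda %.2f\n",
    x$spring_scale, x$barrier,
    x$profile$lambda[which.max(x$profile$energy)]))
  invisible(x)
}

#' Per-site repulsion core diameters for the toy
#'
#' Ordinary beads get a small excluded-volume core; gate beads carry wide
#' cores so that a gate ring narrower than its core diameter occludes the
#' channel to tracers while a wider ring lets them through. The bead just
#' above each matrix gate bead carries a medium core that seals the
#' lateral gaps between the three gate cores in the closed state (the
#' hydrophobic-packing layer above the matrix salt-bridge network).
#' Defaults: plain 2, cytoplasmic gate 10.5 (closed at ring radius 9,
#' open at 13), matrix gate 8 (closed at 6, open at 10), matrix packing
#' layer 8.
#'
#' @param topology the toy `site_model`.
#' @param sigma_bead,sigma_gate_cyt,sigma_gate_mat,sigma_mat_packing
#'   core diameters.
#' @return numeric vector over protein sites.
#' @export
toy_repulsion_sigmas <- function(topology, sigma_bead = 2,
                                 sigma_gate_cyt = 10.5,
                                 sigma_gate_mat = 8,
                                 sigma_mat_packing = 8) {
  sig <- rep(sigma_bead, n_sites(topology))
  sig[sites_with_tag(topology, "gate_cyt") + 1L] <- sigma_gate_cyt
  gm <- sites_with_tag(topology, "gate_mat")
  sig[gm + 1L] <- sigma_gate_mat
  # the next bead up the same helix seals the gaps between gate cores
  sig[gm + 2L] <- sigma_mat_packing
  sig
}

#' Add tracer particles to a reference state
#'
#' Tracers (solvent surrogates) are appended to the topology with the
#' `tracer` tag and initialized in a slab above the cytoplasmic gate by
#' rejection sampling against the repulsion cores, so no tracer starts
#' inside a core. Tracers interact with protein beads only through the
#' soft repulsion, so open channels admit them and packed gates exclude
#' them.
#'
#' @param ref a `reference_pair`.
#' @param spec a `toy_transporter_spec` (defaults to `ref$spec`);
#'   `spec$n_tracers` tracers are added.
#' @param state which reference state to initialize around.
#' @return list: `topology` (augmented `site_model`), `coords`
#'   (full N x 3), `tracer_idx`, `protein_idx` (0-based),
#'   `sigma_protein`, and ready-made `repulsion` and `wall` force terms.
#' @export
add_tracers <- function(ref, spec = ref$spec, state = c("of", "if")) {
  state <- match.arg(state)
  base <- if (state == "of") ref$of_state$coords else ref$if_state$coords
  topo <- ref$topology
  np <- n_sites(topo)
  nt <- spec$n_tracers
  sig <- toy_repulsion_sigmas(topo)
  if (nt == 0L) {
    return(list(topology = topo, coords = base,
                tracer_idx = integer(0), protein_idx = seq_len(np) - 1L,
                sigma_protein = sig, repulsion = NULL, wall = NULL))
  }
  zs <- max(base[, 3])
  rmax <- max(spec$gate_radius_cyt_OF, spec$r_mid) + 3
  set.seed(spec$seed)
  pts <- matrix(0, nt, 3)
  placed <- 0L
  tries <- 0L
  while (placed < nt) {
    tries <- tries + 1L
    if (tries > 20000L)
      stop("could not place tracers outside repulsion cores")
    cand <- c(stats::runif(1, -rmax, rmax), stats::runif(1, -rmax, rmax),
              stats::runif(1, zs + 1, zs + 7))
    d <- sqrt(colSums((t(base) - cand)^2))
    if (all(d > sig) &&
        (placed == 0L ||
         min(sqrt(colSums((t(pts[seq_len(placed), , drop = FALSE]) -
                             cand)^2))) > 1.5)) {
      placed <- placed + 1L
      pts[placed, ] <- cand
    }
  }
  tr_topo <- site_model(name = sprintf("W%d", seq_len(nt)),
                        domain = "solvent",
                        tags = rep(list("tracer"), nt))
  full <- bind_sites(topo, tr_topo)
  tracer_idx <- np + seq_len(nt) - 1L
  protein_idx <- seq_len(np) - 1L
  rep_term <- soft_repulsion_term(tracer_idx, protein_idx, sig)
  wall <- cylinder_wall_term(tracer_idx, radius = rmax + 2,
                             zlo = min(base[, 3]) - 8,
                             zhi = zs + 8)
  list(topology = full, coords = rbind(base, pts),
       tracer_idx = tracer_idx, protein_idx = protein_idx,
       sigma_protein = sig, repulsion = rep_term, wall = wall)
}

#' Assemble the complete toy system
#'
#' Convenience builder: reference states, calibrated double-basin
#' potential, optional tracers, and the full force-term list for one
#' starting state.
#'
#' @param spec a `toy_transporter_spec`.
#' @param state starting state.
#' @param tracers include tracer particles.
#' @return list: `ref`, `potential` (`double_basin_spec`), `topology`,
#'   `coords`, `terms` (force-term list), `tracer_idx`, `protein_idx`.
#' @export
toy_system <- function(spec = toy_transporter_spec(),
                       state = c("of", "if"), tracers = FALSE) {
  state <- match.arg(state)
  ref <- build_reference_states(spec)
  pot <- build_double_basin_spec(ref)
  if (tracers && spec$n_tracers > 0) {
    aug <- add_tracers(ref, spec, state)
    terms <- c(pot$terms, list(aug$repulsion, aug$wall))
    list(ref = ref, potential = pot, topology = aug$topology,
         coords = aug$coords, terms = terms,
         tracer_idx = aug$tracer_idx, protein_idx = aug$protein_idx)
  } else {
    base <- if (state == "of") ref$of_state$coords else ref$if_state$coords
    np <- n_sites(ref$topology)
    list(ref = ref, potential = pot, topology = ref$topology,
         coords = base, terms = pot$terms,
         tracer_idx = integer(0), protein_idx = seq_len(np) - 1L)
  }
}
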