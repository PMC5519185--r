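test_that("outward push on a symmetric triangle is balanced and radial", {
  ang <- 2 * pi * (0:2) / 3
  tri <- cbind(4 * cos(ang), 4 * sin(ang), 1)
  mean_structure <- rbind(tri, c(0, 0, 5))
  p <- design_outward_push(mean_structure, 0:2, magnitude = 2)
  expect_equal(colSums(p$forces), c(0, 0, 0), tolerance = 1e-12)
  for (k in 1:3) {
    rhat <- c(cos(ang[k]), sin(ang[k]), 0)
    expect_equal(p$forces[k, ], 2 * rhat, tolerance = 1e-12)
  }
})

test_that("outward push is three-fold symmetric on the toy motif sites", {
  spec <- toy_transporter_spec()
  ref <- build_reference_states(spec)
  acid <- sites_with_tag(ref$topology, "acidic")
  p <- design_outward_push(ref$of_state$coords, acid, magnitude = 1)
  R <- rotation_z(2 * pi / 3)
  rot <- p$forces %*% t(R)
  # rotation advances each domain's site to the next domain's site
  expect_equal(rot, p$forces[c(2, 3, 1), ], tolerance = 1e-9)
})

test_that("two collinear sites push apart along their axis", {
  m <- rbind(c(-2, 0, 0), c(2, 0, 0), c(0, 0, 9))
  p <- design_outward_push(m, 0:1, magnitude = 1.5, axis = c(0, 0, 1))
  expect_equal(p$forces[1, ], c(-1.5, 0, 0))
  expect_equal(p$forces[2, ], c(1.5, 0, 0))
  expect_error(design_outward_push(rbind(c(0, 0, 0), c(0, 0, 4)), 0:1),
               "zero direction")
})

test_that("pair contraction gives equal/opposite forces, no net torque", {
  m <- rbind(c(0, 0, 0), c(3, 0, 0))
  p <- design_pair_contraction(m, cbind(0L, 1L), magnitude = 2)
  expect_equal(p$forces[1, ], c(2, 0, 0))
  expect_equal(p$forces[2, ], c(-2, 0, 0))
  expect_equal(colSums(p$forces), c(0, 0, 0))
  trq <- colSums(rbind(vec_cross(m[1, ], p$forces[1, ]),
                       vec_cross(m[2, ], p$forces[2, ])))
  expect_equal(trq, c(0, 0, 0), tolerance = 1e-12)
  expect_error(design_pair_contraction(rbind(m[1, ], m[1, ]),
                                       cbind(0L, 1L)),
               "degenerate-pair")
})

test_that("pair contraction shrinks the pair distance in overdamped flow", {
  m <- rbind(c(0, 0, 0), c(3, 0, 0))
  p <- design_pair_contraction(m, cbind(0L, 1L), magnitude = 1)
  # forward-Euler overdamped integration under the constant design force
  x <- m
  for (i in 1:50) x <- x + 0.05 * p$forces
  d0 <- 3; d1 <- sqrt(sum((x[2, ] - x[1, ])^2))
  expect_lt(d1, d0)
})

test_that("symmetric inter-domain pairs give a symmetric force set", {
  spec <- toy_transporter_spec()
  ref <- build_reference_states(spec)
  pairs <- gate_contraction_pairs(ref$topology)
  expect_equal(nrow(pairs), 3)
  p <- design_pair_contraction(ref$of_state$coords, pairs, magnitude = 1)
  R <- rotation_z(2 * pi / 3)
  rot <- p$forces %*% t(R)
  expect_equal(rot, p$forces[c(2, 3, 1), ], tolerance = 1e-9)
})

test_that("segment seeds are deterministic and within integer range", {
  s1 <- lrpf_segment_seed(7, 3, 0)
  expect_identical(s1, lrpf_segment_seed(7, 3, 0))
  expect_false(s1 == lrpf_segment_seed(7, 3, 1))
  expect_false(s1 == lrpf_segment_seed(8, 3, 0))
  expect_true(s1 >= 1 && s1 < 2^31)
})

test_that("a zero-f_max cycle reproduces the unbiased run bit for bit", {
  sys <- toy_system()
  params <- langevin_params(n_steps = 1L, seed = 1L, save_stride = 10L)
  config <- lrpf_config(f_max = 0, biased_steps = 400L,
                        unbiased_steps = 800L, max_cycles = 1L, seed = 5L)
  boot_p <- params
  boot_p$n_steps <- config$unbiased_steps
  boot_p$seed <- lrpf_segment_seed(config$seed, 0, 1)
  boot <- run_langevin(sys$coords, sys$terms, boot_p, sys$topology)
  cov0 <- estimate_covariance(boot, shrinkage = config$shrinkage)
  cyc <- suppressWarnings(
    run_cycle(attr(boot, "final_coords"), config, sys$terms,
              sys$topology, params, cov0, cycle = 1))
  # plain unbiased segments with the same seed schedule
  p_b <- params; p_b$n_steps <- config$biased_steps
  p_b$seed <- lrpf_segment_seed(config$seed, 1, 0)
  plain_b <- run_langevin(attr(boot, "final_coords"), sys$terms, p_b,
                          sys$topology)
  p_u <- params; p_u$n_steps <- config$unbiased_steps
  p_u$seed <- lrpf_segment_seed(config$seed, 1, 1)
  plain_u <- run_langevin(attr(plain_b, "final_coords"), sys$terms, p_u,
                          sys$topology)
  expect_identical(cyc$biased_traj$coords, plain_b$coords)
  expect_identical(cyc$unbiased_traj$coords, plain_u$coords)
})

test_that("cycle records carry monitors, bias summary and seeds", {
  sys <- toy_system()
  params <- langevin_params(n_steps = 1L, seed = 1L, save_stride = 10L)
  mon <- if_monitor(sys$ref)
  mon[[2]] <- list(name = "gate_cyt_rg", metric = "gate_rg",
                   selection = "tag:gate_cyt", comparator = "<",
                   threshold = 1)
  config <- lrpf_config(biased_steps = 400L, unbiased_steps = 800L,
                        max_cycles = 1L, seed = 2L, monitors = mon)
  res <- run_lrpf(sys$coords, config, sys$terms, sys$topology, params)
  expect_equal(length(res$records), 1)
  rec <- res$records[[1]]
  expect_named(rec$monitors, c("rmsd_to_if", "gate_cyt_rg"))
  expect_true(all(is.finite(unlist(rec$monitors))))
  expect_equal(rec$bias_max_norm, config$f_max, tolerance = 1e-9)
  expect_named(rec$seeds, c("biased", "unbiased"))
  expect_equal(nrow(res$per_domain), 1)
  expect_equal(ncol(res$per_domain), 3)
})

test_that("max_cycles = 1 gives exactly one record and replay matches", {
  sys <- toy_system()
  params <- langevin_params(n_steps = 1L, seed = 1L, save_stride = 10L)
  config <- lrpf_config(biased_steps = 300L, unbiased_steps = 600L,
                        max_cycles = 1L, seed = 3L)
  a <- run_lrpf(sys$coords, config, sys$terms, sys$topology, params)
  b <- run_lrpf(sys$coords, config, sys$terms, sys$topology, params)
  expect_equal(length(a$records), 1)
  expect_identical(a$final_coords, b$final_coords)
  expect_identical(a$records[[1]]$monitors, b$records[[1]]$monitors)
})

test_that("the LRPF benchmark transitions where unbiased runs do not", {
  # desk-scale analog of driving the alternating-access transition two
  # orders of magnitude faster than the spontaneous rate: biased cycling
  # crosses within a few cycles, equal-length unbiased runs never leave
  # the starting basin (3 seeds here; the full 10-seed benchmark runs in
  # the acceptance suite)
  sys <- toy_system()
  of <- sys$ref$of_state$coords
  params <- langevin_params(n_steps = 1L, seed = 1L, save_stride = 5L)
  succ <- 0
  total_steps <- integer(0)
  for (sd in 1:3) {
    config <- lrpf_config(monitors = if_monitor(sys$ref), seed = sd)
    res <- run_lrpf(sys$coords, config, sys$terms, sys$topology, params)
    succ <- succ + (res$termination == "monitor")
    total_steps <- c(total_steps, config$unbiased_steps +
                       length(res$records) *
                       (config$biased_steps + config$unbiased_steps))
  }
  expect_equal(succ, 3)
  for (sd in 1:3) {
    tr <- run_langevin(sys$coords, sys$terms,
                       langevin_params(n_steps = max(total_steps),
                                       seed = 100L + sd,
                                       save_stride = 50L), sys$topology)
    wr <- windowed_mean_rmsd(tr, of, 120)
    expect_lt(max(wr), 1.5)
  }
})

test_that("per-domain displacement asymmetry is logged under noise", {
  sys <- toy_system()
  params <- langevin_params(n_steps = 1L, seed = 1L, save_stride = 5L)
  config <- lrpf_config(monitors = if_monitor(sys$ref), seed = 4L,
                        max_cycles = 5L)
  res <- run_lrpf(sys$coords, config, sys$terms, sys$topology, params)
  pd <- res$per_domain
  expect_true(nrow(pd) >= 1)
  # symmetric forces on a thermally noisy landscape: instantaneous
  # per-domain displacements differ even though the design is symmetric
  expect_gt(max(abs(pd[1, ] - mean(pd[1, ]))), 0)
})

test_that("stage sequences validate types and chain coordinates", {
  sys <- toy_system()
  params <- langevin_params(n_steps = 1L, seed = 1L, save_stride = 10L)
  expect_error(
    run_stage_sequence(list(list(type = "warp")), sys$coords, sys$terms,
                       sys$topology, params),
    "unknown stage type")
  empty <- run_stage_sequence(list(), sys$coords, sys$terms,
                              sys$topology, params)
  expect_length(empty$reports, 0)
  expect_identical(empty$final_coords, as.matrix(sys$coords))

  stages <- list(
    list(type = "unbiased", name = "relax", n_steps = 300L, seed = 7L),
    list(type = "targeted", name = "pull_if",
         target = sys$ref$if_state$coords, k_t = 50, n_steps = 500L,
         seed = 8L))
  res <- run_stage_sequence(stages, sys$coords, sys$terms, sys$topology,
                            params)
  expect_named(res$reports, c("relax", "pull_if"))
  # stage boundaries are bit-identical between report and chained coords
  expect_identical(res$reports$relax$end_coords,
                   res$reports$pull_if$start_coords)
  expect_identical(res$final_coords, res$reports$pull_if$end_coords)
})

test_that("the canonical staged demo transitions, expels the ligand
           analog, and stays in the IF basin", {
  # stage plan: matrix-opening LRPF -> cytoplasm-closing LRPF -> thermal
  # relaxation -> steered expulsion of a bound ligand analog through the
  # open matrix gate -> apo relaxation
  spec <- toy_transporter_spec()
  ref <- build_reference_states(spec)
  pot <- build_double_basin_spec(ref)
  np <- n_sites(ref$topology)
  # one ligand-analog particle parked in the pore center
  lig_topo <- site_model(name = "LIG", domain = "solvent",
                         tags = list("tracer"))
  topo <- bind_sites(ref$topology, lig_topo)
  coords <- rbind(ref$of_state$coords, c(0, 0, 0))
  sig <- toy_repulsion_sigmas(ref$topology)
  sig[] <- 2  # ligand feels excluded volume only, so gates do not trap it
  terms <- c(pot$terms, list(
    soft_repulsion_term(np, 0:(np - 1L), sig),
    cylinder_wall_term(np, radius = 18, zlo = -16, zhi = 16)))
  ifc_full <- rbind(ref$if_state$coords, c(0, 0, 0))
  prot <- 0:(np - 1L)
  mon <- list(list(name = "rmsd_to_if", metric = "rmsd",
                   selection = prot, reference = ifc_full,
                   comparator = "<", threshold = 1.5))
  params <- langevin_params(n_steps = 1L, seed = 1L, save_stride = 5L)
  stages <- list(
    list(type = "lrpf", name = "open_matrix",
         config = lrpf_config(monitors = mon, seed = 1L)),
    list(type = "lrpf", name = "close_cytoplasm",
         config = lrpf_config(perturbation_design = "pair_contraction",
                              monitors = mon, max_cycles = 2L, seed = 2L)),
    list(type = "unbiased", name = "relax", n_steps = 6000L, seed = 3L),
    list(type = "steered", name = "expel_ligand", n_steps = 8000L,
         seed = 4L,
         steered = steered_term("projection", group1 = np,
                                axis = c(0, 0, 1), k_pull = 20,
                                center0 = 0, velocity = -0.3)),
    list(type = "unbiased", name = "apo_relax", n_steps = 20000L,
         seed = 5L))
  res <- run_stage_sequence(stages, coords, terms, topo, params)
  expect_equal(res$reports$open_matrix$termination, "monitor")
  # the ligand analog left through the matrix side
  expect_lt(res$reports$expel_ligand$end_coords[np + 1L, 3], -8)
  expect_gt(res$reports$expel_ligand$work, 0)
  # the apo protein stays inward-facing
  apo <- res$trajectories$apo_relax
  wr <- windowed_mean_rmsd(
    trajectory(NULL, apo$coords[, prot + 1L, , drop = FALSE],
               times = apo$times),
    ref$if_state$coords, min(1200, n_frames(apo)))
  expect_lt(max(wr), 1.5)
})
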