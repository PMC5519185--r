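test_that("kabsch recovers identity and removes rigid motions", {
  set.seed(1)
  x <- matrix(rnorm(18), 6, 3)
  fit <- kabsch_superpose(x, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)

  ang <- 37 * pi / 180
  moved <- x %*% t(rotation_z(ang)) + matrix(c(3, -1, 2), 6, 3,
                                             byrow = TRUE)
  fit2 <- kabsch_superpose(moved, x)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-12)
  expect_equal(apply_superposition(moved, fit2), x, tolerance = 1e-10)
})

test_that("kabsch matches the quaternion oracle on random point sets", {
  set.seed(2)
  for (i in 1:100) {
    x <- matrix(rnorm(18, sd = 2), 6, 3)
    y <- matrix(rnorm(18, sd = 2), 6, 3)
    fit <- kabsch_superpose(x, y)
    expect_lt(abs(fit$rmsd - quaternion_rmsd(x, y)), 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
})

test_that("kabsch keeps a proper rotation on reflection-inducing input", {
  set.seed(3)
  x <- matrix(rnorm(15), 5, 3)
  y <- x; y[, 1] <- -y[, 1]  # mirrored set
  fit <- kabsch_superpose(y, x)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
  expect_lt(abs(fit$rmsd - quaternion_rmsd(y, x)), 1e-8)
})

test_that("kabsch rejects degenerate input", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "rank-deficiency")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "at least 3")
})

test_that("C++ and R superpositions agree", {
  set.seed(4)
  x <- matrix(rnorm(24), 8, 3); y <- matrix(rnorm(24), 8, 3)
  rcpp <- lrpath:::.cpp_kabsch(x, y)
  # C++ fits y onto x; the R routine fits mobile onto reference
  rr <- kabsch_superpose(y, x)
  expect_equal(rcpp$rmsd, rr$rmsd, tolerance = 1e-10)
  expect_equal(rcpp$rotation, rr$rotation, tolerance = 1e-8)
})

test_that("rmsd series is zero on copies and monotone along the morph", {
  sys <- toy_system()
  of <- sys$ref$of_state$coords; ifc <- sys$ref$if_state$coords
  n <- nrow(of)
  copies <- array(0, dim = c(4, n, 3))
  for (i in 1:4) copies[i, , ] <- of
  tr <- trajectory(sys$topology, copies)
  expect_equal(max(rmsd_timeseries(tr, of)$values), 0, tolerance = 1e-10)

  morph <- array(0, dim = c(11, n, 3))
  for (i in 1:11) morph[i, , ] <- (1 - (i - 1) / 10) * of + (i - 1) / 10 * ifc
  trm <- trajectory(sys$topology, morph)
  r <- rmsd_timeseries(trm, of)$values
  expect_true(all(diff(r) > 0))
  # reordering the selection does not change the value
  sel <- select(sys$topology, "domain:I")
  a <- rmsd_timeseries(trm, of, sel)$values
  b <- rmsd_timeseries(trm, of, rev(sel))$values
  expect_equal(a, b)
})

test_that("helix angle matches constructed orientations", {
  along_z <- cbind(0, 0, seq(0, 7, 1))
  expect_equal(helix_angle(along_z), 0, tolerance = 1e-9)
  along_x <- cbind(seq(0, 7, 1), 0, 0)
  expect_equal(helix_angle(along_x), 90, tolerance = 1e-9)
  tilted <- cbind(sin(pi / 6) * 0:7, 0, cos(pi / 6) * 0:7)
  expect_equal(helix_angle(tilted), 30, tolerance = 1e-6)
  ball <- rbind(diag(3), -diag(3))
  expect_error(helix_angle(ball), "degenerate-axis")
})

test_that("contact series agrees with a brute-force all-pairs scan", {
  set.seed(5)
  sm <- site_model(name = sprintf("B%d", 1:8), domain = "I")
  arr <- array(rnorm(6 * 8 * 3, sd = 3), dim = c(6, 8, 3))
  tr <- trajectory(sm, arr)
  selA <- 0:3; selB <- 4:7
  s <- contact_series(tr, selA, selB, cutoff = 4.5)
  for (i in 1:6) {
    x <- arr[i, , ]
    dmin <- min(as.matrix(dist(x))[1:4, 5:8])
    expect_equal(s$values[i], dmin, tolerance = 1e-10)
  }
  frac <- contact_series(tr, selA, selB, cutoff = 4.5,
                         mode = "fraction_pairs")
  d <- as.matrix(dist(arr[1, , ]))[1:4, 5:8]
  expect_equal(frac$values[1], mean(d < 4.5))
  expect_error(contact_series(tr, 0:3, 3:5, 4.5), "overlap")
})

test_that("fixed-distance pairs are in or out of contact by cutoff", {
  sm <- site_model(name = c("A", "B"), domain = "I")
  arr <- array(0, dim = c(5, 2, 3))
  for (i in 1:5) arr[i, 2, 1] <- 3
  tr <- trajectory(sm, arr)
  wide <- contact_series(tr, 0L, 1L, cutoff = 4.5)
  expect_true(all(attr(wide, "in_contact")))
  tight <- contact_series(tr, 0L, 1L, cutoff = 2)
  expect_false(any(attr(tight, "in_contact")))
})

test_that("salt-bridge hysteresis forms once and ignores margin jitter", {
  sm <- site_model(name = c("D", "K"), domain = "I",
                   tags = list("acidic", "basic"))
  mk_traj <- function(dists) {
    arr <- array(0, dim = c(length(dists), 2, 3))
    arr[, 2, 1] <- dists
    trajectory(sm, arr)
  }
  crossing <- mk_traj(c(6, 5.5, 4.8, 3.9, 3.5, 3.6))
  s <- saltbridge_series(crossing, 0L, 1L, cutoff = 4.0, margin = 0.5)
  expect_equal(attr(s, "n_form_events"), 1L)
  expect_equal(attr(s, "n_break_events"), 0L)

  jitter <- mk_traj(c(3.5, 4.1, 4.4, 4.2, 4.4, 4.1))
  s2 <- saltbridge_series(jitter, 0L, 1L, cutoff = 4.0, margin = 0.5)
  expect_equal(attr(s2, "n_break_events"), 0L)
  expect_true(all(attr(s2, "formed")))

  swapped <- saltbridge_series(crossing, 1L, 0L, cutoff = 4.0)
  expect_equal(s$values, swapped$values)
})

test_that("hydrogen-bond criterion counts bonded frames", {
  sm <- site_model(name = c("D", "A"), domain = "I")
  dists <- c(2.8, 5.0, 3.0, 3.4, 4.0, 2.9, 5.5, 6.0, 3.6, 5.1)
  arr <- array(0, dim = c(10, 2, 3))
  arr[, 2, 1] <- dists
  tr <- trajectory(sm, arr)
  s <- hbond_series(tr, 0L, 1L, d_cut = 3.5)
  expect_equal(attr(s, "fraction_bonded"), 0.4)
  expect_identical(attr(s, "bonded"), dists < 3.5)
})

test_that("occupancy grid counts are exact window fractions", {
  sm <- site_model(name = "W", domain = "solvent", tags = list("tracer"))
  arr <- array(0, dim = c(10, 1, 3))
  # inside voxel [0,1)^3 in 4 of 10 frames, far away otherwise
  inside <- c(1, 3, 6, 9)
  for (i in 1:10)
    arr[i, 1, ] <- if (i %in% inside) c(0.5, 0.5, 0.5) else c(7.5, 7.5, 7.5)
  tr <- trajectory(sm, arr)
  g <- occupancy_grid(tr, NULL, spacing = 1, window = 10)
  expect_equal(grid_value_at(g, c(0.5, 0.5, 0.5)), 0.4)
  expect_equal(grid_value_at(g, c(7.5, 7.5, 7.5)), 0.6)
  expect_true(threshold_mask(g, 0.3)[1, 1, 1])
  expect_true(all(g$values >= 0 & g$values <= 1))

  static <- trajectory(sm, array(rep(0.5, 9), dim = c(3, 1, 3)))
  gs <- occupancy_grid(static, NULL, spacing = 1)
  expect_equal(max(gs$values), 1.0)
  expect_equal(sum(gs$values > 0), 1)
})

test_that("count_in_region matches point-in-region arithmetic", {
  set.seed(7)
  sm <- site_model(name = sprintf("W%d", 1:20), domain = "solvent",
                   tags = rep(list("tracer"), 20))
  arr <- array(rnorm(5 * 20 * 3, sd = 4), dim = c(5, 20, 3))
  tr <- trajectory(sm, arr)
  slab <- list(type = "slab", zmin = -2, zmax = 2)
  s <- count_in_region(tr, "tag:tracer", slab)
  for (i in 1:5)
    expect_equal(s$values[i],
                 sum(arr[i, , 3] >= -2 & arr[i, , 3] <= 2))
  sph <- list(type = "sphere", center = c(0, 0, 0), radius = 3)
  s2 <- count_in_region(tr, "tag:tracer", sph)
  for (i in 1:5)
    expect_equal(s2$values[i], sum(rowSums(arr[i, , ]^2) <= 9))
  empty <- count_in_region(tr, integer(0), slab)
  expect_equal(max(empty$values), 0)
})

test_that("gate_rg geometry identities hold", {
  ring <- cbind(5 * cos(2 * pi * (0:2) / 3), 5 * sin(2 * pi * (0:2) / 3), 2)
  expect_equal(gate_rg(ring), 5, tolerance = 1e-12)
  expect_equal(gate_rg(ring * 2), 10, tolerance = 1e-12)
  expect_equal(gate_rg(ring, axis_projection = TRUE), 5, tolerance = 1e-12)
  expect_error(gate_rg(ring[1, , drop = FALSE]), "single site")
})

test_that("gate_rg is monotone along the OF to IF morph", {
  sys <- toy_system()
  of <- sys$ref$of_state$coords; ifc <- sys$ref$if_state$coords
  gc <- sites_with_tag(sys$topology, "gate_cyt")
  gm <- sites_with_tag(sys$topology, "gate_mat")
  lam <- seq(0, 1, length.out = 11)
  cyt <- vapply(lam, function(l) gate_rg((1 - l) * of + l * ifc, gc), 1)
  mat <- vapply(lam, function(l) gate_rg((1 - l) * of + l * ifc, gm), 1)
  expect_true(all(diff(cyt) < 0))  # cytoplasmic gate closes
  expect_true(all(diff(mat) > 0))  # matrix gate opens
})

test_that("rmsf is zero for static input and rigid-motion invariant", {
  sm <- site_model(name = sprintf("B%d", 1:5), domain = "I")
  x <- matrix(rnorm(15), 5, 3)
  arr <- array(0, dim = c(6, 5, 3))
  for (i in 1:6) arr[i, , ] <- x
  expect_equal(max(rmsf(trajectory(sm, arr))), 0, tolerance = 1e-10)

  set.seed(11)
  wiggly <- array(rnorm(20 * 5 * 3, sd = 0.1), dim = c(20, 5, 3))
  for (i in 1:20) wiggly[i, , ] <- x + wiggly[i, , ]
  base <- rmsf(trajectory(sm, wiggly))
  moved <- wiggly
  for (i in 1:20)
    moved[i, , ] <- wiggly[i, , ] %*% t(rotation_z(i / 3)) +
      matrix(c(i, -i, 2 * i), 5, 3, byrow = TRUE)
  expect_equal(rmsf(trajectory(sm, moved)), base, tolerance = 1e-3)
})

test_that("rmsf of a harmonic site matches the analytic variance", {
  k <- 2; kT <- 1
  sys <- make_harmonic_network(seed = 13)
  term <- tether_term(0:4, sys$ref, k)
  params <- langevin_params(temperature = kT, friction = 1, dt = 0.01,
                            n_steps = 300000L, seed = 5L,
                            save_stride = 30L)
  tr <- run_langevin(sys$ref, term, params)
  sm <- site_model(name = sprintf("B%d", 1:5), domain = "I")
  tr$topology <- sm
  vals <- rmsf(tr)
  # each site fluctuates with variance kT/k per coordinate, but the
  # superposition fit absorbs the 6 rigid-body combinations of the 3n
  # coordinates, leaving (3n - 6)/(3n) of the variance as internal RMSF
  n <- 5
  expected <- (3 * kT / k) * (3 * n - 6) / (3 * n)
  expect_equal(mean(vals^2), expected, tolerance = 0.1)
})

test_that("all distance metrics are invariant under global rigid motion", {
  set.seed(17)
  sm <- site_model(name = sprintf("B%d", 1:6), domain = "I")
  arr <- array(rnorm(4 * 6 * 3, sd = 2), dim = c(4, 6, 3))
  tr <- trajectory(sm, arr)
  R <- rotation_z(0.8)
  moved <- arr
  for (i in 1:4)
    moved[i, , ] <- arr[i, , ] %*% t(R) + matrix(c(5, 6, 7), 6, 3,
                                                 byrow = TRUE)
  tr2 <- trajectory(sm, moved)
  expect_equal(contact_series(tr, 0:2, 3:5, 4)$values,
               contact_series(tr2, 0:2, 3:5, 4)$values, tolerance = 1e-10)
  ref <- arr[1, , ]
  expect_equal(rmsd_timeseries(tr, ref)$values,
               rmsd_timeseries(tr2, ref)$values, tolerance = 1e-8)
  expect_equal(vapply(1:4, function(i) gate_rg(moved[i, , ]), 1),
               vapply(1:4, function(i) gate_rg(arr[i, , ]), 1),
               tolerance = 1e-10)
})
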