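#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares proper rotation and translation mapping `mobile` onto
#' `reference`. Reflections are corrected by flipping the smallest
#' singular direction, so `det(rotation) = +1` always.
#'
#' @param mobile N x 3 coordinate matrix.
#' @param reference N x 3 coordinate matrix.
#' @param weights optional non-negative per-site weights.
#' @return list with `rotation` (3 x 3, det +1), `translation`
#'   (length 3), and `rmsd` (weighted RMS residual after the fit).
#'   Mobile rows transform as `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 sites")
  if (nrow(reference) != n) stop("coordinate sets differ in size")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  xm <- sweep(mobile, 2, cm)
  xr <- sweep(reference, 2, cr)
  H <- t(xm * w) %*% xr
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("rank-deficiency error: sites are collinear or degenerate")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- xm %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - xr)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% t(R)),
       rmsd = rmsd)
}

#' Apply a superposition fit to coordinates
#' @param coords N x 3 matrix.
#' @param fit result of [kabsch_superpose()].
#' @return transformed N x 3 matrix.
#' @export
apply_superposition <- function(coords, fit) {
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, -fit$translation)
}

#' Metric time series container
#' @param name metric name.
#' @param times numeric frame times (strictly increasing).
#' @param values numeric values, one per time.
#' @param selection provenance string describing the selection used.
#' @return an object of class `metric_series`.
#' @export
metric_series <- function(name, times, values, selection = "") {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("metric times must be strictly increasing")
  structure(list(name = name, times = as.numeric(times),
                 values = as.numeric(values), selection = selection),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("metric_series '%s': %d points, range [%g, %g]\n", x$name,
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

.resolve_sel <- function(traj, selection) {
  if (is.null(selection)) return(seq_len(dim(traj$coords)[2]))
  if (is.character(selection)) {
    if (is.null(traj$topology))
      stop("string selections need a topology on the trajectory")
    return(select(traj$topology, selection) + 1L)
  }
  as.integer(selection) + 1L  # 0-based indices in, 1-based out
}

#' Per-frame superposed RMSD to a reference structure
#'
#' @param traj a `trajectory`.
#' @param reference N x 3 reference coordinates (or a `frame`).
#' @param selection selection string or 0-based indices; `NULL` = all.
#' @return a `metric_series` named `rmsd`.
#' @export
rmsd_timeseries <- function(traj, reference, selection = NULL) {
  if (inherits(reference, "frame")) reference <- reference$coords
  idx <- .resolve_sel(traj, selection)
  ref <- as.matrix(reference)[idx, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    kabsch_superpose(frame_coords(traj, i)[idx, , drop = FALSE], ref)$rmsd
  }, numeric(1))
  metric_series("rmsd", traj$times, vals,
                if (is.character(selection)) selection else "")
}

#' Helix tilt angle against a reference axis
#'
#' The angle between the dominant principal axis of the selected sites and
#' `reference_axis`, folded into `[0, 90]` degrees.
#'
#' @param coords N x 3 coordinates of one frame (or a `frame`).
#' @param selection 0-based site indices of the helix (>= 3 sites), or
#'   `NULL` for all rows.
#' @param reference_axis 3-vector (default z, the channel axis).
#' @return angle in degrees.
#' @export
helix_angle <- function(coords, selection = NULL, reference_axis = c(0, 0, 1)) {
  if (inherits(coords, "frame")) coords <- coords$coords
  x <- as.matrix(coords)
  if (!is.null(selection)) x <- x[as.integer(selection) + 1L, , drop = FALSE]
  if (nrow(x) < 3L) stop("helix_angle needs at least 3 sites")
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  if (sv$d[1] < 1e-10 || (sv$d[1] - sv$d[2]) < 1e-6 * sv$d[1])
    stop("degenerate-axis error: no dominant principal axis")
  ax <- sv$v[, 1]
  ref <- reference_axis / sqrt(sum(reference_axis^2))
  cosang <- abs(sum(ax * ref))
  acos(pmin(1, cosang)) * 180 / pi
}

.pair_min_dist <- function(xa, xb) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(max(0, min(d2)))
}

#' Inter-selection contact time series
#'
#' @param traj a `trajectory`.
#' @param selA,selB disjoint selections (strings or 0-based indices).
#' @param cutoff contact distance cutoff (default 4.5, the usual
#'   heavy-atom hydrophobic-contact value).
#' @param mode `"min_distance"` (per-frame minimum inter-selection
#'   distance) or `"fraction_pairs"` (fraction of site pairs within
#'   cutoff).
#' @return a `metric_series`; attribute `in_contact` is the boolean track
#'   at the cutoff.
#' @export
contact_series <- function(traj, selA, selB, cutoff = 4.5,
                           mode = c("min_distance", "fraction_pairs")) {
  mode <- match.arg(mode)
  ia <- .resolve_sel(traj, selA)
  ib <- .resolve_sel(traj, selB)
  if (!length(ia) || !length(ib)) stop("selections must be non-empty")
  if (length(intersect(ia, ib)))
    stop("selection error: contact selections overlap")
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    x <- frame_coords(traj, i)
    xa <- x[ia, , drop = FALSE]; xb <- x[ib, , drop = FALSE]
    if (mode == "min_distance") .pair_min_dist(xa, xb)
    else {
      d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
      mean(d2 < cutoff^2)
    }
  }, numeric(1))
  s <- metric_series(paste0("contact_", mode), traj$times, vals)
  attr(s, "in_contact") <- if (mode == "min_distance") vals < cutoff
                           else vals > 0
  s
}

#' Salt-bridge distance series with hysteresis events
#'
#' Minimum distance between acidic and basic selections plus a
#' formed/broken state track: a bridge forms when the distance drops below
#' `cutoff` and breaks only beyond `cutoff + margin`.
#'
#' @param traj a `trajectory`.
#' @param acidic,basic selections (ideally tagged `acidic` / `basic`; a
#'   warning is emitted otherwise and geometry is used regardless).
#' @param cutoff salt-bridge cutoff (default 4.0).
#' @param margin hysteresis margin (default 0.5).
#' @return a `metric_series` with attributes `formed` (logical track),
#'   `n_form_events` and `n_break_events`.
#' @export
saltbridge_series <- function(traj, acidic, basic, cutoff = 4.0,
                              margin = 0.5) {
  if (!is.null(traj$topology)) {
    for (s in list(acidic, basic)) {
      if (is.character(s)) next
      tags <- unlist(traj$topology$tags[as.integer(s) + 1L])
      if (!any(c("acidic", "basic") %in% tags))
        warning("saltbridge_series: selection carries no acidic/basic ",
                "tag; proceeding on geometry")
    }
  }
  ia <- .resolve_sel(traj, acidic)
  ib <- .resolve_sel(traj, basic)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    x <- frame_coords(traj, i)
    .pair_min_dist(x[ia, , drop = FALSE], x[ib, , drop = FALSE])
  }, numeric(1))
  formed <- logical(length(vals))
  state <- vals[1] < cutoff
  n_form <- 0L; n_break <- 0L
  for (i in seq_along(vals)) {
    if (!state && vals[i] < cutoff) { state <- TRUE; n_form <- n_form + 1L }
    else if (state && vals[i] > cutoff + margin) {
      state <- FALSE; n_break <- n_break + 1L
    }
    formed[i] <- state
  }
  s <- metric_series("saltbridge_min_distance", traj$times, vals)
  attr(s, "formed") <- formed
  attr(s, "n_form_events") <- n_form
  attr(s, "n_break_events") <- n_break
  s
}

#' Hydrogen-bond (distance-criterion) series
#'
#' For coarse-grained sites only the donor-acceptor distance criterion is
#' applied; an angle criterion would need donor-antecedent geometry that
#' bead models do not carry.
#'
#' @param traj a `trajectory`.
#' @param donor,acceptor selections.
#' @param d_cut distance cutoff (default 3.5).
#' @return a `metric_series` of minimum donor-acceptor distances with
#'   attributes `bonded` (logical track) and `fraction_bonded`.
#' @export
hbond_series <- function(traj, donor, acceptor, d_cut = 3.5) {
  ia <- .resolve_sel(traj, donor)
  ib <- .resolve_sel(traj, acceptor)
  if (!length(ia) || !length(ib)) stop("selections must be non-empty")
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    x <- frame_coords(traj, i)
    .pair_min_dist(x[ia, , drop = FALSE], x[ib, , drop = FALSE])
  }, numeric(1))
  s <- metric_series("hbond_min_distance", traj$times, vals)
  attr(s, "bonded") <- vals < d_cut
  attr(s, "fraction_bonded") <- mean(vals < d_cut)
  s
}

#' Occupancy grid over a trailing window of frames
#'
#' Voxel occupancy is the fraction of the last `window` frames in which at
#' least one selected site center falls inside the voxel (half-open
#' `[lo, hi)` membership per axis, so no face is counted twice).
#'
#' @param traj a `trajectory`.
#' @param selection selection string or 0-based indices.
#' @param spacing voxel edge length (default 1 model unit).
#' @param window number of trailing frames to use (<= `n_frames`).
#' @return an `occupancy_grid` object: `origin`, `spacing`, `dims`,
#'   `values` (3D array in `[0, 1]`), `window`.
#' @export
occupancy_grid <- function(traj, selection = NULL, spacing = 1.0,
                           window = n_frames(traj)) {
  if (window > n_frames(traj)) stop("window exceeds frame count")
  if (window < 1) stop("window must be at least 1 frame")
  idx <- .resolve_sel(traj, selection)
  frames <- seq(n_frames(traj) - window + 1L, n_frames(traj))
  pts <- do.call(rbind, lapply(frames, function(i)
    frame_coords(traj, i)[idx, , drop = FALSE]))
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  if (any(!is.finite(lo))) stop("grid error: empty selection")
  origin <- floor(lo / spacing) * spacing
  dims <- pmax(1L, as.integer(floor((hi - origin) / spacing)) + 1L)
  counts <- array(0L, dim = dims)
  for (i in frames) {
    x <- frame_coords(traj, i)[idx, , drop = FALSE]
    v <- floor(sweep(x, 2, origin) / spacing) + 1L
    keep <- v[, 1] >= 1 & v[, 1] <= dims[1] & v[, 2] >= 1 &
      v[, 2] <= dims[2] & v[, 3] >= 1 & v[, 3] <= dims[3]
    v <- unique(v[keep, , drop = FALSE])
    if (nrow(v)) counts[v] <- counts[v] + 1L
  }
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 values = counts / window, window = window),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("occupancy_grid: %d x %d x %d voxels, spacing %g, window %d\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, x$window))
  invisible(x)
}

#' Threshold an occupancy grid at a contour level
#' @param grid an `occupancy_grid`.
#' @param level contour level in `[0, 1]`; the conventional water-density
#'   contour is 0.3.
#' @return logical 3D array, `TRUE` where occupancy >= level.
#' @export
threshold_mask <- function(grid, level = 0.3) grid$values >= level

#' Occupancy value at a point
#' @param grid an `occupancy_grid`.
#' @param point length-3 coordinate.
#' @return occupancy fraction of the voxel containing `point` (0 outside
#'   the grid).
#' @export
grid_value_at <- function(grid, point) {
  v <- floor((point - grid$origin) / grid$spacing) + 1L
  if (any(v < 1) || any(v > grid$dims)) return(0)
  grid$values[v[1], v[2], v[3]]
}

#' Count selected sites inside a region, per frame
#'
#' @param traj a `trajectory`.
#' @param selection selection string or 0-based indices.
#' @param region `list(type = "slab", zmin =, zmax =)` or
#'   `list(type = "sphere", center =, radius =)`.
#' @return a `metric_series` of counts.
#' @export
count_in_region <- function(traj, selection, region) {
  idx <- .resolve_sel(traj, selection)
  if (is.null(region$type) ||
      !region$type %in% c("slab", "sphere"))
    stop("region must have type 'slab' or 'sphere'")
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    if (!length(idx)) return(0)
    x <- frame_coords(traj, i)[idx, , drop = FALSE]
    if (region$type == "slab")
      sum(x[, 3] >= region$zmin & x[, 3] <= region$zmax)
    else
      sum(rowSums(sweep(x, 2, region$center)^2) <= region$radius^2)
  }, numeric(1))
  metric_series("count_in_region", traj$times, vals)
}

#' Gate radius of gyration
#'
#' Root-mean-square distance of the gate sites from their centroid — the
#' channel-closure order parameter. With `axis_projection` the computation
#' is done in the plane normal to the channel axis (z).
#'
#' @param coords N x 3 coordinates of a frame (or a `frame`).
#' @param selection 0-based indices of the gate sites (>= 2).
#' @param axis_projection drop the z component before computing.
#' @return gyration radius (length units of the input).
#' @export
gate_rg <- function(coords, selection = NULL, axis_projection = FALSE) {
  if (inherits(coords, "frame")) coords <- coords$coords
  x <- as.matrix(coords)
  if (!is.null(selection)) x <- x[as.integer(selection) + 1L, , drop = FALSE]
  if (nrow(x) < 2L) stop("gate_rg undefined for a single site")
  if (axis_projection) x <- x[, 1:2, drop = FALSE]
  xc <- sweep(x, 2, colMeans(x))
  sqrt(mean(rowSums(xc^2)))
}

#' Per-site root-mean-square fluctuation
#'
#' Frames are superposed onto the (iterated) mean structure first, so a
#' global rigid-body motion contributes nothing.
#'
#' @param traj a `trajectory` with >= 2 frames.
#' @param selection selection string or 0-based indices; `NULL` = all.
#' @return numeric per-site RMSF values over the selection.
#' @export
rmsf <- function(traj, selection = NULL) {
  if (n_frames(traj) < 2) stop("rmsf needs at least 2 frames")
  idx <- .resolve_sel(traj, selection)
  nf <- n_frames(traj)
  arr <- array(0, dim = c(nf, length(idx), 3))
  for (i in seq_len(nf)) arr[i, , ] <- frame_coords(traj, i)[idx, , drop = FALSE]
  m <- apply(arr, c(2, 3), mean)
  for (pass in 1:2) {
    for (i in seq_len(nf)) {
      fit <- kabsch_superpose(matrix(arr[i, , ], ncol = 3), m)
      arr[i, , ] <- apply_superposition(matrix(arr[i, , ], ncol = 3), fit)
    }
    m <- apply(arr, c(2, 3), mean)
  }
  dev2 <- array(0, dim = dim(arr))
  for (i in seq_len(nf))
    dev2[i, , ] <- (matrix(arr[i, , ], ncol = 3) - m)^2
  sqrt(apply(dev2, 2, mean) * 3)  # mean over frames and dims, x3 => per-site
}
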