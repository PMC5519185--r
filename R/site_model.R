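#' @useDynLib lrpath, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.allowed_tags <- c("gate_cyt", "gate_mat", "acidic", "basic",
                   "hydrophobic", "tracer")

#' Site model: the coarse-grained topology
#'
#' A `site_model` holds one record per coarse-grained site (bead): a short
#' name, a domain label, an optional helix label, a set of functional tags
#' (gate, acidic, basic, hydrophobic, tracer) and a mass. Site ids are
#' 0-based and contiguous; 1-based serials appear only at PDB boundaries.
#'
#' @param name character vector of short site labels.
#' @param domain character vector of domain labels (e.g. "I", "II", "III");
#'   recycled if length 1.
#' @param helix character vector of helix labels or `NA`; recycled.
#' @param tags list of character vectors, one per site, drawn from
#'   `gate_cyt, gate_mat, acidic, basic, hydrophobic, tracer`.
#' @param mass positive numeric masses (model units); recycled.
#' @return An object of class `site_model`.
#' @export
site_model <- function(name, domain, helix = NA_character_,
                       tags = NULL, mass = 1) {
  n <- length(name)
  if (n < 1L) stop("site_model needs at least one site")
  domain <- rep_len(as.character(domain), n)
  helix <- rep_len(as.character(helix), n)
  mass <- rep_len(as.numeric(mass), n)
  if (is.null(tags)) tags <- rep(list(character(0)), n)
  if (length(tags) != n) stop("tags must have one entry per site")
  tags <- lapply(tags, as.character)
  bad <- setdiff(unique(unlist(tags)), .allowed_tags)
  if (length(bad))
    stop("unknown site tags: ", paste(bad, collapse = ", "),
         " (allowed: ", paste(.allowed_tags, collapse = ", "), ")")
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("site masses must be positive and finite")
  if (any(is.na(domain)))
    stop("every site needs exactly one domain label")
  structure(
    list(site_id = seq_len(n) - 1L, name = as.character(name),
         domain = domain, helix = helix, tags = tags, mass = mass),
    class = "site_model")
}

#' @export
print.site_model <- function(x, ...) {
  cat("site_model:", n_sites(x), "sites,",
      length(unique(x$domain)), "domains\n")
  tg <- sort(table(unlist(x$tags)), decreasing = TRUE)
  if (length(tg))
    cat("  tags:", paste(names(tg), tg, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Number of sites in a topology
#' @param topology a `site_model`.
#' @return integer site count.
#' @export
n_sites <- function(topology) length(topology$site_id)

#' Indices of sites carrying a tag
#' @param topology a `site_model`.
#' @param tag a single tag name.
#' @return 0-based integer indices.
#' @export
sites_with_tag <- function(topology, tag) {
  which(vapply(topology$tags, function(t) tag %in% t, logical(1))) - 1L
}

#' Concatenate two site models
#' @param a,b `site_model` objects.
#' @return a `site_model` with `b`'s sites appended (ids renumbered).
#' @export
bind_sites <- function(a, b) {
  site_model(name = c(a$name, b$name), domain = c(a$domain, b$domain),
             helix = c(a$helix, b$helix), tags = c(a$tags, b$tags),
             mass = c(a$mass, b$mass))
}

#' Single coordinate frame
#'
#' @param coords N x 3 numeric matrix of site coordinates.
#' @param time non-negative time stamp.
#' @param box optional length-3 box vector.
#' @return An object of class `frame`.
#' @export
frame <- function(coords, time = 0, box = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("frame coords must be an N x 3 matrix")
  if (!all(is.finite(coords))) stop("frame coords must be finite")
  if (!is.finite(time) || time < 0) stop("frame time must be >= 0")
  if (!is.null(box) && length(box) != 3L) stop("box must be a 3-vector")
  structure(list(coords = coords, time = as.numeric(time), box = box),
            class = "frame")
}

#' Trajectory container
#'
#' Frames are stored as an `n_frames x N x 3` array with strictly
#' increasing time stamps and a constant site count.
#'
#' @param topology a `site_model` (site count must match coordinates).
#' @param coords `n_frames x N x 3` array, or a list of `frame` objects.
#' @param times numeric vector of frame times (ignored when `coords` is a
#'   list of frames).
#' @param units coordinate unit label, carried through to metrics.
#' @param box optional 3-vector.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(topology, coords, times = NULL, units = "model",
                       box = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    times <- vapply(coords, function(f) f$time, numeric(1))
    arr <- array(0, dim = c(length(coords), nrow(coords[[1]]$coords), 3))
    for (i in seq_along(coords)) arr[i, , ] <- coords[[i]]$coords
    coords <- arr
  }
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an n_frames x N x 3 array")
  nf <- dim(coords)[1]
  if (is.null(times)) times <- seq_len(nf) - 1
  if (length(times) != nf) stop("times length must equal frame count")
  if (nf > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (!is.null(topology) && dim(coords)[2] != n_sites(topology))
    stop("coordinate array width (", dim(coords)[2],
         ") does not match topology size (", n_sites(topology), ")")
  if (!all(is.finite(coords))) stop("trajectory coordinates must be finite")
  structure(list(topology = topology, coords = coords,
                 times = as.numeric(times), units = units, box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", n_frames(x), "frames x", dim(x$coords)[2], "sites",
      sprintf("(t = %g..%g %s)\n", x$times[1], x$times[n_frames(x)],
              x$units))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame from a trajectory
#' @param traj a `trajectory`.
#' @param i frame index (1-based).
#' @return a `frame`.
#' @export
get_frame <- function(traj, i) {
  frame(traj$coords[i, , , drop = TRUE], time = traj$times[i], box = traj$box)
}

#' Coordinates of one frame as a matrix
#' @param traj a `trajectory`.
#' @param i frame index (1-based); defaults to the last frame.
#' @return N x 3 matrix.
#' @export
frame_coords <- function(traj, i = n_frames(traj)) {
  matrix(traj$coords[i, , ], ncol = 3)
}

#' Mean structure of a trajectory (optionally superposed)
#'
#' @param traj a `trajectory`.
#' @param superpose superpose frames on the running mean (two passes of
#'   Kabsch fitting) before averaging, removing rigid-body drift.
#' @return N x 3 matrix of mean coordinates.
#' @export
mean_structure <- function(traj, superpose = TRUE) {
  arr <- traj$coords
  nf <- dim(arr)[1]
  m <- apply(arr, c(2, 3), mean)
  if (!superpose || nf < 2) return(m)
  for (pass in 1:2) {
    for (i in seq_len(nf)) {
      fit <- kabsch_superpose(matrix(arr[i, , ], ncol = 3), m)
      arr[i, , ] <- apply_superposition(matrix(arr[i, , ], ncol = 3), fit)
    }
    m <- apply(arr, c(2, 3), mean)
  }
  m
}
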