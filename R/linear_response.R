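#' Estimate a positional variance-covariance model from a trajectory
#'
#' Each frame is rigid-body superposed onto the running mean structure
#' (iterated twice) before moments are taken, so the covariance reflects
#' internal fluctuations rather than diffusion. The sample covariance `S`
#' is shrunk toward its diagonal, `C = (1 - lambda) S + lambda diag(S)`,
#' which keeps the matrix-vector products of the linear-response step
#' stable when the segment is short relative to `3N`.
#'
#' @param traj a `trajectory` with >= 2 frames.
#' @param selection selection string or 0-based indices; `NULL` = all.
#' @param superpose remove rigid-body motion before taking moments.
#' @param shrinkage shrinkage weight `lambda` in `[0, 1]` (default 0.05).
#' @param temperature temperature (kT units) the segment was run at.
#' @return a `covariance_model`: `mean_coords` (n x 3), `covariance`
#'   (3n x 3n, coordinate order x1 y1 z1 x2 ...), `n_frames`,
#'   `temperature`, `shrinkage`, `selection` (0-based indices),
#'   `singular` flag.
#' @export
estimate_covariance <- function(traj, selection = NULL, superpose = TRUE,
                                shrinkage = 0.05, temperature = 1.0) {
  nf <- n_frames(traj)
  if (nf < 2) stop("covariance needs at least 2 frames")
  if (nf < 10)
    warning("covariance from fewer than 10 frames is poorly determined")
  if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must be in [0, 1]")
  if (temperature <= 0) stop("temperature must be positive")
  idx <- .resolve_sel(traj, selection)
  if (!length(idx)) stop("selection is empty")
  n <- length(idx)
  X <- matrix(0, nf, 3 * n)  # rows: frames; cols: x1 y1 z1 x2 ...
  for (i in seq_len(nf)) {
    x <- frame_coords(traj, i)[idx, , drop = FALSE]
    X[i, ] <- as.vector(t(x))
  }
  m <- matrix(colMeans(X), ncol = 3, byrow = TRUE)
  if (superpose && n >= 3) {
    for (pass in 1:2) {
      for (i in seq_len(nf)) {
        x <- matrix(X[i, ], ncol = 3, byrow = TRUE)
        fit <- kabsch_superpose(x, m)
        X[i, ] <- as.vector(t(apply_superposition(x, fit)))
      }
      m <- matrix(colMeans(X), ncol = 3, byrow = TRUE)
    }
  }
  S <- stats::cov(X)
  C <- (1 - shrinkage) * S + shrinkage * diag(diag(S), nrow = nrow(S))
  singular <- (nf - 1) < 3 * n && shrinkage == 0
  structure(list(mean_coords = m, covariance = C, n_frames = nf,
                 temperature = temperature, shrinkage = shrinkage,
                 selection = idx - 1L, singular = singular),
            class = "covariance_model")
}

#' @export
print.covariance_model <- function(x, ...) {
  cat(sprintf(
    "covariance_model: %d sites (%d x %d), %d frames, T = %g, lambda = %g%s\n",
    nrow(x$mean_coords), nrow(x$covariance), ncol(x$covariance),
    x$n_frames, x$temperature, x$shrinkage,
    if (isTRUE(x$singular)) " [singular]" else ""))
  invisible(x)
}

#' Build a covariance model from an explicit matrix
#'
#' For analytic covariances (e.g. `kT H^-1` of a harmonic network).
#'
#' @param mean_coords n x 3 mean structure.
#' @param covariance 3n x 3n symmetric matrix.
#' @param temperature temperature (kT units).
#' @param selection 0-based site indices the model spans.
#' @return a `covariance_model`.
#' @export
covariance_model <- function(mean_coords, covariance, temperature = 1.0,
                             selection = NULL) {
  mean_coords <- as.matrix(mean_coords)
  n <- nrow(mean_coords)
  if (!isTRUE(all.equal(dim(covariance), c(3L * n, 3L * n))))
    stop("covariance must be 3n x 3n")
  if (is.null(selection)) selection <- seq_len(n) - 1L
  structure(list(mean_coords = mean_coords, covariance = as.matrix(covariance),
                 n_frames = NA_integer_, temperature = temperature,
                 shrinkage = 0, selection = as.integer(selection),
                 singular = FALSE),
            class = "covariance_model")
}

#' Perturbation set: sparse local forces at named sites
#'
#' @param sites 0-based site indices.
#' @param forces length(sites) x 3 matrix of force vectors.
#' @param label short label carried into bias-field provenance.
#' @return a `perturbation_set`.
#' @export
perturbation_set <- function(sites, forces, label = "perturb") {
  forces <- as.matrix(forces)
  if (length(sites) != nrow(forces))
    stop("one force vector per site required")
  if (length(sites) && all(abs(forces) < 1e-300))
    stop("perturbation set is identically zero")
  structure(list(sites = as.integer(sites), forces = forces,
                 label = label),
            class = "perturbation_set")
}

#' Predict the mean conformational response to a perturbative force
#'
#' Linear response: `d<r> = beta C f`, with `beta = 1/temperature`, `C`
#' the positional covariance and `f` the zero-padded dense perturbative
#' force vector.
#'
#' @param model a `covariance_model`.
#' @param perturb a `perturbation_set` (site indices must lie inside the
#'   model's selection).
#' @return n x 3 matrix of predicted mean displacements over the model's
#'   sites.
#' @export
predict_response <- function(model, perturb) {
  if (model$temperature <= 0) stop("model temperature must be positive")
  n <- nrow(model$mean_coords)
  pos <- match(perturb$sites, model$selection)
  if (anyNA(pos))
    stop("perturbation sites outside the covariance model's selection")
  f <- numeric(3 * n)
  for (k in seq_along(pos)) {
    f[(3 * (pos[k] - 1) + 1):(3 * pos[k])] <-
      f[(3 * (pos[k] - 1) + 1):(3 * pos[k])] + perturb$forces[k, ]
  }
  disp <- as.numeric(model$covariance %*% f) / model$temperature
  matrix(disp, ncol = 3, byrow = TRUE)
}

#' Convert a predicted displacement field into a biasing-force field
#'
#' The bias on each site is parallel to its predicted displacement; the
#' whole field is rescaled so the maximum per-site force norm equals
#' `f_max`. An all-zero displacement yields an all-zero field (with a
#' warning), as does `f_max = 0`.
#'
#' @param displacement n x 3 displacement field.
#' @param f_max cap on the per-site force norm (>= 0).
#' @param source provenance label.
#' @return a `bias_field`: `forces` (n x 3), `f_max`, `source`.
#' @export
build_bias <- function(displacement, f_max, source = "") {
  if (f_max < 0) stop("f_max must be >= 0")
  d <- as.matrix(displacement)
  norms <- sqrt(rowSums(d^2))
  peak <- max(norms)
  if (peak < 1e-300) {
    warning("all-zero displacement field: bias field is zero")
    forces <- d * 0
  } else {
    forces <- d * (f_max / peak)
  }
  structure(list(forces = forces, f_max = f_max, source = source),
            class = "bias_field")
}

#' @export
print.bias_field <- function(x, ...) {
  norms <- sqrt(rowSums(x$forces^2))
  cat(sprintf("bias_field: %d sites, max |f| = %g (f_max %g)%s\n",
              nrow(x$forces), max(norms), x$f_max,
              if (nzchar(x$source)) paste0(" [", x$source, "]") else ""))
  invisible(x)
}

#' Fluctuation-dissipation self-test of the linear-response step
#'
#' Runs paired simulations with the constant force `f` switched on and
#' off (same seeds), measures the mean displacement between the two, and
#' compares it with the `beta C f` prediction: per-site cosine similarity
#' and overall magnitude ratio. Differencing against the unperturbed
#' companion runs cancels both the sampling noise that is shared through
#' the seeds and any anharmonic shift of the thermal mean away from the
#' potential minimum.
#'
#' @param model a `covariance_model` estimated from (or analytic for) the
#'   unperturbed system.
#' @param perturb a `perturbation_set`.
#' @param force_terms the unperturbed system's force terms.
#' @param params a `langevin_params` for the perturbed runs.
#' @param n_repeats number of independent perturbed runs to average.
#' @param equil_fraction fraction of each run discarded as equilibration.
#' @return list: `predicted`, `observed` (n x 3), `cosine` (mean per-site
#'   cosine similarity weighted by predicted magnitude), `magnitude_ratio`
#'   (|observed| / |predicted|), `pass` flag (cosine > 0.9 and ratio
#'   between 0.8 and 1.25).
#' @export
verify_response <- function(model, perturb, force_terms, params,
                            n_repeats = 4, equil_fraction = 0.2) {
  n_total <- nrow(model$mean_coords)
  fmat <- matrix(0, n_total, 3)
  pos <- match(perturb$sites, model$selection)
  fmat[pos, ] <- perturb$forces
  predicted <- predict_response(model, perturb)
  obs <- matrix(0, n_total, 3)
  for (r in seq_len(n_repeats)) {
    p <- params
    p$seed <- params$seed + r
    seg_mean <- function(terms) {
      tr <- run_langevin(model$mean_coords, terms, p)
      drop_n <- ceiling(equil_fraction * n_frames(tr))
      keep <- seq(drop_n + 1L, n_frames(tr))
      apply(tr$coords[keep, , , drop = FALSE], c(2, 3), mean)
    }
    m_on <- seg_mean(c(.as_term_list(force_terms),
                       list(bias_term(fmat))))
    m_off <- seg_mean(.as_term_list(force_terms))
    obs <- obs + (m_on - m_off) / n_repeats
  }
  pn <- sqrt(rowSums(predicted^2))
  on <- sqrt(rowSums(obs^2))
  nz <- pn > 1e-12 & on > 1e-12
  cosine <- if (any(nz)) {
    cs <- rowSums(predicted[nz, , drop = FALSE] * obs[nz, , drop = FALSE]) /
      (pn[nz] * on[nz])
    sum(cs * pn[nz]) / sum(pn[nz])
  } else NA_real_
  ratio <- sqrt(sum(obs^2) / max(sum(predicted^2), 1e-300))
  list(predicted = predicted, observed = obs, cosine = cosine,
       magnitude_ratio = ratio,
       pass = is.finite(cosine) && cosine > 0.9 &&
         ratio > 0.8 && ratio < 1.25)
}
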