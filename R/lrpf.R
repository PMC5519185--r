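#' Outward-push perturbation design
#'
#' For each site, the force points from the sites' centroid toward the
#' site, projected onto the plane normal to `axis` and renormalized to
#' `magnitude` — the "push the acidic motif sites radially outward"
#' design that opens a gate ring.
#'
#' @param mean_structure N x 3 mean structure the directions are read
#'   from.
#' @param sites 0-based indices of the perturbed sites (>= 2).
#' @param magnitude force magnitude per site (> 0).
#' @param axis channel axis (default z).
#' @return a `perturbation_set` labeled `outward_push`.
#' @export
design_outward_push <- function(mean_structure, sites, magnitude = 1,
                                axis = c(0, 0, 1)) {
  if (length(sites) < 2) stop("outward push needs at least 2 sites")
  if (magnitude <= 0) stop("magnitude must be positive")
  x <- as.matrix(mean_structure)[sites + 1L, , drop = FALSE]
  ctr <- colMeans(x)
  a <- axis / sqrt(sum(axis^2))
  f <- matrix(0, length(sites), 3)
  for (k in seq_len(nrow(x))) {
    d <- x[k, ] - ctr
    d <- d - sum(d * a) * a
    nd <- sqrt(sum(d^2))
    if (nd < 1e-10)
      stop("zero direction error: site ", sites[k],
           " coincides with the centroid in the gate plane")
    f[k, ] <- magnitude * d / nd
  }
  perturbation_set(sites, f, label = "outward_push")
}

#' Pair-contraction perturbation design
#'
#' Equal and opposite forces of `magnitude` along each pair's connecting
#' unit vector, oriented to shorten the pair distance — the "pull the
#' inter-domain charged groups together" design that closes a gate.
#' Per-site contributions from multiple pairs are summed.
#'
#' @param mean_structure N x 3 mean structure.
#' @param pairs two-column matrix (or list of length-2 vectors) of
#'   0-based site index pairs.
#' @param magnitude force magnitude per pair (> 0).
#' @return a `perturbation_set` labeled `pair_contraction`.
#' @export
design_pair_contraction <- function(mean_structure, pairs, magnitude = 1) {
  if (magnitude <= 0) stop("magnitude must be positive")
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  x <- as.matrix(mean_structure)
  acc <- new.env(parent = emptyenv())
  fmap <- list()
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    d <- x[j + 1L, ] - x[i + 1L, ]
    nd <- sqrt(sum(d^2))
    if (nd < 1e-10)
      stop("degenerate-pair error: sites ", i, " and ", j, " coincide")
    u <- d / nd
    ki <- as.character(i); kj <- as.character(j)
    fmap[[ki]] <- (if (is.null(fmap[[ki]])) 0 else fmap[[ki]]) +
      magnitude * u
    fmap[[kj]] <- (if (is.null(fmap[[kj]])) 0 else fmap[[kj]]) -
      magnitude * u
  }
  sites <- as.integer(names(fmap))
  ord <- order(sites)
  forces <- do.call(rbind, fmap[ord])
  dimnames(forces) <- NULL
  perturbation_set(sites[ord], forces, label = "pair_contraction")
}

#' Symmetric inter-domain gate pairs of the toy
#'
#' Pairs successive cytoplasmic-gate sites around the ring (domain I-II,
#' II-III, III-I), the toy analog of the inter-domain salt bridges that
#' zip the cytoplasmic gate shut.
#'
#' @param topology the toy `site_model`.
#' @param tag gate tag to pair (default `gate_cyt`).
#' @return two-column matrix of 0-based index pairs.
#' @export
gate_contraction_pairs <- function(topology, tag = "gate_cyt") {
  idx <- sites_with_tag(topology, tag)
  if (length(idx) < 2) stop("need at least two tagged gate sites")
  cbind(idx, idx[c(seq_along(idx)[-1], 1L)])
}

#' LRPF protocol configuration
#'
#' @param perturbation_design `"outward_push"` or `"pair_contraction"`.
#' @param sites selection string for the perturbed sites (outward push).
#' @param pairs 0-based index pairs (pair contraction).
#' @param magnitude perturbative force magnitude.
#' @param biased_steps steps of the biased segment per cycle (>= 1).
#' @param unbiased_steps steps of the relaxation segment per cycle
#'   (>= 1); also the length of the cycle-0 bootstrap segment that
#'   provides the first covariance.
#' @param f_max cap on the per-site biasing-force norm.
#' @param max_cycles maximum number of cycles (>= 1).
#' @param monitors list of monitor specs, each
#'   `list(name =, metric = "rmsd"|"gate_rg", selection =, reference =,
#'   comparator = "<"|">"|"plateau", threshold =)`; monitors are
#'   evaluated on each cycle's unbiased mean structure and the first one
#'   that fires (in config order) terminates the run.
#' @param seed global integer seed; per-segment seeds derive from it via
#'   [lrpf_segment_seed()].
#' @param axis channel axis for the outward-push design.
#' @param shrinkage covariance shrinkage per cycle.
#' @param cov_selection selection the covariance is estimated over
#'   (default `"not tag:tracer"`).
#' @return an `lrpf_config`.
#' @export
lrpf_config <- function(perturbation_design = c("outward_push",
                                                "pair_contraction"),
                        sites = "tag:acidic", pairs = NULL, magnitude = 1,
                        biased_steps = 3000L, unbiased_steps = 6000L,
                        f_max = 2.5, max_cycles = 40L, monitors = list(),
                        seed = 1L, axis = c(0, 0, 1), shrinkage = 0.05,
                        cov_selection = "not tag:tracer") {
  perturbation_design <- match.arg(perturbation_design)
  if (biased_steps < 1 || unbiased_steps < 1)
    stop("biased_steps and unbiased_steps must be >= 1")
  if (max_cycles < 1) stop("max_cycles must be >= 1")
  if (f_max < 0) stop("f_max must be >= 0")
  structure(list(perturbation_design = perturbation_design, sites = sites,
                 pairs = pairs, magnitude = magnitude,
                 biased_steps = as.integer(biased_steps),
                 unbiased_steps = as.integer(unbiased_steps),
                 f_max = f_max, max_cycles = as.integer(max_cycles),
                 monitors = monitors, seed = as.integer(seed), axis = axis,
                 shrinkage = shrinkage, cov_selection = cov_selection),
            class = "lrpf_config")
}

#' Deterministic per-segment seed schedule
#'
#' Every biased and unbiased segment of an LRPF run draws its RNG seed
#' from the global seed, the cycle index and the segment id, so a run is
#' exactly replayable and an unbiased run with the same schedule is
#' frame-for-frame comparable.
#'
#' @param seed global seed.
#' @param cycle cycle index (0 = bootstrap).
#' @param segment 0 = biased, 1 = unbiased.
#' @return integer seed in `[1, 2^31 - 1)`.
#' @export
lrpf_segment_seed <- function(seed, cycle, segment) {
  as.integer((as.double(seed) * 7919 + cycle * 1031 + segment * 127) %%
               2147483646) + 1L
}

.design_perturbation <- function(config, mean_coords, topology) {
  if (config$perturbation_design == "outward_push") {
    sites <- if (is.character(config$sites))
      select(topology, config$sites) else as.integer(config$sites)
    design_outward_push(mean_coords, sites, config$magnitude, config$axis)
  } else {
    pairs <- config$pairs
    if (is.null(pairs)) pairs <- gate_contraction_pairs(topology)
    design_pair_contraction(mean_coords, pairs, config$magnitude)
  }
}

.eval_monitor <- function(mon, mean_coords, topology, history) {
  val <- switch(mon$metric,
    rmsd = {
      idx <- if (is.null(mon$selection)) seq_len(nrow(mean_coords))
             else if (is.character(mon$selection))
               select(topology, mon$selection) + 1L
             else as.integer(mon$selection) + 1L
      kabsch_superpose(mean_coords[idx, , drop = FALSE],
                       as.matrix(mon$reference)[idx, , drop = FALSE])$rmsd
    },
    gate_rg = {
      idx <- if (is.character(mon$selection))
        select(topology, mon$selection) else as.integer(mon$selection)
      gate_rg(mean_coords, idx)
    },
    stop("unknown monitor metric: ", mon$metric))
  fired <- switch(mon$comparator,
    "<" = val < mon$threshold,
    ">" = val > mon$threshold,
    plateau = {
      vals <- c(history, val)
      if (length(vals) < 5) FALSE else {
        y <- utils::tail(vals, 5)
        abs(stats::coef(stats::lm(y ~ seq_along(y)))[2]) < mon$threshold
      }
    },
    stop("unknown monitor comparator: ", mon$comparator))
  list(value = val, fired = fired)
}

.per_domain_displacement <- function(mean_coords, ref_coords, topology) {
  fit <- kabsch_superpose(mean_coords, ref_coords)
  aligned <- apply_superposition(mean_coords, fit)
  doms <- unique(topology$domain[topology$domain != "solvent"])
  vapply(doms, function(d) {
    rows <- which(topology$domain == d)
    sqrt(mean(rowSums((aligned[rows, , drop = FALSE] -
                         ref_coords[rows, , drop = FALSE])^2)))
  }, numeric(1))
}

#' Run one LRPF cycle
#'
#' One cycle is: (1) a biased segment under the current biasing forces;
#' (2) an unbiased relaxation segment; (3) covariance and mean-structure
#' re-estimation from the unbiased segment; (4) perturbation redesign
#' from the new mean; (5) a new bias field. Monitors are evaluated on the
#' new mean structure.
#'
#' @param coords starting coordinates (full system).
#' @param config an `lrpf_config`.
#' @param force_terms static force terms of the system.
#' @param topology full `site_model`.
#' @param params `langevin_params` template (temperature, friction, dt,
#'   save_stride; steps and seeds are taken from `config`).
#' @param covmodel `covariance_model` from the previous unbiased segment.
#' @param cycle cycle index (>= 1).
#' @param monitor_history named list of previous monitor value vectors
#'   (for plateau detection).
#' @return list: `record` (a `cycle_record`), `coords` (final), `covmodel`
#'   (new), `biased_traj`, `unbiased_traj`.
#' @export
run_cycle <- function(coords, config, force_terms, topology, params,
                      covmodel, cycle, monitor_history = list()) {
  perturb <- .design_perturbation(config, covmodel$mean_coords, topology)
  disp <- predict_response(covmodel, perturb)
  bias <- suppressWarnings(build_bias(disp, config$f_max,
                                      source = perturb$label))
  nfull <- n_sites(topology)
  fmat <- matrix(0, nfull, 3)
  fmat[covmodel$selection + 1L, ] <- bias$forces
  p_b <- params
  p_b$n_steps <- config$biased_steps
  p_b$seed <- lrpf_segment_seed(config$seed, cycle, 0)
  biased <- run_langevin(coords, c(.as_term_list(force_terms),
                                   list(bias_term(fmat))), p_b, topology)
  p_u <- params
  p_u$n_steps <- config$unbiased_steps
  p_u$seed <- lrpf_segment_seed(config$seed, cycle, 1)
  unbiased <- run_langevin(attr(biased, "final_coords"), force_terms, p_u,
                           topology)
  newcov <- estimate_covariance(unbiased, selection = config$cov_selection,
                                shrinkage = config$shrinkage,
                                temperature = params$temperature)
  monitors <- list()
  for (mon in config$monitors) {
    monitors[[mon$name]] <- .eval_monitor(mon, newcov$mean_coords,
                                          topology,
                                          monitor_history[[mon$name]])
  }
  bias_norms <- sqrt(rowSums(bias$forces^2))
  sym <- .bias_symmetry_score(bias$forces, topology)
  record <- structure(
    list(cycle = cycle, mean_structure = newcov$mean_coords,
         bias_max_norm = max(bias_norms), bias_symmetry = sym,
         perturbation = perturb$label,
         monitors = lapply(monitors, `[[`, "value"),
         fired = vapply(monitors, `[[`, logical(1), "fired"),
         seeds = c(biased = p_b$seed, unbiased = p_u$seed)),
    class = "cycle_record")
  list(record = record, coords = attr(unbiased, "final_coords"),
       covmodel = newcov, biased_traj = biased, unbiased_traj = unbiased)
}

.bias_symmetry_score <- function(forces, topology) {
  doms <- unique(topology$domain[topology$domain != "solvent"])
  if (length(doms) < 2) return(NA_real_)
  per <- vapply(doms, function(d)
    sqrt(mean(rowSums(forces[which(topology$domain[
      seq_len(nrow(forces))] == d), , drop = FALSE]^2))), numeric(1))
  if (max(per) < 1e-300) return(0)
  (max(per) - min(per)) / max(per)
}

#' Run a full LRPF simulation
#'
#' Bootstraps with an unbiased segment (cycle 0) that provides the first
#' covariance, then iterates [run_cycle()] until a monitor fires
#' (termination `"monitor"`), `max_cycles` is exhausted
#' (`"exhausted"`), or a segment fails (`"failed"`).
#'
#' @inheritParams run_cycle
#' @param coords0 initial coordinates.
#' @param keep_trajectories keep per-segment trajectories in the result
#'   (memory-heavy; default concatenates unbiased-segment frames only).
#' @return an `lrpf_result`: `records` (list of `cycle_record`),
#'   `termination`, `fired_monitor`, `final_coords`, `trajectory`
#'   (concatenated unbiased frames), `monitor_series` (data.frame),
#'   `per_domain` (matrix of per-domain displacement from the bootstrap
#'   mean, one row per cycle), `config`.
#' @export
run_lrpf <- function(coords0, config, force_terms, topology, params,
                     keep_trajectories = FALSE) {
  p_u <- params
  p_u$n_steps <- config$unbiased_steps
  p_u$seed <- lrpf_segment_seed(config$seed, 0, 1)
  boot <- run_langevin(coords0, force_terms, p_u, topology)
  covmodel <- estimate_covariance(boot, selection = config$cov_selection,
                                  shrinkage = config$shrinkage,
                                  temperature = params$temperature)
  ref_mean <- covmodel$mean_coords
  coords <- attr(boot, "final_coords")
  records <- list()
  history <- list()
  per_domain <- NULL
  segs <- if (keep_trajectories) list(bootstrap = boot) else list()
  frames <- list(boot)
  termination <- "exhausted"
  fired_monitor <- NA_character_
  for (cycle in seq_len(config$max_cycles)) {
    step <- tryCatch(
      run_cycle(coords, config, force_terms, topology, params, covmodel,
                cycle, history),
      error = function(e) e)
    if (inherits(step, "error")) {
      termination <- "failed"
      attr(termination, "message") <- conditionMessage(step)
      break
    }
    records[[cycle]] <- step$record
    coords <- step$coords
    covmodel <- step$covmodel
    for (nm in names(step$record$monitors))
      history[[nm]] <- c(history[[nm]], step$record$monitors[[nm]])
    pd <- .per_domain_displacement(
      covmodel$mean_coords[seq_len(nrow(ref_mean)), , drop = FALSE],
      ref_mean, topology)
    per_domain <- rbind(per_domain, pd)
    frames[[length(frames) + 1L]] <- step$unbiased_traj
    if (keep_trajectories) {
      segs[[paste0("cycle", cycle, "_biased")]] <- step$biased_traj
      segs[[paste0("cycle", cycle, "_unbiased")]] <- step$unbiased_traj
    }
    if (any(step$record$fired)) {
      termination <- "monitor"
      fired_monitor <- names(step$record$fired)[step$record$fired][1]
      break
    }
  }
  mseries <- if (length(history))
    data.frame(cycle = seq_len(max(lengths(history))),
               lapply(history, function(h)
                 c(h, rep(NA, max(lengths(history)) - length(h)))))
  else data.frame(cycle = integer(0))
  structure(list(records = records, termination = termination,
                 fired_monitor = fired_monitor, final_coords = coords,
                 trajectory = .concat_trajectories(frames, topology),
                 monitor_series = mseries, per_domain = per_domain,
                 segments = segs, config = config,
                 final_covmodel = covmodel),
            class = "lrpf_result")
}

.concat_trajectories <- function(trajs, topology) {
  arrs <- lapply(trajs, function(t) t$coords)
  nf <- vapply(trajs, n_frames, integer(1))
  offset <- 0
  times <- numeric(0)
  for (t in trajs) {
    times <- c(times, t$times + offset)
    offset <- offset + t$times[n_frames(t)]
  }
  arr <- array(0, dim = c(sum(nf), dim(arrs[[1]])[2], 3))
  at <- 0L
  for (a in arrs) {
    arr[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  trajectory(topology, arr, times = times)
}

#' @export
print.lrpf_result <- function(x, ...) {
  cat(sprintf("lrpf_result: %d cycles, termination '%s'%s\n",
              length(x$records), x$termination,
              if (!is.na(x$fired_monitor))
                paste0(" (monitor '", x$fired_monitor, "')") else ""))
  invisible(x)
}

#' Run a sequence of pipeline stages
#'
#' Chains stages on final coordinates. Stage types: `lrpf` (fields
#' `config`), `unbiased` (`n_steps`, `seed`), `steered` (`steered` term,
#' `n_steps`, `seed`), `targeted` (`target`, `k_t`, `rmsd0`, `n_steps`,
#' `seed`). Unknown types are rejected before any stage runs. Each stage
#' reports its seeds, start/end coordinates and monitor extrema.
#'
#' @param stages ordered list of stage configs, each a named list with a
#'   `type` field.
#' @param coords0 initial coordinates.
#' @param force_terms static force terms shared by all stages.
#' @param topology full `site_model`.
#' @param params `langevin_params` template.
#' @return a `stage_sequence_result`: `reports` (per stage),
#'   `final_coords`, `trajectories` (per stage).
#' @export
run_stage_sequence <- function(stages, coords0, force_terms, topology,
                               params) {
  known <- c("lrpf", "unbiased", "steered", "targeted")
  for (s in stages)
    if (is.null(s$type) || !s$type %in% known)
      stop("config error: unknown stage type '",
           if (is.null(s$type)) "<missing>" else s$type, "'")
  coords <- as.matrix(coords0)
  reports <- list()
  trajs <- list()
  for (si in seq_along(stages)) {
    s <- stages[[si]]
    nm <- if (!is.null(s$name)) s$name else paste0("stage", si)
    start_coords <- coords
    if (s$type == "lrpf") {
      res <- run_lrpf(coords, s$config, force_terms, topology, params)
      coords <- res$final_coords
      trajs[[nm]] <- res$trajectory
      reports[[nm]] <- list(
        type = "lrpf", name = nm, cycles = length(res$records),
        termination = res$termination, fired = res$fired_monitor,
        seeds = s$config$seed,
        monitor_extrema = if (nrow(res$monitor_series))
          lapply(res$monitor_series[-1], range, na.rm = TRUE) else list(),
        start_coords = start_coords, end_coords = coords)
    } else {
      p <- params
      p$n_steps <- as.integer(s$n_steps)
      p$seed <- as.integer(s$seed)
      terms <- .as_term_list(force_terms)
      if (s$type == "steered") terms <- c(terms, list(s$steered))
      if (s$type == "targeted")
        terms <- c(terms, list(targeted_term(
          if (is.null(s$idx)) seq_len(nrow(s$target)) - 1L else s$idx,
          s$target, s$k_t, if (is.null(s$rmsd0)) 0 else s$rmsd0)))
      tr <- run_langevin(coords, terms, p, topology)
      coords <- attr(tr, "final_coords")
      trajs[[nm]] <- tr
      reports[[nm]] <- list(
        type = s$type, name = nm, n_steps = p$n_steps, seeds = p$seed,
        work = if (s$type == "steered")
          utils::tail(attr(tr, "work"), 1) else NULL,
        monitor_extrema = list(
          potential = range(attr(tr, "potential"))),
        start_coords = start_coords, end_coords = coords)
    }
  }
  structure(list(reports = reports, final_coords = coords,
                 trajectories = trajs),
            class = "stage_sequence_result")
}
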