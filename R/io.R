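#' Read a structure from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records (via bio3d) into a `site_model`
#' plus a single coordinate `frame`. Chains map to domains through
#' `chain_map`; atom names become site names.
#'
#' @param path path to a PDB file.
#' @param ca_only keep only atoms named `CA`.
#' @param chain_map named character vector mapping chain ids to domain
#'   labels; unmapped chains keep their chain id as domain.
#' @return list with elements `topology` (`site_model`) and `frame`.
#' @export
read_pdb <- function(path, ca_only = FALSE, chain_map = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  for (ln in which(rec)) {
    l <- lines[ln]
    if (nchar(l) < 54)
      stop("PDB parse error at line ", ln,
           ": record shorter than coordinate columns")
    xyz <- c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz))))
      stop("PDB parse error at line ", ln,
           ": malformed coordinate columns")
  }
  if (!any(rec)) stop("empty PDB input: no ATOM records in ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atom <- pdb$atom
  if (ca_only) {
    keep <- trimws(atom$elety) == "CA"
    if (!any(keep)) stop("empty PDB input: no CA atoms in ", path)
    atom <- atom[keep, , drop = FALSE]
  }
  chain <- ifelse(is.na(atom$chain), "A", atom$chain)
  domain <- chain
  if (!is.null(chain_map)) {
    mapped <- chain %in% names(chain_map)
    domain[mapped] <- unname(chain_map[chain[mapped]])
  }
  topo <- site_model(name = trimws(atom$elety), domain = domain,
                     helix = NA_character_)
  fr <- frame(cbind(atom$x, atom$y, atom$z), time = 0)
  list(topology = topo, frame = fr)
}

#' Write a structure to a PDB file
#'
#' Coordinates go out in fixed 8.3 columns; the B-factor column can carry a
#' per-site scalar (by default the per-site norm of a bias field) for
#' visualization. Domains map to chain ids; site ids become 1-based
#' serials.
#'
#' @param topology a `site_model`.
#' @param coords N x 3 coordinate matrix (or a `frame`).
#' @param path output file.
#' @param bfactor optional numeric per-site values for the B-factor column.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(topology, coords, path, bfactor = NULL) {
  if (inherits(coords, "frame")) coords <- coords$coords
  n <- n_sites(topology)
  if (nrow(coords) != n) stop("coordinate rows must match topology size")
  if (is.null(bfactor)) bfactor <- rep(0, n)
  doms <- unique(topology$domain)
  chain <- LETTERS[match(topology$domain, doms)]
  nm <- substr(topology$name, 1, 4)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coords)),
                   type = rep("ATOM", n),
                   eleno = seq_len(n),
                   elety = ifelse(nzchar(nm), nm, "CA"),
                   resid = rep("GLY", n),
                   chain = chain,
                   resno = seq_len(n),
                   b = round(bfactor, 2))
  invisible(path)
}

#' Read a multi-frame extended-XYZ trajectory
#'
#' Each frame is a site-count line, a comment line carrying `time=<t>`,
#' then one `label x y z` line per site.
#'
#' @param path path to an extended-XYZ file.
#' @param topology optional `site_model`; synthesized from the first
#'   frame's labels when omitted.
#' @return a `trajectory`.
#' @export
read_xyz_trajectory <- function(path, topology = NULL) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) < length(lines)]
  if (!length(lines) || !nzchar(trimws(lines[1])))
    stop("empty XYZ input: ", path)
  pos <- 1L
  frames <- list()
  times <- numeric(0)
  n_ref <- NA_integer_
  labels <- NULL
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1)
      stop("XYZ format error at line ", pos, ": expected site count")
    if (is.na(n_ref)) n_ref <- n
    if (n != n_ref)
      stop("XYZ format error at line ", pos,
           ": inconsistent per-frame site count (", n, " vs ", n_ref, ")")
    if (pos + 1L + n > length(lines))
      stop("XYZ format error: truncated frame starting at line ", pos)
    comment <- lines[pos + 1L]
    tm <- regmatches(comment,
                     regexpr("time=([-0-9.eE+]+)", comment))
    t_val <- if (length(tm)) as.numeric(sub("time=", "", tm))
             else length(times)
    body <- lines[(pos + 2L):(pos + 1L + n)]
    fields <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(fields) < 4L)
    if (length(bad))
      stop("XYZ format error at line ", pos + 1L + bad[1],
           ": expected 'label x y z'")
    if (is.null(labels)) labels <- vapply(fields, `[[`, "", 1L)
    xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    if (!all(is.finite(xyz)))
      stop("XYZ format error: non-numeric coordinates in frame at line ",
           pos)
    frames[[length(frames) + 1L]] <- xyz
    times <- c(times, t_val)
    pos <- pos + 2L + n
  }
  if (!length(frames)) stop("empty XYZ input: ", path)
  arr <- array(0, dim = c(length(frames), n_ref, 3))
  for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
  if (is.null(topology))
    topology <- site_model(name = labels, domain = "A")
  trajectory(topology, arr, times = times)
}

#' Write a trajectory as extended XYZ
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  n <- dim(traj$coords)[2]
  labels <- if (!is.null(traj$topology)) traj$topology$name
            else rep("X", n)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(traj))) {
    writeLines(as.character(n), con)
    writeLines(sprintf("time=%.9g units=%s", traj$times[i], traj$units),
               con)
    xyz <- frame_coords(traj, i)
    writeLines(sprintf("%s %.6f %.6f %.6f", labels, xyz[, 1], xyz[, 2],
                       xyz[, 3]), con)
  }
  invisible(path)
}
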