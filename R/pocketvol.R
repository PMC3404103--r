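#' Bondi-style van der Waals radii (Angstrom)
#'
#' Radii used by the probe-accessibility test; unknown elements are
#' rejected rather than silently defaulted.
#' @return named numeric vector, element symbol to radius in Angstrom.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98,
    X = 1.70)  # X: generic pseudo-atom used by the synthetic generators
}

#' Probe specification for grid accessibility
#'
#' @param probe_radius probe radius in Angstrom; the default 1.4 is a
#'   water-sized probe.
#' @param grid_spacing grid spacing in Angstrom (default 0.5).
#' @param radii named vdW radius table, element -> Angstrom.
#' @return a `probe_spec` list.
#' @export
probe_spec <- function(probe_radius = 1.4, grid_spacing = 0.5,
                       radii = vdw_radii()) {
  if (probe_radius <= 0 || grid_spacing <= 0) {
    stop("probe_radius and grid_spacing must be > 0")
  }
  structure(list(probe_radius = probe_radius, grid_spacing = grid_spacing,
                 radii = radii), class = "probe_spec")
}

#' Spherical region of interest
#'
#' @param center either a 3-vector (Angstrom) or an atom spec
#'   `list(chain, resnum, atom)` resolved against the structure; the grid
#'   is anchored at this center so results are translation-reproducible.
#' @param radius region radius in Angstrom (default 18, the receptor-region
#'   convention around S620).
#' @return a `region_spec` list.
#' @export
region_spec <- function(center, radius = 18) {
  structure(list(center = center, radius = radius), class = "region_spec")
}

.resolve_center <- function(region, model) {
  ctr <- region$center
  if (is.numeric(ctr) && length(ctr) == 3) return(as.numeric(ctr))
  as.numeric(model$xyz[.lookup_atom(model, ctr), ])
}

# 26-connected component labelling of a logical 3-D array by frontier BFS.
# Returns an integer array of component labels (0 = not accessible).
.label_components <- function(acc) {
  d <- dim(acc)
  # pad by one cell so neighbor index arithmetic cannot wrap
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- acc
  dp <- dim(pad)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  lin_off <- off[, 1] + off[, 2] * dp[1] + off[, 3] * dp[1] * dp[2]
  labels <- array(0L, dp)
  todo <- which(pad)
  comp <- 0L
  remaining <- pad
  while (length(todo <- which(remaining))) {
    comp <- comp + 1L
    frontier <- todo[1]
    remaining[frontier] <- FALSE
    labels[frontier] <- comp
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, lin_off, "+")))
      nb <- nb[remaining[nb]]
      if (!length(nb)) break
      remaining[nb] <- FALSE
      labels[nb] <- comp
      frontier <- nb
    }
  }
  labels[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
}

#' Grid-based probe accessibility of a region
#'
#' Lays a cubic grid (anchored at the region center) over the spherical
#' region and marks a grid point accessible if and only if its distance to
#' every protein heavy atom is at least that atom's vdW radius plus the
#' probe radius (probe-center accessibility). Accessible points are
#' partitioned into 26-connected components; volumes are point counts times
#' the grid-cell volume.
#'
#' @param model a `structure_model`, or a bare coordinate matrix with
#'   `topology`.
#' @param region a [region_spec()].
#' @param probe a [probe_spec()].
#' @param topology topology model for a bare matrix.
#' @return a `pocket_result`: list with `points` (accessible grid
#'   coordinates, one row per point), `component` (label per point),
#'   `volume` (total, Angstrom^3), `component_count`,
#'   `largest_component_volume`, `spacing`.
#' @export
grid_accessibility <- function(model, region, probe = probe_spec(),
                               topology = NULL) {
  if (inherits(model, "structure_model")) {
    topology <- model
    xyz <- model$xyz
  } else {
    if (is.null(topology)) stop("topology required for a bare coordinate matrix")
    xyz <- as.matrix(model)
  }
  ctr <- .resolve_center(region, list(atoms = topology$atoms, xyz = xyz))
  h <- probe$grid_spacing
  elem <- topology$atoms$element
  heavy <- which(elem != "H")
  unknown <- setdiff(unique(elem[heavy]), names(probe$radii))
  if (length(unknown)) {
    stop("no vdW radius for element(s): ", paste(unknown, collapse = ", "))
  }
  if (nrow(xyz)) {
    bb_lo <- apply(xyz, 2, min) - 5; bb_hi <- apply(xyz, 2, max) + 5
    if (any(ctr + region$radius < bb_lo) || any(ctr - region$radius > bb_hi)) {
      warning("region lies outside the structure bounding box (+5 A margin)")
    }
  }

  m <- ceiling(region$radius / h)
  ax <- seq(-m, m) * h
  d <- length(ax)
  # in-region mask (sphere)
  r2grid <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  acc <- r2grid <= region$radius^2
  # block points near each heavy atom; all coordinates relative to ctr
  excl <- probe$radii[elem[heavy]] + probe$probe_radius
  rel <- sweep(xyz[heavy, , drop = FALSE], 2, ctr)
  for (k in seq_along(heavy)) {
    r <- excl[k]; p <- rel[k, ]
    ii <- which(abs(ax - p[1]) <= r)
    jj <- which(abs(ax - p[2]) <= r)
    kk <- which(abs(ax - p[3]) <= r)
    if (!length(ii) || !length(jj) || !length(kk)) next
    dx2 <- (ax[ii] - p[1])^2
    dy2 <- (ax[jj] - p[2])^2
    dz2 <- (ax[kk] - p[3])^2
    blk <- outer(outer(dx2, dy2, "+"), dz2, "+") < r^2
    acc[ii, jj, kk] <- acc[ii, jj, kk, drop = FALSE] & !blk
  }
  labels <- .label_components(acc)
  pts_idx <- which(acc, arr.ind = TRUE)
  pts <- cbind(x = ax[pts_idx[, 1]] + ctr[1],
               y = ax[pts_idx[, 2]] + ctr[2],
               z = ax[pts_idx[, 3]] + ctr[3])
  comp <- labels[pts_idx]
  cell <- h^3
  comp_sizes <- if (length(comp)) tabulate(comp) else integer(0)
  structure(list(points = pts, component = comp,
                 volume = length(comp) * cell,
                 component_count = length(comp_sizes),
                 largest_component_volume =
                   if (length(comp_sizes)) max(comp_sizes) * cell else 0,
                 spacing = h, center = ctr, region_radius = region$radius),
            class = "pocket_result")
}

#' @export
print.pocket_result <- function(x, ...) {
  cat(sprintf(
    "<pocket_result> V = %.1f A^3 in %d component(s); largest %.1f A^3 (h = %g A)\n",
    x$volume, x$component_count, x$largest_component_volume, x$spacing))
  invisible(x)
}

#' Per-frame pocket volume series
#'
#' Applies [grid_accessibility()] to every trajectory frame and reports the
#' largest-component volume per frame plus the open fraction at a volume
#' threshold (default: half the first frame's volume, a reference-state
#' convention; the underlying data admit any threshold).
#'
#' @param traj a `trajectory`.
#' @param region a [region_spec()].
#' @param probe a [probe_spec()].
#' @param open_threshold volume threshold (Angstrom^3) above which a frame
#'   counts as open; `NULL` uses half of frame 1's largest-component volume.
#' @return data.frame `time`, `volume` (largest component, Angstrom^3),
#'   `open`; attribute `open_fraction` and `open_threshold`.
#' @export
pocket_timeseries <- function(traj, region, probe = probe_spec(),
                              open_threshold = NULL) {
  nf <- n_frames(traj)
  if (nf < 1) stop("empty trajectory")
  vols <- numeric(nf)
  for (i in seq_len(nf)) {
    res <- tryCatch(
      grid_accessibility(frame_coords(traj, i), region, probe,
                         topology = traj$topology),
      error = function(e) stop("frame ", i, ": ", conditionMessage(e)))
    vols[i] <- res$largest_component_volume
  }
  if (is.null(open_threshold)) open_threshold <- vols[1] / 2
  out <- data.frame(time = traj$times, volume = vols,
                    open = vols >= open_threshold)
  attr(out, "open_threshold") <- open_threshold
  attr(out, "open_fraction") <- mean(out$open)
  out
}

#' Write accessible grid points as PDB pseudo-atoms
#'
#' Visualization aid: each accessible grid point becomes a HETATM-style
#' pseudo-atom (written as ATOM records, element X) so the pocket can be
#' inspected in a molecular viewer.
#'
#' @param result a `pocket_result`.
#' @param path output PDB path.
#' @param component restrict to one component label (default all).
#' @return `path`, invisibly.
#' @export
write_pocket_pdb <- function(result, path, component = NULL) {
  pts <- result$points
  if (!is.null(component)) pts <- pts[result$component == component, , drop = FALSE]
  n <- nrow(pts)
  atoms <- data.frame(chain = "P", resnum = seq_len(n), resname = "PKT",
                      atom = paste0("X", seq_len(n) %% 10), element = "X",
                      stringsAsFactors = FALSE)
  # keep one pseudo-atom per residue number so identities stay unique
  m <- structure_model(atoms, pts, sort = FALSE)
  write_pdb(m, path)
}
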