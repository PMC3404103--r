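#' Build the conductive-to-collapsed reaction coordinate
#'
#' Superposes the collapsed reference onto the conductive reference on the
#' selected atoms and takes the normalized coordinate difference as the
#' collective coordinate. For a two-structure set this direction is exactly
#' the sole non-degenerate principal component of the pair (the
#' mean-centered difference direction), so the coordinate is implemented as
#' the explicit difference rather than an eigen-decomposition; the sign is
#' fixed so that the collapsed reference maps to +1.
#'
#' @param ref_conductive,ref_collapsed `structure_model` reference
#'   conformations (conductive = state A, s = 0; collapsed = state B,
#'   s = 1).
#' @param selection selection expression (see [select_atoms()]) resolving to
#'   the same atom identities in both references; typically the SF backbone,
#'   e.g. `"resnum 624-628 and name N CA C O"`.
#' @param superpose_refs superpose the collapsed onto the conductive
#'   reference before differencing (default `TRUE`); set `FALSE` only when
#'   the two references are already in one coordinate frame and the raw
#'   difference is wanted.
#' @return a `reaction_coordinate` with fields `ref_a`, `ref_b` (superposed
#'   selection coordinates), `unit_vector` (flattened 3N, unit norm), `span`
#'   (|B - A| in Angstrom), `selection` (expression) and `identity` (atom
#'   identity table used for mapping into other topologies).
#' @export
build_reaction_coordinate <- function(ref_conductive, ref_collapsed, selection,
                                      superpose_refs = TRUE) {
  selA <- select_atoms(ref_conductive, selection)
  selB <- select_atoms(ref_collapsed, selection)
  idA <- ref_conductive$atoms[selA, c("chain", "resnum", "atom")]
  idB <- ref_collapsed$atoms[selB, c("chain", "resnum", "atom")]
  if (nrow(idA) != nrow(idB) || !all(idA == idB)) {
    stop("selection resolves to different atoms in the two references")
  }
  if (nrow(idA) < 3) stop("reaction coordinate needs at least 3 atoms")
  A <- ref_conductive$xyz[selA, , drop = FALSE]
  Braw <- ref_collapsed$xyz[selB, , drop = FALSE]
  B <- if (superpose_refs) {
    apply_superposition(superpose(Braw, A), Braw)
  } else {
    Braw
  }
  D <- B - A
  span <- sqrt(sum(D^2))
  if (span < 1e-6) {
    stop("degenerate reaction coordinate: references identical after ",
         "superposition (span < 1e-6 A)")
  }
  u <- D / span
  rownames(idA) <- NULL
  structure(list(ref_a = A, ref_b = B, unit_mat = u,
                 unit_vector = as.vector(t(u)), span = span,
                 selection = selection, identity = idA),
            class = "reaction_coordinate")
}

#' @export
print.reaction_coordinate <- function(x, ...) {
  cat(sprintf("<reaction_coordinate> %d atoms, span %.3f A, selection \"%s\"\n",
              nrow(x$ref_a), x$span, x$selection))
  invisible(x)
}

.resolve_rc_indices <- function(rc, topology) {
  key <- paste(topology$atoms$chain, topology$atoms$resnum, topology$atoms$atom)
  idx <- match(paste(rc$identity$chain, rc$identity$resnum, rc$identity$atom),
               key)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop(sprintf("reaction-coordinate atom %s/%d/%s absent from topology",
                 rc$identity$chain[miss], rc$identity$resnum[miss],
                 rc$identity$atom[miss]))
  }
  idx
}

.project_xyz <- function(sel_xyz, rc) {
  sp <- superpose(sel_xyz, rc$ref_a)
  moved <- apply_superposition(sp, sel_xyz)
  sum((moved - rc$ref_a) * rc$unit_mat) / rc$span
}

#' Project a frame onto the reaction coordinate
#'
#' The frame's selection atoms are superposed onto the conductive reference
#' and the displacement is projected onto the unit difference vector:
#' `s = ((frame - A) . u) / span`, so s = 0 at the conductive and s = 1 at
#' the collapsed reference. Values outside `[0, 1]` are permitted
#' (overshooting excursions occur in practice).
#'
#' @param frame a `structure_model`, or an `n x 3` coordinate matrix
#'   congruent with `topology`.
#' @param rc a `reaction_coordinate`.
#' @param topology `structure_model` describing `frame` when it is a bare
#'   matrix.
#' @return dimensionless collapse coordinate `s` (scalar).
#' @export
project_frame <- function(frame, rc, topology = NULL) {
  if (inherits(frame, "structure_model")) {
    topology <- frame
    xyz <- frame$xyz
  } else {
    if (is.null(topology)) stop("topology required for a bare coordinate matrix")
    xyz <- as.matrix(frame)
  }
  idx <- .resolve_rc_indices(rc, topology)
  .project_xyz(xyz[idx, , drop = FALSE], rc)
}

#' Project every frame of a trajectory
#'
#' @param traj a `trajectory`.
#' @param rc a `reaction_coordinate`.
#' @return a `projection_trace`: data.frame with `time` (ps), `s`
#'   (dimensionless) and `s_angstrom` (`s * span`, the raw displacement).
#' @export
project_trajectory <- function(traj, rc) {
  idx <- .resolve_rc_indices(rc, traj$topology)
  s <- vapply(seq_len(n_frames(traj)), function(i) {
    .project_xyz(traj$coords[i, idx, , drop = TRUE], rc)
  }, numeric(1))
  out <- data.frame(time = traj$times, s = s, s_angstrom = s * rc$span)
  class(out) <- c("projection_trace", "data.frame")
  out
}

#' Post-burn-in endpoint projection
#'
#' Arithmetic mean of the collapse coordinate over all frames at or after
#' the burn-in time; the default burn-in of 40 ns discards the approach
#' transient so the endpoint characterizes the plateau.
#'
#' @param traj a `trajectory` (or a `projection_trace`).
#' @param rc a `reaction_coordinate` (ignored for a precomputed trace).
#' @param burn_in burn-in time in ps (default 40000 = 40 ns).
#' @return mean plateau projection, dimensionless.
#' @export
endpoint_projection <- function(traj, rc = NULL, burn_in = 40000) {
  tr <- if (inherits(traj, "projection_trace")) traj else {
    project_trajectory(traj, rc)
  }
  keep <- tr$time >= burn_in
  if (!any(keep)) {
    stop(sprintf("no frames at or after burn-in (%g ps); trajectory ends at %g ps",
                 burn_in, max(tr$time)))
  }
  mean(tr$s[keep])
}

#' Ensemble mean and standard error of projection traces
#'
#' Combines independent runs on a common time grid (nearest-frame matching;
#' single-run traces are not smoothed) into per-time-point mean and
#' SEM = sd / sqrt(n).
#'
#' @param trajs list of at least 2 `trajectory` objects (or
#'   `projection_trace` data.frames).
#' @param rc a `reaction_coordinate` (needed for trajectories).
#' @param grid common time grid (ps); defaults to the first run's times.
#' @return an `ensemble_trace`: data.frame with `time`, `mean_s`, `sem_s`,
#'   and attribute `n_runs`.
#' @export
ensemble_trace <- function(trajs, rc = NULL, grid = NULL) {
  if (length(trajs) < 2) stop("ensemble statistics need at least 2 runs")
  traces <- lapply(trajs, function(x) {
    if (inherits(x, "projection_trace")) x else project_trajectory(x, rc)
  })
  if (is.null(grid)) grid <- traces[[1]]$time
  S <- vapply(traces, function(tr) {
    tr$s[vapply(grid, function(t) which.min(abs(tr$time - t)), integer(1))]
  }, numeric(length(grid)))
  out <- data.frame(time = grid,
                    mean_s = rowMeans(S),
                    sem_s = apply(S, 1, sd) / sqrt(ncol(S)))
  attr(out, "n_runs") <- length(traces)
  class(out) <- c("ensemble_trace", "data.frame")
  out
}

#' @export
plot.ensemble_trace <- function(x, ...) {
  graphics::plot(x$time / 1000, x$mean_s, type = "l",
                 xlab = "time (ns)", ylab = "collapse coordinate s", ...)
  graphics::polygon(c(x$time, rev(x$time)) / 1000,
                    c(x$mean_s - x$sem_s, rev(x$mean_s + x$sem_s)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(x$time / 1000, x$mean_s)
  invisible(x)
}
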