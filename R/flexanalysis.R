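#' Root-mean-square fluctuation of selected atoms
#'
#' Two-pass RMSF: every frame is first superposed (on `align_selection`)
#' onto frame 1, the trajectory-mean structure is computed, all original
#' frames are refit onto that mean, and the fluctuation of each measured
#' atom about its mean position is taken:
#' `rmsf_i = sqrt(mean over frames of |r_i - <r_i>|^2)`.
#' Fitting to the mean structure rather than an arbitrary frame removes the
#' reference-frame bias of a single-pass fit. No mass weighting is applied.
#'
#' @param traj a `trajectory` with at least 2 frames.
#' @param measure_selection selection expression for the atoms whose
#'   fluctuation is reported (e.g. carbonyl oxygens
#'   `"resnum 624-627 and name O"`).
#' @param align_selection selection expression for the rigid fit (>= 3
#'   atoms); defaults to `measure_selection`.
#' @return an `rmsf_profile`: list with `atoms` (identity table + `rmsf` in
#'   Angstrom), `by_residue` (mean over chains per residue),
#'   `by_residue_chain`, and the two selection expressions.
#' @export
rmsf <- function(traj, measure_selection, align_selection = measure_selection) {
  if (n_frames(traj) < 2) {
    stop("RMSF undefined for a single frame (need >= 2)")
  }
  msel <- select_atoms(traj$topology, measure_selection)
  asel <- select_atoms(traj$topology, align_selection)
  if (length(msel) < 1) stop("empty measure selection")
  if (length(asel) < 3) stop("alignment selection needs >= 3 atoms")
  nf <- n_frames(traj)

  fit_all <- function(ref_align) {
    # superpose each frame on ref_align using the alignment atoms,
    # returning measured-atom coordinates per frame
    out <- array(NA_real_, c(nf, length(msel), 3))
    for (i in seq_len(nf)) {
      fr <- traj$coords[i, , , drop = TRUE]
      sp <- superpose(fr[asel, , drop = FALSE], ref_align)
      out[i, , ] <- apply_superposition(sp, fr[msel, , drop = FALSE])
    }
    out
  }
  align_coords <- function(ref_align) {
    out <- array(NA_real_, c(nf, length(asel), 3))
    for (i in seq_len(nf)) {
      fr <- traj$coords[i, , , drop = TRUE]
      sp <- superpose(fr[asel, , drop = FALSE], ref_align)
      out[i, , ] <- apply_superposition(sp, fr[asel, , drop = FALSE])
    }
    out
  }

  # pass 1: mean alignment structure from a fit to frame 1
  ref0 <- traj$coords[1, asel, , drop = TRUE]
  if (length(asel) == 1) dim(ref0) <- c(1, 3)
  a1 <- align_coords(ref0)
  mean_align <- apply(a1, c(2, 3), mean)
  # pass 2: refit original frames to the mean structure
  fitted <- fit_all(mean_align)
  mean_pos <- apply(fitted, c(2, 3), mean)
  dev2 <- (fitted - rep(mean_pos, each = nf))^2
  # mean over frames of the squared 3-D displacement = 3 * mean over all
  # frame x coordinate entries
  rmsf_atom <- sqrt(3 * rowMeans(matrix(aperm(dev2, c(2, 1, 3)),
                                        nrow = length(msel))))

  at <- traj$topology$atoms[msel, c("chain", "resnum", "resname", "atom")]
  at$rmsf <- rmsf_atom
  rownames(at) <- NULL
  by_rc <- aggregate(rmsf ~ resnum + resname + chain, data = at, FUN = mean)
  by_r <- aggregate(rmsf ~ resnum + resname, data = at, FUN = mean)
  structure(list(atoms = at,
                 by_residue = by_r[order(by_r$resnum), ],
                 by_residue_chain = by_rc[order(by_rc$resnum, by_rc$chain), ],
                 measure_selection = measure_selection,
                 align_selection = align_selection),
            class = "rmsf_profile")
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf("<rmsf_profile> %d atoms, mean RMSF %.3f A\n",
              nrow(x$atoms), mean(x$atoms$rmsf)))
  print(x$by_residue, row.names = FALSE)
  invisible(x)
}

#' RMSF summaries across a restraint-distance scan
#'
#' Tabulates per-residue RMSF (averaged over the four subunits) against the
#' scan label d, one row per scan point sorted by d, for curves of SF
#' carbonyl flexibility versus the S620-N629 separation.
#'
#' @param profiles named list of `rmsf_profile` objects; names are the scan
#'   distances d in Angstrom (or supply `d`).
#' @param d numeric scan labels overriding the list names.
#' @return data.frame: one row per d, columns `d`, `rmsf_mean` (grand mean
#'   over measured atoms) and one column per residue (e.g. `S624`...,
#'   built from one-letter code + residue number).
#' @export
rmsf_vs_scan <- function(profiles, d = NULL) {
  if (length(profiles) < 1) stop("no scan points")
  if (is.null(d)) d <- as.numeric(names(profiles))
  if (anyNA(d)) stop("scan distances d must be numeric (list names or d=)")
  res0 <- profiles[[1]]$by_residue[, c("resnum", "resname")]
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    br <- p$by_residue
    if (!identical(br$resnum, res0$resnum)) {
      stop("scan points use inconsistent residue selections")
    }
    cols <- setNames(as.list(br$rmsf), .residue_label(br$resname, br$resnum))
    cbind(data.frame(d = d[i], rmsf_mean = mean(p$atoms$rmsf)),
          as.data.frame(cols))
  })
  out <- do.call(rbind, rows)
  out[order(out$d), , drop = FALSE]
}

.aa1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")

.residue_label <- function(resname, resnum) {
  one <- .aa1[resname]
  one[is.na(one)] <- "X"
  paste0(one, resnum)
}
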