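#' Geometric hydrogen-bond criteria
#'
#' Default criteria follow the common MD-analysis convention:
#' donor-acceptor distance <= 3.5 Angstrom and, when explicit hydrogens are
#' present, a deviation of the hydrogen from the donor-acceptor line of at
#' most 30 degrees. In `heavy` mode (no hydrogens) the distance test is
#' combined with an antecedent angle C-D...A >= 90 degrees to suppress
#' geometric false positives.
#'
#' @param max_da_distance maximum donor-acceptor heavy-atom distance,
#'   Angstrom.
#' @param max_hda_angle maximum H-D-A deviation angle, degrees (explicit
#'   mode only); must be in (0, 90].
#' @param hydrogen_mode `"heavy"` (heavy atoms only, default) or
#'   `"explicit"` (requires hydrogens on donors).
#' @param min_antecedent_angle minimum C-D...A angle in heavy mode, degrees.
#' @return an `hbond_criteria` list.
#' @export
hbond_criteria <- function(max_da_distance = 3.5, max_hda_angle = 30,
                           hydrogen_mode = c("heavy", "explicit"),
                           min_antecedent_angle = 90) {
  hydrogen_mode <- match.arg(hydrogen_mode)
  if (max_da_distance <= 0) stop("max_da_distance must be > 0")
  if (max_hda_angle <= 0 || max_hda_angle > 90) {
    stop("max_hda_angle must be in (0, 90] degrees")
  }
  structure(list(max_da_distance = max_da_distance,
                 max_hda_angle = max_hda_angle,
                 hydrogen_mode = hydrogen_mode,
                 min_antecedent_angle = min_antecedent_angle),
            class = "hbond_criteria")
}

.angle_deg <- function(v1, v2) {
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# hydrogens covalently attached to atom i (element H, same residue, <1.2 A)
.attached_h <- function(atoms, xyz, i) {
  cand <- which(atoms$element == "H" &
                atoms$chain == atoms$chain[i] &
                atoms$resnum == atoms$resnum[i])
  if (!length(cand)) return(integer(0))
  d2 <- rowSums((xyz[cand, , drop = FALSE] -
                 matrix(xyz[i, ], length(cand), 3, byrow = TRUE))^2)
  cand[d2 < 1.2^2]
}

# heavy-atom covalent neighbors of atom i (<1.8 A, not hydrogen)
.antecedents <- function(atoms, xyz, i) {
  cand <- which(atoms$element != "H" &
                atoms$chain == atoms$chain[i] &
                atoms$resnum == atoms$resnum[i])
  cand <- setdiff(cand, i)
  if (!length(cand)) return(integer(0))
  d2 <- rowSums((xyz[cand, , drop = FALSE] -
                 matrix(xyz[i, ], length(cand), 3, byrow = TRUE))^2)
  cand[d2 < 1.8^2]
}

#' Detect hydrogen bonds in one frame
#'
#' Tests every donor-acceptor pair against the geometric criteria. Self
#' pairs, pairs within the same residue and covalently bonded pairs
#' (distance < 1.6 Angstrom) are excluded. Records are returned in
#' deterministic order (donor index, then acceptor index).
#'
#' @param model a `structure_model`, or an `n x 3` coordinate matrix with
#'   `topology` supplied.
#' @param donors,acceptors `atom_selection` objects or selection
#'   expressions; donor atoms must be N or O.
#' @param criteria an [hbond_criteria()].
#' @param topology topology model when `model` is a bare matrix.
#' @return data.frame with one row per bond: `donor`, `hydrogen` (NA in
#'   heavy mode), `acceptor` (atom indices), `donor_chain`,
#'   `acceptor_chain`, `da_distance`, `hda_angle` (NA in heavy mode) and
#'   `type` (`"intra"`/`"inter"`).
#' @export
detect_hbonds <- function(model, donors, acceptors,
                          criteria = hbond_criteria(), topology = NULL) {
  if (inherits(model, "structure_model")) {
    topology <- model
    xyz <- model$xyz
  } else {
    if (is.null(topology)) stop("topology required for a bare coordinate matrix")
    xyz <- as.matrix(model)
  }
  atoms <- topology$atoms
  if (is.character(donors)) donors <- select_atoms(topology, donors)
  if (is.character(acceptors)) acceptors <- select_atoms(topology, acceptors)
  di <- as.integer(donors); ai <- as.integer(acceptors)
  bad <- !atoms$element[di] %in% c("N", "O")
  if (any(bad)) {
    stop("donor atoms must be N or O (offending atom: ",
         atoms$atom[di[which(bad)[1]]], ")")
  }
  if (criteria$hydrogen_mode == "explicit" &&
      !any(atoms$element == "H")) {
    stop("explicit hydrogen mode but the model has no hydrogens; ",
         "use hydrogen_mode = 'heavy'")
  }
  recs <- list()
  for (d in di) {
    dx <- xyz[d, ]
    dd <- sqrt(rowSums((xyz[ai, , drop = FALSE] -
                        matrix(dx, length(ai), 3, byrow = TRUE))^2))
    same_res <- atoms$chain[ai] == atoms$chain[d] &
                atoms$resnum[ai] == atoms$resnum[d]
    ok <- dd <= criteria$max_da_distance & dd >= 1.6 & ai != d & !same_res
    for (k in which(ok)) {
      a <- ai[k]
      hyd <- NA_integer_; hda <- NA_real_
      if (criteria$hydrogen_mode == "explicit") {
        hs <- .attached_h(atoms, xyz, d)
        if (!length(hs)) next  # not a protonated donor
        angs <- vapply(hs, function(h) {
          .angle_deg(xyz[h, ] - dx, xyz[a, ] - dx)
        }, numeric(1))
        if (min(angs) > criteria$max_hda_angle) next
        hyd <- hs[which.min(angs)]; hda <- min(angs)
      } else {
        ante <- .antecedents(atoms, xyz, d)
        if (length(ante)) {
          angs <- vapply(ante, function(cc) {
            .angle_deg(xyz[cc, ] - dx, xyz[a, ] - dx)
          }, numeric(1))
          if (max(angs) < criteria$min_antecedent_angle) next
        }
      }
      recs[[length(recs) + 1L]] <- data.frame(
        donor = d, hydrogen = hyd, acceptor = a,
        donor_chain = atoms$chain[d], acceptor_chain = atoms$chain[a],
        da_distance = dd[k], hda_angle = hda,
        type = if (atoms$chain[d] == atoms$chain[a]) "intra" else "inter",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(recs)) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), donor_chain = character(0),
                      acceptor_chain = character(0),
                      da_distance = numeric(0), hda_angle = numeric(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  out[order(out$donor, out$acceptor), , drop = FALSE]
}

.focal_sidechain_idx <- function(topology, focal_resnum) {
  at <- topology$atoms
  idx <- which(at$resnum == focal_resnum &
               !at$atom %in% c("N", "CA", "C", "O") &
               at$element %in% c("N", "O"))
  if (!length(idx)) {
    stop("focal residue ", focal_resnum,
         " has no polar side-chain atoms in the topology")
  }
  idx
}

#' Time-resolved intra-/inter-subunit H-bond counts of a focal side chain
#'
#' For every frame, counts hydrogen bonds in which the focal residue's polar
#' side-chain atoms (in any chain) participate as donor or acceptor, split
#' into intra-subunit (partner in the same chain) and inter-subunit
#' (partner in any other chain) bonds; the per-chain counts are summed over
#' the four subunits.
#'
#' @param traj a `trajectory`.
#' @param focal_resnum residue number of the focal residue (default 629,
#'   the asparagine switch).
#' @param partners selection expression for candidate partner atoms
#'   (default all N/O atoms).
#' @param criteria an [hbond_criteria()].
#' @return an `hbond_series`: data.frame with `time`, `n_intra`, `n_inter`.
#' @export
hbond_series <- function(traj, focal_resnum = 629,
                         partners = "element N O",
                         criteria = hbond_criteria()) {
  top <- traj$topology
  focal <- .focal_sidechain_idx(top, focal_resnum)
  chains_with <- unique(top$atoms$chain[focal])
  if (!setequal(chains_with, top$chain_order)) {
    stop("focal residue ", focal_resnum, " absent from chain(s): ",
         paste(setdiff(top$chain_order, chains_with), collapse = ","))
  }
  part <- select_atoms(top, partners)
  pol <- intersect(as.integer(part),
                   which(top$atoms$element %in% c("N", "O")))
  donors_focal <- structure(focal, class = "atom_selection")
  donors_other <- structure(setdiff(pol, focal), class = "atom_selection")
  acc_all <- structure(pol, class = "atom_selection")
  acc_focal <- structure(focal, class = "atom_selection")

  nf <- n_frames(traj)
  n_intra <- integer(nf); n_inter <- integer(nf)
  for (i in seq_len(nf)) {
    fr <- traj$coords[i, , , drop = TRUE]
    b1 <- detect_hbonds(fr, donors_focal, acc_all, criteria, topology = top)
    b2 <- detect_hbonds(fr, donors_other, acc_focal, criteria, topology = top)
    bonds <- rbind(b1, b2)
    n_intra[i] <- sum(bonds$type == "intra")
    n_inter[i] <- sum(bonds$type == "inter")
  }
  out <- data.frame(time = traj$times, n_intra = n_intra, n_inter = n_inter)
  attr(out, "focal_resnum") <- focal_resnum
  attr(out, "criteria") <- criteria
  class(out) <- c("hbond_series", "data.frame")
  out
}

#' Rolling-mean smoothing of an H-bond series
#'
#' Presentation-layer smoothing of the raw integer counts (centred rolling
#' mean, window truncated at the edges); the raw series is left untouched.
#'
#' @param series an `hbond_series`.
#' @param window window length in frames (odd recommended).
#' @return data.frame `time`, `n_intra_smooth`, `n_inter_smooth`.
#' @export
smooth_hbond_series <- function(series, window = 25) {
  n <- nrow(series)
  half <- floor(window / 2)
  sm <- function(x) {
    vapply(seq_len(n), function(i) {
      mean(x[max(1, i - half):min(n, i + half)])
    }, numeric(1))
  }
  data.frame(time = series$time,
             n_intra_smooth = sm(series$n_intra),
             n_inter_smooth = sm(series$n_inter))
}

#' Windowed intra-/inter-subunit contact fractions
#'
#' Splits the series into consecutive windows of `window` frames and
#' reports, per window, the fraction of all focal-residue hydrogen bonds
#' that are intra- and inter-subunit. Frames with no bonds contribute
#' nothing to either numerator or denominator; a window with no bonds at
#' all yields `NA` fractions.
#'
#' @param series an `hbond_series`.
#' @param window window length in frames; defaults to the full series.
#' @return data.frame with `t_start`, `t_end`, `intra_fraction`,
#'   `inter_fraction`, `n_bonds`.
#' @export
contact_fraction <- function(series, window = nrow(series)) {
  n <- nrow(series)
  if (window < 1 || window > n) {
    stop("window must be between 1 and the series length (", n, ")")
  }
  starts <- seq(1, n, by = window)
  rows <- lapply(starts, function(s) {
    e <- min(s + window - 1, n)
    ni <- sum(series$n_intra[s:e]); nx <- sum(series$n_inter[s:e])
    tot <- ni + nx
    data.frame(t_start = series$time[s], t_end = series$time[e],
               intra_fraction = if (tot > 0) ni / tot else NA_real_,
               inter_fraction = if (tot > 0) nx / tot else NA_real_,
               n_bonds = tot)
  })
  do.call(rbind, rows)
}
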