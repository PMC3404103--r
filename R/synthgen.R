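# Synthetic-data generators. All geometry is idealized (the package tests
# analysis code, not structural realism): a four-chain selectivity-filter
# stand-in with 4-fold symmetry about z, plus S620/N629 stand-ins carrying
# the Cbeta and side-chain amide atoms the analyses need. Every generator
# seeds one Mersenne-Twister stream from `seed` and emits a ground-truth
# sidecar; downstream recovery tests read truth only from the sidecars.

.sf_resnames <- c(`624` = "SER", `625` = "VAL", `626` = "GLY",
                  `627` = "PHE", `628` = "GLY")

# local-frame atom offsets (radial, tangential, z) for one SF residue.
# Carbonyl O sits at tangential offset 0 on purpose: the collapsed-state
# displacement is then purely radial with zero net translation and zero net
# torque over the 4-fold ring, so rigid superposition of the two references
# is exactly the identity and the programmed span survives unchanged.
.sf_offsets <- rbind(N  = c(4.0, -0.6, -1.1),
                     CA = c(4.4,  0.0, -0.5),
                     C  = c(4.0,  0.5,  0.3),
                     O  = c(3.2,  0.0,  0.6))

.chain_frame <- function(ci) {
  th <- (ci - 1) * pi / 2
  er <- c(cos(th), sin(th), 0)
  et <- c(-sin(th), cos(th), 0)
  list(er = er, et = et, ez = c(0, 0, 1))
}

.place <- function(fr, radial, tang, z) {
  radial * fr$er + tang * fr$et + z * fr$ez
}

#' Idealized conductive/collapsed reference pair
#'
#' Builds a four-chain (A-D, 4-fold symmetric about z) selectivity-filter
#' stand-in: residues 624-628 with backbone N/CA/C/O stacked along z, plus
#' an S620 stand-in (with CB and OG) behind the filter and an N629 stand-in
#' (with CB, CG, OD1, ND2) above it. The collapsed form pinches the central
#' carbonyl oxygens (residues 625 and 626) radially inward by
#' `collapse_shift` Angstrom per atom; both forms share one coordinate
#' frame, so the difference-vector span is exactly
#' `collapse_shift * sqrt(8)` (8 displaced atoms).
#'
#' @param collapse_shift inward carbonyl displacement per atom, Angstrom
#'   (default 0.7).
#' @param cb_distance S620 CB to N629 CB separation, Angstrom (default 10).
#' @return list with `conductive`, `collapsed` (`structure_model`s), `span`
#'   (exact, Angstrom), `sf_selection` (the SF backbone selection
#'   expression) and `displaced` (identity table of the moved atoms).
#' @export
make_reference_pair <- function(collapse_shift = 0.7, cb_distance = 10) {
  chains <- c("A", "B", "C", "D")
  rows <- list(); xyz <- list()
  add <- function(chain, resnum, resname, atom, element, pos) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resnum = resnum, resname = resname, atom = atom,
      element = element, stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <<- pos
  }
  for (ci in seq_along(chains)) {
    ch <- chains[ci]; fr <- .chain_frame(ci)
    # S620 stand-in behind the filter
    base620 <- list(N = c(8.2, -0.6, 0.2), CA = c(8.6, 0.0, 0.9),
                    C = c(8.2, 0.6, 1.7), O = c(7.6, 0.4, 2.4),
                    CB = c(7.6, -0.8, 1.6), OG = c(7.5, 0.0, 2.6))
    for (nm in names(base620)) {
      el <- substr(nm, 1, 1)
      add(ch, 620L, "SER", nm, el, .place(fr, base620[[nm]][1],
                                          base620[[nm]][2], base620[[nm]][3]))
    }
    # SF residues 624-628
    for (rn in 624:628) {
      z0 <- (rn - 624) * 3.2
      for (an in rownames(.sf_offsets)) {
        o <- .sf_offsets[an, ]
        add(ch, rn, .sf_resnames[as.character(rn)], an,
            substr(an, 1, 1), .place(fr, o[1], o[2], o[3] + z0))
      }
    }
    # N629 stand-in above the filter; CB placed cb_distance from S620 CB
    cb620 <- .place(fr, 7.6, -0.8, 1.6)
    dir629 <- c(fr$er * 0.4 + c(0, 0, 1) * 0.9165)  # unit-ish; normalize
    dir629 <- dir629 / sqrt(sum(dir629^2))
    cb629 <- cb620 + cb_distance * dir629
    add(ch, 629L, "ASN", "N",  "N", .place(fr, 10.0, -0.5, 17.0))
    add(ch, 629L, "ASN", "CA", "C", .place(fr, 10.4,  0.0, 17.6))
    add(ch, 629L, "ASN", "C",  "C", .place(fr, 10.0,  0.5, 18.4))
    add(ch, 629L, "ASN", "O",  "O", .place(fr, 9.4,   0.3, 19.0))
    add(ch, 629L, "ASN", "CB", "C", cb629)
    add(ch, 629L, "ASN", "CG", "C", cb629 + c(0, 0, 1.5))
    add(ch, 629L, "ASN", "OD1", "O", .place(fr, 13.0, 0.0, 16.0))
    add(ch, 629L, "ASN", "ND2", "N", cb629 + c(0, 0, 2.7))
  }
  atoms <- do.call(rbind, rows)
  xyz <- do.call(rbind, xyz)
  conductive <- structure_model(atoms, xyz, chain_order = chains)
  # collapsed: pinch carbonyl O of 625/626 inward (radially) by collapse_shift
  xyz2 <- conductive$xyz
  at <- conductive$atoms
  moved <- which(at$resnum %in% c(625L, 626L) & at$atom == "O")
  for (i in moved) {
    ci <- match(at$chain[i], chains)
    fr <- .chain_frame(ci)
    xyz2[i, ] <- xyz2[i, ] - collapse_shift * fr$er
  }
  collapsed <- structure_model(at, xyz2, chain_order = chains, sort = FALSE)
  list(conductive = conductive, collapsed = collapsed,
       span = collapse_shift * sqrt(length(moved)),
       sf_selection = "resnum 624-628 and name N CA C O",
       displaced = at[moved, c("chain", "resnum", "atom")])
}

#' Synthetic collapse trajectory with programmed coordinate path
#'
#' Each frame is `A + s_true(t) * (B - A)` plus iid Gaussian positional
#' noise of standard deviation `sigma` on every coordinate of every atom.
#'
#' @param s_true numeric vector (one value per frame) or a function of time
#'   (ps) giving the programmed collapse coordinate.
#' @param times frame times, ps.
#' @param sigma positional noise sd per coordinate, Angstrom.
#' @param seed RNG seed (Mersenne-Twister).
#' @param refs a reference pair from [make_reference_pair()].
#' @return a `trajectory` with attribute `truth`: data.frame
#'   `time`, `s_true`.
#' @export
make_collapse_trajectory <- function(s_true, times, sigma = 0, seed = 1,
                                     refs = make_reference_pair()) {
  if (is.function(s_true)) s_true <- vapply(times, s_true, numeric(1))
  stopifnot(length(s_true) == length(times))
  set.seed(seed)
  A <- refs$conductive$xyz; B <- refs$collapsed$xyz
  D <- B - A
  nf <- length(times); na <- nrow(A)
  coords <- array(NA_real_, c(nf, na, 3))
  for (i in seq_len(nf)) {
    coords[i, , ] <- A + s_true[i] * D +
      if (sigma > 0) matrix(rnorm(na * 3, 0, sigma), na, 3) else 0
  }
  tr <- trajectory(refs$conductive, coords, times = times)
  attr(tr, "truth") <- data.frame(time = times, s_true = s_true)
  tr
}

# default programmed path: linear rise from 0 to the plateau at t_plateau,
# constant afterwards
.ramp_path <- function(plateau, t_plateau = 40000) {
  function(t) if (t >= t_plateau) plateau else plateau * t / t_plateau
}

#' Synthetic distance-scan ensemble
#'
#' For each scan distance d, generates `runs` independent trajectories
#' whose collapse coordinate ramps to the programmed plateau `s_true(d)`
#' at `t_plateau` and stays there, with Gaussian positional noise; the
#' S620-N629 CB separation of the underlying geometry is set to d. When
#' `dir` is given, all trajectories and references are written as
#' (multi-model) PDB plus a YAML manifest and a truth TSV, and the
#' manifest path is returned; otherwise an in-memory manifest is returned.
#'
#' @param d_values scan distances, Angstrom.
#' @param s_true_fn function of d giving the programmed plateau (default
#'   `(10 - d) / 5`).
#' @param runs trajectories per d (default 4).
#' @param times frame times, ps (default 0..50 ns in 1-ns steps).
#' @param sigma positional noise sd, Angstrom (default 0.3).
#' @param seed base RNG seed; run (d, r) uses a deterministic offset.
#' @param t_plateau ramp end, ps.
#' @param dir optional output directory for the file-based manifest.
#' @return manifest list (or path to `manifest.yaml` when `dir` is given)
#'   with attribute `truth`: data.frame `d`, `run`, `s_plateau`.
#' @export
make_scan_ensemble <- function(d_values, s_true_fn = function(d) (10 - d) / 5,
                               runs = 4, times = seq(0, 50000, by = 1000),
                               sigma = 0.3, seed = 1, t_plateau = 40000,
                               dir = NULL) {
  groups <- list(); truth <- list()
  for (gi in seq_along(d_values)) {
    d <- d_values[gi]
    refs <- make_reference_pair(cb_distance = d)
    plateau <- s_true_fn(d)
    trajs <- list()
    for (r in seq_len(runs)) {
      sub_seed <- (seed * 1000L + gi * 100L + r) %% .Machine$integer.max
      trajs[[r]] <- make_collapse_trajectory(.ramp_path(plateau, t_plateau),
                                             times, sigma = sigma,
                                             seed = sub_seed, refs = refs)
      truth[[length(truth) + 1L]] <-
        data.frame(d = d, run = r, s_plateau = plateau)
    }
    groups[[gi]] <- list(d = d, trajectories = trajs, refs = refs)
  }
  truth <- do.call(rbind, truth)
  refs0 <- make_reference_pair()
  manifest <- list(selection = refs0$sf_selection,
                   burn_in = 40000,
                   cb_pair = list(a = list(resnum = 620, atom = "CB"),
                                  b = list(resnum = 629, atom = "CB")),
                   focal_resnum = 629,
                   fit_window = c(5, 11),
                   refs = list(conductive = refs0$conductive,
                               collapsed = refs0$collapsed),
                   groups = groups)
  if (is.null(dir)) {
    attr(manifest, "truth") <- truth
    return(manifest)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pc <- file.path(dir, "ref_conductive.pdb")
  pk <- file.path(dir, "ref_collapsed.pdb")
  write_pdb(refs0$conductive, pc); write_pdb(refs0$collapsed, pk)
  man_file <- list(selection = manifest$selection, burn_in = 40000,
                   cb_pair = manifest$cb_pair, focal_resnum = 629,
                   fit_window = c(5, 11),
                   refs = list(conductive = "ref_conductive.pdb",
                               collapsed = "ref_collapsed.pdb"),
                   groups = list())
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    paths <- character(length(g$trajectories))
    for (r in seq_along(g$trajectories)) {
      paths[r] <- sprintf("traj_d%g_run%d.pdb", g$d, r)
      write_pdb(g$trajectories[[r]], file.path(dir, paths[r]))
    }
    man_file$groups[[gi]] <- list(d = g$d, trajectories = paths)
  }
  yaml::write_yaml(man_file, file.path(dir, "manifest.yaml"))
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  file.path(dir, "manifest.yaml")
}

#' Synthetic intra/inter hydrogen-bond toggle trajectory
#'
#' Per frame, a seeded Bernoulli draw puts every chain's N629 ND2 stand-in
#' either 2.9 Angstrom from its own chain's S620 OG (intra configuration)
#' or 2.9 Angstrom from the next chain's G628 backbone O (inter
#' configuration); all other atoms are static and all competing
#' donor-acceptor distances are kept beyond the default 3.5-Angstrom
#' cutoff.
#'
#' @param n_frames number of frames.
#' @param inter_fraction Bernoulli probability of the inter configuration.
#' @param seed RNG seed.
#' @param dt frame spacing, ps.
#' @return a `trajectory` with attribute `truth`: data.frame `time`,
#'   `state` (`"intra"`/`"inter"`).
#' @export
make_hbond_toggle <- function(n_frames = 500, inter_fraction = 0.3,
                              seed = 1, dt = 10) {
  refs <- make_reference_pair()
  top <- refs$conductive
  set.seed(seed)
  state <- ifelse(runif(n_frames) < inter_fraction, "inter", "intra")
  chains <- top$chain_order
  nd2 <- vapply(chains, function(ch) {
    .lookup_atom(top, list(chain = ch, resnum = 629, atom = "ND2"))
  }, integer(1))
  og <- vapply(chains, function(ch) {
    .lookup_atom(top, list(chain = ch, resnum = 620, atom = "OG"))
  }, integer(1))
  o628 <- vapply(chains, function(ch) {
    .lookup_atom(top, list(chain = ch, resnum = 628, atom = "O"))
  }, integer(1))
  nf <- n_frames; na <- nrow(top$xyz)
  coords <- array(rep(top$xyz, each = nf), c(nf, na, 3))
  for (i in seq_len(nf)) {
    for (ci in seq_along(chains)) {
      fr <- .chain_frame(ci)
      pos <- if (state[i] == "intra") {
        top$xyz[og[ci], ] + 2.9 * fr$er      # outward from own OG
      } else {
        nxt <- ci %% 4L + 1L
        frn <- .chain_frame(nxt)
        top$xyz[o628[nxt], ] + 2.9 * frn$er  # outward from neighbor G628 O
      }
      coords[i, nd2[ci], ] <- pos
    }
  }
  tr <- trajectory(top, coords, times = seq_len(nf) * dt - dt)
  attr(tr, "truth") <- data.frame(time = tr$times, state = state,
                                  stringsAsFactors = FALSE)
  tr
}

.fibonacci_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Spherical-shell cavity structure with analytically known interior
#'
#' A shell of carbon pseudo-atoms (vdW 1.7 Angstrom) on a Fibonacci sphere
#' of radius `shell_radius`, dense enough (spacing ~0.5 Angstrom) that a
#' water-sized probe cannot leak through: the probe-center accessible
#' interior is a sphere of radius `shell_radius - (1.7 + probe_radius)`
#' centred at the origin, so the accessible volume is known in closed form.
#'
#' @param shell_radius shell radius, Angstrom (default 7.7, giving a
#'   4.6-Angstrom accessible interior for a 1.4-Angstrom probe).
#' @param spacing approximate inter-atom spacing on the shell, Angstrom.
#' @return a `structure_model` with attribute `truth`: list
#'   `shell_radius`, `accessible_radius` (for a 1.4 probe),
#'   `accessible_volume`.
#' @export
make_cavity_structure <- function(shell_radius = 7.7, spacing = 0.5) {
  n <- ceiling(4 * pi * shell_radius^2 / spacing^2)
  pts <- .fibonacci_sphere(n, shell_radius)
  atoms <- data.frame(chain = "A", resnum = seq_len(n), resname = "CAV",
                      atom = "C", element = "C", stringsAsFactors = FALSE)
  m <- structure_model(atoms, pts, sort = FALSE)
  r_acc <- shell_radius - (1.7 + 1.4)
  attr(m, "truth") <- list(shell_radius = shell_radius,
                           accessible_radius = r_acc,
                           accessible_volume = 4 / 3 * pi * r_acc^3)
  m
}

#' Open/closed cavity trajectory
#'
#' Frames alternate (or follow `pattern`) between the open shell and a
#' radially shrunk closed shell; atom identities are constant so the
#' frames form a valid trajectory.
#'
#' @param n_frames number of frames.
#' @param pattern logical vector (recycled), `TRUE` = open; default
#'   alternating starting open.
#' @param open_radius,closed_radius shell radii, Angstrom.
#' @param spacing shell atom spacing, Angstrom.
#' @return a `trajectory` with attribute `truth`: data.frame `time`,
#'   `open`, plus `open_volume`/`closed_volume` (analytic, 1.4 probe).
#' @export
make_cavity_trajectory <- function(n_frames = 10, pattern = c(TRUE, FALSE),
                                   open_radius = 7.7, closed_radius = 4.9,
                                   spacing = 0.5) {
  open_struct <- make_cavity_structure(open_radius, spacing)
  scale <- closed_radius / open_radius
  openv <- rep_len(pattern, n_frames)
  na <- nrow(open_struct$xyz)
  coords <- array(NA_real_, c(n_frames, na, 3))
  for (i in seq_len(n_frames)) {
    coords[i, , ] <- if (openv[i]) open_struct$xyz else open_struct$xyz * scale
  }
  tr <- trajectory(open_struct, coords, times = seq_len(n_frames) - 1)
  vol <- function(R) {
    r <- R - 3.1
    if (r <= 0) 0 else 4 / 3 * pi * r^3
  }
  attr(tr, "truth") <- list(
    table = data.frame(time = tr$times, open = openv),
    open_volume = vol(open_radius), closed_volume = vol(closed_radius))
  tr
}

#' Synthetic voltage-clamp recordings with known parameters
#'
#' Generates (i) a normalized tail-current activation table following an
#' ascending Boltzmann, (ii) a single-exponential deactivation trace, and
#' (iii) inactivation test-pulse traces whose 100-ms remaining/instantaneous
#' ratios follow a descending Boltzmann, each with optional Gaussian noise
#' and an exact ground-truth sidecar.
#'
#' @param V_half,k activation Boltzmann parameters, mV (defaults -28.5 and
#'   7.41).
#' @param tau deactivation time constant, ms (default 73.2).
#' @param ss_V_half,ss_k steady-state inactivation Boltzmann parameters,
#'   mV (defaults -18.8 and 7).
#' @param potentials activation test potentials, mV.
#' @param ss_potentials inactivation test potentials, mV.
#' @param tau_inact fast inactivation time constant of the test-pulse
#'   traces, ms.
#' @param noise_sd Gaussian noise sd (normalized units / current units).
#' @param seed RNG seed.
#' @return list with `iv` (V, amplitude), `deactivation` (time, current),
#'   `ss_traces` (list of data.frames time, current, one per
#'   `ss_potentials`), `ss_truth` (V, ratio actually realized at 100 ms),
#'   and `truth` (the generating parameters).
#' @export
make_recordings <- function(V_half = -28.5, k = 7.41, tau = 73.2,
                            ss_V_half = -18.8, ss_k = 7,
                            potentials = seq(-90, 40, by = 10),
                            ss_potentials = seq(-60, 40, by = 10),
                            tau_inact = 20, noise_sd = 0, seed = 1) {
  set.seed(seed)
  noisy <- function(x) if (noise_sd > 0) x + rnorm(length(x), 0, noise_sd) else x
  iv <- data.frame(V = potentials,
                   amplitude = noisy(boltzmann(potentials, V_half, k)))
  t_de <- seq(0, 600, by = 1)
  deact <- data.frame(time = t_de,
                      current = noisy(exp(-t_de / tau)))
  # inactivation test pulses: dense sampling near onset so the
  # instantaneous-amplitude extrapolation is essentially exact
  t_ss <- sort(unique(c(seq(0, 2, by = 0.01), seq(2, 150, by = 0.5))))
  ss_traces <- list(); ss_ratio <- numeric(length(ss_potentials))
  for (i in seq_along(ss_potentials)) {
    r_inf <- boltzmann(ss_potentials[i], ss_V_half, ss_k,
                       direction = "descending")
    cur <- (1 - r_inf) * exp(-t_ss / tau_inact) + r_inf
    ss_ratio[i] <- (1 - r_inf) * exp(-100 / tau_inact) + r_inf
    ss_traces[[i]] <- data.frame(time = t_ss, current = noisy(cur))
  }
  names(ss_traces) <- as.character(ss_potentials)
  list(iv = iv, deactivation = deact, ss_traces = ss_traces,
       ss_truth = data.frame(V = ss_potentials, ratio = ss_ratio),
       truth = list(V_half = V_half, k = k, tau = tau,
                    ss_V_half = ss_V_half, ss_k = ss_k,
                    tau_inact = tau_inact, noise_sd = noise_sd))
}
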