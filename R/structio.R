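# Canonical backbone atom rank used for deterministic atom ordering:
# N, CA, C, O first, then side-chain atoms alphabetically.
.atom_rank <- function(name) {
  bb <- match(name, c("N", "CA", "C", "O"))
  ifelse(is.na(bb), 4L + rank_alpha(name), bb)
}

rank_alpha <- function(x) {
  # stable alphabetical rank within the full name vector
  as.integer(factor(x, levels = sort(unique(x))))
}

#' Construct a structure model
#'
#' A `structure_model` holds an ordered atom table and an N x 3 coordinate
#' matrix in Angstrom. Atoms are sorted deterministically by chain (in
#' `chain_order`), residue number, and canonical atom-name rank (N, CA, C, O,
#' then side-chain atoms alphabetically), so that coordinate vectors built
#' from two models with the same atoms are congruent.
#'
#' @param atoms data.frame with columns `chain`, `resnum`, `resname`, `atom`,
#'   `element`.
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param chain_order optional character vector fixing the cyclic subunit
#'   order; defaults to order of first appearance.
#' @param sort logical; canonically sort atoms (default `TRUE`).
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, xyz, chain_order = NULL, sort = TRUE) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("chain", "resnum", "resname", "atom", "element")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3) {
    stop("xyz must be an n_atoms x 3 matrix")
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (is.null(chain_order)) chain_order <- unique(atoms$chain)
  if (!setequal(chain_order, unique(atoms$chain)) ||
      anyDuplicated(chain_order)) {
    stop("chain_order must list every chain exactly once")
  }
  if (sort) {
    ord <- order(match(atoms$chain, chain_order), atoms$resnum,
                 .atom_rank(atoms$atom))
    atoms <- atoms[ord, , drop = FALSE]
    xyz <- xyz[ord, , drop = FALSE]
  }
  key <- paste(atoms$chain, atoms$resnum, atoms$atom)
  if (anyDuplicated(key)) {
    stop("duplicate atom identity (chain, resnum, atom): ",
         key[anyDuplicated(key)])
  }
  rownames(atoms) <- NULL
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz, chain_order = chain_order),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d chain(s) [%s], %d residue(s)\n",
              nrow(x$atoms), length(x$chain_order),
              paste(x$chain_order, collapse = ","),
              nrow(unique(x$atoms[c("chain", "resnum")]))))
  invisible(x)
}

#' Construct a trajectory
#'
#' Frames are stored as an `n_frames x n_atoms x 3` array congruent with the
#' topology model's atom order; times are in picoseconds and must be strictly
#' increasing.
#'
#' @param topology a `structure_model` describing every frame's atoms.
#' @param coords array `n_frames x n_atoms x 3` (Angstrom), or a list of
#'   `n_atoms x 3` matrices.
#' @param times numeric vector of frame times in ps; defaults to
#'   `0, 1, 2, ...`.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(topology, coords, times = NULL) {
  stopifnot(inherits(topology, "structure_model"))
  if (is.list(coords)) {
    coords <- aperm(simplify2array(coords), c(3, 1, 2))
  }
  if (length(dim(coords)) != 3 || dim(coords)[2] != nrow(topology$atoms) ||
      dim(coords)[3] != 3) {
    stop("coords must be n_frames x n_atoms x 3 and match the topology")
  }
  n <- dim(coords)[1]
  if (is.null(times)) times <- seq_len(n) - 1
  if (length(times) != n) stop("times length must equal frame count")
  if (n > 1 && any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(topology = topology, coords = coords, times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, t = %g..%g ps\n",
              dim(x$coords)[1], dim(x$coords)[2],
              min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as a coordinate matrix
#' @param traj a `trajectory`.
#' @param i frame index (1-based).
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(traj, i) {
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  colnames(m) <- c("x", "y", "z")
  m
}

.infer_element <- function(atom_name) {
  # strip digits/primes; for 4-char names starting with digit (e.g. 1HB1)
  nm <- gsub("[0-9']", "", atom_name)
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "MN"),
         substr(paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))), 1, 2),
         substr(nm, 1, 1))
}

#' Read a PDB file
#'
#' Parses fixed-column `ATOM` records; `HETATM` records are ignored and
#' alternate locations other than blank or `'A'` are dropped. Insertion codes
#' are rejected. A single-`MODEL` (or model-less) file yields a
#' `structure_model`; a multi-model file yields a `trajectory` whose frames
#' are the `MODEL`/`ENDMDL` blocks with times `0, 1, 2, ...` ps unless
#' `times` is given.
#'
#' @param path path to a PDB file.
#' @param times optional frame times (ps) for multi-model files.
#' @param sort canonically sort atoms (default `TRUE`); the same order is
#'   applied to every model.
#' @return a `structure_model` or a `trajectory`.
#' @export
read_pdb <- function(path, times = NULL, sort = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- substr(rec, 1, 4) == "ATOM"
  is_model <- rec == "MODEL "
  is_end <- rec == "ENDMDL"
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id[] <- 1L
  model_id[model_id == 0L] <- 1L

  atom_idx <- which(is_atom)
  if (!length(atom_idx)) stop("no ATOM records in ", path)
  al <- lines[atom_idx]
  bad <- nchar(al) < 54
  if (any(bad)) {
    stop("malformed ATOM line ", atom_idx[which(bad)[1]], " in ", path,
         " (shorter than 54 columns)")
  }
  name <- trimws(substr(al, 13, 16))
  altloc <- substr(al, 17, 17)
  resname <- trimws(substr(al, 18, 20))
  chain <- substr(al, 22, 22)
  resnum <- suppressWarnings(as.integer(substr(al, 23, 26)))
  icode <- substr(al, 27, 27)
  x <- suppressWarnings(as.numeric(substr(al, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(al, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(al, 47, 54)))
  elem <- trimws(substr(al, 77, 78))
  bad <- is.na(resnum) | is.na(x) | is.na(y) | is.na(z)
  if (any(bad)) {
    stop("malformed ATOM line ", atom_idx[which(bad)[1]], " in ", path)
  }
  if (any(icode != " ")) {
    stop("insertion codes not supported (line ",
         atom_idx[which(icode != " ")[1]], ")")
  }
  keep <- altloc %in% c(" ", "A")
  name <- name[keep]; resname <- resname[keep]; chain <- chain[keep]
  resnum <- resnum[keep]; elem <- elem[keep]
  xyz <- cbind(x = x[keep], y = y[keep], z = z[keep])
  mid <- model_id[atom_idx][keep]
  elem[elem == ""] <- .infer_element(name[elem == ""])

  split_idx <- split(seq_along(mid), mid)
  n_models <- length(split_idx)
  first <- split_idx[[1]]
  atoms <- data.frame(chain = chain[first], resnum = resnum[first],
                      resname = resname[first], atom = name[first],
                      element = elem[first], stringsAsFactors = FALSE)
  model1 <- structure_model(atoms, xyz[first, , drop = FALSE], sort = sort)
  if (n_models == 1L) return(model1)

  # multi-model: check topology consistency, reuse model-1 canonical order
  key1 <- paste(chain[first], resnum[first], name[first])
  # mapping from each model's raw order to the canonical model-1 order
  canon_key <- paste(model1$atoms$chain, model1$atoms$resnum, model1$atoms$atom)
  frames <- array(NA_real_, c(n_models, nrow(model1$atoms), 3))
  for (m in seq_len(n_models)) {
    idx <- split_idx[[m]]
    keym <- paste(chain[idx], resnum[idx], name[idx])
    if (length(idx) != length(first) || !setequal(keym, key1)) {
      stop("topology mismatch: model ", m, " has different atoms than model 1")
    }
    frames[m, , ] <- xyz[idx[match(canon_key, keym)], , drop = FALSE]
  }
  if (is.null(times)) {
    # REMARK 250 TIME records written by write_pdb(), one per model
    tl <- grepl("^REMARK 250 TIME ", lines)
    if (sum(tl) == n_models) {
      times <- as.numeric(sub("^REMARK 250 TIME +([-0-9.eE+]+) PS.*$", "\\1",
                              lines[tl]))
    }
  }
  trajectory(model1, frames, times = times)
}

.format_atom_name <- function(name, element) {
  # standard PDB alignment: element-aligned at column 14 for short names
  ifelse(nchar(name) >= 4, sprintf("%-4s", name),
         ifelse(nchar(element) == 2,
                sprintf("%-4s", name),
                sprintf(" %-3s", name)))
}

#' Write a PDB file
#'
#' Writes fixed-column `ATOM` records; a `trajectory` is written as one
#' `MODEL`/`ENDMDL` block per frame. Coordinates are rounded to 3 decimals
#' (PDB precision).
#'
#' @param x a `structure_model` or `trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt_block <- function(model, xyz) {
    a <- model$atoms
    sprintf("ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            seq_len(nrow(a)) %% 100000L,
            .format_atom_name(a$atom, a$element), " ",
            a$resname, a$chain, a$resnum, " ",
            xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
            toupper(a$element))
  }
  if (inherits(x, "structure_model")) {
    writeLines(fmt_block(x, x$xyz), con)
    writeLines("END", con)
  } else if (inherits(x, "trajectory")) {
    for (m in seq_len(n_frames(x))) {
      writeLines(sprintf("MODEL %8d", m), con)
      # keep frame times across round trips
      writeLines(sprintf("REMARK 250 TIME %.6f PS", x$times[m]), con)
      writeLines(fmt_block(x$topology, frame_coords(x, m)), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    stop("x must be a structure_model or trajectory")
  }
  invisible(path)
}

#' Select atoms by expression
#'
#' The selection grammar is a conjunction of clauses joined by `and`:
#' \describe{
#'   \item{`chain A B`}{one or more chain ids}
#'   \item{`resnum 624-627` or `resnum 620 629`}{residue numbers or ranges}
#'   \item{`resname SER ASN`}{3-letter residue codes}
#'   \item{`name O OG1`}{PDB atom names}
#'   \item{`element N O`}{element symbols}
#' }
#' e.g. `"resnum 624-627 and name O"`. Matching is case-sensitive for names.
#' An empty result is allowed and is not an error.
#'
#' @param model a `structure_model`.
#' @param expression selection text.
#' @return an `atom_selection`: integer indices into the model's atom order
#'   with the originating expression attached.
#' @export
select_atoms <- function(model, expression) {
  stopifnot(inherits(model, "structure_model"))
  toks <- strsplit(trimws(expression), "[[:space:]]+")[[1]]
  if (!length(toks) || toks[1] == "") stop("empty selection expression")
  keep <- rep(TRUE, nrow(model$atoms))
  i <- 1
  keywords <- c("chain", "resnum", "resname", "name", "element")
  while (i <= length(toks)) {
    kw <- toks[i]
    if (!kw %in% keywords) {
      stop(sprintf("selection syntax error at token %d ('%s'): expected one of %s",
                   i, kw, paste(keywords, collapse = "/")))
    }
    j <- i + 1
    vals <- character(0)
    while (j <= length(toks) && !toks[j] %in% c("and", keywords)) {
      vals <- c(vals, toks[j]); j <- j + 1
    }
    if (!length(vals)) {
      stop(sprintf("selection syntax error at token %d: '%s' needs a value",
                   i, kw))
    }
    hit <- switch(kw,
      chain   = model$atoms$chain %in% vals,
      resname = model$atoms$resname %in% vals,
      name    = model$atoms$atom %in% vals,
      element = model$atoms$element %in% vals,
      resnum  = {
        nums <- integer(0)
        for (v in vals) {
          if (grepl("^-?[0-9]+--?[0-9]+$", v) || grepl("^[0-9]+-[0-9]+$", v)) {
            ab <- as.integer(strsplit(v, "(?<=[0-9])-", perl = TRUE)[[1]])
            nums <- c(nums, seq(ab[1], ab[2]))
          } else if (grepl("^-?[0-9]+$", v)) {
            nums <- c(nums, as.integer(v))
          } else {
            stop(sprintf("selection syntax error: bad resnum '%s'", v))
          }
        }
        model$atoms$resnum %in% nums
      })
    keep <- keep & hit
    if (j <= length(toks)) {
      if (toks[j] != "and") {
        stop(sprintf("selection syntax error at token %d ('%s'): expected 'and'",
                     j, toks[j]))
      }
      j <- j + 1
      if (j > length(toks)) stop("selection syntax error: trailing 'and'")
    }
    i <- j
  }
  structure(which(keep), expression = expression, class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("<atom_selection> %d atom(s) from \"%s\"\n",
              length(x), attr(x, "expression")))
  invisible(x)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (determinant +1, never a reflection) and
#' translation minimizing the RMSD of `mobile` onto `reference`.
#'
#' @param mobile,reference `n x 3` coordinate matrices, equal `n >= 3`.
#' @return a `superposition`: list with `rotation` (3 x 3), `translation`
#'   (length 3) and `rmsd` (Angstrom). The fitted mobile coordinates are
#'   `mobile %*% rotation + translation` (rows).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3 ||
      ncol(reference) != 3) {
    stop("mobile and reference must be equal-size n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm); R0 <- sweep(reference, 2, cr)
  C <- crossprod(M, R0)                       # 3x3 covariance
  sv <- svd(C)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1)) {
    stop("degenerate point set (collinear or coincident): cannot superpose")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  Rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)  # maps centered mobile
  Rot <- t(Rot)                                  # row-vector convention
  fitted <- M %*% Rot
  rmsd <- sqrt(sum((fitted - R0)^2) / n)
  translation <- as.numeric(cr - cm %*% Rot)
  structure(list(rotation = Rot, translation = translation, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param sp a `superposition` from [superpose()].
#' @param xyz `n x 3` coordinates.
#' @return transformed `n x 3` coordinates.
#' @export
apply_superposition <- function(sp, xyz) {
  sweep(as.matrix(xyz) %*% sp$rotation, 2, sp$translation, "+")
}

.lookup_atom <- function(model, spec) {
  # spec: list/vector with chain, resnum, atom
  i <- which(model$atoms$chain == spec[["chain"]] &
             model$atoms$resnum == as.integer(spec[["resnum"]]) &
             model$atoms$atom == spec[["atom"]])
  if (!length(i)) {
    stop(sprintf("no atom %s/%s/%s in model",
                 spec[["chain"]], spec[["resnum"]], spec[["atom"]]))
  }
  i[1]
}

#' Interatomic distance
#'
#' Euclidean distance between two atoms of a model (or of one trajectory
#' frame), each given as `list(chain=, resnum=, atom=)`.
#'
#' @param model a `structure_model`, or a `trajectory` together with `frame`.
#' @param a,b atom specs: `list(chain, resnum, atom)`.
#' @param frame frame index when `model` is a trajectory.
#' @return distance in Angstrom.
#' @seealso [pair_distance_by_chain()] for the per-subunit variant.
#' @export
pair_distance <- function(model, a, b, frame = NULL) {
  if (inherits(model, "trajectory")) {
    xyz <- frame_coords(model, if (is.null(frame)) 1L else frame)
    model <- list(atoms = model$topology$atoms)
  } else {
    xyz <- model$xyz
  }
  ia <- .lookup_atom(model, a); ib <- .lookup_atom(model, b)
  sqrt(sum((xyz[ia, ] - xyz[ib, ])^2))
}

#' Per-subunit interatomic distances
#'
#' Measures the same intra-chain atom pair (e.g. S620 CB to N629 CB) in every
#' chain of the model.
#'
#' @param model a `structure_model` or `trajectory` (with `frame`).
#' @param a,b atom specs `list(resnum, atom)`; chain iterates over
#'   `chain_order`.
#' @param frame frame index for trajectories.
#' @return named numeric vector, one distance (Angstrom) per chain.
#' @export
pair_distance_by_chain <- function(model, a, b, frame = NULL) {
  top <- if (inherits(model, "trajectory")) model$topology else model
  out <- vapply(top$chain_order, function(ch) {
    pair_distance(model,
                  c(a, chain = ch),
                  c(b, chain = ch), frame = frame)
  }, numeric(1))
  names(out) <- top$chain_order
  out
}
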