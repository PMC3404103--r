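# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths (no Kabsch, no vectorized grids).

# --- rotation-grid RMSD oracle: nested exhaustive search over Euler angles
euler_rot <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

oracle_rmsd_grid <- function(mobile, reference, levels = 4, n0 = 13) {
  M <- sweep(mobile, 2, colMeans(mobile))
  R0 <- sweep(reference, 2, colMeans(reference))
  rmsd_of <- function(a, b, c) {
    sqrt(mean(rowSums((M %*% t(euler_rot(a, b, c)) - R0)^2)))
  }
  lo <- c(-pi, 0, -pi); hi <- c(pi, pi, pi)
  best <- c(0, 0, 0); best_val <- Inf
  for (lev in seq_len(levels)) {
    as <- seq(lo[1], hi[1], length.out = n0)
    bs <- seq(lo[2], hi[2], length.out = n0)
    cs <- seq(lo[3], hi[3], length.out = n0)
    for (a in as) for (b in bs) for (c in cs) {
      v <- rmsd_of(a, b, c)
      if (v < best_val) { best_val <- v; best <- c(a, b, c) }
    }
    w <- (hi - lo) / (n0 - 1)
    lo <- best - w; hi <- best + w
  }
  best_val
}

# --- two-structure PCA oracle: explicit eigen-decomposition of the 3N x 3N
# covariance of the two flattened conformations
oracle_pca_pc1 <- function(A, B) {
  X <- rbind(as.vector(t(A)), as.vector(t(B)))
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc), symmetric = TRUE)
  ev$vectors[, 1]
}

# --- all-pairs H-bond oracle (plain double loop, heavy-atom mode)
oracle_hbonds_heavy <- function(model, donor_idx, acceptor_idx,
                                max_da = 3.5, min_ante = 90) {
  at <- model$atoms; xyz <- model$xyz
  found <- list()
  for (d in donor_idx) {
    for (a in acceptor_idx) {
      if (a == d) next
      if (at$chain[a] == at$chain[d] && at$resnum[a] == at$resnum[d]) next
      dist <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
      if (dist > max_da || dist < 1.6) next
      # antecedent angle test
      ante_ok <- TRUE
      ante <- which(at$element != "H" & at$chain == at$chain[d] &
                    at$resnum == at$resnum[d])
      ante <- setdiff(ante, d)
      ante <- ante[vapply(ante, function(i) {
        sqrt(sum((xyz[i, ] - xyz[d, ])^2)) < 1.8
      }, logical(1))]
      if (length(ante)) {
        angs <- vapply(ante, function(cc) {
          v1 <- xyz[cc, ] - xyz[d, ]; v2 <- xyz[a, ] - xyz[d, ]
          acos(min(1, max(-1, sum(v1 * v2) /
                            sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        }, numeric(1))
        ante_ok <- max(angs) >= min_ante
      }
      if (ante_ok) found[[length(found) + 1L]] <- c(d, a)
    }
  }
  if (!length(found)) return(matrix(integer(0), 0, 2))
  m <- do.call(rbind, found)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# --- naive grid accessibility oracle: point x atom double loop on the same
# grid construction (center-anchored cubic grid clipped to the sphere)
oracle_accessible_points <- function(model, center, region_radius,
                                     probe_radius, h, radii = vdw_radii()) {
  m <- ceiling(region_radius / h)
  ax <- seq(-m, m) * h
  heavy <- which(model$atoms$element != "H")
  excl <- radii[model$atoms$element[heavy]] + probe_radius
  pts <- list()
  for (i in seq_along(ax)) for (j in seq_along(ax)) for (k in seq_along(ax)) {
    p <- c(ax[i], ax[j], ax[k])
    if (sum(p^2) > region_radius^2) next
    acc <- TRUE
    for (q in seq_along(heavy)) {
      dp <- model$xyz[heavy[q], ] - center - p
      if (sum(dp^2) < excl[q]^2) { acc <- FALSE; break }
    }
    if (acc) pts[[length(pts) + 1L]] <- p + center
  }
  if (!length(pts)) return(matrix(numeric(0), 0, 3))
  do.call(rbind, pts)
}

# canonical string form of a point set for exact comparison
point_key <- function(m) {
  sort(apply(round(m, 6), 1, paste, collapse = ","))
}

# --- small toy builders
toy_model <- function(xyz, chain = "A", resnum = NULL, atom = NULL,
                      resname = "GLY", element = NULL) {
  n <- nrow(xyz)
  if (is.null(resnum)) resnum <- seq_len(n)
  if (is.null(atom)) atom <- rep("CA", n)
  if (is.null(element)) element <- substr(atom, 1, 1)
  structure_model(data.frame(chain = rep_len(chain, n),
                             resnum = rep_len(resnum, n),
                             resname = rep_len(resname, n),
                             atom = rep_len(atom, n),
                             element = rep_len(element, n),
                             stringsAsFactors = FALSE),
                  xyz)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
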