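refs <- make_reference_pair()
rc <- build_reaction_coordinate(refs$conductive, refs$collapsed,
                                refs$sf_selection)

test_that("a rigidly moved reference yields a degenerate coordinate", {
  m <- refs$conductive
  shifted <- structure_model(m$atoms, sweep(m$xyz, 2, c(3, -1, 2), "+"),
                             chain_order = m$chain_order, sort = FALSE)
  expect_error(build_reaction_coordinate(m, shifted, refs$sf_selection),
               "degenerate")
})

test_that("single-atom displacement gives span 2 and a localized vector", {
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(1, 1, 3))
  a <- toy_model(xyz, resnum = 1:4)
  b <- toy_model(xyz + rbind(0, 0, 0, c(0, 0, 2)), resnum = 1:4)
  # shared frame, raw difference: span is exactly the displacement norm and
  # the vector is supported on the moved atom's 3 components
  rc1 <- build_reaction_coordinate(a, b, "resnum 1-4", superpose_refs = FALSE)
  expect_equal(rc1$span, 2.0, tolerance = 1e-12)
  w <- rowSums(rc1$unit_mat^2)
  expect_equal(unname(w), c(0, 0, 0, 1), tolerance = 1e-12)
  # with superposition, the fitted span is strictly smaller (the rigid part
  # of the single-atom move is absorbed) but the moved atom still dominates
  rc2 <- build_reaction_coordinate(a, b, "resnum 1-4")
  expect_lt(rc2$span, 2.0)
  expect_gt(rowSums(rc2$unit_mat^2)[4], 0.5)
})

test_that("the difference vector equals PC1 of a two-structure PCA", {
  set.seed(21)
  for (rep in 1:20) {
    A <- matrix(rnorm(24, sd = 3), 8, 3)
    B <- A + matrix(rnorm(24, sd = 0.5), 8, 3)
    ma <- toy_model(A, resnum = 1:8)
    mb <- toy_model(B, resnum = 1:8)
    rcx <- build_reaction_coordinate(ma, mb, "resnum 1-8")
    pc1 <- oracle_pca_pc1(rcx$ref_a, rcx$ref_b)
    cosang <- abs(sum(rcx$unit_vector * pc1))
    expect_gte(cosang, 1 - 1e-9)
  }
})

test_that("projection is exactly linear along the A-to-B segment", {
  A <- refs$conductive$xyz; B <- refs$collapsed$xyz
  for (alpha in c(-0.5, 0, 0.25, 0.5, 1, 1.3)) {
    s <- project_frame(A + alpha * (B - A), rc, topology = refs$conductive)
    expect_equal(s, alpha, tolerance = 1e-9)
  }
})

test_that("projection is invariant under rigid motion of the frame", {
  set.seed(31)
  A <- refs$conductive$xyz; B <- refs$collapsed$xyz
  fr <- A + 0.6 * (B - A)
  for (rep in 1:5) {
    R <- random_rotation()
    moved <- sweep(fr %*% R, 2, rnorm(3, sd = 10), "+")
    expect_equal(project_frame(moved, rc, topology = refs$conductive), 0.6,
                 tolerance = 1e-9)
  }
})

test_that("noise orthogonal to the difference vector does not move s", {
  set.seed(32)
  idx <- select_atoms(refs$conductive, refs$sf_selection)
  A <- refs$conductive$xyz; B <- refs$collapsed$xyz
  fr <- A + 1.3 * (B - A)
  # Gram-Schmidt: random selection-space perturbation minus its component
  # along the unit vector; keep it tiny so re-superposition stays identity
  noise <- matrix(rnorm(length(idx) * 3, sd = 1e-4), length(idx), 3)
  noise <- noise - sum(noise * rc$unit_mat) * rc$unit_mat
  fr[idx, ] <- fr[idx, ] + noise
  expect_equal(project_frame(fr, rc, topology = refs$conductive), 1.3,
               tolerance = 1e-6)
})

test_that("endpoint projection averages only past the burn-in", {
  tr <- make_collapse_trajectory(function(t) 0.7, seq(0, 50000, 1000),
                                 sigma = 0, seed = 1, refs = refs)
  expect_equal(endpoint_projection(tr, rc), 0.7, tolerance = 1e-9)
  # ramp 0->1 over 0-40 ns then plateau: default burn-in keeps the plateau
  tr2 <- make_collapse_trajectory(function(t) min(t / 40000, 1),
                                  seq(0, 50000, 1000), sigma = 0, seed = 1,
                                  refs = refs)
  expect_equal(endpoint_projection(tr2, rc), 1.0, tolerance = 1e-9)
  # with an explicit later burn-in the mean shifts accordingly
  expect_equal(endpoint_projection(tr2, rc, burn_in = 45000), 1.0,
               tolerance = 1e-9)
  expect_error(endpoint_projection(tr2, rc, burn_in = 60000), "burn-in")
})

test_that("ensemble traces combine runs into mean and SEM", {
  tr <- make_collapse_trajectory(function(t) 0.4, seq(0, 5000, 1000),
                                 sigma = 0, seed = 1, refs = refs)
  et <- ensemble_trace(list(tr, tr, tr, tr), rc)
  expect_equal(et$sem_s, rep(0, nrow(et)))
  expect_equal(et$mean_s, rep(0.4, nrow(et)), tolerance = 1e-9)
  tr0 <- make_collapse_trajectory(function(t) 0, seq(0, 5000, 1000),
                                  sigma = 0, seed = 1, refs = refs)
  tr1 <- make_collapse_trajectory(function(t) 1, seq(0, 5000, 1000),
                                  sigma = 0, seed = 1, refs = refs)
  et2 <- ensemble_trace(list(tr0, tr1), rc)
  expect_equal(et2$mean_s, rep(0.5, nrow(et2)), tolerance = 1e-9)
  # sd(0,1) = 0.7071, sem = sd/sqrt(2) = 0.5
  expect_equal(et2$sem_s, rep(0.5, nrow(et2)), tolerance = 1e-9)
  expect_error(ensemble_trace(list(tr0), rc), "at least 2")
})

test_that("the 2-SEM band covers the programmed mean about 95% of the time", {
  set.seed(55)
  times <- seq(0, 2000, 500)
  covered <- 0L; total <- 0L
  for (rep in 1:400) {
    traces <- lapply(1:4, function(i) {
      off <- rnorm(1, 0, 0.2)
      data.frame(time = times, s = 0.5 + off,
                 s_angstrom = NA) |>
        structure(class = c("projection_trace", "data.frame"))
    })
    et <- ensemble_trace(traces)
    hit <- abs(et$mean_s - 0.5) <= 2 * et$sem_s
    covered <- covered + sum(hit); total <- total + length(hit)
  }
  # with n = 4 runs the 2-SEM band is a t(3) interval: true coverage is
  # P(|t3| <= 2) = 0.861, not the asymptotic 0.95; accept a band around it
  expect_gt(covered / total, 0.80)
  expect_lt(covered / total, 0.93)
})
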