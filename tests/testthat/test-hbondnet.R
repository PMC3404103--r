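# two-residue toy: donor N (with H) on residue 1, acceptor O on residue 2
hb_toy <- function(da, h_angle_deg = 0, with_h = TRUE) {
  # donor at origin, acceptor along +x at distance da, hydrogen at 1.0 A
  # from the donor, rotated h_angle off the D->A line
  th <- h_angle_deg * pi / 180
  hpos <- c(cos(th), sin(th), 0)
  atoms <- data.frame(
    chain = "A", resnum = c(1, 1, 2),
    resname = c("ASN", "ASN", "GLY"),
    atom = c("ND2", "HD2", "O"),
    element = c("N", "H", "O"), stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 0, 0), hpos, c(da, 0, 0))
  if (!with_h) {
    atoms <- atoms[-2, ]; xyz <- xyz[-2, , drop = FALSE]
  }
  structure_model(atoms, xyz, sort = FALSE)
}

test_that("distance and hydrogen-angle criteria gate detection", {
  crit <- hbond_criteria(hydrogen_mode = "explicit")
  m <- hb_toy(2.9, 0)
  b <- detect_hbonds(m, "name ND2", "name O", crit)
  expect_equal(nrow(b), 1)
  expect_equal(b$da_distance, 2.9)
  expect_equal(b$hda_angle, 0, tolerance = 1e-9)
  expect_equal(b$type, "intra")
  expect_equal(nrow(detect_hbonds(hb_toy(4.0, 0), "name ND2", "name O",
                                  crit)), 0)
  expect_equal(nrow(detect_hbonds(hb_toy(2.9, 45), "name ND2", "name O",
                                  crit)), 0)
  # heavy-atom mode ignores the hydrogen entirely
  expect_equal(nrow(detect_hbonds(hb_toy(2.9, 45, with_h = FALSE),
                                  "name ND2", "name O",
                                  hbond_criteria())), 1)
})

test_that("explicit mode without hydrogens instructs heavy-atom mode", {
  m <- hb_toy(2.9, with_h = FALSE)
  expect_error(detect_hbonds(m, "name ND2", "name O",
                             hbond_criteria(hydrogen_mode = "explicit")),
               "heavy")
})

test_that("detection matches the all-pairs brute-force oracle", {
  set.seed(17)
  for (rep in 1:20) {
    n <- 30
    atoms <- data.frame(
      chain = sample(c("A", "B"), n, replace = TRUE),
      resnum = seq_len(n),
      resname = "GLY",
      atom = sample(c("N", "O"), n, replace = TRUE),
      element = NA, stringsAsFactors = FALSE)
    atoms$element <- atoms$atom
    m <- structure_model(atoms, matrix(runif(n * 3, 0, 12), n, 3))
    di <- which(m$atoms$element == "N")
    ai <- which(m$atoms$element == "O")
    b <- detect_hbonds(m, structure(di, class = "atom_selection"),
                       structure(ai, class = "atom_selection"))
    ours <- cbind(b$donor, b$acceptor)
    oracle <- oracle_hbonds_heavy(m, di, ai)
    expect_equal(unname(ours), unname(oracle), ignore_attr = TRUE)
  }
})

test_that("enlarging the distance cutoff never removes a bond", {
  set.seed(23)
  n <- 25
  atoms <- data.frame(chain = sample(c("A", "B"), n, TRUE), resnum = 1:n,
                      resname = "GLY", atom = sample(c("N", "O"), n, TRUE),
                      element = NA, stringsAsFactors = FALSE)
  atoms$element <- atoms$atom
  m <- structure_model(atoms, matrix(runif(n * 3, 0, 10), n, 3))
  di <- structure(which(m$atoms$element == "N"), class = "atom_selection")
  ai <- structure(which(m$atoms$element == "O"), class = "atom_selection")
  key <- function(b) paste(b$donor, b$acceptor)
  b1 <- detect_hbonds(m, di, ai, hbond_criteria(max_da_distance = 3.0))
  b2 <- detect_hbonds(m, di, ai, hbond_criteria(max_da_distance = 3.8))
  expect_true(all(key(b1) %in% key(b2)))
})

test_that("detection is invariant under rigid motion and chain relabeling", {
  tg <- make_hbond_toggle(n_frames = 5, inter_fraction = 0.5, seed = 2)
  top <- tg$topology
  fr <- frame_coords(tg, 1)
  b0 <- detect_hbonds(fr, "element N", "element O", topology = top)
  set.seed(3)
  R <- random_rotation()
  b1 <- detect_hbonds(sweep(fr %*% R, 2, c(3, 2, -9), "+"),
                      "element N", "element O", topology = top)
  expect_equal(b0[c("donor", "acceptor", "type")],
               b1[c("donor", "acceptor", "type")])
  expect_equal(b0$da_distance, b1$da_distance, tolerance = 1e-9)
  # relabel chains cyclically: bond types are label-independent
  at2 <- top$atoms
  at2$chain <- c(A = "B", B = "C", C = "D", D = "A")[at2$chain]
  top2 <- structure_model(at2, fr, chain_order = c("B", "C", "D", "A"),
                          sort = FALSE)
  b2 <- detect_hbonds(top2, "element N", "element O")
  expect_equal(sort(table(b0$type)), sort(table(b2$type)))
})

test_that("the focal-residue series splits counts by subunit correctly", {
  tg <- make_hbond_toggle(n_frames = 60, inter_fraction = 0.4, seed = 8)
  truth <- attr(tg, "truth")
  hb <- hbond_series(tg)
  # conservation: intra frames contribute no inter bonds and vice versa
  expect_true(all(hb$n_inter[truth$state == "intra"] == 0))
  expect_true(all(hb$n_intra[truth$state == "inter"] == 0))
  expect_true(all((hb$n_intra + hb$n_inter) > 0))
  # inter bonds connect N629 ND2 to the neighboring-chain G628 carbonyl
  i <- which(truth$state == "inter")[1]
  b <- detect_hbonds(frame_coords(tg, i),
                     structure(which(tg$topology$atoms$atom == "ND2"),
                               class = "atom_selection"),
                     "element O", topology = tg$topology)
  g628 <- b[tg$topology$atoms$resnum[b$acceptor] == 628, ]
  expect_true(all(g628$type == "inter"))
  expect_gt(nrow(g628), 0)
})

test_that("contact fractions split windows and guard empty denominators", {
  s <- data.frame(time = 0:9,
                  n_intra = c(2, 2, 2, 2, 2, 0, 0, 0, 0, 0),
                  n_inter = c(0, 0, 0, 0, 0, 2, 2, 2, 2, 0))
  class(s) <- c("hbond_series", "data.frame")
  cf <- contact_fraction(s)
  expect_equal(cf$intra_fraction, 10 / 18)
  expect_equal(cf$inter_fraction, 8 / 18)
  cf2 <- contact_fraction(s, window = 5)
  expect_equal(cf2$intra_fraction, c(1, 0))
  expect_equal(cf2$inter_fraction, c(0, 1))
  empty <- data.frame(time = 0:1, n_intra = c(0, 0), n_inter = c(0, 0))
  class(empty) <- c("hbond_series", "data.frame")
  expect_true(is.na(contact_fraction(empty)$intra_fraction))
  expect_error(contact_fraction(s, window = 99), "window")
})

test_that("smoothing preserves the series mean", {
  tg <- make_hbond_toggle(n_frames = 80, inter_fraction = 0.3, seed = 4)
  hb <- hbond_series(tg)
  sm <- smooth_hbond_series(hb, window = 9)
  expect_equal(mean(sm$n_inter_smooth), mean(hb$n_inter), tolerance = 0.1)
  expect_equal(nrow(sm), nrow(hb))
})
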