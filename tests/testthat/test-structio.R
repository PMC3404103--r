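test_that("PDB write/read round-trips a single model to 3 decimals", {
  refs <- make_reference_pair()
  m <- refs$conductive
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, f)
  m2 <- read_pdb(f)
  expect_s3_class(m2, "structure_model")
  expect_equal(m2$atoms[c("chain", "resnum", "resname", "atom", "element")],
               m$atoms[c("chain", "resnum", "resname", "atom", "element")])
  expect_equal(m2$xyz, round(m$xyz, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("PDB round-trip preserves trajectories, frame times included", {
  refs <- make_reference_pair()
  tr <- make_collapse_trajectory(c(0, 0.5, 1), times = c(0, 500, 1500),
                                 sigma = 0.1, seed = 3, refs = refs)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(tr, f)
  tr2 <- read_pdb(f)
  expect_s3_class(tr2, "trajectory")
  expect_equal(n_frames(tr2), 3)
  expect_equal(tr2$times, c(0, 500, 1500))
  expect_equal(tr2$coords, round(tr$coords, 3), tolerance = 1e-9)
})

test_that("a hand-written multi-model file parses into frames 0,1,2 ps", {
  lines <- character(0)
  for (m in 1:3) {
    lines <- c(lines, sprintf("MODEL %8d", m))
    for (i in 1:10) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, i, i + m / 10, 0, 0))
    }
    lines <- c(lines, "ENDMDL")
  }
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  tr <- read_pdb(f)
  expect_s3_class(tr, "trajectory")
  expect_equal(n_frames(tr), 3)
  expect_equal(tr$times, c(0, 1, 2))
  expect_equal(dim(tr$coords)[2], 10)
  expect_equal(tr$coords[2, 1, 1], 1.2)
})

test_that("ATOM records land in the fixed columns", {
  m <- toy_model(matrix(c(1.5, -2.25, 300.125), 1, 3),
                 resnum = 7, atom = "CA", resname = "ALA")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, f)
  line <- readLines(f)[1]
  expect_identical(substr(line, 1, 6), "ATOM  ")
  expect_identical(substr(line, 13, 16), " CA ")
  expect_identical(substr(line, 18, 20), "ALA")
  expect_identical(substr(line, 22, 22), "A")
  expect_identical(substr(line, 23, 26), "   7")
  expect_identical(substr(line, 31, 38), "   1.500")
  expect_identical(substr(line, 39, 46), "  -2.250")
  expect_identical(substr(line, 47, 54), " 300.125")
  expect_identical(substr(line, 77, 78), " C")
})

test_that("parser rejects malformed lines with a line number", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  GLY A   1       1.000   2.000   3.000",
               "ATOM      2  CA  GLY"), f)
  expect_error(read_pdb(f), "line 2")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00",
    "ATOM      2  CA  GLY A   2A      1.000   2.000   3.000  1.00  0.00"), f)
  expect_error(read_pdb(f), "insertion code")
})

test_that("inconsistent atom counts across models raise a topology error", {
  refs <- make_reference_pair()
  f <- withr::local_tempfile(fileext = ".pdb")
  tr <- make_collapse_trajectory(c(0, 1), times = c(0, 1), refs = refs)
  write_pdb(tr, f)
  lines <- readLines(f)
  atom_lines <- which(startsWith(lines, "ATOM"))
  writeLines(lines[-atom_lines[length(atom_lines)]], f)
  expect_error(read_pdb(f), "topology mismatch")
})

test_that("altloc B records are dropped, blank and A kept", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA BGLY A   1       9.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  GLY A   1       2.000   0.000   0.000  1.00  0.00           C"), f)
  m <- read_pdb(f)
  expect_equal(nrow(m$atoms), 2)
  expect_false(9 %in% m$xyz[, 1])
})

test_that("bio3d reads back what write_pdb produced", {
  refs <- make_reference_pair()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(refs$conductive, f)
  b <- bio3d::read.pdb(f)
  expect_equal(nrow(b$atom), nrow(refs$conductive$atoms))
  ours <- refs$conductive
  theirs <- matrix(b$xyz, ncol = 3, byrow = TRUE)
  # bio3d keeps file order == our canonical order
  expect_equal(theirs, round(ours$xyz, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(b$atom$resno, ours$atoms$resnum)
  expect_equal(b$atom$elety, ours$atoms$atom)
})

test_that("selection grammar resolves chains, residue ranges and names", {
  refs <- make_reference_pair()
  m <- refs$conductive
  expect_length(select_atoms(m, "resnum 624-627 and name O"), 16)
  expect_length(select_atoms(m, "chain A"),
                sum(m$atoms$chain == "A"))
  expect_length(select_atoms(m, "name XX"), 0)
  expect_length(select_atoms(m, "resname ASN and name ND2"), 4)
  expect_length(select_atoms(m, "element O and chain A B"),
                sum(m$atoms$element == "O" & m$atoms$chain %in% c("A", "B")))
  expect_error(select_atoms(m, "resnum 624-627 and banana O"), "token 4")
  expect_error(select_atoms(m, "name"), "needs a value")
})

test_that("selections are independent of input record order", {
  refs <- make_reference_pair()
  m <- refs$conductive
  set.seed(11)
  perm <- sample(nrow(m$atoms))
  m2 <- structure_model(m$atoms[perm, ], m$xyz[perm, ],
                        chain_order = m$chain_order)
  s1 <- select_atoms(m, "resnum 624-628 and name N CA C O")
  s2 <- select_atoms(m2, "resnum 624-628 and name N CA C O")
  expect_equal(m$atoms[s1, ], m2$atoms[s2, ], ignore_attr = TRUE)
  expect_equal(m$xyz[s1, ], m2$xyz[s2, ], ignore_attr = TRUE)
})

test_that("superposition recovers rigid motions exactly", {
  set.seed(4)
  X <- matrix(rnorm(30), 10, 3)
  sp <- superpose(X, X)
  expect_equal(sp$rmsd, 0, tolerance = 1e-12)
  th <- pi / 2
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Y <- sweep(X %*% Rz, 2, c(1, 2, 3), "+")
  sp2 <- superpose(X, Y)
  expect_lt(sp2$rmsd, 1e-9)
  expect_equal(apply_superposition(sp2, X), Y, tolerance = 1e-9)
})

test_that("superposition RMSD matches the rotation-grid search oracle", {
  set.seed(7)
  for (rep in 1:3) {
    A <- matrix(rnorm(12, sd = 2), 4, 3)
    B <- matrix(rnorm(12, sd = 2), 4, 3)
    expect_equal(superpose(A, B)$rmsd, oracle_rmsd_grid(A, B),
                 tolerance = 1e-3)
  }
})

test_that("superposition never reflects chiral point sets", {
  tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mirror <- tetra %*% diag(c(-1, 1, 1))
  sp <- superpose(mirror, tetra)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-12)
  expect_gt(sp$rmsd, 0.1)  # a reflection would give 0
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), "degenerate")
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
})

test_that("pair distances and the per-chain variant measure construction", {
  m <- toy_model(rbind(c(0, 0, 0), c(0, 0, 5)), resnum = c(1, 2))
  expect_equal(pair_distance(m, list(chain = "A", resnum = 1, atom = "CA"),
                             list(chain = "A", resnum = 2, atom = "CA")), 5)
  expect_equal(pair_distance(m, list(chain = "A", resnum = 1, atom = "CA"),
                             list(chain = "A", resnum = 1, atom = "CA")), 0)
  expect_error(pair_distance(m, list(chain = "A", resnum = 1, atom = "CB"),
                             list(chain = "A", resnum = 2, atom = "CA")),
               "A/1/CB")
  # tetramer with programmed CB-CB separations 5,6,7,8
  seps <- c(A = 5, B = 6, C = 7, D = 8)
  rows <- list(); xyz <- list()
  for (ci in seq_along(seps)) {
    off <- c(20 * ci, 0, 0)
    rows[[ci]] <- data.frame(chain = names(seps)[ci], resnum = c(1L, 1L, 2L),
                             resname = "ALA", atom = c("CA", "CB", "CB"),
                             element = "C", stringsAsFactors = FALSE)
    xyz[[ci]] <- rbind(off, off, off + c(0, 0, seps[ci]))
  }
  m4 <- structure_model(do.call(rbind, rows), do.call(rbind, xyz))
  d <- pair_distance_by_chain(m4, a = list(resnum = 1, atom = "CB"),
                              b = list(resnum = 2, atom = "CB"))
  expect_equal(d, seps)
})
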