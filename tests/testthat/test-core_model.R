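# Configuration container, file IO, periodic geometry, selections.

test_that("XYZ round trip preserves positions, elements and box", {
  set.seed(11)
  cfg <- configuration(matrix(runif(30, 0, 10), ncol = 3),
                       rep(c("C", "O"), 5), box = diag(c(10, 11, 12)))
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(cfg, f)
  back <- read_xyz(f)$frames[[1]]
  expect_lt(max(abs(back$positions - cfg$positions)), 1e-9)
  expect_identical(back$elements, cfg$elements)
  expect_lt(max(abs(back$box - cfg$box)), 1e-9)
})

test_that("XYZ reader applies the sidecar and rejects malformed files", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "", "O 0 0 0", "H 0.96 0 0"), f)
  traj <- read_xyz(f)
  expect_equal(n_atoms(traj$frames[[1]]), 2)
  expect_equal(nrow(traj$frames[[1]]$bonds), 0)  # no bond guessing

  side <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("charges: [-0.8, 0.4]", "bonds:", "  - [1, 2]",
               "box: [10, 10, 10]"), side)
  cfg <- read_xyz(f, side)$frames[[1]]
  expect_equal(cfg$charges, c(-0.8, 0.4))
  expect_equal(cfg$bonds, matrix(c(1L, 2L), 1))
  expect_equal(cfg$box, diag(c(10, 10, 10)))

  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "", "O 0 0 0", "H 0.96 0 0", "1", "", "O 0 0 0"), bad)
  expect_error(read_xyz(bad), "inconsistent atom count")
  bad2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("x", "", "O 0 0 0"), bad2)
  expect_error(read_xyz(bad2), "malformed atom count")
})

test_that("PDB subset reader handles CRYST1, CONECT and sidecar precedence", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 1",
    "ATOM      1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      2  H1  HOH A   1       0.960   0.000   0.000  1.00  0.00           H",
    "CONECT    1    2",
    "END"), f)
  cfg <- read_pdb_subset(f)
  expect_equal(cfg$box, diag(c(10, 10, 10)))
  expect_equal(cfg$bonds, matrix(c(1L, 2L), 1))
  expect_equal(cfg$elements, c("O", "H"))

  # sidecar box wins only when the file has no CRYST1
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  O   HOH A   1       1.000   2.000   3.000  1.00  0.00           O",
    "END"), f2)
  side <- withr::local_tempfile(fileext = ".yaml")
  writeLines("box: [7, 8, 9]", side)
  cfg2 <- read_pdb_subset(f2, side)
  expect_equal(cfg2$box, diag(c(7, 8, 9)))
  expect_equal(drop(cfg2$positions), c(1, 2, 3))

  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("ATOM      1  O   HOH A   1                               1.00", f3)
  expect_error(read_pdb_subset(f3), "coordinates")
})

test_that("minimum image wraps cubic boxes and matches 27-image search", {
  cfg <- configuration(rbind(c(1, 0, 0), c(9, 0, 0)), c("C", "C"),
                       box = diag(c(10, 10, 10)))
  expect_equal(sqrt(sum(minimum_image_displacement(cfg, 1, 2)^2)), 2)
  free <- configuration(rbind(c(1, 0, 0), c(9, 0, 0)), c("C", "C"))
  expect_equal(sqrt(sum(minimum_image_displacement(free, 1, 2)^2)), 8)

  set.seed(42)
  for (k in 1:100) {
    box <- random_triclinic()
    # difference of two in-cell points, so 27 images cover the nearest
    d <- drop((runif(3) - runif(3)) %*% box)
    expect_equal(drop(min_image(matrix(d, 1), box)),
                 oracle_min_image(d, box), tolerance = 1e-10)
  }
})

test_that("selections are deterministic and realize bonded patterns", {
  w <- water()
  expect_equal(as.integer(select_atoms(w, element = "O")), 1L)
  # water H's are not 'hydroxyl' (O has no heavy neighbour)
  expect_length(select_atoms(w, pattern = "hydroxyl_h"), 0)
  expect_equal(as.integer(select_atoms(methanol(), pattern = "hydroxyl_h")), 3L)
  expect_length(select_atoms(methane(), pattern = "hydroxyl_h"), 0)
  expect_error(select_atoms(w, group = "nope"), "unknown group")
  # idempotent / order-independent
  s <- select_atoms(methanol(), element = "H")
  expect_identical(as.integer(s), sort(as.integer(s)))
})

test_that("hydroxyl census counts O with one H and a heavy neighbour", {
  expect_equal(count_hydroxyls(methanol()), 1)
  expect_equal(count_hydroxyls(water()), 0)
  expect_equal(count_hydroxyls(methane()), 0)
  b <- gen_hydroxyl_box(12, seed = 5)
  expect_equal(count_hydroxyls(b$config), 24)
  nobonds <- configuration(rbind(c(0, 0, 0)), "O")
  expect_error(count_hydroxyls(nobonds), "bond list")
})

test_that("configuration invariants are enforced", {
  expect_error(configuration(rbind(c(NA, 0, 0)), "C"), "finite")
  expect_error(configuration(rbind(c(0, 0, 0)), "C",
                             bonds = rbind(c(1L, 2L))), "out of range")
  expect_error(configuration(rbind(c(0, 0, 0)), "C",
                             box = diag(c(-1, 1, 1))), "det")
  expect_error(configuration(rbind(c(0, 0, 0)), "C", lj_rmin = 0), "rmin")
})
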