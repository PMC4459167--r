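# LJ/Coulomb pair terms, group decomposition, adhesion, forces.

test_that("lj_pair has its well at rmin and its zero at rmin/2^(1/6)", {
  expect_equal(lj_pair(3.5, 0.2, 3.5), -0.2)
  expect_equal(lj_pair(3.5 / 2^(1 / 6), 0.2, 3.5), 0, tolerance = 1e-12)
  expect_lt(abs(lj_pair(50, 0.2, 3.5)), 1e-6)
  expect_error(lj_pair(0, 0.2, 3.5), "r > 0")
  # analytic derivative consistent with central differences
  h <- 1e-6
  for (r in c(3.0, 3.5, 4.5)) {
    fd <- (lj_pair(r + h, 0.2, 3.5) - lj_pair(r - h, 0.2, 3.5)) / (2 * h)
    expect_equal(fibrilkit:::lj_dVdr(r, 0.2, 3.5), fd, tolerance = 1e-6)
  }
})

test_that("coulomb_pair reproduces the force-field constant and signs", {
  expect_equal(coulomb_pair(1, 1, 332.0637), 1.0)
  expect_identical(coulomb_pair(0, 1, 5), 0)
  expect_lt(coulomb_pair(1, -1, 5), 0)
  expect_error(coulomb_pair(1, 1, 0), "r > 0")
})

test_that("group interaction equals a hand sum for two atoms", {
  cfg <- configuration(rbind(c(0, 0, 0), c(4, 0, 0)), c("C", "C"),
                       charges = c(0.3, -0.2),
                       lj_epsilon = c(0.1, 0.1), lj_rmin = c(3.5, 3.5))
  e <- group_interaction(cfg, 1, 2)
  expect_equal(e$vdw, lj_pair(4, 0.1, 3.5))
  expect_equal(e$elec, coulomb_pair(0.3, -0.2, 4))
  expect_identical(e$total, e$vdw + e$elec)
  expect_error(group_interaction(cfg, 1:2, 2), "overlap")
})

test_that("bilayer cross sums match the brute-force oracle and are symmetric", {
  for (s in c(3, 17, 23)) {
    b <- gen_bilayer(seed = s)
    g <- b$config$groups
    e1 <- group_interaction(b$config, g$substrate, g$matrix)
    e2 <- group_interaction(b$config, g$matrix, g$substrate)
    expect_equal(e1$vdw, b$ground_truth$vdw, tolerance = 1e-12)
    expect_equal(e1$elec, b$ground_truth$elec, tolerance = 1e-12)
    expect_equal(e2$total, e1$total, tolerance = 1e-12)
    expect_identical(e1$total, e1$vdw + e1$elec)
  }
})

test_that("cutoff truncates both terms on well-separated slabs", {
  b <- gen_bilayer(gap = 18, seed = 8)
  g <- b$config$groups
  full <- group_interaction(b$config, g$substrate, g$matrix)
  cut <- group_interaction(b$config, g$substrate, g$matrix, cutoff = 12.5)
  expect_identical(cut$vdw, 0)          # every cross pair beyond the cutoff
  expect_lt(abs(full$vdw), 2e-2)        # vdW tail is tiny at 18 A
  expect_gt(abs(full$elec - cut$elec), 1e-4)  # electrostatics is long-range
})

test_that("adhesion identity: E_tot - (E_mat + E_sub) equals the cross sum", {
  b <- gen_bilayer(seed = 31)
  g <- b$config$groups
  e_tot <- total_energy(b$config)
  e_mat <- total_energy(b$config, g$matrix)
  e_sub <- total_energy(b$config, g$substrate)
  cross <- group_interaction(b$config, g$matrix, g$substrate)
  expect_equal(e_tot - e_mat - e_sub, cross$total, tolerance = 1e-12)
  adh <- adhesion_energy(b$config, g$matrix, g$substrate)
  expect_equal(adh$total, b$ground_truth$total, tolerance = 1e-10)
  expect_error(adhesion_energy(b$config, g$matrix, g$substrate,
                               interface_area = 0), "positive")
})

test_that("adhesion per area is intensive under lateral replication", {
  # cutoff below half the original cell keeps the interaction set of each
  # copy identical, so per-area adhesion must replicate exactly
  b <- gen_bilayer(n_sub = 25, n_mat = 25, seed = 12)
  g <- b$config$groups
  a1 <- adhesion_energy(b$config, g$matrix, g$substrate, cutoff = 9)
  big <- replicate_cell(b$config, 2L, 2L, 1L)
  a4 <- adhesion_energy(big, big$groups$matrix, big$groups$substrate,
                        cutoff = 9)
  expect_equal(a4$per_area, a1$per_area, tolerance = 1e-6)
})

test_that("charge_scale = 0 yields exactly zero electrostatic adhesion", {
  b <- gen_bilayer(charge_scale = 0, seed = 5)
  g <- b$config$groups
  adh <- adhesion_energy(b$config, g$matrix, g$substrate)
  expect_identical(adh$elec, 0)
  expect_identical(unname(adh$per_area["elec"]), 0)
})

test_that("energies are invariant under rigid translation and rotation", {
  set.seed(77)
  cfg <- configuration(matrix(runif(24, 0, 6), ncol = 3), rep("C", 8),
                       charges = rnorm(8, 0, 0.1),
                       lj_epsilon = runif(8, 0.05, 0.2),
                       lj_rmin = runif(8, 3, 4))
  e0 <- group_interaction(cfg, 1:4, 5:8)$total
  shifted <- cfg; shifted$positions <- cfg$positions + 13.7
  expect_equal(group_interaction(shifted, 1:4, 5:8)$total, e0,
               tolerance = 1e-9)
  th <- 0.9
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- cfg; rot$positions <- cfg$positions %*% t(R)
  expect_equal(group_interaction(rot, 1:4, 5:8)$total, e0, tolerance = 1e-9)
})

test_that("pair forces obey Newton's third law and match energy gradients", {
  set.seed(5)
  cfg <- configuration(matrix(runif(18, 0, 7), ncol = 3), rep("C", 6),
                       charges = rnorm(6, 0, 0.1),
                       lj_epsilon = runif(6, 0.05, 0.2),
                       lj_rmin = runif(6, 3, 4))
  f <- pair_forces(cfg)
  expect_lt(max(abs(colSums(f))), 1e-10)  # isolated system: zero net force
  # two atoms at the LJ minimum: zero radial force
  two <- configuration(rbind(c(0, 0, 0), c(3.5, 0, 0)), c("C", "C"),
                       lj_epsilon = c(0.2, 0.2), lj_rmin = c(3.5, 3.5))
  expect_lt(max(abs(pair_forces(two))), 1e-12)
  # finite-difference check of all components
  h <- 1e-5
  for (i in c(1, 4)) for (a in 1:3) {
    up <- cfg; up$positions[i, a] <- up$positions[i, a] + h
    dn <- cfg; dn$positions[i, a] <- dn$positions[i, a] - h
    fd <- -(total_energy(up) - total_energy(dn)) / (2 * h)
    expect_equal(f[i, a], fd, tolerance = 1e-5)
  }
  bad <- configuration(rbind(c(0, 0, 0), c(0, 0, 0)), c("C", "C"),
                       lj_epsilon = c(0.1, 0.1), lj_rmin = c(3, 3))
  expect_error(total_energy(bad), "degenerate")
})
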