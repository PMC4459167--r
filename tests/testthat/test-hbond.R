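# Hydrogen-bond detection, energetics, cooperativity, stiffness.

test_that("detection honours the distance and angle criterion boundaries", {
  # linear O-H...O geometry with adjustable H...A distance
  make_pair <- function(r_ha, bend_deg = 0) {
    th <- bend_deg * pi / 180
    configuration(rbind(c(-1.43, 0, 0),                       # donor C
                        c(0, 0, 0),                           # donor O
                        c(0.96, 0, 0),                        # H
                        c(0.96 + r_ha * cos(th), r_ha * sin(th), 0),  # acc O
                        c(0.96 + r_ha * cos(th) + 1.43, r_ha * sin(th), 0)),
                  c("C", "O", "H", "O", "C"),
                  bonds = rbind(c(1L, 2L), c(2L, 3L), c(4L, 5L)))
  }
  expect_equal(nrow(detect_hbonds(make_pair(2.4))), 1)
  expect_equal(nrow(detect_hbonds(make_pair(2.6))), 0)
  # theta_DHA = 180 - bend; 61 degrees of bend -> 119, excluded
  expect_equal(nrow(detect_hbonds(make_pair(1.8, bend_deg = 61))), 0)
  expect_equal(nrow(detect_hbonds(make_pair(1.8, bend_deg = 59))), 1)
  expect_error(detect_hbonds(configuration(rbind(c(0, 0, 0)), "H")), "bond list")
})

test_that("detection recovers constructed networks and matches the O(N^2) oracle", {
  b <- gen_hydroxyl_box(50, r_HA_sd = 0, theta_sd_deg = 0, seed = 7)
  hb <- detect_hbonds(b$config)
  expect_equal(nrow(hb), 50)
  expect_equal(hb[, c("donor_idx", "h_idx", "acceptor_idx")],
               b$ground_truth[order(b$ground_truth$h_idx),
                              c("donor_idx", "h_idx", "acceptor_idx")],
               ignore_attr = TRUE)
  for (s in 1:20) {
    g <- gen_hydroxyl_box(15, r_HA_sd = 0.15, theta_sd_deg = 10,
                          seed = 300 + s)
    hb <- detect_hbonds(g$config)
    orc <- oracle_hbonds(g$config)
    expect_equal(as.matrix(hb[, c("donor_idx", "h_idx", "acceptor_idx")]),
                 orc, ignore_attr = TRUE)
    # every detected bond satisfies both criteria
    expect_true(all(hb$r_HA <= 2.5))
    expect_true(all(hb$theta_DHA >= 120))
  }
})

test_that("12-10 energy has its well at (R_hb, 180 deg) and node at 90 deg", {
  p <- hbond_params(D_hb = 4, R_hb = 2.75)
  expect_equal(hbond_energy(2.75, 180, p), -4)
  expect_equal(hbond_energy(3.3, 90, p), 0)
  expect_equal(hbond_energy(1.9, 90, p), 0)
  expect_error(hbond_energy(-1, 150, p), "R_DA")
  # radial minimum sits at R_hb (independent 1-D minimization)
  opt <- optimize(function(r) hbond_energy(r, 180, p), c(2, 4))
  expect_equal(opt$minimum, 2.75, tolerance = 1e-4)
  expect_error(hbond_params(cos_exponent = 3), "cos_exponent")
})

test_that("energy density converts units correctly and is intensive", {
  box <- configuration(rbind(c(1, 1, 1), c(2, 2, 2)), c("C", "C"),
                       box = diag(c(10, 10, 10)))
  hb <- fibrilkit:::empty_hbonds()
  expect_equal(hbond_energy_density(box, hb)$density_J_m3, 0)
  hb1 <- rbind(hb, data.frame(donor_idx = 1L, h_idx = 1L, acceptor_idx = 2L,
                              r_HA = 1.9, R_DA = 2.8, theta_DHA = 170,
                              energy = -2))
  d <- hbond_energy_density(box, hb1)
  expect_equal(d$density_J_m3, 2 * 6.9477e-21 / 1e-27, tolerance = 1e-12)
  # duplicating box and contents leaves the density unchanged
  b <- gen_hydroxyl_box(20, seed = 13)
  hb <- detect_hbonds(b$config)
  d1 <- hbond_energy_density(b$config, hb)
  big <- replicate_cell(b$config, 2L, 1L, 1L)
  d2 <- hbond_energy_density(big, detect_hbonds(big))
  expect_equal(d2$density_J_m3, d1$density_J_m3, tolerance = 1e-9)
  free <- configuration(rbind(c(0, 0, 0)), "C")
  expect_error(hbond_energy_density(free, hb), "periodic")
})

test_that("cooperativity chains follow the donor-accepts-a-bond rule", {
  # O1-H...O2-H...O3: the O2 donor also accepts, one chain of two bonds
  chain2 <- data.frame(donor_idx = c(1L, 4L), h_idx = c(2L, 5L),
                       acceptor_idx = c(4L, 7L),
                       r_HA = 1.9, R_DA = 2.8, theta_DHA = 170, energy = -2)
  cc <- cooperativity_chains(chain2)
  expect_length(cc$chains, 1)
  expect_length(cc$chains[[1]], 2)
  expect_equal(cc$participation_fraction, 1)
  # an isolated bond forms no chain
  lone <- chain2[1, ]
  expect_length(cooperativity_chains(lone)$chains, 0)
  # random networks: participation equals a brute-force edge census
  set.seed(64)
  for (k in 1:10) {
    nb <- 12
    hb <- data.frame(donor_idx = sample(1:8, nb, TRUE) * 3L - 2L,
                     h_idx = seq_len(nb) * 100L,
                     acceptor_idx = sample(1:8, nb, TRUE) * 3L - 2L,
                     r_HA = 1.9, R_DA = 2.8, theta_DHA = 170, energy = -2)
    hb <- hb[hb$donor_idx != hb$acceptor_idx, ]
    cc <- cooperativity_chains(hb)
    in_edge <- outer(hb$donor_idx, hb$acceptor_idx, "==")
    linked <- which(rowSums(in_edge) > 0 | colSums(in_edge) > 0)
    expect_equal(sort(unique(unlist(cc$chains))), sort(linked))
  }
})

test_that("LJ stiffness is the closed-form second derivative", {
  expect_equal(lj_stiffness(1.2e-20, 1.85e-10), 25.24, tolerance = 1e-3)
  expect_equal(lj_stiffness(1, 2) * 4, lj_stiffness(1, 1))  # k ~ r^-2
  expect_error(lj_stiffness(-1, 1), "positive")
  # matches numerical V'' at the minimum across 3 decades of parameters
  set.seed(8)
  for (k in 1:12) {
    eps <- 10^runif(1, -21, -18); rm <- 10^runif(1, -10.5, -9.5)
    h <- rm * 1e-4
    V <- function(r) eps * ((rm / r)^12 - 2 * (rm / r)^6)
    vpp <- (V(rm + h) - 2 * V(rm) + V(rm - h)) / h^2
    expect_equal(lj_stiffness(eps, rm), vpp, tolerance = 1e-6)
  }
})

test_that("geometry stats are plain means and ranges of the bond table", {
  one <- data.frame(donor_idx = 1L, h_idx = 2L, acceptor_idx = 3L,
                    r_HA = 1.75, R_DA = 2.7, theta_DHA = 163, energy = -1)
  st <- hbond_geometry_stats(one)
  expect_equal(st$mean_r_HA, 1.75)
  expect_equal(st$mean_theta, 163)
  b <- gen_hydroxyl_box(30, r_HA_sd = 0.1, theta_sd_deg = 8, seed = 44)
  hb <- detect_hbonds(b$config)
  st <- hbond_geometry_stats(hb)
  expect_equal(st$mean_r_HA, mean(hb$r_HA))
  expect_equal(st$range_theta, c(min(hb$theta_DHA), max(hb$theta_DHA)))
  expect_error(hbond_geometry_stats(fibrilkit:::empty_hbonds()), "empty")
})
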