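# Generators: reproducibility, ground-truth construction, capacity errors.

test_that("generators are bit-reproducible for a fixed seed", {
  a <- gen_hydroxyl_box(8, seed = 21)
  b <- gen_hydroxyl_box(8, seed = 21)
  expect_identical(a, b)
  expect_identical(gen_bilayer(n_sub = 10, n_mat = 10, seed = 9),
                   gen_bilayer(n_sub = 10, n_mat = 10, seed = 9))
  expect_identical(gen_cooling_curve(seed = 3), gen_cooling_curve(seed = 3))
  expect_false(identical(gen_hydroxyl_box(8, seed = 21),
                         gen_hydroxyl_box(8, seed = 22)))
})

test_that("hydroxyl box realizes the requested geometry distribution", {
  b <- gen_hydroxyl_box(0, seed = 1)
  expect_equal(n_atoms(b$config), 0)
  expect_equal(nrow(b$ground_truth), 0)

  # sd = 0: every contact at exactly the target geometry
  b <- gen_hydroxyl_box(20, r_HA_mean = 1.85, r_HA_sd = 0,
                        theta_mean_deg = 150, theta_sd_deg = 0, seed = 2)
  expect_equal(b$ground_truth$r_HA, rep(1.85, 20))
  expect_equal(b$ground_truth$theta_DHA, rep(150, 20))

  # sd > 0: sample means near targets (law of large numbers over 10 seeds)
  rs <- NULL; ts <- NULL
  for (s in 1:10) {
    g <- gen_hydroxyl_box(25, r_HA_sd = 0.05, theta_sd_deg = 5,
                          seed = 100 + s)$ground_truth
    rs <- c(rs, g$r_HA); ts <- c(ts, g$theta_DHA)
  }
  expect_lt(abs(mean(rs) - 1.88), 3 * 0.05 / sqrt(length(rs)))
  expect_lt(abs(mean(ts) - 150.96), 3 * 5 / sqrt(length(ts)))

  expect_error(gen_hydroxyl_box(200, box_edge = 10, seed = 1), "too small")
})

test_that("every generated structure passes configuration invariants", {
  for (s in 1:5) {
    cfg <- gen_hydroxyl_box(10, r_HA_sd = 0.05, theta_sd_deg = 4,
                            seed = s)$config
    expect_s3_class(cfg, "fk_config")
    expect_true(all(is.finite(cfg$positions)))
    expect_true(all(cfg$bonds >= 1 & cfg$bonds <= n_atoms(cfg)))
    expect_gt(det(cfg$box), 0)
  }
})

test_that("bilayer ground truth switches off with its scales", {
  b0 <- gen_bilayer(n_sub = 15, n_mat = 15, charge_scale = 0, seed = 4)
  expect_identical(b0$ground_truth$elec, 0)
  b00 <- gen_bilayer(n_sub = 15, n_mat = 15, charge_scale = 0, lj_scale = 0,
                     seed = 4)
  expect_identical(b00$ground_truth$total, 0)
  expect_error(gen_bilayer(gap = 0), "overlap")
})

test_that("strain series carries the stated frames and analytic modulus", {
  s <- gen_strain_series("harmonic_sc", max_strain = 0.01, steps = 10,
                         k_spring = 10, a = 3, seed = 1)
  expect_length(s$traj, 11)  # unstrained reference + 10 strained frames
  expect_equal(diff(s$ground_truth$strains), rep(0.001, 10))
  expect_equal(s$ground_truth$true_modulus, 10 / 3 * 6.9477)
  expect_error(gen_strain_series("harmonic_sc", max_strain = 0.2), "max_strain")
  expect_error(gen_strain_series("harmonic_sc", steps = 2), "steps")
})

test_that("cooling curve is continuous, noisy as requested, and validated", {
  expect_error(gen_cooling_curve(tg_true = 900), "inside T_range")
  expect_error(gen_cooling_curve(slope_glass = 5e-4, slope_melt = 2e-4),
               "slope_melt")
  cur <- gen_cooling_curve(noise_sd = 0, seed = 6)
  expect_s3_class(cur, "fk_vtcurve")
  expect_equal(nrow(cur), 48)
  gt <- attr(cur, "ground_truth")
  # noiseless curve lies exactly on the two-slope model
  pred <- gt$v_tg + ifelse(cur$temperature < gt$tg_true,
                           gt$slope_glass * (cur$temperature - gt$tg_true),
                           gt$slope_melt * (cur$temperature - gt$tg_true))
  expect_equal(cur$specific_volume, pred)
})

test_that("surface slab puts hydroxyl and alkyl hydrogens at their levels", {
  for (s in 1:10) {
    sl <- gen_surface_slab(z_OH = 18.3, z_CH = 19.8, n_each = 60, seed = s)
    oh <- density_profile(sl, select_atoms(sl, pattern = "hydroxyl_h"), "z", 0.2)
    ch <- density_profile(sl, select_atoms(sl, pattern = "alkyl_h"), "z", 0.2)
    expect_lt(abs(attr(oh, "mode") - 18.3), 0.21)
    expect_lt(abs(attr(ch, "mode") - 19.8), 0.21)
  }
  one <- gen_surface_slab(n_each = 40, seed = 1)
  # restricting to one species gives a single-mode profile
  oh_only <- density_profile(one, select_atoms(one, pattern = "hydroxyl_h"),
                             "z", 0.5)
  occ <- oh_only$relative_concentration > 0
  expect_lt(diff(range(oh_only$bin_center[occ])), 2)
  expect_error(gen_surface_slab(z_OH = 5, z_CH = 5), "distinct")
})
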