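# Synthetic-configuration generators with oracle-computed ground truth.
# These emulate the statistical structure the analyses assume — amorphous
# hydroxyl-bearing boxes with a controlled hydrogen-bond network, two-slab
# substrate/matrix assemblies, affine strain series of analytic lattices,
# two-slope cooling curves, and surface slabs with hydrogens at two heights
# — so every stage is testable without external trajectories. Ground
# truths are computed by independent oracles (plain double-loop pair sums,
# energy-only finite differences), never by the modules under test.

# run expr with a private, explicitly seeded RNG stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

runit <- function() {
  v <- stats::rnorm(3L)
  v / sqrt(sum(v^2))
}

# random unit vector perpendicular to u
rperp <- function(u) {
  repeat {
    w <- stats::rnorm(3L)
    w <- w - sum(w * u) * u
    n <- sqrt(sum(w^2))
    if (n > 1e-8) return(w / n)
  }
}

#' Amorphous box of hydroxyl pairs with a constructed hydrogen-bond network
#'
#' Places `n_pairs` donor/acceptor hydroxyl fragments (each a C-O-H
#' triad, so donor identification is exercised on a carbon skeleton) in a
#' periodic cubic box. Each pair realizes a sampled H...acceptor distance
#' and donor-H-acceptor angle; rejection sampling keeps pair centres at
#' least 4 Angstrom apart and any cross-pair atom contact above 2.7
#' Angstrom, so no accidental contact can satisfy the 2.5 Angstrom
#' detection criterion.
#'
#' @param n_pairs number of donor/acceptor pairs.
#' @param box_edge cubic box edge (Angstrom).
#' @param r_HA_mean,r_HA_sd H...acceptor distance distribution (Angstrom).
#' @param theta_mean_deg,theta_sd_deg donor-H-acceptor angle distribution
#'   (degrees).
#' @param seed RNG seed.
#' @return list with `config` (`fk_config`) and `ground_truth` (data.frame
#'   of constructed contacts plus the generator parameters).
#' @export
gen_hydroxyl_box <- function(n_pairs, box_edge = 26,
                             r_HA_mean = 1.88, r_HA_sd = 0,
                             theta_mean_deg = 150.96, theta_sd_deg = 0,
                             seed = 1) {
  with_seed(seed, {
    box <- diag(rep(box_edge, 3L))
    oh <- 0.96; co <- 1.43
    cos_t <- cos(109.5 * pi / 180)
    pos <- matrix(0, 0L, 3L)
    centres <- matrix(0, 0L, 3L)
    gt <- data.frame(donor_idx = integer(0), h_idx = integer(0),
                     acceptor_idx = integer(0), r_HA = numeric(0),
                     theta_DHA = numeric(0), R_DA = numeric(0))
    min_img_d <- function(d) {
      d <- d - box_edge * floor(d / box_edge + 0.5)
      sqrt(rowSums(d^2))
    }
    for (p in seq_len(n_pairs)) {
      ok <- FALSE
      for (attempt in seq_len(5000L)) {
        r_HA <- stats::rnorm(1L, r_HA_mean, r_HA_sd)
        theta <- stats::rnorm(1L, theta_mean_deg, theta_sd_deg)
        tr <- theta * pi / 180
        o_d <- stats::runif(3L, 0, box_edge)
        u <- runit()
        h_d <- o_d + oh * u
        w <- rperp(u)
        v <- cos(pi - tr) * u + sin(pi - tr) * w
        o_a <- h_d + r_HA * v
        h_a <- o_a + oh * v
        cd <- cos_t * u + sqrt(1 - cos_t^2) * rperp(u)
        c_d <- o_d + co * cd
        ca <- cos_t * v + sqrt(1 - cos_t^2) * rperp(v)
        c_a <- o_a + co * ca
        frag <- rbind(c_d, o_d, h_d, c_a, o_a, h_a)
        centre <- (h_d + o_a) / 2
        if (nrow(pos)) {
          dc <- min_img_d(centres - matrix(centre, nrow(centres), 3L, byrow = TRUE))
          if (min(dc) < 4) next
          dd <- min_img_d(pos[rep(seq_len(nrow(pos)), times = 6L), ] -
                          frag[rep(1:6, each = nrow(pos)), ])
          if (min(dd) < 2.7) next
        }
        base <- nrow(pos)
        pos <- rbind(pos, frag)
        centres <- rbind(centres, centre)
        gt <- rbind(gt, data.frame(
          donor_idx = base + 2L, h_idx = base + 3L, acceptor_idx = base + 5L,
          r_HA = r_HA, theta_DHA = theta,
          R_DA = sqrt(sum((min_image(matrix(o_d - o_a, 1L), box))^2))))
        ok <- TRUE
        break
      }
      if (!ok) stop(sprintf(
        "box edge %.1f too small to place %d hydroxyl pairs", box_edge, n_pairs))
    }
    n <- nrow(pos)
    el <- rep(c("C", "O", "H", "C", "O", "H"), length.out = n)
    bonds <- NULL
    if (n_pairs > 0) {
      base <- 6L * (seq_len(n_pairs) - 1L)
      bonds <- rbind(cbind(base + 1L, base + 2L), cbind(base + 2L, base + 3L),
                     cbind(base + 4L, base + 5L), cbind(base + 5L, base + 6L))
    }
    chg <- rep(c(0.2, -0.5, 0.3, 0.2, -0.5, 0.3), length.out = n)
    eps <- rep(c(0.1, 0.1, 0.01, 0.1, 0.1, 0.01), length.out = n)
    rmn <- rep(c(4.0, 3.5, 2.0, 4.0, 3.5, 2.0), length.out = n)
    cfg <- configuration(pos, el, charges = chg, lj_epsilon = eps,
                         lj_rmin = rmn, bonds = bonds, box = box)
    list(config = cfg,
         ground_truth = gt,
         params = list(n_pairs = n_pairs, box_edge = box_edge,
                       r_HA_mean = r_HA_mean, r_HA_sd = r_HA_sd,
                       theta_mean_deg = theta_mean_deg,
                       theta_sd_deg = theta_sd_deg, seed = seed))
  })
}

#' Two-slab substrate/matrix assembly with an oracle interface energy
#'
#' Random atoms in two non-overlapping slabs separated by `gap`, periodic
#' in x and y only (vacuum slab geometry). The ground-truth interface
#' energy — with its vdW/electrostatic split — is computed by a plain
#' double-loop pair sum over all cross pairs, independent of the vectorized
#' module code.
#'
#' @param n_sub,n_mat atoms in substrate and matrix slabs.
#' @param gap vertical gap between slabs (Angstrom, > 0).
#' @param charge_scale,lj_scale multipliers on the random charges and LJ
#'   well depths (0 switches the term off exactly).
#' @param box_xy lateral box edge (Angstrom).
#' @param seed RNG seed.
#' @return list with `config` (groups `substrate`, `matrix`) and
#'   `ground_truth` (`vdw`, `elec`, `total` in kcal/mol).
#' @export
gen_bilayer <- function(n_sub = 50, n_mat = 50, gap = 3,
                        charge_scale = 1, lj_scale = 1,
                        box_xy = 20, seed = 1) {
  if (gap <= 0) stop("slabs overlap: gap must be > 0")
  with_seed(seed, {
    thick <- 4
    z_sub <- c(10, 10 + thick)
    z_mat <- c(z_sub[2L] + gap, z_sub[2L] + gap + thick)
    place_slab <- function(n, zr) {
      pts <- matrix(0, 0L, 3L)
      for (k in seq_len(n)) {
        for (attempt in seq_len(5000L)) {
          p <- c(stats::runif(2L, 0, box_xy), stats::runif(1L, zr[1L], zr[2L]))
          if (nrow(pts)) {
            d <- pts - matrix(p, nrow(pts), 3L, byrow = TRUE)
            d[, 1:2] <- d[, 1:2] - box_xy * floor(d[, 1:2] / box_xy + 0.5)
            if (min(sqrt(rowSums(d^2))) < 1.8) next
          }
          pts <- rbind(pts, p)
          break
        }
        if (nrow(pts) < k) stop("slab too crowded: cannot place atoms")
      }
      pts
    }
    pos <- rbind(place_slab(n_sub, z_sub), place_slab(n_mat, z_mat))
    dimnames(pos) <- NULL
    n <- n_sub + n_mat
    chg <- stats::rnorm(n, 0, 0.1)
    # each slab is a neutral molecular layer: remove its net charge
    chg[seq_len(n_sub)] <- chg[seq_len(n_sub)] - mean(chg[seq_len(n_sub)])
    chg[n_sub + seq_len(n_mat)] <- chg[n_sub + seq_len(n_mat)] -
      mean(chg[n_sub + seq_len(n_mat)])
    chg <- chg * charge_scale
    eps <- stats::runif(n, 0.05, 0.15) * lj_scale
    rmn <- stats::runif(n, 3, 4)
    box_z <- z_mat[2L] + 40
    cfg <- configuration(pos, rep("C", n), charges = chg, lj_epsilon = eps,
                         lj_rmin = rmn, box = diag(c(box_xy, box_xy, box_z)),
                         groups = list(substrate = seq_len(n_sub),
                                       matrix = n_sub + seq_len(n_mat)))
    cfg$periodic_dims <- c(TRUE, TRUE, FALSE)
    # independent oracle: scalar double loop, minimum image in x,y only
    kC <- 332.0637
    vdw <- 0; elec <- 0
    for (i in seq_len(n_sub)) {
      for (j in (n_sub + 1L):n) {
        dx <- pos[i, 1L] - pos[j, 1L]; dx <- dx - box_xy * round(dx / box_xy)
        dy <- pos[i, 2L] - pos[j, 2L]; dy <- dy - box_xy * round(dy / box_xy)
        dz <- pos[i, 3L] - pos[j, 3L]
        r <- sqrt(dx^2 + dy^2 + dz^2)
        r6i <- rmn[i]^6; r6j <- rmn[j]^6
        rm <- ((r6i + r6j) / 2)^(1 / 6)
        ep <- if (r6i + r6j > 0)
          2 * sqrt(eps[i] * eps[j]) * rmn[i]^3 * rmn[j]^3 / (r6i + r6j) else 0
        vdw <- vdw + ep * ((rm / r)^12 - 2 * (rm / r)^6)
        elec <- elec + kC * chg[i] * chg[j] / r
      }
    }
    list(config = cfg,
         ground_truth = list(vdw = vdw, elec = elec, total = vdw + elec),
         params = list(n_sub = n_sub, n_mat = n_mat, gap = gap,
                       charge_scale = charge_scale, lj_scale = lj_scale,
                       box_xy = box_xy, seed = seed))
  })
}

#' Affine strain series of an analytic lattice
#'
#' Builds a periodic reference lattice and `steps` affinely strained copies
#' along `axis` with strain spacing `max_strain / steps`. For the harmonic
#' simple-cubic lattice (nearest-neighbour springs `k_spring`, spacing
#' `a`) the modulus is analytic, `E = k_spring / a`. For the LJ FCC
#' lattice the ground truth is the least-squares slope of finite-difference
#' stresses `sigma(eps) = (1/V) dE/deps` (energy evaluations only,
#' h = 1e-4) over the same strain points — a route through energies, not
#' forces.
#'
#' @param base_lattice `"harmonic_sc"` or `"lj_fcc"`.
#' @param axis strain axis (1:3 or "x","y","z").
#' @param max_strain maximum engineering strain (<= 0.05).
#' @param steps number of strained frames (>= 3).
#' @param seed recorded for provenance (the lattices are deterministic).
#' @param n_cells lattice repeats per direction.
#' @param k_spring,a harmonic lattice parameters (kcal/mol/A^2, Angstrom).
#' @param eps,rmin LJ lattice parameters (kcal/mol, Angstrom).
#' @return list with `traj` (`fk_traj`, reference frame first) and
#'   `ground_truth$true_modulus` (GPa).
#' @export
gen_strain_series <- function(base_lattice = c("harmonic_sc", "lj_fcc"),
                              axis = 3L, max_strain = 0.01, steps = 10L,
                              seed = 1, n_cells = 3L,
                              k_spring = 10, a = 3, eps = 0.2, rmin = 3.5) {
  base_lattice <- match.arg(base_lattice)
  if (max_strain > 0.05) stop("max_strain must be <= 0.05 (small-strain regime)")
  if (steps < 3L) stop("steps must be >= 3")
  axis <- axis_index(axis)
  if (base_lattice == "harmonic_sc") {
    # n_cells >= 3 keeps the +1 neighbour springs distinct unordered pairs
    if (n_cells < 3L) stop("harmonic_sc requires n_cells >= 3")
    g <- as.matrix(expand.grid(x = 0:(n_cells - 1L), y = 0:(n_cells - 1L),
                               z = 0:(n_cells - 1L))) * a
    n <- nrow(g)
    idx <- array(seq_len(n), dim = rep(n_cells, 3L))
    ijk <- as.matrix(expand.grid(i = 1:n_cells, j = 1:n_cells, k = 1:n_cells))
    bonds <- NULL
    for (dim in 1:3) {
      nb <- ijk
      nb[, dim] <- nb[, dim] %% n_cells + 1L
      bonds <- rbind(bonds, cbind(idx[ijk], idx[nb]))
    }
    ref <- configuration(g, rep("C", n), bonds = bonds,
                         box = diag(rep(n_cells * a, 3L)),
                         bond_k = k_spring, bond_r0 = a)
    true_modulus <- k_spring / a * fk_units$kcalmol_A3_to_GPa
  } else {
    a0 <- rmin * sqrt(2)
    basis <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
    cells <- as.matrix(expand.grid(x = 0:(n_cells - 1L), y = 0:(n_cells - 1L),
                                   z = 0:(n_cells - 1L)))
    pos <- (cells[rep(seq_len(nrow(cells)), each = 4L), ] +
            basis[rep(1:4, times = nrow(cells)), ]) * a0
    n <- nrow(pos)
    ref <- configuration(pos, rep("C", n), lj_epsilon = rep(eps, n),
                         lj_rmin = rep(rmin, n),
                         box = diag(rep(n_cells * a0, 3L)))
    true_modulus <- NULL # filled below from the energy-only oracle
  }
  strains <- c(0, seq_len(steps) * max_strain / steps)
  frames <- lapply(strains, function(s) apply_strain(ref, s, axis))
  traj <- trajectory(frames)
  if (base_lattice == "lj_fcc") {
    h <- 1e-4
    # Cauchy stress at each strained state: energy derivative with respect
    # to an incremental strain about that state, per its current volume
    sigma_fd <- vapply(strains, function(s) {
      fr <- apply_strain(ref, s, axis)
      ep <- total_energy(apply_strain(fr, h, axis))
      em <- total_energy(apply_strain(fr, -h, axis))
      (ep - em) / (2 * h) / det(fr$box) * fk_units$kcalmol_A3_to_GPa
    }, numeric(1L))
    true_modulus <- unname(stats::coef(stats::lm(sigma_fd ~ strains))[2L])
  }
  list(traj = traj,
       ground_truth = list(true_modulus = true_modulus, strains = strains),
       params = list(base_lattice = base_lattice, axis = axis,
                     max_strain = max_strain, steps = steps, seed = seed,
                     n_cells = n_cells, k_spring = k_spring, a = a,
                     eps = eps, rmin = rmin))
}

#' Two-slope specific-volume cooling curve with noise
#'
#' Piecewise-linear specific volume v(T), continuous at the true glass
#' transition, sampled at `n_points` random temperatures (emulating
#' NPT snapshots taken at random steps of a cooling ramp) with Gaussian
#' noise.
#'
#' @param tg_true true breakpoint (K), inside `T_range`.
#' @param slope_glass,slope_melt expansivities below/above the transition
#'   (cc/g/K); the melt slope must exceed the glass slope, both positive.
#' @param T_range length-2 temperature range (K).
#' @param n_points number of samples.
#' @param noise_sd Gaussian noise (cc/g).
#' @param v_tg specific volume at the transition (cc/g).
#' @param seed RNG seed.
#' @return An `fk_vtcurve` with the generator parameters as attribute
#'   `ground_truth`.
#' @export
gen_cooling_curve <- function(tg_true = 450, slope_glass = 2e-4,
                              slope_melt = 5e-4, T_range = c(100, 700),
                              n_points = 48L, noise_sd = 0.002,
                              v_tg = 0.74, seed = 1) {
  if (tg_true <= min(T_range) || tg_true >= max(T_range))
    stop("tg_true must lie strictly inside T_range")
  if (!(slope_melt > slope_glass && slope_glass > 0))
    stop("require slope_melt > slope_glass > 0")
  with_seed(seed, {
    temps <- sort(stats::runif(n_points, min(T_range), max(T_range)))
    v <- v_tg + ifelse(temps < tg_true,
                       slope_glass * (temps - tg_true),
                       slope_melt * (temps - tg_true))
    v <- v + stats::rnorm(n_points, 0, noise_sd)
    curve <- vtcurve(temps, v)
    attr(curve, "ground_truth") <- list(
      tg_true = tg_true, slope_glass = slope_glass, slope_melt = slope_melt,
      T_range = T_range, n_points = n_points, noise_sd = noise_sd,
      v_tg = v_tg, seed = seed)
    curve
  })
}

#' Surface slab with hydroxyl and alkyl hydrogens at two heights
#'
#' Emulates a crystal surface whose O-H hydrogens sit lower than its C-H
#' hydrogens: `n_each` hydroxyl (C-O-H) and alkyl (C-H) fragments with the
#' hydrogens at `z_OH` and `z_CH` (0.1 Angstrom jitter), periodic in the
#' lateral directions.
#'
#' @param z_OH,z_CH hydrogen heights (Angstrom), distinct.
#' @param n_each fragments per species.
#' @param box_xy lateral box edge (Angstrom).
#' @param seed RNG seed.
#' @return An `fk_config`.
#' @export
gen_surface_slab <- function(z_OH = 18.3, z_CH = 19.8, n_each = 100L,
                             box_xy = 30, seed = 1) {
  if (abs(z_OH - z_CH) < 1e-9) stop("z levels must be distinct")
  with_seed(seed, {
    pos <- matrix(0, 0L, 3L); el <- character(0)
    bonds <- matrix(integer(0), ncol = 2L)
    add_frag <- function(coords, elems, blist) {
      base <- nrow(pos)
      pos <<- rbind(pos, coords); el <<- c(el, elems)
      bonds <<- rbind(bonds, blist + base)
    }
    for (k in seq_len(n_each)) {
      xy <- stats::runif(2L, 0, box_xy)
      zh <- z_OH + stats::rnorm(1L, 0, 0.1)
      add_frag(rbind(c(xy, zh - 0.96 - 1.43), c(xy, zh - 0.96), c(xy, zh)),
               c("C", "O", "H"), rbind(c(1L, 2L), c(2L, 3L)))
    }
    for (k in seq_len(n_each)) {
      xy <- stats::runif(2L, 0, box_xy)
      zh <- z_CH + stats::rnorm(1L, 0, 0.1)
      add_frag(rbind(c(xy, zh - 1.09), c(xy, zh)),
               c("C", "H"), rbind(c(1L, 2L)))
    }
    zmax <- max(z_OH, z_CH) + 20
    cfg <- configuration(pos, el, bonds = bonds,
                         box = diag(c(box_xy, box_xy, zmax)))
    cfg$periodic_dims <- c(TRUE, TRUE, FALSE)
    cfg
  })
}
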