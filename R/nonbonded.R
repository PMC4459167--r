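# Pairwise non-bonded energetics: Lennard-Jones (r_min convention) plus
# Coulomb point charges under the minimum image, group-group decomposition
# and interfacial adhesion per unit area. Covalently bonded (1-2) pairs are
# excluded from all non-bonded sums; when a configuration carries harmonic
# bond parameters those pairs contribute 0.5 k (r - r0)^2 springs instead.

#' Lennard-Jones pair energy (r_min convention)
#'
#' `V(r) = eps * ((rmin/r)^12 - 2 (rmin/r)^6)`, with minimum `-eps` at
#' `r = rmin` and zero crossing at `rmin / 2^(1/6)`.
#'
#' @param r separation (Angstrom), vectorized.
#' @param eps well depth (kcal/mol).
#' @param rmin equilibrium distance (Angstrom).
#' @return energy (kcal/mol).
#' @export
lj_pair <- function(r, eps, rmin) {
  if (any(r <= 0)) stop("lj_pair requires r > 0")
  s6 <- (rmin / r)^6
  eps * (s6^2 - 2 * s6)
}

# dV/dr of lj_pair
lj_dVdr <- function(r, eps, rmin) {
  s6 <- (rmin / r)^6
  -12 * eps / r * (s6^2 - s6)
}

#' Coulomb pair energy
#'
#' `k_C q1 q2 / r` with `k_C` = 332.0637 kcal.A/(mol.e^2).
#'
#' @param q1,q2 partial charges (e).
#' @param r separation (Angstrom), vectorized.
#' @return energy (kcal/mol).
#' @export
coulomb_pair <- function(q1, q2, r) {
  if (any(r <= 0)) stop("coulomb_pair requires r > 0")
  fk_units$coulomb_k * q1 * q2 / r
}

#' Combine per-atom LJ parameters into pair parameters
#'
#' @param eps_i,eps_j,rmin_i,rmin_j per-atom parameters.
#' @param mixing `"sixth_power"` (COMPASS-style, the default) or
#'   `"lorentz_berthelot"`.
#' @return list with `eps`, `rmin` vectors.
#' @export
mix_lj <- function(eps_i, eps_j, rmin_i, rmin_j,
                   mixing = c("sixth_power", "lorentz_berthelot")) {
  mixing <- match.arg(mixing)
  if (mixing == "lorentz_berthelot") {
    list(eps = sqrt(eps_i * eps_j), rmin = (rmin_i + rmin_j) / 2)
  } else {
    r6i <- rmin_i^6; r6j <- rmin_j^6
    rmin <- ((r6i + r6j) / 2)^(1 / 6)
    eps <- ifelse(r6i + r6j > 0,
                  2 * sqrt(eps_i * eps_j) * rmin_i^3 * rmin_j^3 / (r6i + r6j),
                  0)
    list(eps = eps, rmin = rmin)
  }
}

config_periodic_dims <- function(config) {
  config$periodic_dims %||% c(TRUE, TRUE, TRUE)
}

bonded_key <- function(bonds, n) {
  if (nrow(bonds) == 0L) return(numeric(0))
  bonds[, 1L] * (n + 1) + bonds[, 2L]
}

# pairwise LJ+Coulomb over an explicit (i, j) pair list, in list order
pair_energies <- function(config, ii, jj, cutoff = NULL,
                          mixing = "sixth_power") {
  if (!length(ii)) return(list(vdw = 0, elec = 0, n_pairs = 0L))
  d <- min_image(config$positions[ii, , drop = FALSE] -
                 config$positions[jj, , drop = FALSE],
                 config$box, config_periodic_dims(config))
  r <- sqrt(rowSums(d^2))
  if (any(r < 1e-12)) {
    k <- which(r < 1e-12)[1L]
    stop(sprintf("degenerate geometry: atoms %d and %d coincide", ii[k], jj[k]))
  }
  # drop covalently bonded pairs from the non-bonded sum
  n <- n_atoms(config)
  lo <- pmin(ii, jj); hi <- pmax(ii, jj)
  keep <- !(lo * (n + 1) + hi) %in% bonded_key(config$bonds, n)
  if (!is.null(cutoff)) keep <- keep & r <= cutoff
  ii <- ii[keep]; jj <- jj[keep]; r <- r[keep]
  p <- mix_lj(config$lj_epsilon[ii], config$lj_epsilon[jj],
              config$lj_rmin[ii], config$lj_rmin[jj], mixing)
  list(vdw = sum(lj_pair(r, p$eps, p$rmin)),
       elec = sum(coulomb_pair(config$charges[ii], config$charges[jj], r)),
       n_pairs = length(r))
}

energy_breakdown <- function(vdw, elec, n_pairs, area = NULL) {
  out <- list(vdw = vdw, elec = elec, total = vdw + elec, n_pairs = n_pairs)
  if (!is.null(area)) {
    conv <- fk_units$kcalmol_A2_to_mJm2
    # attraction (negative raw energy) reported as positive adhesion
    out$per_area <- c(vdw = -vdw / area * conv,
                      elec = -elec / area * conv,
                      total = -(vdw + elec) / area * conv)
    out$area <- area
  }
  structure(out, class = "fk_energy")
}

#' @export
print.fk_energy <- function(x, ...) {
  cat(sprintf("<fk_energy> vdW %.6g  elec %.6g  total %.6g kcal/mol (%d pairs)\n",
              x$vdw, x$elec, x$total, x$n_pairs))
  if (!is.null(x$per_area))
    cat(sprintf("  adhesion per area: vdW %.4g  elec %.4g  total %.4g mJ/m^2\n",
                x$per_area["vdw"], x$per_area["elec"], x$per_area["total"]))
  invisible(x)
}

#' Group-group interaction energy
#'
#' Sums LJ and Coulomb energies over all cross pairs (i in A, j in B) under
#' the minimum image, in deterministic i-major order. `total = vdw + elec`
#' exactly (same summation order).
#'
#' @param config an `fk_config` with per-atom LJ parameters.
#' @param selA,selB disjoint atom selections (indices).
#' @param cutoff pair cutoff in Angstrom, or NULL for exact all-pair sums
#'   (the default; cutoff applies to both LJ and Coulomb, untruncated
#'   long-range electrostatics being the point of the exact sum).
#' @param mixing LJ mixing rule, see [mix_lj()].
#' @return An `fk_energy` breakdown.
#' @export
group_interaction <- function(config, selA, selB, cutoff = NULL,
                              mixing = "sixth_power") {
  selA <- sort(unique(as.integer(selA)))
  selB <- sort(unique(as.integer(selB)))
  if (length(intersect(selA, selB)))
    stop("selections overlap; group interaction requires disjoint groups")
  if (!length(selA) || !length(selB)) stop("empty selection")
  ii <- rep(selA, each = length(selB))
  jj <- rep(selB, times = length(selA))
  e <- pair_energies(config, ii, jj, cutoff, mixing)
  energy_breakdown(e$vdw, e$elec, e$n_pairs)
}

#' Total non-bonded (+ harmonic bond) energy of a selection
#'
#' All unique pairs within `sel`; bonded pairs contribute springs when the
#' configuration carries `bond_k`/`bond_r0`, and are excluded from the
#' non-bonded sum always.
#'
#' @param config an `fk_config`.
#' @param sel atom indices (default: all atoms).
#' @param cutoff,mixing as in [group_interaction()].
#' @return total energy (kcal/mol).
#' @export
total_energy <- function(config, sel = NULL, cutoff = NULL,
                         mixing = "sixth_power") {
  sel <- if (is.null(sel)) seq_len(n_atoms(config)) else sort(unique(as.integer(sel)))
  pr <- pair_index(length(sel))
  e <- pair_energies(config, sel[pr[, 1L]], sel[pr[, 2L]], cutoff, mixing)
  etot <- e$vdw + e$elec
  if (!is.null(config$bond_k) && nrow(config$bonds) > 0L) {
    b <- config$bonds
    inside <- b[, 1L] %in% sel & b[, 2L] %in% sel
    if (any(inside)) {
      bb <- b[inside, , drop = FALSE]
      k <- rep_len(config$bond_k, nrow(config$bonds))[inside]
      r0 <- rep_len(config$bond_r0, nrow(config$bonds))[inside]
      d <- min_image(config$positions[bb[, 1L], , drop = FALSE] -
                     config$positions[bb[, 2L], , drop = FALSE],
                     config$box, config_periodic_dims(config))
      r <- sqrt(rowSums(d^2))
      etot <- etot + sum(0.5 * k * (r - r0)^2)
    }
  }
  etot
}

#' Adhesion energy of a matrix/substrate assembly
#'
#' `E_adh = E_tot - (E_mat + E_sub)`: the total energy of the assembly
#' minus the energies of the isolated matrix and substrate. For the
#' pairwise-additive potentials used here this equals the cross-group
#' interaction sum exactly. Reported per interface area in mJ/m^2 (one
#' interface), with attraction (negative raw energy) as positive adhesion;
#' the signed raw energies are retained in `vdw`, `elec`, `total`.
#'
#' @param config an `fk_config` whose groups include the two selections.
#' @param sel_mat,sel_sub matrix and substrate atom indices.
#' @param interface_area interface area (Angstrom^2); `NULL` takes the x-y
#'   cross-section of the box.
#' @param cutoff,mixing as in [group_interaction()].
#' @return An `fk_energy` with `per_area` in mJ/m^2.
#' @export
adhesion_energy <- function(config, sel_mat, sel_sub, interface_area = NULL,
                            cutoff = NULL, mixing = "sixth_power") {
  if (is.null(interface_area)) {
    if (is.null(config$box)) stop("interface area required for non-periodic systems")
    a <- config$box[1L, 1:2]; b <- config$box[2L, 1:2]
    interface_area <- abs(a[1L] * b[2L] - a[2L] * b[1L])
  }
  if (interface_area <= 0) stop("interface area must be positive")
  cross <- group_interaction(config, sel_mat, sel_sub, cutoff, mixing)
  energy_breakdown(cross$vdw, cross$elec, cross$n_pairs, area = interface_area)
}

#' Per-atom non-bonded forces
#'
#' Analytic gradients of the LJ + Coulomb (+ harmonic bond) energy;
#' per-pair contributions obey Newton's third law by construction.
#'
#' @param config an `fk_config`.
#' @param cutoff pair cutoff (Angstrom) or NULL for all pairs.
#' @param mixing LJ mixing rule.
#' @return N x 3 matrix of forces (kcal/mol/Angstrom).
#' @export
pair_forces <- function(config, cutoff = NULL, mixing = "sixth_power") {
  n <- n_atoms(config)
  f <- matrix(0, n, 3L)
  pw <- pairwise_terms(config, cutoff, mixing)
  if (!nrow(pw$pairs)) return(f)
  # force on i from j: -dV/dr * unit(r_i - r_j)
  fmag <- -pw$dVdr / pw$r
  fij <- pw$d * fmag
  for (a in 1:3) {
    f[, a] <- f[, a] +
      unname(tapply(fij[, a], factor(pw$pairs[, 1L], levels = seq_len(n)), sum,
                    default = 0)) -
      unname(tapply(fij[, a], factor(pw$pairs[, 2L], levels = seq_len(n)), sum,
                    default = 0))
  }
  f
}

# shared pair machinery for forces and virial stress: all unique pairs with
# minimum-image displacement d = r_i - r_j, separation r, and dV/dr
pairwise_terms <- function(config, cutoff = NULL, mixing = "sixth_power") {
  n <- n_atoms(config)
  pr <- pair_index(n)
  empty <- list(pairs = matrix(integer(0), ncol = 2L),
                d = matrix(0, 0L, 3L), r = numeric(0), dVdr = numeric(0))
  if (!nrow(pr)) return(empty)
  d <- min_image(config$positions[pr[, 1L], , drop = FALSE] -
                 config$positions[pr[, 2L], , drop = FALSE],
                 config$box, config_periodic_dims(config))
  r <- sqrt(rowSums(d^2))
  if (any(r < 1e-12)) {
    k <- which(r < 1e-12)[1L]
    stop(sprintf("degenerate geometry: atoms %d and %d coincide",
                 pr[k, 1L], pr[k, 2L]))
  }
  key <- bonded_key(config$bonds, n)
  is_bonded <- (pr[, 1L] * (n + 1) + pr[, 2L]) %in% key
  dVdr <- numeric(nrow(pr))
  nb <- !is_bonded
  if (!is.null(cutoff)) nb <- nb & r <= cutoff
  if (any(nb)) {
    p <- mix_lj(config$lj_epsilon[pr[nb, 1L]], config$lj_epsilon[pr[nb, 2L]],
                config$lj_rmin[pr[nb, 1L]], config$lj_rmin[pr[nb, 2L]], mixing)
    dVdr[nb] <- lj_dVdr(r[nb], p$eps, p$rmin) -
      fk_units$coulomb_k * config$charges[pr[nb, 1L]] *
      config$charges[pr[nb, 2L]] / r[nb]^2
  }
  if (!is.null(config$bond_k) && any(is_bonded)) {
    # match bonded pairs to their spring parameters
    key_all <- pr[is_bonded, 1L] * (n + 1) + pr[is_bonded, 2L]
    idx <- match(key_all, key)
    k <- rep_len(config$bond_k, nrow(config$bonds))[idx]
    r0 <- rep_len(config$bond_r0, nrow(config$bonds))[idx]
    dVdr[is_bonded] <- k * (r[is_bonded] - r0)
  }
  keep <- dVdr != 0 | !is_bonded
  if (!is.null(cutoff)) keep <- keep & (r <= cutoff | is_bonded)
  list(pairs = pr[keep, , drop = FALSE], d = d[keep, , drop = FALSE],
       r = r[keep], dVdr = dVdr[keep])
}
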