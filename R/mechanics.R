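# Virial stress of static configurations and Young's modulus from affine
# strain series. The kinetic virial term is omitted throughout: inputs are
# minimized snapshots, not finite-temperature ensembles.

#' Virial stress tensor of a periodic configuration
#'
#' Potential (static) part of the virial stress,
#' `sigma_ab = (1/V) sum_pairs (dV/dr / r) r_a r_b`, which equals
#' `+(1/V) dE/d(eps_ab)` under affine strain — the continuum,
#' tension-positive convention. Symmetric by construction.
#'
#' @param config a periodic `fk_config`.
#' @param cutoff pair cutoff (Angstrom) or NULL.
#' @param mixing LJ mixing rule.
#' @return 3 x 3 stress tensor in GPa.
#' @export
virial_stress <- function(config, cutoff = NULL, mixing = "sixth_power") {
  if (is.null(config$box)) stop("virial stress requires a periodic box")
  V <- det(config$box)
  pw <- pairwise_terms(config, cutoff, mixing)
  sigma <- matrix(0, 3L, 3L)
  if (nrow(pw$pairs)) {
    w <- pw$dVdr / pw$r
    for (a in 1:3) for (b in a:3) {
      sigma[a, b] <- sum(w * pw$d[, a] * pw$d[, b])
      sigma[b, a] <- sigma[a, b]
    }
  }
  sigma / V * fk_units$kcalmol_A3_to_GPa
}

#' Young's modulus from an affine strain series
#'
#' Each frame of the trajectory is an affinely strained copy of the first
#' (reference) frame along `axis`; engineering strains are read off the box
#' edge relative to the reference. Axial virial stress is regressed on
#' strain with an intercept (absorbing residual pre-stress of the
#' minimized reference); the slope is the modulus. Frames with non-finite
#' stress are rejected and reported.
#'
#' @param traj an `fk_traj` strain series (reference frame first).
#' @param axis 1, 2 or 3 (or "x","y","z").
#' @param cutoff,mixing forwarded to [virial_stress()].
#' @return list with `E` (GPa), and a `series` data.frame (strain,
#'   stress_axial GPa), `fit_intercept`, `r_squared`, `n_rejected`.
#' @export
youngs_modulus <- function(traj, axis = 3L, cutoff = NULL,
                           mixing = "sixth_power") {
  axis <- axis_index(axis)
  ref <- traj$frames[[1L]]
  if (is.null(ref$box)) stop("strain series requires periodic frames")
  L0 <- ref$box[axis, axis]
  strain <- vapply(traj$frames, function(f) f$box[axis, axis] / L0 - 1,
                   numeric(1L))
  stress <- vapply(traj$frames, function(f) {
    s <- try(virial_stress(f, cutoff, mixing), silent = TRUE)
    if (inherits(s, "try-error")) NA_real_ else s[axis, axis]
  }, numeric(1L))
  ok <- is.finite(stress)
  if (sum(ok) < 3L) stop("fewer than 3 valid frames in strain series")
  fit <- stats::lm(stress[ok] ~ strain[ok])
  list(E = unname(stats::coef(fit)[2L]),
       fit_intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared,
       n_rejected = sum(!ok),
       series = data.frame(strain = strain[ok], stress_axial = stress[ok]))
}

axis_index <- function(axis) {
  if (is.character(axis)) axis <- match(tolower(axis), c("x", "y", "z"))
  axis <- as.integer(axis)
  if (is.na(axis) || axis < 1L || axis > 3L) stop("axis must be x, y or z")
  axis
}

#' Affinely strain a configuration along one axis
#'
#' Scales both the box and the coordinates by `(1 + strain)` along `axis`
#' (engineering strain).
#'
#' @param config a periodic `fk_config`.
#' @param strain engineering strain.
#' @param axis 1, 2, 3 or "x","y","z".
#' @return the strained `fk_config`.
#' @export
apply_strain <- function(config, strain, axis = 3L) {
  axis <- axis_index(axis)
  config$positions[, axis] <- config$positions[, axis] * (1 + strain)
  config$box[, axis] <- config$box[, axis] * (1 + strain)
  config
}
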