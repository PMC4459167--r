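# Glass-transition breakpoint fitting, densities, rule-of-mixture and
# stoichiometric composition algebra, diffusion timing.

#' Specific-volume vs temperature curve
#'
#' @param temperatures strictly monotone temperatures (K), length >= 6.
#' @param specific_volume specific volumes (cc/g).
#' @return An `fk_vtcurve` data.frame.
#' @export
vtcurve <- function(temperatures, specific_volume) {
  temperatures <- as.numeric(temperatures)
  specific_volume <- as.numeric(specific_volume)
  if (length(temperatures) != length(specific_volume))
    stop("temperatures and specific_volume must have equal length")
  if (length(temperatures) < 6L) stop("need at least 6 points")
  d <- diff(temperatures)
  if (!(all(d > 0) || all(d < 0))) stop("temperatures must be strictly monotone")
  structure(data.frame(temperature = temperatures,
                       specific_volume = specific_volume),
            class = c("fk_vtcurve", "data.frame"))
}

# SSE of the continuous two-segment (hinge) model with breakpoint Tb
hinge_sse <- function(Tb, T, v) {
  fit <- stats::lm(v ~ T + pmax(T - Tb, 0))
  sum(stats::resid(fit)^2)
}

#' Glass-transition temperature from a specific-volume curve
#'
#' Fits a continuous two-segment linear model v(T) with the breakpoint
#' chosen by grid search over interior data temperatures — the outer 10%
#' of the temperature range is excluded, since breakpoints that depend on
#' the temperature boundaries are not transitions — refined by
#' golden-section search to 0.1 K. When the two-segment model improves the
#' single-line SSE by less than `min_improvement` the curve is flagged as
#' having no transition.
#'
#' @param curve an `fk_vtcurve` (or data.frame with `temperature`,
#'   `specific_volume`).
#' @param exclude_frac fraction of the temperature range excluded at each
#'   end (default 0.1).
#' @param min_improvement minimal relative SSE improvement over a single
#'   line (default 0.05).
#' @return list: `tg` (K, NA when no transition), `slope_glass`,
#'   `slope_melt` (cc/g/K), `sse`, `no_transition`.
#' @export
fit_glass_transition <- function(curve, exclude_frac = 0.1,
                                 min_improvement = 0.05) {
  T <- curve$temperature; v <- curve$specific_volume
  if (length(T) < 6L) stop("need at least 6 points")
  rng <- range(T)
  lo <- rng[1L] + exclude_frac * diff(rng)
  hi <- rng[2L] - exclude_frac * diff(rng)
  cand <- sort(T[T > lo & T < hi])
  if (length(cand) < 2L) stop("too few interior candidate breakpoints")
  sse_grid <- vapply(cand, hinge_sse, numeric(1L), T = T, v = v)
  b <- which.min(sse_grid)
  span <- c(cand[max(1L, b - 1L)], cand[min(length(cand), b + 1L)])
  opt <- stats::optimize(hinge_sse, interval = span, T = T, v = v, tol = 0.1)
  tg <- opt$minimum; sse2 <- opt$objective
  if (sse_grid[b] < sse2) { tg <- cand[b]; sse2 <- sse_grid[b] }
  fit1 <- stats::lm(v ~ T)
  sse1 <- sum(stats::resid(fit1)^2)
  # a perfect single line (sse1 at rounding level) offers nothing for a
  # hinge to improve
  tiny <- 1e-12 * sum((v - mean(v))^2)
  improvement <- if (sse1 > tiny) (sse1 - sse2) / sse1 else 0
  no_transition <- improvement < min_improvement
  fit2 <- stats::lm(v ~ T + pmax(T - tg, 0))
  cf <- stats::coef(fit2)
  list(tg = if (no_transition) NA_real_ else tg,
       slope_glass = unname(cf[2L]),
       slope_melt = unname(cf[2L] + cf[3L]),
       sse = sse2, no_transition = no_transition)
}

#' Mass density of a periodic configuration
#'
#' @param config a periodic `fk_config` with masses.
#' @return density (g/cc).
#' @export
mass_density <- function(config) {
  if (is.null(config$box)) stop("density requires a periodic box")
  sum(config$masses) / det(config$box) * fk_units$amu_A3_to_gcc
}

#' Two-component mixture specification
#'
#' Lignin (L) and hemicellulose (H) component properties and their
#' volumetric ratio, the inputs of the rule-of-mixture and composition
#' calculations.
#'
#' @param rho_L,rho_H component densities (g/cc).
#' @param M_L,M_H molecular masses (g/mol).
#' @param r_LH lignin:hemicellulose volume ratio (dimensionless).
#' @return An `fk_mixture` list.
#' @export
mixture_spec <- function(rho_L, rho_H, M_L = NA_real_, M_H = NA_real_,
                         r_LH = 1.0) {
  vals <- c(rho_L, rho_H, r_LH)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("densities and volume ratio must be positive")
  structure(list(rho_L = rho_L, rho_H = rho_H, M_L = M_L, M_H = M_H,
                 r_LH = r_LH), class = "fk_mixture")
}

#' Rule-of-mixture density of the two-component composite
#'
#' Volume-fraction-weighted mean:
#' `rho = (r_LH * rho_L + rho_H) / (r_LH + 1)`.
#'
#' @param spec an [mixture_spec()].
#' @return density (g/cc).
#' @export
mixture_density <- function(spec) {
  (spec$r_LH * spec$rho_L + spec$rho_H) / (spec$r_LH + 1)
}

#' Ratio of lignin to hemicellulose unit counts
#'
#' From equating the volume ratio
#' `(N_L M_L / rho_L) / (N_H M_H / rho_H) = r_LH`:
#' `N_L / N_H = r_LH * (rho_L / rho_H) * (M_H / M_L)`.
#'
#' @param spec an [mixture_spec()] with molecular masses.
#' @return dimensionless count ratio.
#' @export
composition_ratio <- function(spec) {
  if (!is.finite(spec$M_L) || !is.finite(spec$M_H))
    stop("composition_ratio requires molecular masses")
  spec$r_LH * (spec$rho_L / spec$rho_H) * (spec$M_H / spec$M_L)
}

#' Diffusion time to travel a distance
#'
#' One-dimensional mean-squared-displacement relation `t = x^2 / (2 D)`,
#' used to budget how long a mobile layer needs to reach its substrate.
#'
#' @param distance travel distance (m), >= 0.
#' @param D diffusion constant (m^2/s), > 0.
#' @return time (s).
#' @export
diffusion_time <- function(distance, D) {
  if (any(distance < 0) || any(D <= 0))
    stop("distance must be >= 0 and D > 0")
  distance^2 / (2 * D)
}

#' Percent excess of a over b
#'
#' `100 (a - b) / b`.
#'
#' @param a,b values; `b` nonzero.
#' @return percent.
#' @export
percent_excess <- function(a, b) {
  if (any(b == 0)) stop("reference value must be nonzero")
  100 * (a - b) / b
}
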