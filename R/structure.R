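# Radial distribution functions, peak detection, axial concentration
# profiles. RDFs use the standard shell-volume / ideal-gas normalization so
# g(r) -> 1 at large r in homogeneous systems.

# all cross minimum-image distances between two position sets; fast path
# for diagonal (orthorhombic) boxes
cross_distances <- function(posA, posB, box, periodic_dims = c(TRUE, TRUE, TRUE)) {
  diagonal <- !is.null(box) && all(box[row(box) != col(box)] == 0)
  if (is.null(box) || diagonal) {
    d2 <- matrix(0, nrow(posA), nrow(posB))
    for (a in 1:3) {
      da <- outer(posA[, a], posB[, a], "-")
      if (diagonal && periodic_dims[a]) {
        L <- box[a, a]
        da <- da - L * floor(da / L + 0.5)
      }
      d2 <- d2 + da^2
    }
    sqrt(d2)
  } else {
    ii <- rep(seq_len(nrow(posA)), times = nrow(posB))
    jj <- rep(seq_len(nrow(posB)), each = nrow(posA))
    d <- min_image(posA[ii, , drop = FALSE] - posB[jj, , drop = FALSE],
                   box, periodic_dims)
    matrix(sqrt(rowSums(d^2)), nrow(posA), nrow(posB))
  }
}

#' Radial distribution function between two selections
#'
#' Histograms minimum-image pair distances over the frames of a trajectory
#' and normalizes by the spherical shell volume `4 pi r^2 dr`, the number
#' density of the B selection, and the count of A atoms, so that g(r) = 1
#' for an ideal gas. Self pairs are excluded when the selections coincide;
#' frames are equal-weighted.
#'
#' @param traj an `fk_traj` (or a single `fk_config`).
#' @param selA,selB atom index selections.
#' @param dr bin width (Angstrom, default 0.05).
#' @param r_max histogram range; default half the minimum box dimension
#'   minus one bin.
#' @return An `fk_rdf`: data.frame (`bin_center`, `g`) with metadata
#'   attributes.
#' @export
rdf <- function(traj, selA, selB, dr = 0.05, r_max = NULL) {
  if (inherits(traj, "fk_config")) traj <- trajectory(list(traj))
  selA <- sort(unique(as.integer(selA)))
  selB <- sort(unique(as.integer(selB)))
  if (!length(selA) || !length(selB)) stop("empty selection")
  if (dr <= 0) stop("dr must be positive")
  ref <- traj$frames[[1L]]
  if (is.null(ref$box)) stop("rdf requires a periodic box")
  Lmin <- min(abs(diag(ref$box)))
  if (is.null(r_max)) r_max <- Lmin / 2 - dr
  if (r_max > Lmin / 2 + 1e-9)
    stop("r_max exceeds half the minimum box dimension")
  breaks <- seq(0, r_max, by = dr)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  counts <- numeric(length(breaks) - 1L)
  same <- identical(selA, selB)
  for (f in traj$frames) {
    dm <- cross_distances(f$positions[selA, , drop = FALSE],
                          f$positions[selB, , drop = FALSE],
                          f$box, config_periodic_dims(f))
    if (same) diag(dm) <- NA_real_
    d <- dm[!is.na(dm) & dm < r_max]
    counts <- counts + graphics::hist(d, breaks = breaks, plot = FALSE)$counts
  }
  V <- det(ref$box)
  centers <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  widths <- diff(breaks)
  rho_B <- (length(selB) - same) / V
  norm <- length(traj$frames) * length(selA) * rho_B * 4 * pi * centers^2 * widths
  g <- counts / norm
  structure(data.frame(bin_center = centers, g = g),
            class = c("fk_rdf", "data.frame"),
            selA_label = attr(selA, "label") %||% "A",
            selB_label = attr(selB, "label") %||% "B",
            n_frames = length(traj$frames), dr = dr, r_max = r_max)
}

#' Detect peaks in a radial distribution function
#'
#' Local maxima of g(r) with topographic prominence at least
#' `min_prominence`, reported sorted by position (ties broken by smaller
#' r).
#'
#' @param rdf_result an `fk_rdf` (or any data.frame with `bin_center`,
#'   `g`).
#' @param min_prominence prominence threshold in g-units (default 0.1).
#' @return data.frame (`position`, `height`); possibly zero rows.
#' @export
find_rdf_peaks <- function(rdf_result, min_prominence = 0.1) {
  g <- rdf_result$g
  x <- rdf_result$bin_center
  n <- length(g)
  peaks <- data.frame(position = numeric(0), height = numeric(0))
  if (n < 3L) return(peaks)
  for (i in 2:(n - 1L)) {
    if (!(g[i] > g[i - 1L] && g[i] >= g[i + 1L])) next
    # prominence: drop to the highest saddle separating this peak from a
    # higher one (or from the record boundary)
    left <- g[seq_len(i - 1L)]
    higher_l <- which(left > g[i])
    base_l <- if (length(higher_l)) min(g[(max(higher_l) + 1L):(i - 1L)])
              else min(left)
    right <- g[(i + 1L):n]
    higher_r <- which(right > g[i])
    base_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1L)])
              else min(right)
    prom <- g[i] - max(base_l, base_r)
    if (prom >= min_prominence)
      peaks <- rbind(peaks, data.frame(position = x[i], height = g[i]))
  }
  peaks[order(peaks$position), , drop = FALSE]
}

#' Relative concentration profile along a box axis
#'
#' Bins the selected atoms' coordinates along one axis and normalizes the
#' counts to mean 1 over the occupied bins (bins with at least one atom),
#' matching the relative-concentration convention of surface analyses.
#'
#' @param config an `fk_config`.
#' @param sel atom index selection (non-empty).
#' @param axis 1:3 or "x","y","z".
#' @param bin_width bin width (Angstrom).
#' @return An `fk_profile`: data.frame (`bin_center`,
#'   `relative_concentration`) with the `mode` (bin centre of the maximum)
#'   as an attribute.
#' @export
density_profile <- function(config, sel, axis = 3L, bin_width = 0.2) {
  axis <- axis_index(axis)
  sel <- as.integer(sel)
  if (!length(sel)) stop("empty selection")
  if (bin_width <= 0) stop("bin_width must be positive")
  z <- config$positions[sel, axis]
  lo <- if (!is.null(config$box)) min(0, min(z)) else min(z) - bin_width / 2
  hi <- if (!is.null(config$box)) max(config$box[axis, axis], max(z))
        else max(z) + bin_width / 2
  breaks <- seq(lo, hi + bin_width, by = bin_width)
  counts <- graphics::hist(z, breaks = breaks, plot = FALSE)$counts
  centers <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  occupied <- counts > 0L
  rel <- counts / mean(counts[occupied])
  structure(data.frame(bin_center = centers, relative_concentration = rel),
            class = c("fk_profile", "data.frame"),
            axis = axis, bin_width = bin_width,
            mode = centers[which.max(counts)])
}
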