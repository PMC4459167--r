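#' Molecular configuration
#'
#' The universal container every analysis in the package consumes: atomic
#' positions with elements, masses, partial charges and per-atom
#' Lennard-Jones parameters, an explicit covalent bond list, an optional
#' periodic box, and named atom groups.
#'
#' LJ parameters use the r_min (equilibrium-distance) convention,
#' `V(r) = eps * ((rmin/r)^12 - 2 (rmin/r)^6)`; sigma-form inputs must be
#' converted on construction (`rmin = 2^(1/6) * sigma`). Bonds are explicit
#' input — nothing in the package guesses bonds from distances unless
#' `infer_bonds()` is called deliberately, because hydrogen-bond donor
#' identification must not depend on guessed topology.
#'
#' @param positions numeric N x 3 matrix of coordinates (Angstrom).
#' @param elements character vector of N chemical symbols.
#' @param masses numeric N vector (amu); defaults to standard atomic masses
#'   looked up from `elements`.
#' @param charges numeric N vector (elementary charge e); default 0.
#' @param lj_epsilon numeric N vector of LJ well depths (kcal/mol); default 0.
#' @param lj_rmin numeric N vector of LJ equilibrium distances (Angstrom);
#'   default 1 (irrelevant wherever epsilon is 0).
#' @param bonds integer M x 2 matrix of 1-based atom index pairs (may have
#'   zero rows).
#' @param box 3 x 3 matrix whose rows are lattice vectors (Angstrom), or
#'   NULL for a non-periodic system.
#' @param groups named list of integer index vectors.
#' @param bond_k,bond_r0 optional harmonic bond parameters (kcal/mol/A^2 and
#'   Angstrom, scalar or length M): when present, bonded pairs interact
#'   through `0.5 k (r - r0)^2` springs and are excluded from the non-bonded
#'   sums. Used by the analytic lattice generators.
#' @return An object of class `fk_config`.
#' @export
configuration <- function(positions, elements,
                          masses = NULL, charges = NULL,
                          lj_epsilon = NULL, lj_rmin = NULL,
                          bonds = NULL, box = NULL, groups = list(),
                          bond_k = NULL, bond_r0 = NULL) {
  positions <- as.matrix(positions)
  dimnames(positions) <- NULL
  if (ncol(positions) != 3L) stop("positions must be an N x 3 matrix")
  n <- nrow(positions)
  if (!all(is.finite(positions))) stop("non-finite coordinates")
  elements <- canonical_element(as.character(elements))
  if (length(elements) != n) stop("elements length must match positions")
  if (is.null(masses)) masses <- element_mass(elements)
  if (is.null(charges)) charges <- numeric(n)
  if (is.null(lj_epsilon)) lj_epsilon <- numeric(n)
  if (is.null(lj_rmin)) lj_rmin <- rep(1, n)
  stopifnot(length(masses) == n, length(charges) == n,
            length(lj_epsilon) == n, length(lj_rmin) == n)
  if (any(lj_epsilon < 0)) stop("lj_epsilon must be >= 0")
  if (any(lj_rmin <= 0)) stop("lj_rmin must be > 0")
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2L)
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (nrow(bonds) > 0L) {
    if (any(bonds < 1L) || any(bonds > n)) stop("bond index out of range")
    bonds <- t(apply(bonds, 1L, sort))
    bonds <- unique(bonds)
    bonds <- bonds[order(bonds[, 1L], bonds[, 2L]), , drop = FALSE]
  }
  if (!is.null(box)) {
    box <- matrix(as.numeric(box), 3L, 3L)
    if (det(box) <= 0) stop("periodic box must have det(box) > 0")
  }
  groups <- lapply(groups, function(g) {
    g <- sort(unique(as.integer(g)))
    if (length(g) && (min(g) < 1L || max(g) > n)) stop("group index out of range")
    g
  })
  structure(
    list(positions = positions, elements = elements, masses = as.numeric(masses),
         charges = as.numeric(charges), lj_epsilon = as.numeric(lj_epsilon),
         lj_rmin = as.numeric(lj_rmin), bonds = bonds, box = box,
         groups = groups, bond_k = bond_k, bond_r0 = bond_r0),
    class = "fk_config")
}

#' @export
print.fk_config <- function(x, ...) {
  cat(sprintf("<fk_config> %d atoms, %d bonds, %s, %d group(s)\n",
              n_atoms(x), nrow(x$bonds),
              if (is.null(x$box)) "non-periodic" else "periodic",
              length(x$groups)))
  invisible(x)
}

#' Number of atoms in a configuration
#' @param config an `fk_config`.
#' @export
n_atoms <- function(config) nrow(config$positions)

#' Trajectory of configurations sharing a topology
#'
#' @param frames list of `fk_config` objects with identical atom counts,
#'   elements and bond lists (the box may vary frame to frame, as it does
#'   in a strain series).
#' @param frame_times optional numeric vector of frame times (ps).
#' @return An object of class `fk_traj`.
#' @export
trajectory <- function(frames, frame_times = NULL) {
  stopifnot(length(frames) >= 1L)
  ref <- frames[[1L]]
  for (f in frames) {
    if (n_atoms(f) != n_atoms(ref)) stop("frames differ in atom count")
    if (!identical(f$elements, ref$elements)) stop("frames differ in elements")
    if (!identical(f$bonds, ref$bonds)) stop("frames differ in bonds")
  }
  structure(list(frames = frames, frame_times = frame_times),
            class = "fk_traj")
}

#' @export
print.fk_traj <- function(x, ...) {
  cat(sprintf("<fk_traj> %d frame(s) of %d atoms\n",
              length(x$frames), n_atoms(x$frames[[1L]])))
  invisible(x)
}

#' @export
length.fk_traj <- function(x) length(x$frames)

# --- element bookkeeping -----------------------------------------------

.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     P = 30.974, S = 32.06, X = 1)

canonical_element <- function(e) {
  e <- trimws(e)
  out <- paste0(toupper(substr(e, 1L, 1L)), tolower(substr(e, 2L, nchar(e))))
  out[nchar(e) == 0L] <- "X"
  out
}

element_mass <- function(elements) {
  m <- .element_masses[elements]
  m[is.na(m)] <- 1
  unname(m)
}

covalent_radius <- function(elements) {
  r <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, P = 1.07, S = 1.05)[elements]
  r[is.na(r)] <- 0.8
  unname(r)
}

# --- periodic geometry -------------------------------------------------

#' Minimum-image displacement between two atoms
#'
#' Returns the displacement from atom `j` to atom `i` under the nearest
#' periodic image. The canonical fractional wrap is refined by a 3x3x3
#' neighbour-image search so the result is the true nearest image even in
#' strongly skewed triclinic boxes; without a box the plain difference is
#' returned.
#'
#' @param config an `fk_config`.
#' @param i,j atom indices (1-based).
#' @return length-3 displacement vector (Angstrom).
#' @export
minimum_image_displacement <- function(config, i, j) {
  d <- config$positions[i, ] - config$positions[j, ]
  drop(min_image(matrix(d, 1L), config$box))
}

#' Apply the minimum-image convention to displacement vectors
#'
#' @param d numeric M x 3 matrix of raw displacement vectors.
#' @param box 3 x 3 lattice matrix (rows are lattice vectors) or NULL.
#' @param periodic_dims logical length-3: which lattice directions are
#'   treated as periodic (slab systems wrap in x,y only).
#' @return M x 3 matrix of minimum-image displacements.
#' @export
min_image <- function(d, box, periodic_dims = c(TRUE, TRUE, TRUE)) {
  d <- matrix(d, ncol = 3L)
  if (is.null(box)) return(d)
  if (abs(det(box)) < 1e-12) stop("singular periodic box")
  inv <- solve(box)
  frac <- d %*% inv
  wrap <- frac
  wrap[, periodic_dims] <- frac[, periodic_dims] -
    floor(frac[, periodic_dims, drop = FALSE] + 0.5)
  best <- wrap %*% box
  bestn <- rowSums(best^2)
  offsets <- as.matrix(expand.grid(a = -1:1, b = -1:1, c = -1:1))
  offsets[, !periodic_dims] <- 0
  offsets <- unique(offsets)
  for (k in seq_len(nrow(offsets))) {
    off <- offsets[k, ]
    if (all(off == 0)) next
    cand <- best + matrix(off %*% box, nrow(best), 3L, byrow = TRUE)
    candn <- rowSums(cand^2)
    better <- candn < bestn - 1e-12
    if (any(better)) {
      best[better, ] <- cand[better, , drop = FALSE]
      bestn[better] <- candn[better]
    }
  }
  best
}

# --- selections --------------------------------------------------------

#' Select atoms by element, group name, or bonded pattern
#'
#' Selections are deterministic (sorted, unique). The bonded patterns are
#' the ones the analyses need:
#' \describe{
#'   \item{`hydroxyl_h`}{hydrogens bonded to an oxygen that also has at
#'     least one heavy-atom (non-H) neighbour, i.e. the H of an O-H group
#'     on a carbon skeleton. Water hydrogens do not qualify.}
#'   \item{`alkyl_h`}{hydrogens bonded to carbon.}
#' }
#'
#' @param config an `fk_config`.
#' @param element select all atoms of this chemical symbol.
#' @param group select a named group stored in the configuration.
#' @param pattern one of `"hydroxyl_h"`, `"alkyl_h"`.
#' @param label optional label attached to the selection.
#' @return An `fk_selection`: sorted integer indices with a `label`
#'   attribute.
#' @export
select_atoms <- function(config, element = NULL, group = NULL,
                         pattern = NULL, label = NULL) {
  n_args <- sum(!is.null(element), !is.null(group), !is.null(pattern))
  if (n_args != 1L) stop("give exactly one of element, group, pattern")
  if (!is.null(element)) {
    idx <- which(config$elements == canonical_element(element))
    if (is.null(label)) label <- paste0("element=", element)
  } else if (!is.null(group)) {
    if (!group %in% names(config$groups))
      stop(sprintf("unknown group '%s'", group))
    idx <- config$groups[[group]]
    if (is.null(label)) label <- group
  } else {
    idx <- switch(pattern,
      hydroxyl_h = hydroxyl_hydrogens(config),
      alkyl_h = bonded_hydrogens(config, "C"),
      stop(sprintf("unknown pattern '%s'", pattern)))
    if (is.null(label)) label <- pattern
  }
  as_selection(idx, label)
}

as_selection <- function(idx, label = "") {
  structure(sort(unique(as.integer(idx))), label = label,
            class = "fk_selection")
}

neighbour_list <- function(config) {
  n <- n_atoms(config)
  nb <- vector("list", n)
  b <- config$bonds
  for (k in seq_len(nrow(b))) {
    nb[[b[k, 1L]]] <- c(nb[[b[k, 1L]]], b[k, 2L])
    nb[[b[k, 2L]]] <- c(nb[[b[k, 2L]]], b[k, 1L])
  }
  nb
}

bonded_hydrogens <- function(config, partner_element) {
  b <- config$bonds
  if (nrow(b) == 0L) return(integer(0))
  el <- config$elements
  h1 <- b[el[b[, 1L]] == "H" & el[b[, 2L]] == partner_element, 1L]
  h2 <- b[el[b[, 2L]] == "H" & el[b[, 1L]] == partner_element, 2L]
  sort(unique(c(h1, h2)))
}

hydroxyl_hydrogens <- function(config) {
  el <- config$elements
  nb <- neighbour_list(config)
  hs <- bonded_hydrogens(config, "O")
  keep <- vapply(hs, function(h) {
    os <- nb[[h]][el[nb[[h]]] == "O"]
    any(vapply(os, function(o) any(el[nb[[o]]] != "H"), logical(1L)))
  }, logical(1L))
  hs[keep]
}

#' Hydroxyl-oxygen census
#'
#' Counts oxygens bonded to exactly one hydrogen and at least one heavy
#' atom — the O-H groups of a polymer skeleton. Water oxygens (two H, no
#' heavy neighbour) deliberately do not count.
#'
#' @param config an `fk_config` with a bond list.
#' @return integer count.
#' @export
count_hydroxyls <- function(config) {
  if (nrow(config$bonds) == 0L && n_atoms(config) > 0L &&
      any(config$elements == "O"))
    stop("bond list required to identify hydroxyl groups")
  el <- config$elements
  nb <- neighbour_list(config)
  os <- which(el == "O")
  sum(vapply(os, function(o) {
    nbe <- el[nb[[o]]]
    sum(nbe == "H") == 1L && any(nbe != "H")
  }, logical(1L)))
}

#' Infer covalent bonds from distances (optional heuristic)
#'
#' Off by default everywhere; bonds are normally explicit input. Cutoff is
#' `scale` times the sum of covalent radii.
#'
#' @param config an `fk_config`.
#' @param scale cutoff multiplier (default 1.2).
#' @return the configuration with the inferred bond list.
#' @export
infer_bonds <- function(config, scale = 1.2) {
  n <- n_atoms(config)
  if (n < 2L) return(config)
  rad <- covalent_radius(config$elements)
  pr <- pair_index(n)
  d <- sqrt(rowSums(min_image(config$positions[pr[, 1L], , drop = FALSE] -
                              config$positions[pr[, 2L], , drop = FALSE],
                              config$box)^2))
  keep <- d <= scale * (rad[pr[, 1L]] + rad[pr[, 2L]])
  config$bonds <- pr[keep, , drop = FALSE]
  config
}

#' Replicate a periodic configuration into a supercell
#'
#' Copies atoms, bonds, groups and per-atom parameters `nx x ny x nz`
#' times along the lattice vectors and scales the box accordingly. Used to
#' check that intensive quantities (densities, moduli, adhesion per area)
#' are invariant under supercell duplication.
#'
#' @param config a periodic `fk_config`.
#' @param nx,ny,nz replication factors (positive integers).
#' @return the replicated `fk_config`.
#' @export
replicate_cell <- function(config, nx = 2L, ny = 1L, nz = 1L) {
  if (is.null(config$box)) stop("replication requires a periodic box")
  reps <- as.matrix(expand.grid(x = 0:(nx - 1L), y = 0:(ny - 1L),
                                z = 0:(nz - 1L)))
  n <- n_atoms(config)
  pos <- NULL; bonds <- NULL
  groups <- lapply(config$groups, function(g) integer(0))
  for (k in seq_len(nrow(reps))) {
    shift <- drop(reps[k, ] %*% config$box)
    pos <- rbind(pos, sweep(config$positions, 2L, shift, "+"))
    off <- (k - 1L) * n
    if (nrow(config$bonds)) bonds <- rbind(bonds, config$bonds + off)
    for (gn in names(groups)) groups[[gn]] <- c(groups[[gn]],
                                                config$groups[[gn]] + off)
  }
  m <- nrow(reps)
  out <- configuration(pos, rep(config$elements, m),
                       masses = rep(config$masses, m),
                       charges = rep(config$charges, m),
                       lj_epsilon = rep(config$lj_epsilon, m),
                       lj_rmin = rep(config$lj_rmin, m),
                       bonds = bonds,
                       box = diag(c(nx, ny, nz)) %*% config$box,
                       groups = groups,
                       bond_k = config$bond_k, bond_r0 = config$bond_r0)
  out$periodic_dims <- config$periodic_dims
  out
}

# all unordered pairs i < j as a matrix
pair_index <- function(n) {
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  cbind(i, j)
}
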