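# Hydrogen-bond analysis: geometric detection (distance + angle criteria
# under the minimum image), a 12-10 CHARMM/DREIDING-style energy with an
# angular cosine term, cooperativity chains through the donor/acceptor
# graph, volumetric energy density, and the closed-form stiffness of an
# LJ-modelled hydrogen bond.

#' Hydrogen-bond detection and energy parameters
#'
#' @param D_hb well depth (kcal/mol).
#' @param R_hb equilibrium donor-acceptor distance (Angstrom).
#' @param cos_exponent even exponent of the angular cosine factor (2 or
#'   4; 4 is the DREIDING convention).
#' @param d_max maximum H...acceptor distance for detection (Angstrom;
#'   default 2.5).
#' @param theta_min minimum donor-H-acceptor angle for detection (degrees;
#'   default 120).
#' @return An `fk_hbond_params` list.
#' @export
hbond_params <- function(D_hb = 4.0, R_hb = 2.75, cos_exponent = 4L,
                         d_max = 2.5, theta_min = 120) {
  if (D_hb <= 0 || R_hb <= 0) stop("D_hb and R_hb must be positive")
  if (!cos_exponent %in% c(2L, 4L)) stop("cos_exponent must be 2 or 4")
  structure(list(D_hb = D_hb, R_hb = R_hb,
                 cos_exponent = as.integer(cos_exponent),
                 d_max = d_max, theta_min = theta_min),
            class = "fk_hbond_params")
}

#' 12-10 hydrogen-bond energy
#'
#' `E = D_hb * (5 (R_hb/R_DA)^12 - 6 (R_hb/R_DA)^10) * cos^p(theta_DHA)`,
#' the CHARMM/DREIDING-like form: minimum `-D_hb` at `R_DA = R_hb`,
#' `theta = 180` degrees; zero at `theta = 90` degrees.
#'
#' @param R_DA donor-acceptor distance (Angstrom), vectorized.
#' @param theta_DHA donor-H-acceptor angle (degrees), vectorized.
#' @param params an [hbond_params()] object.
#' @return energy (kcal/mol).
#' @export
hbond_energy <- function(R_DA, theta_DHA, params = hbond_params()) {
  if (any(R_DA <= 0)) stop("hbond_energy requires R_DA > 0")
  s <- params$R_hb / R_DA
  params$D_hb * (5 * s^12 - 6 * s^10) * cospi(theta_DHA / 180)^params$cos_exponent
}

#' Detect hydrogen bonds by geometric criteria
#'
#' Donors are hydrogens covalently bound to O or N; acceptors are O or N
#' atoms other than the donor heavy atom. A contact qualifies when the
#' H...acceptor minimum-image distance is at most `d_max` and the
#' donor-H-acceptor angle is at least `theta_min`. All qualifying
#' acceptors per hydrogen are reported unless `unique_per_h` keeps only
#' the lowest-energy partner. Deterministic ordering: by `h_idx`, then
#' `acceptor_idx`.
#'
#' @param config an `fk_config` with an explicit bond list.
#' @param params an [hbond_params()] object.
#' @param unique_per_h keep only the lowest-energy acceptor per hydrogen.
#' @return An `fk_hbonds` data.frame: `donor_idx`, `h_idx`,
#'   `acceptor_idx`, `r_HA`, `R_DA`, `theta_DHA`, `energy`.
#' @export
detect_hbonds <- function(config, params = hbond_params(),
                          unique_per_h = FALSE) {
  el <- config$elements
  if (nrow(config$bonds) == 0L && any(el == "H"))
    stop("bond list required to identify hydrogen-bond donors")
  nb <- neighbour_list(config)
  hs <- which(el == "H")
  hs <- hs[vapply(hs, function(h) any(el[nb[[h]]] %in% c("O", "N")),
                  logical(1L))]
  donors <- vapply(hs, function(h) nb[[h]][el[nb[[h]]] %in% c("O", "N")][1L],
                   integer(1L))
  acceptors <- which(el %in% c("O", "N"))
  out <- empty_hbonds()
  if (!length(hs) || !length(acceptors)) return(out)
  pd <- config_periodic_dims(config)
  for (k in seq_along(hs)) {
    h <- hs[k]; d <- donors[k]
    acc <- acceptors[acceptors != d]
    if (!length(acc)) next
    v_ha <- min_image(config$positions[acc, , drop = FALSE] -
                      matrix(config$positions[h, ], length(acc), 3L,
                             byrow = TRUE), config$box, pd)
    r_ha <- sqrt(rowSums(v_ha^2))
    near <- which(r_ha <= params$d_max)
    if (!length(near)) next
    v_hd <- drop(min_image(matrix(config$positions[d, ] -
                                  config$positions[h, ], 1L), config$box, pd))
    nd <- sqrt(sum(v_hd^2))
    cosang <- (v_ha[near, , drop = FALSE] %*% v_hd) / (r_ha[near] * nd)
    theta <- acos(pmin(pmax(drop(cosang), -1), 1)) * 180 / pi
    ok <- theta >= params$theta_min
    if (!any(ok)) next
    a_ok <- acc[near][ok]
    v_da <- min_image(config$positions[a_ok, , drop = FALSE] -
                      matrix(config$positions[d, ], length(a_ok), 3L,
                             byrow = TRUE), config$box, pd)
    R_DA <- sqrt(rowSums(v_da^2))
    rec <- data.frame(donor_idx = d, h_idx = h, acceptor_idx = a_ok,
                      r_HA = r_ha[near][ok], R_DA = R_DA,
                      theta_DHA = theta[ok],
                      energy = hbond_energy(R_DA, theta[ok], params))
    if (unique_per_h && nrow(rec) > 1L)
      rec <- rec[which.min(rec$energy), , drop = FALSE]
    out <- rbind(out, rec)
  }
  out <- out[order(out$h_idx, out$acceptor_idx), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fk_hbonds", "data.frame")
  out
}

empty_hbonds <- function() {
  structure(data.frame(donor_idx = integer(0), h_idx = integer(0),
                       acceptor_idx = integer(0), r_HA = numeric(0),
                       R_DA = numeric(0), theta_DHA = numeric(0),
                       energy = numeric(0)),
            class = c("fk_hbonds", "data.frame"))
}

#' Volumetric hydrogen-bond energy density
#'
#' Sum of absolute hydrogen-bond energies divided by the box volume,
#' in J/m^3 — the quantity that ranks materials by how much cohesive
#' hydrogen bonding a unit volume carries.
#'
#' @param config a periodic `fk_config`.
#' @param hbonds an `fk_hbonds` table (e.g. from [detect_hbonds()]).
#' @return list: `density_J_m3`, `count`, `mean_energy_kcal_mol`.
#' @export
hbond_energy_density <- function(config, hbonds) {
  if (is.null(config$box))
    stop("energy density requires a periodic box (volume undefined)")
  V_A3 <- det(config$box)
  total <- sum(abs(hbonds$energy))
  list(density_J_m3 = total * fk_units$kcalmol_to_J / (V_A3 * 1e-30),
       count = nrow(hbonds),
       mean_energy_kcal_mol = if (nrow(hbonds)) mean(hbonds$energy) else NA_real_)
}

#' Cooperativity chains in a hydrogen-bond network
#'
#' A bond is strengthened when its donor oxygen simultaneously accepts
#' another hydrogen bond. Directed graph on bonds with an edge i -> j when
#' the donor heavy atom of bond i is the acceptor of bond j; chains are
#' the maximal simple paths of at least two bonds.
#'
#' @param hbonds an `fk_hbonds` table.
#' @return list: `chains` (list of integer vectors of row indices into
#'   `hbonds`), `participation_fraction` (fraction of bonds in at least
#'   one chain).
#' @export
cooperativity_chains <- function(hbonds) {
  n <- nrow(hbonds)
  if (n < 2L) return(list(chains = list(), participation_fraction = 0))
  edges <- NULL
  for (i in seq_len(n)) {
    j <- which(hbonds$acceptor_idx == hbonds$donor_idx[i])
    if (length(j)) edges <- rbind(edges, cbind(i, j))
  }
  if (is.null(edges)) return(list(chains = list(), participation_fraction = 0))
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  paths <- list()
  for (v in seq_len(igraph::vcount(g))) {
    sp <- igraph::all_simple_paths(g, from = v, mode = "out")
    paths <- c(paths, lapply(sp, as.integer))
  }
  paths <- paths[lengths(paths) >= 2L]
  # keep only maximal paths (not a contiguous sub-path of a longer one)
  keys <- vapply(paths, function(p) paste0(",", paste(p, collapse = ","), ","),
                 "")
  is_sub <- vapply(seq_along(paths), function(i) {
    any(vapply(seq_along(paths), function(j) {
      i != j && nchar(keys[j]) > nchar(keys[i]) &&
        grepl(keys[i], keys[j], fixed = TRUE)
    }, logical(1L)))
  }, logical(1L))
  chains <- paths[!is_sub]
  list(chains = chains,
       participation_fraction = length(unique(unlist(chains))) / n)
}

#' Stiffness of an LJ-modelled hydrogen bond
#'
#' Second derivative of the r_m-form Lennard-Jones potential at its
#' minimum: `k = V''(r_m) = 72 eps / r_m^2`. SI in, SI out.
#'
#' @param eps well depth (J).
#' @param r_m equilibrium distance (m).
#' @return stiffness (J/m^2).
#' @export
lj_stiffness <- function(eps, r_m) {
  if (any(eps <= 0) || any(r_m <= 0)) stop("eps and r_m must be positive")
  72 * eps / r_m^2
}

#' Summary geometry statistics of a hydrogen-bond set
#'
#' @param hbonds a non-empty `fk_hbonds` table.
#' @return list: `mean_r_HA`, `range_r_HA`, `mean_theta`, `range_theta`.
#' @export
hbond_geometry_stats <- function(hbonds) {
  if (!nrow(hbonds)) stop("empty hydrogen-bond list")
  list(mean_r_HA = mean(hbonds$r_HA), range_r_HA = range(hbonds$r_HA),
       mean_theta = mean(hbonds$theta_DHA),
       range_theta = range(hbonds$theta_DHA))
}
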