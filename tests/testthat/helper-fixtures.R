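# Tiny molecule fixtures and scalar brute-force oracles, all built in code.

water <- function() {
  configuration(rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
                c("O", "H", "H"), bonds = rbind(c(1L, 2L), c(1L, 3L)))
}

methanol <- function() {
  # C-O-H backbone with three methyl hydrogens
  configuration(rbind(c(0, 0, 0),        # C
                      c(1.43, 0, 0),     # O
                      c(1.77, 0.90, 0),  # H (hydroxyl)
                      c(-0.51, 0.51, 0.86), c(-0.51, 0.51, -0.86),
                      c(-0.51, -1.02, 0)),
                c("C", "O", "H", "H", "H", "H"),
                bonds = rbind(c(1L, 2L), c(2L, 3L), c(1L, 4L), c(1L, 5L),
                              c(1L, 6L)))
}

methane <- function() {
  configuration(rbind(c(0, 0, 0), c(0.63, 0.63, 0.63), c(-0.63, -0.63, 0.63),
                      c(-0.63, 0.63, -0.63), c(0.63, -0.63, -0.63)),
                c("C", "H", "H", "H", "H"),
                bonds = cbind(1L, 2:5))
}

# exhaustive 27-image nearest displacement (independent of min_image)
oracle_min_image <- function(d, box) {
  best <- d; bestn <- sum(d^2)
  for (a in -1:1) for (b in -1:1) for (cc in -1:1) {
    cand <- d + a * box[1, ] + b * box[2, ] + cc * box[3, ]
    if (sum(cand^2) < bestn - 1e-12) { best <- cand; bestn <- sum(cand^2) }
  }
  best
}

# scalar O(N^2) hydrogen-bond scan, independent of detect_hbonds
oracle_hbonds <- function(config, d_max = 2.5, theta_min = 120) {
  el <- config$elements
  box <- config$box
  mi <- function(d) if (is.null(box)) d else oracle_min_image(d, box)
  # donor of each H: first bonded O/N
  donor_of <- rep(NA_integer_, n_atoms(config))
  for (k in seq_len(nrow(config$bonds))) {
    i <- config$bonds[k, 1]; j <- config$bonds[k, 2]
    if (el[i] == "H" && el[j] %in% c("O", "N") && is.na(donor_of[i]))
      donor_of[i] <- j
    if (el[j] == "H" && el[i] %in% c("O", "N") && is.na(donor_of[j]))
      donor_of[j] <- i
  }
  found <- NULL
  for (h in which(el == "H")) {
    d <- donor_of[h]
    if (is.na(d)) next
    for (a in which(el %in% c("O", "N"))) {
      if (a == d) next
      v_ha <- mi(config$positions[a, ] - config$positions[h, ])
      r <- sqrt(sum(v_ha^2))
      if (r > d_max) next
      v_hd <- mi(config$positions[d, ] - config$positions[h, ])
      ct <- sum(v_ha * v_hd) / (r * sqrt(sum(v_hd^2)))
      theta <- acos(max(-1, min(1, ct))) * 180 / pi
      if (theta >= theta_min) found <- rbind(found, c(d, h, a))
    }
  }
  if (is.null(found)) return(matrix(integer(0), ncol = 3L))
  found[order(found[, 2], found[, 3]), , drop = FALSE]
}

# random skewed triclinic box with positive determinant
random_triclinic <- function() {
  repeat {
    box <- diag(stats::runif(3, 6, 12)) + matrix(stats::runif(9, -2, 2), 3, 3)
    if (det(box) > 50) return(box)
  }
}
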