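#!/usr/bin/env Rscript
# Stage 2 — hydrogen-bond network and structure analysis of the three
# material-analogue boxes from stage 1: detection, geometry statistics,
# 12-10 energies and volumetric energy density, cooperativity chains, the
# hydroxyl-H vs O radial distribution function with its peaks, and the
# surface-slab concentration profiles. Tables land in results/.

library(fibrilkit)

data_dir <- "results/data"
stopifnot(dir.exists(data_dir)) # run analysis/01_synthesize.R first
dir.create("results", showWarnings = FALSE)

materials <- c("hemicellulose_like", "lcc_like", "lignin_like")
summary_rows <- list()
for (m in materials) {
  cfg <- read_xyz(file.path(data_dir, paste0(m, ".xyz")),
                  file.path(data_dir, paste0(m, ".yaml")))$frames[[1]]
  hb <- detect_hbonds(cfg)
  st <- hbond_geometry_stats(hb)
  dens <- hbond_energy_density(cfg, hb)
  coop <- cooperativity_chains(hb)
  write.csv(as.data.frame(hb),
            file.path("results", paste0("hbonds_", m, ".csv")),
            row.names = FALSE)
  summary_rows[[m]] <- data.frame(
    material = m, n_hbonds = nrow(hb),
    n_hydroxyls = count_hydroxyls(cfg),
    mean_r_HA = st$mean_r_HA, min_r_HA = st$range_r_HA[1],
    max_r_HA = st$range_r_HA[2], mean_theta = st$mean_theta,
    energy_density_J_m3 = dens$density_J_m3,
    cooperativity_fraction = coop$participation_fraction)
  message(sprintf(
    "%-20s %3d H-bonds / %3d hydroxyls; <r_HA> %.3f A, <theta> %.1f deg, %.3g J/m^3, %.0f%% in chains",
    m, nrow(hb), count_hydroxyls(cfg), st$mean_r_HA, st$mean_theta,
    dens$density_J_m3, 100 * coop$participation_fraction))
}
hb_summary <- do.call(rbind, summary_rows)
write.csv(hb_summary, "results/hbond_summary.csv", row.names = FALSE)
# denser hydroxyl networks should carry more volumetric H-bond energy
stopifnot(all(diff(hb_summary$energy_density_J_m3) < 0))
message("H-bond energy density ranks with hydroxyl density, as expected")

# hydroxyl-H vs O RDF of the densest box: covalent peak then H-bond peak
cfg <- read_xyz(file.path(data_dir, "hemicellulose_like.xyz"),
                file.path(data_dir, "hemicellulose_like.yaml"))$frames[[1]]
r <- rdf(cfg, select_atoms(cfg, pattern = "hydroxyl_h"),
         select_atoms(cfg, element = "O"), dr = 0.1, r_max = 8)
write.csv(as.data.frame(r), "results/rdf_hydroxylH_O.csv", row.names = FALSE)
pk <- find_rdf_peaks(r, min_prominence = 1.0)
write.csv(pk, "results/rdf_peaks.csv", row.names = FALSE)
message(sprintf("RDF peaks (A): %s — first non-covalent peak at %.2f A",
                paste(sprintf("%.2f", pk$position), collapse = ", "),
                pk$position[pk$position > 1.2][1]))

# surface slab: hydroxyl vs alkyl hydrogen layering along z
sl <- read_xyz(file.path(data_dir, "surface_slab.xyz"),
               file.path(data_dir, "surface_slab.yaml"))$frames[[1]]
p_oh <- density_profile(sl, select_atoms(sl, pattern = "hydroxyl_h"), "z", 0.2)
p_ch <- density_profile(sl, select_atoms(sl, pattern = "alkyl_h"), "z", 0.2)
write.csv(data.frame(bin_center = p_oh$bin_center,
                     rel_conc_OH = p_oh$relative_concentration,
                     rel_conc_CH = p_ch$relative_concentration),
          "results/surface_profiles.csv", row.names = FALSE)
message(sprintf(
  "surface hydrogens: O-H layer peaks at %.1f A, C-H layer at %.1f A (C-H more exposed)",
  attr(p_oh, "mode"), attr(p_ch, "mode")))
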