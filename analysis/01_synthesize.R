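#!/usr/bin/env Rscript
# Stage 1 — build the synthetic study systems all later stages analyse:
# a hydroxyl-network box per material analogue (hydroxyl density is the
# knob that separates hemicellulose-, LCC- and lignin-like matrices),
# substrate/matrix bilayer assemblies, affine strain series of analytic
# lattices, cooling curves, and a two-level surface slab. Everything is
# written as XYZ + YAML sidecar + ground-truth JSON under results/data/.

library(fibrilkit)
library(jsonlite)
library(yaml)

seed <- 20260927L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

write_system <- function(cfg, name, extra = list()) {
  write_xyz(cfg, file.path(out, paste0(name, ".xyz")))
  side <- list(charges = cfg$charges, lj_epsilon = cfg$lj_epsilon,
               lj_rmin = cfg$lj_rmin, masses = cfg$masses,
               bonds = lapply(seq_len(nrow(cfg$bonds)),
                              function(k) cfg$bonds[k, ]),
               groups = cfg$groups)
  write_yaml(side, file.path(out, paste0(name, ".yaml")), precision = 15L)
  if (length(extra))
    write_json(extra, file.path(out, paste0(name, "_truth.json")),
               auto_unbox = TRUE, digits = NA)
}

# hydroxyl-network boxes: same box, increasing hydroxyl-pair counts
pair_counts <- c(hemicellulose_like = 60, lcc_like = 40, lignin_like = 24)
for (m in names(pair_counts)) {
  b <- gen_hydroxyl_box(pair_counts[[m]], box_edge = 30,
                        r_HA_mean = 1.88, r_HA_sd = 0.12,
                        theta_mean_deg = 150.96, theta_sd_deg = 9,
                        seed = seed + match(m, names(pair_counts)))
  write_system(b$config, m,
               list(n_contacts = nrow(b$ground_truth), params = b$params))
  message(sprintf("%-20s %4d atoms, %3d constructed H-bond contacts",
                  m, n_atoms(b$config), nrow(b$ground_truth)))
}

# bilayer assemblies: full interaction, vdW-only, gap scan
bl <- gen_bilayer(n_sub = 50, n_mat = 50, gap = 5, seed = seed)
write_system(bl$config, "bilayer", bl$ground_truth)
bl_vdw <- gen_bilayer(n_sub = 50, n_mat = 50, gap = 5, charge_scale = 0,
                      seed = seed)
write_system(bl_vdw$config, "bilayer_vdw_only", bl_vdw$ground_truth)
message(sprintf("bilayer oracle interface energy: %.4f kcal/mol",
                bl$ground_truth$total))

# strain series (kept in memory by later stages; store the reference frame)
s_h <- gen_strain_series("harmonic_sc", seed = seed)
s_lj <- gen_strain_series("lj_fcc", seed = seed)
write_xyz(s_h$traj, file.path(out, "strain_harmonic.xyz"))
write_xyz(s_lj$traj, file.path(out, "strain_ljfcc.xyz"))
write_json(list(harmonic = s_h$ground_truth$true_modulus,
                lj_fcc = s_lj$ground_truth$true_modulus),
           file.path(out, "strain_truth.json"), auto_unbox = TRUE, digits = NA)
message(sprintf("strain series: analytic E = %.4f GPa, LJ-FCC oracle E = %.4f GPa",
                s_h$ground_truth$true_modulus, s_lj$ground_truth$true_modulus))

# one example cooling curve (stage 5 re-generates an ensemble)
cur <- gen_cooling_curve(tg_true = 450, seed = seed)
write.csv(as.data.frame(cur), file.path(out, "cooling_curve.csv"),
          row.names = FALSE)

# surface slab with the two hydrogen layers
sl <- gen_surface_slab(z_OH = 18.3, z_CH = 19.8, n_each = 100, seed = seed)
write_system(sl, "surface_slab")
message("wrote synthetic systems to ", out)
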