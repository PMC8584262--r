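#!/usr/bin/env Rscript
# Structural and dynamic observables of a synthetic reference bilayer.
#
# Generates a 648-lipid bilayer (324 per leaflet) at the POPC reference
# conditions -- APL 60.7 A^2, P-P thickness 3.78 nm, D 7.7 um^2/s, 303.15 K
# -- and recovers every observable with the package estimators: Voronoi
# area per lipid (with the tessellation-conservation check), P/C2-plane
# thickness, leaflet interdigitation, and the Einstein-relation lateral
# diffusion coefficient.

library(membramech)
dir.create("results", showWarnings = FALSE)
set.seed(101)

cat("== Synthetic reference bilayer: 324 lipids/leaflet ==\n")
gen <- make_lattice_membrane(n_lipids_per_leaflet = 324L, apl = 60.7,
                             thickness = 37.8, z_sigma = 1, xy_sigma = 1.5,
                             d_coeff = 7.7, tilt_sigma = 0.15,
                             n_frames = 60L, dt = 0.1, seed = 101L)
lf <- assign_leaflets(gen$frames, gen$topology)
refs <- reference_points(gen$frames, gen$topology)

apl <- area_per_lipid(gen$frames, lf, gen$topology, refs = refs)
mt_p <- membrane_thickness(gen$frames, lf, gen$topology, "P")
mt_c2 <- membrane_thickness(gen$frames, lf, gen$topology, "C2")
inter <- interdigitation(gen$frames, lf, gen$topology)
diff <- lateral_diffusion(gen$frames, lf, gen$topology, refs = refs)

tab <- data.frame(
  observable = c("APL", "MT_P-P", "MT_C2-C2", "interdigitation",
                 "2D diffusion"),
  value = c(as.numeric(apl$system_apl), as.numeric(mt_p$thickness),
            as.numeric(mt_c2$thickness), as.numeric(inter$width),
            as.numeric(diff$D)),
  uncertainty = c(apl$system_apl_se, mt_p$sd, mt_c2$sd, inter$sd,
                  diff$D_se),
  unit = c("A^2", "nm", "nm", "A", "um^2/s"),
  generator_target = c(60.7, 3.78, 3.78 - 0.2, NA, 7.7)
)
write.csv(tab, "results/table1_observables.csv", row.names = FALSE)
print(tab, digits = 4)
cat(sprintf("\nAPL recovered within %.2f%% of the generator target;\n",
            100 * abs(as.numeric(apl$system_apl) / 60.7 - 1)))
cat(sprintf("diffusion within %.2f%%. Results in results/table1_observables.csv\n",
            100 * abs(as.numeric(diff$D) / 7.7 - 1)))
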