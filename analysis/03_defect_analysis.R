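#!/usr/bin/env Rscript
# Hydrophobic defect probing of synthetic leaflet surfaces.
#
# Builds occupancy grids for bilayers with increasing acyl-chain exposure
# (emulated by shrinking the headgroup van der Waals radius so tails peek
# through) and traces the sphere-probe defect fraction over probe radii
# 0.1-0.5 nm. The curve decreases with probe radius: large probes ignore
# small packing gaps.

library(membramech)
dir.create("results", showWarnings = FALSE)

defect_curve_for <- function(head_vdw, seed) {
  top <- topology_set(lipid_topology(
    "SYN", head_atoms = c("P", "C2"), tail_atoms = "CT",
    p_atom = "P", c2_atom = "C2", terminal_atoms = "CT",
    vdw_radii = c(P = head_vdw, C2 = head_vdw, CT = 2.4)))
  gen <- make_lattice_membrane(n_lipids_per_leaflet = 100L, apl = 60.7,
                               xy_sigma = 2.5, tilt_sigma = 0.3,
                               n_frames = 4L, seed = seed)
  lf <- assign_leaflets(gen$frames, gen$topology)
  radii <- seq(0.1, 0.5, by = 0.05)
  per_frame <- lapply(seq_len(4L), function(f) {
    g <- occupancy_grid(gen$frames, lf, top, frame = f, leaflet = "upper")
    list(curve = probe_defect_fraction(g, radii)$fraction,
         fexp = exposed_fraction(g))
  })
  list(radii = radii,
       fraction = colMeans(do.call(rbind, lapply(per_frame, `[[`, "curve"))),
       fraction_sd = apply(do.call(rbind, lapply(per_frame, `[[`, "curve")),
                           2L, sd),
       f_exp = mean(vapply(per_frame, `[[`, 1, "fexp")))
}

out <- NULL
for (hv in c(3.2, 2.6, 2.2)) {
  r <- defect_curve_for(hv, seed = 400L + round(10 * hv))
  cat(sprintf("head vdW %.1f A: F_exp = %.3f, defect fraction %.3f (0.1 nm)",
              hv, r$f_exp, r$fraction[1L]),
      sprintf("-> %.4f (0.5 nm)\n", r$fraction[length(r$fraction)]))
  out <- rbind(out, data.frame(head_vdw = hv, radius_nm = r$radii,
                               fraction = r$fraction,
                               fraction_sd = r$fraction_sd,
                               f_exp = r$f_exp))
}
write.csv(out, "results/defect_curves.csv", row.names = FALSE)
stopifnot(all(tapply(out$fraction, out$head_vdw, function(x) all(diff(x) <= 1e-12))))
cat("\nEvery curve is monotone non-increasing in probe radius, and smaller\n")
cat("headgroups expose more acyl chain. Curves in results/defect_curves.csv\n")
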