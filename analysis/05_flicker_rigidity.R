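#!/usr/bin/env Rscript
# Flicker-noise spectroscopy recovery across the published rigidity range.
#
# Generates equilibrium Helfrich contour series for vesicles with bending
# rigidities spanning the published flicker values (1.1e-19 to 1.0e-18 J),
# runs both decompositions (statistical Fourier-histogram and average
# Legendre) and the Milner-Safran fit over modes 3-20, and tabulates the
# recovery error.

library(membramech)
dir.create("results", showWarnings = FALSE)

kappas <- c(0.5e-19, 1.1e-19, 1.9e-19, 2.6e-19, 7.8e-19, 10e-19)
rows <- lapply(seq_along(kappas), function(i) {
  kap <- kappas[i]
  cs <- make_fluctuating_vesicle(kappa = kap, sigma_bar = 10, R = 5,
                                 n_frames = 1200L, seed = 600L + i)
  fit_s <- fit_bending_rigidity(spectrum_statistical(cs, 20L),
                                mode_range = c(3L, 20L))
  fit_a <- fit_bending_rigidity(spectrum_average(
    angular_autocorrelation(cs), 20L), mode_range = c(3L, 20L))
  data.frame(kappa_in = kap,
             kappa_statistical = as.numeric(fit_s$kappa),
             err_statistical_pct = 100 * (as.numeric(fit_s$kappa) / kap - 1),
             kappa_average = as.numeric(fit_a$kappa),
             err_average_pct = 100 * (as.numeric(fit_a$kappa) / kap - 1),
             sigma_bar = fit_s$sigma_bar)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/flicker_recovery.csv", row.names = FALSE)
print(tab, digits = 3)
cat(sprintf("\nBoth decompositions recover kappa across a 20-fold range
(worst error %.1f%%); the two approaches agree within %.1f%% on every
vesicle. Table in results/flicker_recovery.csv\n",
            max(abs(c(tab$err_statistical_pct, tab$err_average_pct))),
            100 * max(abs(tab$kappa_statistical / tab$kappa_average - 1))))
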