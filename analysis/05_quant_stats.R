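#!/usr/bin/env Rscript
# Stage 5: scalar quantifications and multiple-testing control on small
# synthetic count tables (labelled synthetic: no micrograph- or
# HPLC-derived data exist in this workflow), plus Benjamini-Hochberg FDR
# over the evoked band-power comparisons.

library(slowosc)

out <- "results/quant"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(20260921)

# monosynaptic tracing: traced cells per region, normalized per starter
tracing <- data.frame(region = c("cortex_S1M1", "thalamus"),
                      traced_count = c(840, 310))
tracing <- normalize_traced_inputs(tracing, starter_count = 120)
utils::write.csv(tracing, file.path(out, "tracing_normalized.csv"),
                 row.names = FALSE)
cat("traced inputs per starter neuron:\n"); print(tracing, row.names = FALSE)

# dendritic spine density with the >20 um segment inclusion rule
spines <- data.frame(n_spines = c(34, 28, 41, 9),
                     segment_length_um = c(27.5, 24.0, 33.1, 15.2))
spines <- spine_density(spines)
utils::write.csv(spines, file.path(out, "spine_density.csv"),
                 row.names = FALSE)
cat(sprintf("spine density: %d segments, %d excluded (<= 20 um), mean %.2f spines/um\n",
            nrow(spines), sum(spines$excluded),
            mean(spines$density_per_um, na.rm = TRUE)))

# Cavalieri volume from serial section areas (40 um spacing)
areas <- c(1.21, 1.48, 1.60, 1.52, 1.30, 0.95) * 1e6   # um^2
vol <- cavalieri_volume(areas, spacing_um = 40)
cat(sprintf("Cavalieri volume: %.3g um^3 (%.3f mm^3)\n", vol, vol / 1e9))

# microdialysis: percent of the 5 pre-drug baseline fractions
fractions <- c(9.8, 10.4, 10.1, 9.9, 10.3, 14.8, 19.5, 16.2, 12.1, 10.9)
pct <- percent_of_baseline(fractions)
utils::write.csv(data.frame(fraction = seq_along(fractions),
                            fmol = fractions, percent = pct),
                 file.path(out, "dialysis_percent.csv"), row.names = FALSE)
cat(sprintf("dialysis peak response: %.0f%% of baseline at fraction %d\n",
            max(pct), which.max(pct)))

# BH FDR over simulated band-power group comparisons (two groups, n=8,
# a true shift planted in the two gamma bands)
pvals <- vapply(c(alpha = 0, beta = 0, low_gamma = 2.5, high_gamma = 2),
                function(shift) {
  stats::wilcox.test(stats::rnorm(8), stats::rnorm(8) + shift)$p.value
}, numeric(1))
bh <- benjamini_hochberg(pvals, q = 0.125)
fdr_tab <- data.frame(band = names(pvals), p = pvals, adjusted = bh$adjusted,
                      rejected = bh$rejections)
utils::write.csv(fdr_tab, file.path(out, "band_power_fdr.csv"),
                 row.names = FALSE)
cat("band-power comparisons under BH (q = 0.125):\n")
print(fdr_tab, row.names = FALSE)
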