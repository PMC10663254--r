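#!/usr/bin/env Rscript
# Stage 3: spectral analysis of the spontaneous recording. Welch PSD over
# the z-scored LFP (2 s Hann windows, 50% overlap, 0.1 Hz bins) and band
# power in the alpha/beta/low-gamma/high-gamma bands.

library(slowosc)

out <- "results/spectral"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rec <- read_recording_csv("results/data/recording.csv")
psd <- welch_psd(rec, window_s = 2, bin_hz = 0.1)
utils::write.csv(data.frame(frequency_hz = psd$frequencies,
                            power = psd$power),
                 file.path(out, "psd.csv"), row.names = FALSE)
bp <- band_power(psd)
utils::write.csv(bp, file.path(out, "band_power.csv"), row.names = FALSE)

cat(sprintf("PSD: %d segments of %g s, %.1f Hz resolution\n",
            psd$n_segments, psd$window_s, psd$bin_hz))
low <- psd$frequencies >= 0.5 & psd$frequencies <= 2
cat(sprintf("slow-oscillation peak: %.1f Hz\n",
            psd$frequencies[low][which.max(psd$power[low])]))
for (i in seq_len(nrow(bp)))
  cat(sprintf("  %-10s %3g-%3g Hz  mean power %.3e\n",
              bp$band[i], bp$lo_hz[i], bp$hi_hz[i], bp$power[i]))
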