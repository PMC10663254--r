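#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data — a 200 s slow-oscillation LFP
# recording at 5 kHz with ground-truth Up/Down intervals, and a set of
# thalamic-stimulation evoked trials (50 pulses per intensity, 40-320 uA)
# spread over a 32-channel surface array. Everything downstream (state
# detection, spectra, evoked metrics) consumes these files.

library(slowosc)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260921L

params <- slow_osc_params(duration = 200, seed = seed)
sim <- simulate_slow_oscillation(params)
write_recording_csv(sim$recording, file.path(out, "recording.csv"))
write_intervals_csv(sim$truth, file.path(out, "truth_intervals.csv"))

iv <- sim$truth$intervals
up <- iv$state == 1
cat(sprintf("slow oscillation: %d Up / %d Down intervals over %g s\n",
            sum(up), sum(!up), params$duration))
cat(sprintf("realized mean Up duration: %.3f s (requested %.2f s)\n",
            mean((iv$end_s - iv$start_s)[up]), params$up_dur_mean))

proto <- stim_protocol()                        # 50 pulses at 0.1 Hz
shape <- evoked_shape(seed = seed)
base <- simulate_evoked_trials(proto, shape)
arr <- simulate_array_recording(array_geometry(), source_channel = 10,
                                decay_length_um = 900, base)
# the raw (trials x channels x time) array is bulky; later stages regenerate
# it deterministically from this protocol record instead of reading it back
jsonlite::write_json(list(seed = seed, n_pulses = proto$n_pulses,
                intensities_ua = proto$intensities_ua,
                rate_hz = proto$rate_hz, source_channel = 10,
                decay_length_um = 900),
           file.path(out, "evoked_protocol.json"), auto_unbox = TRUE)
cat(sprintf("evoked: %d intensities x %d pulses x %d channels simulated\n",
            length(proto$intensities_ua), proto$n_pulses,
            dim(arr$epochs[[1]])[2]))
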