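#!/usr/bin/env Rscript
# Step 3: group candidates into click trains, apply the qualification
# rules (>= 8 clicks, mean ICI in (10 ms, 0.1 s), >= 10 dB above
# background), cap trains at twice the group size per session, and extract
# the eight parameters from the highest-amplitude click of each train.

library(clickpam)

if (!file.exists("scratch/scene.wav"))
  stop("run analysis/01_simulate_scene.R and 02_detect_clicks.R first")

rec <- read_recording("scratch/scene.wav")
filtered <- bandpass(rec)
sp <- segment_spectra(filtered)
noise <- estimate_noise_spectrum(sp)
cands <- remove_false_positives(
  detect_candidates(filtered, noise = noise, spectra = sp),
  rec = filtered)

trains <- group_into_trains(cands, max_gap = 0.3, session_id = "session1")
trains <- lapply(trains, qualify_train, rec = filtered, noise = noise)
tt <- trains_table(trains)
write.csv(tt, "results/trains.csv", row.names = FALSE)
cat(sprintf("%d trains, %d qualified (rejections: %s)\n",
            nrow(tt), sum(tt$qualified),
            paste(unique(tt$rejection_reasons[tt$rejection_reasons != ""]),
                  collapse = ", ")))

qualified <- Filter(function(t) isTRUE(t$qualified), trains)
session <- session_record("mixed", 1, group_size = 6)
selected <- cap_trains_per_session(qualified, session, seed = 1)
cat(sprintf("Capped at 2 x group size (%d): %d selected\n",
            2 * session$group_size, length(selected)))

# label each selected train by the species of the nearest truth click
truth <- read.csv("results/truth.csv")
features <- do.call(rbind, lapply(selected, function(tr) {
  best <- select_highest_amplitude(tr)
  sp_label <- truth$species[which.min(abs(truth$time_s - best$time_s))]
  extract_features(best, filtered, species = sp_label,
                   session_id = tr$session_id, train_id = tr$train_id)
}))
write.csv(features, "results/features_scene.csv", row.names = FALSE)
cat(sprintf("Extracted %d feature rows -> results/features_scene.csv\n",
            nrow(features)))
print(features[c("species", "train_id", "duration_us", "peak_khz",
                 "centroid_khz")], digits = 3)
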