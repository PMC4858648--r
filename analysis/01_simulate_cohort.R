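#!/usr/bin/env Rscript
# Simulate the study cohort: 15 subjects, mean-EPI-like volumes with
# 116 textured ROIs (43 expected / 73 non-expected, including the two
# fixed control ROIs per subject). Volumes and masks are written as
# NIfTI under scratch/cohort/ (bulky, regenerable); the ROI manifest
# goes under results/.

library(fmritex)

seed <- 1L
out_img <- "scratch/cohort"
dir.create(out_img, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- image_gen_config(seed = seed)
ds <- generate_volume_dataset(cfg)

manifest <- ds$manifest
manifest$mask_path <- file.path(out_img, paste0(manifest$roi_id, "_mask.nii.gz"))
manifest$volume_path <- file.path(out_img,
                                  paste0(manifest$subject_id, "_mean.nii.gz"))
for (sid in names(ds$volumes))
  write_volume(ds$volumes[[sid]], file.path(out_img, paste0(sid, "_mean.nii.gz")))
for (i in seq_along(ds$rois))
  write_volume(ds$rois[[i]]$mask * 1L,
               file.path(out_img, paste0(ds$rois[[i]]$roi_id, "_mask.nii.gz")),
               spacing = cfg$spacing)
write_roi_manifest(manifest, "results/cohort_manifest.csv")

s <- summarize_labels(manifest$label)
cat(sprintf("cohort: %d subjects, %d ROIs (%d E / %d NE; prevalence %.0f%%/%.0f%%)\n",
            length(ds$volumes), nrow(manifest), s$n_e, s$n_ne,
            s$prevalence_e_pct, s$prevalence_ne_pct))
cat("volumes and masks under", out_img, "- manifest in results/cohort_manifest.csv\n")
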