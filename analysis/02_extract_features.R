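#!/usr/bin/env Rscript
# Radiomic texture extraction: read the simulated cohort back from disk
# (exercising the NIfTI path), quantize each ROI to 8 gray levels,
# accumulate the four directional GLCMs over its slices, and average the
# 20 features over directions. Writes results/feature_table.csv.

library(fmritex)

manifest <- read_roi_manifest("results/cohort_manifest.csv")
volumes <- lapply(split(manifest$volume_path, manifest$subject_id),
                  function(p) read_volume(p[1]))
rois <- lapply(seq_len(nrow(manifest)), function(i) {
  row <- manifest[i, ]
  roi_mask(read_volume(row$mask_path)$data, row$subject_id, row$roi_id,
           row$label)
})

ft <- extract_feature_table(volumes, rois, n_levels = 8L, distance = 1L)
write_feature_table(ft, "results/feature_table.csv")

cat(sprintf("extracted %d x %d feature matrix (8 gray levels, distance 1)\n",
            nrow(ft), length(texture_feature_names)))
cat(sprintf("median ROI size: %d voxels\n", median(ft$n_voxels)))
cat("written to results/feature_table.csv\n")
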