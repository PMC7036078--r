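#!/usr/bin/env Rscript

# In-silico arm: simulate intrinsic LBBB and the four RV pacing scenarios
# (apical anterior / mid / posterior, mid-septal) on the default idealized
# biventricular geometry, compute each map's activation metrics, and compare
# every paced map against LBBB. Writes the mesh, activation maps, metric
# sets and the comparison table under results/insilico/.

library(pacesim)

cfg <- run_config(seed = 1, out_dir = "results/insilico")
res <- run_fig5_experiment(cfg)

cat("Simulated", length(res$maps), "scenarios on a mesh of",
  nrow(res$mesh$vertices), "vertices\n\n")
for (nm in names(res$metrics)) print(res$metrics[[nm]])

cat("\nPaced scenarios vs intrinsic LBBB:\n")
print(res$comparisons, digits = 3)

rvsp <- res$comparisons[res$comparisons$scenario == "RVSP", ]
rvap <- res$comparisons[res$comparisons$scenario != "RVSP", ]
cat(sprintf(
  "\nBest LBBB surrogate: %s (r = %.2f vs %.2f-%.2f for apical pacing).\n",
  res$best_match, rvsp$pearson_r, min(rvap$pearson_r), max(rvap$pearson_r)
))
cat(sprintf(
  "Latest-activation-region shift: %.1f mm with septal pacing vs %.1f-%.1f mm with apical pacing.\n",
  rvsp$latest_region_shift_mm,
  min(rvap$latest_region_shift_mm), max(rvap$latest_region_shift_mm)
))
cat("Artifacts written to results/insilico/\n")
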