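#!/usr/bin/env Rscript
# Render the pooled neuropil-thread density heatmaps (raw binned counts
# and the Gaussian-smoothed surface) for each region as PNG figures under
# results/figures/.

suppressPackageStartupMessages({library(stereotau); library(ggplot2)})

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
bundles <- file.path("results/bundles", c("prefrontal", "parietal"))
out <- run_pipeline(bundles)

for (tag in names(out$heatmaps)) {
  hm <- out$heatmaps[[tag]]
  df <- as.data.frame(hm, which = "smoothed")
  gg <- ggplot(df, aes(x / 1000, y / 1000, fill = value)) +
    geom_raster() +
    scale_fill_viridis_c(name = "markers/bin") +
    coord_equal() +
    labs(title = paste("Pooled neuropil-thread distribution:", tag),
         x = "x (mm)", y = "y (mm)") +
    theme_minimal()
  path <- file.path("results/figures", paste0("heatmap_", tag, ".png"))
  ggsave(path, gg, width = 8, height = 4, dpi = 150)
  cat("wrote", path, "\n")
}
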