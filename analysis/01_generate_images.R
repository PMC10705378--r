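#!/usr/bin/env Rscript
# Generates the synthetic vascular-bed image series: one two-channel field
# per "day", with recruitment increasing over days 1-3 the way tri-culture
# spheroid devices recruit monocytes into the central well. Writes TIFFs,
# ground-truth masks and cell tables under results/images/.

suppressMessages(library(monorecruit))

seed <- 1
out_dir <- "results/images"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

geom <- ivas_geometry(pixel_size_um = 3)
# 100 perfused monocytes per field; over days, luminal cells extravasate and
# are recruited into the well
day_counts <- list(
  `1` = c(luminal = 60, extravasated = 30, recruited = 10),
  `2` = c(luminal = 40, extravasated = 35, recruited = 25),
  `3` = c(luminal = 25, extravasated = 35, recruited = 40)
)

for (day in names(day_counts)) {
  ct <- day_counts[[day]]
  b <- generate_vessel_image(geom, ct["luminal"], ct["extravasated"],
                             ct["recruited"], snr = 10,
                             seed = seed + as.integer(day))
  paths <- write_image_bundle(b, out_dir, prefix = sprintf("day%s", day))
  cat(sprintf("day %s: wrote %s (truth: %d luminal, %d extravasated, %d recruited)\n",
              day, basename(paths[["image"]]), ct[1], ct[2], ct[3]))
}
cat("done; images and ground truth under", out_dir, "\n")
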