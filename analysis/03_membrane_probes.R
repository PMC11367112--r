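#!/usr/bin/env Rscript

# Stage 3 — membrane fluidity and hydration.
#
# Computes TMA-DPH fluorescence anisotropy (L-format, with the instrument
# G-factor) and Laurdan generalized polarization from the intensity tables
# written by stage 1, and summarises each condition as mean +/- SEM.

library(tevcf)

quads <- read.table(file.path("results", "probe_anisotropy_intensities.tsv"),
                    header = TRUE, sep = "\t")
quads <- anisotropy_from_quadruples(quads, g_mode = "per_sample")
pairs <- read.table(file.path("results", "probe_gp_intensities.tsv"),
                    header = TRUE, sep = "\t")
pairs <- gp_from_pairs(pairs)

values <- rbind(
  data.frame(value = quads$r, group = quads$treatment, assay = "anisotropy"),
  data.frame(value = pairs$gp, group = pairs$treatment, assay = "gp"))
write.table(values, file.path("results", "probe_values.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

for (assay in c("anisotropy", "gp")) {
  sub <- values[values$assay == assay, ]
  s <- batch_probe_summary(sub$value, sub$group)
  cat(assay, "by condition:\n")
  print(s, row.names = FALSE, digits = 3)
}
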