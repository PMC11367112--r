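#!/usr/bin/env Rscript

# Stage 1 — generate the synthetic study.
#
# The study has three arms: TEVCF sweep cohorts for the gating analysis
# (control, ceramide-loaded, glucosylceramide-loaded oocytes), polarized /
# two-band intensity sets for the membrane-probe arm, and two-channel ring-
# cell image pairs for the dipole-potential arm. Everything is generated
# from the condition ground truths in `condition_params()`, so each later
# stage can be judged by how well it recovers those numbers.
#
# Raw sweep files are bulky and go under scratch/; small manifests and the
# probe tables go under results/.

library(tevcf)

seed <- 1L
raw_dir <- file.path("scratch", "raw_sweeps")
res_dir <- "results"
dir.create(raw_dir, showWarnings = FALSE, recursive = TRUE)
dir.create(res_dir, showWarnings = FALSE)

manifest <- list()
for (cond in c("control", "cer", "glccer")) {
  cfg <- condition_cohort_config(cond, seed = seed + match(cond, c("control", "cer", "glccer")))
  cohort <- simulate_cohort(cfg)
  for (ss in cohort) {
    path <- file.path(raw_dir, paste0(ss$cell_id, ".tsv"))
    write_sweep_set(ss, path)
    manifest[[length(manifest) + 1]] <- data.frame(
      cell_id = ss$cell_id, treatment = ss$treatment_label,
      day_id = ss$day_id, file = path,
      true_v_half_f = ss$ground_truth$v_half_f,
      true_v_half_g = ss$ground_truth$v_half_g)
  }
  cat(sprintf("simulated %d %s cells (F-V V1/2 %.1f mV, G-V V1/2 %.1f mV)\n",
              cfg$n_cells, cond, cfg$ground_truth$v_half_f,
              cfg$ground_truth$v_half_g))
}
manifest <- do.call(rbind, manifest)
write.table(manifest, file.path(res_dir, "sweep_manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# membrane-probe arm: 9 samples per condition and assay
probes <- list()
for (cond in c("control", "cer", "glccer")) {
  p <- condition_params(cond)
  q <- simulate_polarized_intensities(p$anisotropy, g_true = 1.1, n = p$n_probe,
                                      seed = seed + 30 + match(cond, c("control", "cer", "glccer")))
  probes[[paste0(cond, "_r")]] <- cbind(treatment = cond, assay = "anisotropy", q)
  e <- simulate_gp_intensities(p$gp, n = p$n_probe,
                               seed = seed + 40 + match(cond, c("control", "cer", "glccer")))
  probes[[paste0(cond, "_gp")]] <- cbind(treatment = cond, assay = "gp", e)
}
for (assay in c("anisotropy", "gp")) {
  tab <- do.call(rbind, c(unname(Filter(function(x) x$assay[1] == assay, probes)),
                          list(make.row.names = FALSE)))
  write.table(tab, file.path(res_dir, paste0("probe_", assay, "_intensities.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("wrote probe intensity tables for 3 conditions x 2 assays\n")

# imaging arm: a reduced set of image pairs per condition for the scripted
# walk-through (the acceptance run regenerates the full 20 per condition)
img_dir <- file.path("scratch", "raw_images")
dir.create(img_dir, showWarnings = FALSE, recursive = TRUE)
img_manifest <- list()
for (cond in c("control", "cer", "glccer")) {
  p <- condition_params(cond)
  for (i in 1:5) {
    img <- simulate_ratio_images(p$rexc, n_cells = 30 + i,
                                 seed = seed * 100 + 10 * match(cond, c("control", "cer", "glccer")) + i)
    tp <- file.path(img_dir, sprintf("%s_%02d.tif", cond, i))
    sp <- file.path(img_dir, sprintf("%s_%02d_seeds.tsv", cond, i))
    write_ratio_image_set(img, tp, sp)
    img_manifest[[length(img_manifest) + 1]] <- data.frame(
      image_id = sprintf("%s_%02d", cond, i), treatment = cond,
      tiff = tp, seeds = sp, true_ratio = p$rexc)
  }
}
write.table(do.call(rbind, img_manifest),
            file.path(res_dir, "image_manifest.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote 15 synthetic image pairs\n")
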