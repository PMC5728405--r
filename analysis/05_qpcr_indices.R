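#!/usr/bin/env Rscript
# Step 5 — qPCR standard-curve quantification.  Fits each primer's in-run
# dilution series, converts Cq values to relative concentrations,
# normalises to the reference gene, checks fractionation purity (nuclear
# marker) and RT-minus wells, and derives splicing/export indices.

suppressPackageStartupMessages(library(ddrquant))

out_dir <- "results/run"
cfg <- pipeline_config(overrides = list(seed = 20260921L))
run_pipeline(cfg, out_dir, stages = "qpcr")

qc <- jsonlite::read_json(file.path(out_dir, "qpcr_qc.json"))
cat("Standard-curve efficiencies:\n")
for (p in names(qc$curves))
  cat(sprintf("  %-10s efficiency %.3f  R^2 %.4f\n", p,
              qc$curves[[p]]$efficiency, qc$curves[[p]]$r_squared))
cat("Fractionation purity (nuclear marker):",
    paste(names(qc$purity), unlist(qc$purity), collapse = ", "), "\n")
cat("RT-minus wells:", paste(names(qc$rt_minus), unlist(qc$rt_minus),
                             collapse = ", "), "\n")

idx <- read_table_csv(file.path(out_dir, "splicing_indices.csv"))
cat("\nSplicing/export indices (reference-normalised):\n")
print(idx[, c("transcript", "condition", "pre_nuclear", "post_nuclear",
              "nc_ratio_post")], row.names = FALSE)
cat("\nIn the double knockdown the pre-spliced transcript accumulates in the\n")
cat("nucleus and the post-spliced N/C ratio rises: a joint splicing and\n")
cat("export defect.\n")
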