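#!/usr/bin/env Rscript
# Step 6 — codon arithmetic for the recurrent nonsense substitutions, plus
# the provenance record for the whole run.

suppressPackageStartupMessages(library(ddrquant))

out_dir <- "results/run"
cfg <- pipeline_config(overrides = list(seed = 20260921L))
run_pipeline(cfg, out_dir, stages = c("annotate", "report"))

ann <- read_table_csv(file.path(out_dir, "variant_codons.csv"))
cat("Recurrent nonsense substitutions (1-based CDS coordinates):\n")
for (i in seq_len(nrow(ann)))
  cat(sprintf("  %s -> codon %d, codon position %d (R%d*)\n",
              ann$substitution[i], ann$codon_index[i],
              ann$position_in_codon[i], ann$codon_index[i]))
cat("\nBoth substitutions hit the first position of an arginine codon,\n")
cat("converting CGA to the TGA stop and truncating the protein.\n")
cat("\nProvenance written to", file.path(out_dir, "provenance.json"), "\n")
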