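#!/usr/bin/env Rscript
# Step 1: generate the two study datasets -- a null run (no withdrawal effect)
# and a withdrawal-delay run (treated arm matures at half speed between
# withdrawal at DIV67 and recovery at DIV95) -- and write them with their
# ground-truth files and a run manifest.

suppressPackageStartupMessages(library(devindexr))

seed <- 101L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

outputs <- character(0)
for (name in c("null", "withdrawal_delay")) {
  truth <- preset(name, seed = seed)
  cq <- simulate_cq_table(truth)
  cq_path <- file.path("results/data", paste0(name, "_cq.csv"))
  truth_path <- file.path("results/data", paste0(name, "_truth.yaml"))
  write_cq_csv(cq, cq_path)
  write_truth_yaml(truth, truth_path)
  outputs <- c(outputs, cq_path, truth_path)
  cat(sprintf("%-16s %4d rows, %d genes + %s, delta = %.1f -> %s\n",
              name, nrow(cq), nrow(truth$gene_specs), truth$housekeeping_gene,
              truth$design$delta, cq_path))
}
write_run_manifest("results/data/manifest.yaml", outputs = outputs,
                   params = list(presets = c("null", "withdrawal_delay")),
                   seed = seed,
                   stages = c(simulate = "ok"))
cat("manifest: results/data/manifest.yaml\n")
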