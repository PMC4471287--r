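#!/usr/bin/env Rscript
# Generate the synthetic multi-omics study bundle used by every later step:
# three groups of four samples (knockdown, proliferating and differentiating
# non-target controls), an mRNA universe sized like the detectable FPKM > 1
# pool, an nCounter-scale miRNA panel, and a clustered RRBS-like methylome,
# with 60% of knockdown-perturbed features shared (concordantly, and more
# strongly) with the cell-state contrast.

suppressMessages(library(convergeomics))

seed <- 101L
out_dir <- file.path("results", "bundle")

cfg <- sim_config(seed = seed)
bundle <- simulate_bundle(cfg)
write_bundle(bundle, out_dir)

cat("Simulated study bundle (seed", seed, ") ->", out_dir, "\n")
cat(sprintf(" genes: %d | miRNA probes: %d | CpG sites: %d | samples: %d\n",
            cfg$n_genes, cfg$n_mirna, nrow(bundle$methylation$samples[[1]]),
            nrow(bundle$expression$samples)))
cat(sprintf(" planted: %d DE genes (%d shared with the cell state), %d DE miRNAs, %d DM clusters\n",
            nrow(bundle$expression$truth$de_kd),
            length(bundle$expression$truth$shared_ids),
            nrow(bundle$mirna$truth$de_kd),
            length(bundle$methylation$truth$dm_kd_ids)))
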