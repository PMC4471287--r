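#!/usr/bin/env Rscript
# miRNA layer: nCounter-style normalization (positive spike-in then content
# geometric-mean scaling, negative-control detection thresholds), the
# presence filter, per-probe Welch tests, and concordance of the knockdown
# changes with the cell-state contrast.

suppressMessages(library(convergeomics))

bundle <- read_bundle(file.path("results", "bundle"))
norm <- normalize_counts(bundle$mirna$table)

n_ctrl <- sum(norm$lanes$condition == "nt_prolif")
n_kd <- sum(norm$lanes$condition == "kd")
kept <- presence_filter(norm, "nt_prolif", "kd",
                        min_a = n_ctrl - 1, min_b = n_kd - 1)
de_kd <- differential_mirna(norm, c("kd", "nt_prolif"), probes = kept)
conc <- mirna_state_concordance(de_kd, norm, c("nt_diff", "nt_prolif"))

write.table(de_kd, file.path("results", "mirna_de_kd.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Lane scale factors span %.2f-%.2f (positive x content)\n",
            min(norm$positive_factor * norm$content_factor),
            max(norm$positive_factor * norm$content_factor)))
cat(sprintf("Presence filter (%d/%d controls or %d/%d knockdowns): %d of %d probes retained\n",
            n_ctrl - 1, n_ctrl, n_kd - 1, n_kd, length(kept),
            sum(norm$probe_class == "endogenous")))
cat(sprintf("Nominal p < 0.05: %d probes; FDR q < 0.10: %d probes\n",
            sum(de_kd$significant), sum(de_kd$fdr_significant)))
cat(sprintf("State concordance over %d knockdown-significant probes: %.1f%% directionally identical, Pearson r = %.3f (P = %.3g)\n",
            conc$n_shared, 100 * conc$frac_directionally_identical,
            conc$pearson_r, conc$pearson_p))
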