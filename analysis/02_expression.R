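#!/usr/bin/env Rscript
# Expression layer: differential expression of the knockdown and cell-state
# contrasts over the FPKM > 1 detectable pool, then the convergence
# statistics - per-direction hypergeometric overlaps, directional fractions,
# and the log2 fold-change correlation over shared significant genes.

suppressMessages(library(convergeomics))

bundle_dir <- file.path("results", "bundle")
bundle <- read_bundle(bundle_dir)
expr <- bundle$expression

de_kd <- differential_expression(expr$matrix, expr$samples, c("kd", "nt_prolif"))
de_state <- differential_expression(expr$matrix, expr$samples,
                                    c("nt_diff", "nt_prolif"))
conv <- kd_state_convergence(de_kd, de_state)

write.table(de_kd, file.path("results", "expression_de_kd.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(de_state, file.path("results", "expression_de_state.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Detectable pool (both contrasts): %d genes\n", conv$pool_size))
cat(sprintf("Significant at q <= 0.05: %d (knockdown), %d (cell state)\n",
            sum(de_kd$significant), sum(de_state$significant)))
cat(sprintf("Decreased knockdown genes also in the state list: %.1f%% (%.1f%% direction-matched)\n",
            100 * conv$overlap_down$frac_in_state,
            100 * conv$overlap_down$frac_in_state_same_direction))
cat(sprintf("Increased knockdown genes also in the state list: %.1f%% (%.1f%% direction-matched)\n",
            100 * conv$overlap_up$frac_in_state,
            100 * conv$overlap_up$frac_in_state_same_direction))
cat(sprintf("Overall overlap: %d genes, hypergeometric P = %.3g\n",
            conv$overlap_all$intersection_size, conv$overlap_all$p_hyper))
cat(sprintf("log2FC Pearson over %d shared genes: r = %.3f (P = %.3g)\n",
            conv$concordance$n_shared, conv$concordance$pearson_r,
            conv$concordance$pearson_p))
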