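#!/usr/bin/env Rscript
# Aggregate all three layers into the single machine-readable convergence
# report (parameter echo + provenance included) and print the summary.

suppressMessages(library(convergeomics))

report <- run_converge(file.path("results", "bundle"))
write_convergence_report(report, file.path("results", "convergence_report.json"))

print(report)
cat("Report written to results/convergence_report.json\n")
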