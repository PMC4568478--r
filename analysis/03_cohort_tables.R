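#!/usr/bin/env Rscript
# Step 3 — paired pre/intra cohort and the three comparison tables.
#
# Simulates the 14-subject cohort (5 CHS with a +14.3% surgical-side
# MCA-terminal CBF increase, 9 non-CHS controls, between-subject SD 0.07),
# runs every session through the imaging pipeline, and builds the
# relative-CBF/CBV/MTT comparison tables with BH correction at FDR 0.2.

suppressPackageStartupMessages(library(dscperf))
out <- "results/cohort"

cohort <- simulate_cohort(cohort_spec(seed = 20150914L),
                          phantom_spec(grid_shape = c(24L, 24L, 8L),
                                       seed = 20150914L))
write_cohort(cohort, file.path(out, "data"))
res <- run_cohort(list(manifest = file.path(out, "data", "manifest.csv"),
                       out_dir = file.path(out, "tables")))

cat("Cohort tables written to", file.path(out, "tables"), "\n\n")
print(res)
cat("\nRelative-CBF table (MCA-terminal block):\n")
tab <- res$tables$cbf
print(tab[tab$territory == "MCA-terminal", ], row.names = FALSE, digits = 3)
cat("\nThe designed effect shows as a CHS %increase near +14% against a",
    "\nnon-CHS %increase near 0, with the across-group percentage-increase",
    "\ntest at MCA-terminal the most significant cell of the table.\n")
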