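#!/usr/bin/env Rscript
# Step 7 (optional) — replicate published peak/gene counts from the
# supplementary RPKM tables.
#
# Requires the published per-peak accessibility table and per-gene
# expression table exported as TSV (row ids in the first column, the six
# stage columns named L3, 6h, 18h, 24h, 36h, 44h):
#
#   Rscript analysis/07_replicate_supplementary.R data/s1_faire_rpkm.tsv \
#       data/s2_rna_rpkm.tsv
#
# Sweeps the ratio pseudocount over {0, 0.1, 1} and reports total, static
# and dynamic peak counts plus the dynamic-gene count per setting.

suppressMessages(library(chromdyn))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  stop("usage: Rscript analysis/07_replicate_supplementary.R <peaks.tsv> [<rna.tsv>]",
       call. = FALSE)
}
sweep <- replicate_supplementary(args[1],
                                 if (length(args) > 1) args[2])
print(sweep, row.names = FALSE)
dir.create("results", showWarnings = FALSE)
write.table(sweep, "results/supplementary_replication.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/supplementary_replication.tsv\n")
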