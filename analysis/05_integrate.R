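#!/usr/bin/env Rscript
# Step 5 — accessibility x expression integration.
#
# Joint quadrant classification of peak accessibility and assigned-gene
# expression changes (each stage vs its next two, 2-fold rule both sides),
# dynamic-gene calls (RPKM > 1 somewhere and >= 2-fold change), expression
# clustering of dynamic genes, gene/peak trajectory correlations per
# cluster, replicate correlation structure, and quadrant recovery of the
# planted activation/repression couplings.

suppressMessages(library(chromdyn))

seed <- 20240601L
ds <- read_dataset_dir("results/synthetic")
asg <- read.table("results/assignments.tsv", sep = "\t", header = TRUE)

quad <- pairwise_quadrants(ds$signal, ds$expr, asg, fold_threshold = 2,
                           pseudocount = 0.1)
write.table(quad$counts, "results/quadrant_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("quadrant counts (all stage pairs pooled):\n")
print(tapply(quad$counts$count, quad$counts$quadrant, sum))

gene_calls <- classify_dynamic_genes(ds$expr)
cat(sprintf("dynamic genes: %d of %d\n", sum(gene_calls$dynamic),
            nrow(gene_calls)))

lfc <- log2fc_vs_reference(ds$expr, "L3", 0.1)
fom <- fraction_of_max(ds$signal)
dyn <- gene_calls$gene_id[gene_calls$dynamic]
gcl <- kmeans_clusters(lfc[dyn, ], k = 10, seed = seed)
tc <- cluster_trajectory_correlation(lfc, gcl$assignment, fom, asg)
write.table(tc$summary, "results/trajectory_correlation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("per-cluster gene/peak trajectory correlation (median r):\n")
print(tc$summary[, c("cluster", "n", "median", "mean_trajectory_r")])

if (!is.null(ds$replicates)) {
  r <- sample_correlation_matrix(ds$replicates)
  write_matrix(round(r, 4), "results/replicate_correlation.tsv", "sample")
  same <- r["L3_rep1", "L3_rep2"]
  cat(sprintf("replicate concordance, e.g. L3_rep1 vs L3_rep2: r = %.3f\n",
              same))
}

# accessibility profile of an example gene set: genes coupled by activation
truth_genes <- read.table("results/synthetic/truth_genes.tsv", sep = "\t",
                          header = TRUE)
act <- truth_genes$gene_id[truth_genes$coupling == "activation"]
prof <- geneset_profile(ds$signal, asg, act, reference_stage = "L3")
write.table(prof, "results/geneset_profile.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("activation-coupled gene-set profile (mean signal, p vs L3):\n")
print(prof)
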