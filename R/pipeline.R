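#' Read a pipeline input directory
#'
#' Loads the plain-text inputs written by [write_dataset()]: peaks BED,
#' signal/expression matrices, TSS table, and (when present) gene models,
#' FASTA sequences and replicate matrices.
#'
#' @param dir Directory path.
#' @param stages Ordered stage labels expected in the matrices.
#' @return List suitable for [run_pipeline()].
#' @export
read_dataset_dir <- function(dir, stages = default_stages()) {
  out <- list(
    peaks = read_peaks(file.path(dir, "peaks.bed")),
    signal = read_matrix(file.path(dir, "signal.tsv"), stages),
    expr = read_matrix(file.path(dir, "expression.tsv"), stages),
    tss = validate_tss_table(utils::read.table(
      file.path(dir, "tss.tsv"), sep = "\t", header = TRUE,
      stringsAsFactors = FALSE))
  )
  gm <- file.path(dir, "gene_models.tsv")
  if (file.exists(gm)) {
    out$gene_models <- utils::read.table(gm, sep = "\t", header = TRUE,
                                         stringsAsFactors = FALSE)
  }
  fa <- file.path(dir, "peaks.fa")
  if (file.exists(fa)) out$sequences <- read_sequences(fa)
  rp <- file.path(dir, "replicates.tsv")
  if (file.exists(rp)) out$replicates <- read_matrix(rp)
  out
}

#' Run the full time-course analysis pipeline
#'
#' Orchestrates the standard analysis order over one dataset: high-fidelity
#' peak filtering (per-arm Z-scores), static/dynamic classification and
#' adjacent-stage transitions, fraction-of-max k-means clustering with
#' centroid categories, nearest-TSS assignment with feature categories and
#' distance bins, accessibility-by-expression quadrants, dynamic-gene calls,
#' expression clustering with trajectory correlations, and (when sequences
#' and a motif are supplied) motif enrichment of dynamic versus static
#' peaks. Deterministic given the config seed.
#'
#' @param dataset List with `peaks`, `signal`, `expr`, `tss` and optionally
#'   `gene_models`, `sequences`, `replicates` — e.g. the output of
#'   [simulate_dataset()] or [read_dataset_dir] contents.
#' @param config An [analysis_config()].
#' @param motif Optional `pwm` object for the enrichment step.
#' @param out_dir Optional directory; when given, every intermediate table
#'   is persisted as TSV and the report as JSON.
#' @param apply_z_filter Apply the high-fidelity Z filter before the
#'   downstream stages (default TRUE). Set FALSE when the input peak table
#'   is already a high-confidence set (as the synthetic generator emulates);
#'   Z-scores are still computed and reported either way.
#' @return List of class `run_report` with all intermediate results and a
#'   `summary` list of headline counts and fractions.
#' @export
run_pipeline <- function(dataset, config = analysis_config(), motif = NULL,
                         out_dir = NULL, apply_z_filter = TRUE) {
  stopifnot(is.list(dataset))
  for (field in c("peaks", "signal", "expr", "tss")) {
    if (is.null(dataset[[field]])) {
      stop(sprintf("dataset is missing required input '%s'", field),
           call. = FALSE)
    }
  }
  res <- list(config = config)

  # 1. high-fidelity filtering
  z <- suppressWarnings(arm_zscores(dataset$signal, dataset$peaks))
  peaks_hf <- if (apply_z_filter) {
    high_fidelity_filter(dataset$peaks, z, config$z_threshold)
  } else {
    dataset$peaks
  }
  signal <- dataset$signal[peaks_hf$peak_id, , drop = FALSE]
  res$zscores <- z
  res$peaks <- peaks_hf

  # 2. temporal dynamics
  calls <- classify_static_dynamic(signal, config$fold_threshold,
                                   config$pseudocount)
  transitions <- stage_transitions(signal, config$fold_threshold,
                                   config$pseudocount)
  fom <- fraction_of_max(signal)
  clusters <- kmeans_clusters(fom, k = config$k_clusters,
                              seed = config$rng_seed,
                              restarts = config$kmeans_restarts,
                              on_threshold = config$on_threshold,
                              flat_range = config$flat_range)
  res$calls <- calls
  res$transitions <- transitions
  res$fraction_of_max <- fom
  res$clusters <- clusters

  # 3. peak-to-gene annotation
  assignments <- suppressWarnings(assign_nearest_tss(peaks_hf, dataset$tss))
  if (!is.null(dataset$gene_models)) {
    assignments <- classify_features(assignments, dataset$gene_models,
                                     peaks_hf, config$promoter_window)
  }
  labels <- calls$label[match(assignments$peak_id, calls$row_id)]
  bins <- distance_bins(assignments, config$distance_bins_kb, labels)
  res$assignments <- assignments
  res$distance_bins <- bins

  # 4. expression integration
  quad <- pairwise_quadrants(signal, dataset$expr, assignments,
                             fold_threshold = config$fold_threshold,
                             pseudocount = config$pseudocount)
  gene_calls <- classify_dynamic_genes(dataset$expr,
                                       config$expression_floor,
                                       config$fold_threshold,
                                       config$pseudocount)
  res$quadrants <- quad
  res$gene_calls <- gene_calls
  expr_lfc <- log2fc_vs_reference(dataset$expr, config$stages[1],
                                  config$pseudocount)
  dyn_genes <- gene_calls$gene_id[gene_calls$dynamic]
  if (length(dyn_genes) >= config$k_clusters) {
    gclust <- kmeans_clusters(expr_lfc[dyn_genes, , drop = FALSE],
                              k = config$k_clusters,
                              seed = config$rng_seed,
                              restarts = config$kmeans_restarts)
    res$expr_clusters <- gclust
    res$trajectory <- cluster_trajectory_correlation(
      expr_lfc, gclust$assignment, fom, assignments)
  }

  # 5. motif enrichment (dynamic vs static peaks)
  if (!is.null(motif) && !is.null(dataset$sequences)) {
    dyn_ids <- calls$row_id[calls$label == "dynamic"]
    sta_ids <- calls$row_id[calls$label == "static"]
    fg <- dataset$sequences[intersect(dyn_ids, names(dataset$sequences))]
    bg <- dataset$sequences[intersect(sta_ids, names(dataset$sequences))]
    if (length(fg) && length(bg)) {
      res$motif_enrichment <- motif_enrichment(
        motif, fg, bg, config$motif_threshold_fraction)
    }
  }

  n_static <- sum(calls$label == "static")
  res$summary <- list(
    n_peaks_input = nrow(dataset$peaks),
    n_peaks_high_fidelity = nrow(peaks_hf),
    n_static = n_static,
    n_dynamic = nrow(calls) - n_static,
    static_fraction = n_static / nrow(calls),
    dynamic_fraction = 1 - n_static / nrow(calls),
    n_dynamic_genes = sum(gene_calls$dynamic),
    cluster_categories = table(clusters$categories)
  )
  class(res) <- "run_report"
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

write_report <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_peaks(res$peaks, file.path(out_dir, "high_fidelity_peaks.bed"))
  write_matrix(res$zscores, file.path(out_dir, "zscores.tsv"), "peak_id")
  utils::write.table(res$calls, file.path(out_dir, "dynamics_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix(res$fraction_of_max,
               file.path(out_dir, "fraction_of_max.tsv"), "peak_id")
  utils::write.table(
    data.frame(peak_id = names(res$clusters$assignment),
               cluster = unname(res$clusters$assignment)),
    file.path(out_dir, "clusters.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix(res$clusters$centroids,
               file.path(out_dir, "centroids.tsv"), "cluster")
  utils::write.table(res$assignments,
                     file.path(out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$quadrants$counts,
                     file.path(out_dir, "quadrant_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- res$summary
  summ$cluster_categories <- as.list(summ$cluster_categories)
  if (!is.null(res$motif_enrichment)) {
    summ$motif_enrichment <- res$motif_enrichment
  }
  jsonlite::write_json(summ, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat("Time-course analysis report\n")
  cat(sprintf("  peaks: %d input, %d high-fidelity\n",
              s$n_peaks_input, s$n_peaks_high_fidelity))
  cat(sprintf("  static %d (%.1f%%), dynamic %d (%.1f%%)\n",
              s$n_static, 100 * s$static_fraction,
              s$n_dynamic, 100 * s$dynamic_fraction))
  cat(sprintf("  dynamic genes: %d\n", s$n_dynamic_genes))
  cat("  cluster categories:",
      paste(names(s$cluster_categories), as.integer(s$cluster_categories),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Replicate the headline peak and gene counts from supplementary tables
#'
#' Applies the packaged classification rules to user-supplied TSV exports of
#' the published accessibility (peaks x stages) and expression (genes x
#' stages) RPKM tables, sweeping the ratio pseudocount, and reports the
#' total/static/dynamic peak counts and the dynamic-gene count per setting.
#'
#' @param signal_path TSV of peak RPKM over the wild-type stages.
#' @param expr_path TSV of gene RPKM over the same stages (optional).
#' @param stages Ordered stage columns expected in both tables.
#' @param pseudocounts Pseudocount sweep (default 0, 0.1, 1).
#' @param fold_threshold,expression_floor Rule thresholds.
#' @return `data.frame`: one row per pseudocount with `n_peaks`, `n_static`,
#'   `n_dynamic`, `pct_static`, and `n_dynamic_genes` when `expr_path` given.
#' @export
replicate_supplementary <- function(signal_path, expr_path = NULL,
                                    stages = default_stages(),
                                    pseudocounts = c(0, 0.1, 1),
                                    fold_threshold = 2,
                                    expression_floor = 1) {
  signal <- read_matrix(signal_path, stages)
  expr <- if (!is.null(expr_path)) read_matrix(expr_path, stages)
  rows <- lapply(pseudocounts, function(pc) {
    calls <- classify_static_dynamic(signal, fold_threshold, pc)
    n_static <- sum(calls$label == "static")
    out <- data.frame(pseudocount = pc, n_peaks = nrow(calls),
                      n_static = n_static,
                      n_dynamic = nrow(calls) - n_static,
                      pct_static = 100 * n_static / nrow(calls),
                      stringsAsFactors = FALSE)
    if (!is.null(expr)) {
      out$n_dynamic_genes <- sum(classify_dynamic_genes(
        expr, expression_floor, fold_threshold, pc)$dynamic)
    }
    out
  })
  do.call(rbind, rows)
}
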