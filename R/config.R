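#' Default developmental stage labels
#'
#' Six stages of the wing time course: wandering third instar (L3) and
#' 6, 18, 24, 36 and 44 hours after puparium formation.
#'
#' @return Character vector of ordered stage labels.
#' @export
default_stages <- function() {
  c("L3", "6h", "18h", "24h", "36h", "44h")
}

#' Analysis configuration
#'
#' Collects every threshold used by the pipeline in one validated list so
#' analyses are reproducible from a single object.
#'
#' @param fold_threshold Fold-change threshold separating static from dynamic
#'   behaviour (ratio scale, must exceed 1). Default 2.
#' @param pseudocount RPKM pseudocount added to numerator and denominator of
#'   every ratio to guard against division by zero. Default 0.1.
#' @param z_threshold Maximal per-arm Z-score a peak must exceed (strictly) to
#'   be retained as high-fidelity. Default 2.
#' @param k_clusters Number of k-means clusters for temporal profiles.
#'   Default 18.
#' @param promoter_window Integer length-2 vector, strand-aware window around
#'   the TSS (negative = upstream) defining the proximal promoter.
#'   Default c(-500, 150).
#' @param distance_bins_kb Strictly increasing kb bin edges for TSS-distance
#'   histograms. Default c(0.5, 1, 5, 10).
#' @param expression_floor Minimum RPKM a gene must reach in at least one
#'   stage to be eligible as dynamic. Default 1.
#' @param stages Ordered stage labels.
#' @param rng_seed Integer seed controlling every stochastic step.
#' @param motif_pseudocount Pseudocount added per base when converting motif
#'   count matrices to probabilities. Default 0.25.
#' @param motif_threshold_fraction Fraction of the maximal attainable log-odds
#'   score a window must reach to be called a hit. Default 0.8.
#' @param kmeans_restarts Number of seeded k-means restarts; the run with the
#'   lowest within-cluster sum of squares wins. Default 10.
#' @param on_threshold Fraction-of-max value at or above which a stage counts
#'   as "on" when categorising cluster centroids. Default 0.7.
#' @param flat_range Centroid max-min below which a cluster is "flat".
#'   Default 0.3.
#'
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(fold_threshold = 2,
                            pseudocount = 0.1,
                            z_threshold = 2,
                            k_clusters = 18,
                            promoter_window = c(-500L, 150L),
                            distance_bins_kb = c(0.5, 1, 5, 10),
                            expression_floor = 1,
                            stages = default_stages(),
                            rng_seed = 1L,
                            motif_pseudocount = 0.25,
                            motif_threshold_fraction = 0.8,
                            kmeans_restarts = 10L,
                            on_threshold = 0.7,
                            flat_range = 0.3) {
  if (!is.numeric(fold_threshold) || fold_threshold <= 1) {
    stop("`fold_threshold` must be > 1", call. = FALSE)
  }
  if (!is.numeric(pseudocount) || pseudocount < 0) {
    stop("`pseudocount` must be >= 0", call. = FALSE)
  }
  if (length(promoter_window) != 2 || promoter_window[1] > promoter_window[2]) {
    stop("`promoter_window` must be c(upstream, downstream) with upstream <= downstream",
         call. = FALSE)
  }
  if (any(diff(distance_bins_kb) <= 0)) {
    stop("`distance_bins_kb` must be strictly increasing", call. = FALSE)
  }
  cfg <- list(
    fold_threshold = fold_threshold,
    pseudocount = pseudocount,
    z_threshold = z_threshold,
    k_clusters = as.integer(k_clusters),
    promoter_window = as.integer(promoter_window),
    distance_bins_kb = distance_bins_kb,
    expression_floor = expression_floor,
    stages = stages,
    rng_seed = as.integer(rng_seed),
    motif_pseudocount = motif_pseudocount,
    motif_threshold_fraction = motif_threshold_fraction,
    kmeans_restarts = as.integer(kmeans_restarts),
    on_threshold = on_threshold,
    flat_range = flat_range
  )
  class(cfg) <- "analysis_config"
  cfg
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat("  stages:          ", paste(x$stages, collapse = ", "), "\n")
  cat("  fold threshold:  ", x$fold_threshold,
      " (pseudocount ", x$pseudocount, " RPKM)\n", sep = "")
  cat("  Z threshold:     ", x$z_threshold, "\n")
  cat("  k clusters:      ", x$k_clusters, "\n")
  cat("  promoter window: ", x$promoter_window[1], "..",
      x$promoter_window[2], " bp around TSS\n", sep = "")
  cat("  seed:            ", x$rng_seed, "\n")
  invisible(x)
}
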