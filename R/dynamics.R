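#' Fraction-of-maximum temporal profiles
#'
#' Divides each row by its maximum across stages, the normalisation used
#' before temporal clustering so peaks are compared by shape rather than
#' amplitude. All-zero rows stay zero and are flagged.
#'
#' @param signal Non-negative numeric matrix, rows peaks/genes, columns stages.
#' @return Matrix of the same shape with values in `[0, 1]` and a logical
#'   `"all_zero"` attribute marking degenerate rows.
#' @export
fraction_of_max <- function(signal) {
  validate_signal_matrix(signal)
  rowmax <- apply(signal, 1, max)
  zero <- rowmax == 0
  out <- signal / ifelse(zero, 1, rowmax)
  attr(out, "all_zero") <- stats::setNames(zero, rownames(signal))
  out
}

# max pairwise fold change of a row with pseudocount: (max + c) / (min + c)
max_pairwise_fold <- function(signal, pseudocount) {
  (apply(signal, 1, max) + pseudocount) / (apply(signal, 1, min) + pseudocount)
}

#' Classify peaks as static or dynamic
#'
#' A peak is static when its accessibility changes by less than
#' `fold_threshold` between every pair of time points, i.e. when
#' `(max + c) / (min + c) < fold_threshold`; otherwise it is dynamic.
#'
#' @param signal Peaks-by-stages matrix.
#' @param fold_threshold Ratio threshold (> 1), default 2.
#' @param pseudocount Pseudocount `c` added to both sides of the ratio.
#' @return `data.frame` with `row_id`, `label` (static/dynamic) and
#'   `max_pairwise_fold`.
#' @export
classify_static_dynamic <- function(signal, fold_threshold = 2,
                                    pseudocount = 0.1) {
  validate_signal_matrix(signal)
  if (fold_threshold <= 1) stop("`fold_threshold` must be > 1", call. = FALSE)
  if (ncol(signal) < 2) stop("need at least 2 stages", call. = FALSE)
  mpf <- max_pairwise_fold(signal, pseudocount)
  data.frame(row_id = rownames(signal),
             label = ifelse(mpf < fold_threshold, "static", "dynamic"),
             max_pairwise_fold = unname(mpf),
             stringsAsFactors = FALSE)
}

#' Opening/closing transitions between adjacent stages
#'
#' For each adjacent stage pair, a peak is `opening` when its signal rises
#' more than `fold_threshold`-fold over the previous stage, `closing` when it
#' falls below `1/fold_threshold`, and `flat` otherwise.
#'
#' @inheritParams classify_static_dynamic
#' @return Character matrix, rows as in `signal`, one column per transition
#'   named `"<from>-><to>"`.
#' @export
stage_transitions <- function(signal, fold_threshold = 2, pseudocount = 0.1) {
  validate_signal_matrix(signal)
  if (fold_threshold <= 1) stop("`fold_threshold` must be > 1", call. = FALSE)
  if (ncol(signal) < 2) stop("need at least 2 stages", call. = FALSE)
  ns <- ncol(signal)
  ratio <- (signal[, -1, drop = FALSE] + pseudocount) /
    (signal[, -ns, drop = FALSE] + pseudocount)
  lab <- matrix("flat", nrow(signal), ns - 1,
                dimnames = list(rownames(signal),
                                paste0(colnames(signal)[-ns], "->",
                                       colnames(signal)[-1])))
  lab[ratio > fold_threshold] <- "opening"
  lab[ratio < 1 / fold_threshold] <- "closing"
  lab
}

#' Log2 fold change relative to a reference stage
#'
#' `log2((x_s + c) / (x_ref + c))`; the reference column is identically 0.
#'
#' @param signal Non-negative matrix.
#' @param reference_stage Column name of the reference stage.
#' @param pseudocount Pseudocount `c`.
#' @return Matrix of log2 fold changes, same shape as `signal`.
#' @export
log2fc_vs_reference <- function(signal, reference_stage = colnames(signal)[1],
                                pseudocount = 0.1) {
  validate_signal_matrix(signal)
  if (!reference_stage %in% colnames(signal)) {
    stop(sprintf("reference stage '%s' not found", reference_stage),
         call. = FALSE)
  }
  ref <- signal[, reference_stage] + pseudocount
  log2((signal + pseudocount) / ref)
}

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centres by
# sampling proportional to squared distance from the nearest chosen centre
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j + 1, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1, ])^2))
  }
  centers
}

#' Temporal k-means clustering
#'
#' Euclidean k-means over temporal profiles (normally fraction-of-max rows),
#' with k-means++ initialisation and the best of `restarts` seeded runs by
#' total within-cluster sum of squares. Deterministic given `seed`.
#'
#' @param signal Numeric matrix, rows to cluster.
#' @param k Number of clusters (default 18).
#' @param seed Integer seed.
#' @param restarts Number of restarts (default 10).
#' @param on_threshold,flat_range Passed to [label_cluster_category()] for
#'   centroid categories.
#' @return List of class `cluster_result` with `k`, `assignment` (named
#'   integer vector), `centroids` (k x stages), `wcss`, and `categories`
#'   (per-cluster sharp/broad/oscillating/flat labels).
#' @export
kmeans_clusters <- function(signal, k = 18, seed = 1L, restarts = 10L,
                            on_threshold = 0.7, flat_range = 0.3) {
  if (anyNA(signal)) stop("missing values not allowed", call. = FALSE)
  if (nrow(signal) < k) {
    stop(sprintf("need at least k = %d rows, got %d", k, nrow(signal)),
         call. = FALSE)
  }
  x <- unname(signal)
  best <- NULL
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    centers <- unique(kmeanspp_centers(x, k))
    if (nrow(centers) < k) {
      # duplicated rows collapsed; top up with distinct data rows
      extra <- unique(x)[seq_len(min(k, nrow(unique(x)))), , drop = FALSE]
      centers <- unique(rbind(centers, extra))[seq_len(k), , drop = FALSE]
    }
    # Hartigan-Wong rejects some degenerate configurations (e.g. k equal
    # to the number of rows); classical Lloyd iterations handle them
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers, iter.max = 100L)),
      error = function(e) {
        suppressWarnings(stats::kmeans(x, centers = centers,
                                       iter.max = 100L,
                                       algorithm = "Lloyd"))
      })
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  centroids <- best$centers
  colnames(centroids) <- colnames(signal)
  categories <- apply(centroids, 1, label_cluster_category,
                      on_threshold = on_threshold, flat_range = flat_range)
  res <- list(k = as.integer(k),
              assignment = stats::setNames(best$cluster, rownames(signal)),
              centroids = centroids,
              wcss = best$tot.withinss,
              categories = unname(categories))
  class(res) <- "cluster_result"
  res
}

#' Categorise a cluster centroid as sharp, broad, oscillating or flat
#'
#' Stages with centroid value at or above `on_threshold` are "on". A centroid
#' whose max-min spread is below `flat_range` is `flat`; one on-stage is
#' `sharp` (transient opening at a single stage); two or more contiguous
#' on-stages are `broad`; non-contiguous on-stages are `oscillating`.
#' Centroids with no on-stage are treated as flat.
#'
#' @param centroid Numeric vector of fraction-of-max values in `[0, 1]`.
#' @param on_threshold "On" level (default 0.7).
#' @param flat_range Spread below which the profile is flat (default 0.3).
#' @return One of `"sharp"`, `"broad"`, `"oscillating"`, `"flat"`.
#' @export
label_cluster_category <- function(centroid, on_threshold = 0.7,
                                   flat_range = 0.3) {
  if (length(centroid) == 0) stop("empty centroid", call. = FALSE)
  if (max(centroid) - min(centroid) < flat_range) return("flat")
  on <- which(centroid >= on_threshold)
  if (length(on) == 0) return("flat")
  if (length(on) == 1) return("sharp")
  if (all(diff(on) == 1)) return("broad")
  "oscillating"
}

#' Identify dynamically expressed genes
#'
#' A gene is dynamic when it is expressed above `expression_floor` RPKM in at
#' least one stage and changes at least `fold_threshold`-fold between some
#' pair of time points.
#'
#' @param expr Genes-by-stages RPKM matrix.
#' @param expression_floor RPKM floor (default 1); comparison is strict (`>`).
#' @param fold_threshold Ratio threshold (default 2), met with `>=`.
#' @param pseudocount Pseudocount for the ratio.
#' @return `data.frame` with `gene_id`, `dynamic` (logical),
#'   `max_rpkm`, `max_pairwise_fold`.
#' @export
classify_dynamic_genes <- function(expr, expression_floor = 1,
                                   fold_threshold = 2, pseudocount = 0.1) {
  validate_signal_matrix(expr)
  if (fold_threshold <= 1) stop("`fold_threshold` must be > 1", call. = FALSE)
  if (ncol(expr) < 2) stop("need at least 2 stages", call. = FALSE)
  mx <- apply(expr, 1, max)
  mpf <- max_pairwise_fold(expr, pseudocount)
  data.frame(gene_id = rownames(expr),
             dynamic = mx > expression_floor & mpf >= fold_threshold,
             max_rpkm = unname(mx),
             max_pairwise_fold = unname(mpf),
             stringsAsFactors = FALSE)
}
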