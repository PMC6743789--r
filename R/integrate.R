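#' Pearson product-moment correlation
#'
#' Thin, contract-enforcing wrapper used throughout the trajectory analyses:
#' requires equal length >= 3 and non-degenerate variance in both vectors.
#'
#' @param x,y Numeric vectors.
#' @return Correlation coefficient, or `NA` with a `"zero_variance"` message
#'   condition when either vector is constant (callers exclude such pairs).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Pairwise accessibility-by-expression quadrant classification
#'
#' For each ordered stage pair (by default each stage against its next two
#' sequential stages) computes the peak's accessibility log2 fold change and
#' its assigned gene's expression log2 fold change (both with pseudocount)
#' and classifies jointly: a peak is in a quadrant only when both magnitudes
#' reach `log2(fold_threshold)`; otherwise `ns`. Quadrants: `open_up`
#' (accessibility up, expression up), `open_down`, `close_up`, `close_down`.
#'
#' @param signal Peaks-by-stages accessibility matrix.
#' @param expr Genes-by-stages expression matrix.
#' @param assignments Peak-to-gene assignment (`peak_id`, `gene_id`).
#' @param stage_pairs Optional list of `c(from, to)` stage-name pairs;
#'   default: each stage versus its next two sequential stages.
#' @param fold_threshold,pseudocount Fold rule parameters.
#' @param significant Optional logical mask (named by peak id) restricting
#'   quadrant membership, e.g. an externally computed per-peak significance
#'   call; peaks with `FALSE` become `ns`.
#' @return List with `table` (long per-peak `data.frame`: pair, peak_id,
#'   gene_id, faire_log2fc, rna_log2fc, quadrant), `counts` (per pair and
#'   quadrant) and `n_excluded` peaks whose gene is missing from `expr`.
#' @export
pairwise_quadrants <- function(signal, expr, assignments, stage_pairs = NULL,
                               fold_threshold = 2, pseudocount = 0.1,
                               significant = NULL) {
  validate_signal_matrix(signal)
  validate_signal_matrix(expr)
  stages <- colnames(signal)
  if (is.null(stage_pairs)) {
    stage_pairs <- list()
    for (i in seq_along(stages)) {
      for (j in i + 1:2) {
        if (j <= length(stages)) {
          stage_pairs[[length(stage_pairs) + 1L]] <- c(stages[i], stages[j])
        }
      }
    }
  }
  asg <- assignments[!is.na(assignments$gene_id), , drop = FALSE]
  asg <- asg[asg$peak_id %in% rownames(signal), , drop = FALSE]
  in_expr <- asg$gene_id %in% rownames(expr)
  n_excluded <- sum(!in_expr)
  asg <- asg[in_expr, , drop = FALSE]
  lfc_cut <- log2(fold_threshold)
  rows <- vector("list", length(stage_pairs))
  for (p in seq_along(stage_pairs)) {
    s1 <- stage_pairs[[p]][1]
    s2 <- stage_pairs[[p]][2]
    fa <- log2((signal[asg$peak_id, s2] + pseudocount) /
                 (signal[asg$peak_id, s1] + pseudocount))
    ra <- log2((expr[asg$gene_id, s2] + pseudocount) /
                 (expr[asg$gene_id, s1] + pseudocount))
    quad <- rep("ns", length(fa))
    sig <- abs(fa) >= lfc_cut & abs(ra) >= lfc_cut
    if (!is.null(significant)) {
      sig <- sig & significant[asg$peak_id] %in% TRUE
    }
    quad[sig & fa > 0 & ra > 0] <- "open_up"
    quad[sig & fa > 0 & ra < 0] <- "open_down"
    quad[sig & fa < 0 & ra > 0] <- "close_up"
    quad[sig & fa < 0 & ra < 0] <- "close_down"
    rows[[p]] <- data.frame(pair = paste0(s1, "->", s2),
                            peak_id = asg$peak_id, gene_id = asg$gene_id,
                            faire_log2fc = unname(fa),
                            rna_log2fc = unname(ra),
                            quadrant = quad, stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows)
  counts <- as.data.frame(table(pair = table$pair,
                                quadrant = table$quadrant),
                          stringsAsFactors = FALSE)
  names(counts) <- c("pair", "quadrant", "count")
  list(table = table, counts = counts, n_excluded = n_excluded)
}

#' Sample-by-sample Pearson correlation matrix
#'
#' Correlates every pair of sample/replicate columns over all peak rows; the
#' replicate-concordance view of a time course.
#'
#' @param m Peaks-by-samples matrix with >= 2 columns.
#' @return Symmetric correlation matrix with unit diagonal; entries involving
#'   a zero-variance column are `NA`.
#' @export
sample_correlation_matrix <- function(m) {
  if (ncol(m) < 2) stop("need at least 2 columns", call. = FALSE)
  r <- suppressWarnings(stats::cor(m))
  sds <- apply(m, 2, stats::sd)
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- 1
  r
}

#' Per-cluster RNA/accessibility trajectory correlations
#'
#' For every assigned gene-peak pair, correlates the gene's expression log2
#' fold-change trajectory with the peak's fraction-of-max accessibility
#' trajectory across stages, then aggregates per expression cluster
#' (median and quartiles), also reporting the correlation of the two
#' cluster-mean trajectories.
#'
#' @param expr_log2fc Genes-by-stages log2 fold-change matrix.
#' @param clusters Named integer vector: gene id -> cluster index.
#' @param signal_fom Peaks-by-stages fraction-of-max matrix.
#' @param assignments Peak-to-gene assignment.
#' @return List with `pairs` (gene_id, peak_id, cluster, r), `summary`
#'   (per cluster: n, q1, median, q3, mean_trajectory_r) and exclusion
#'   counts (`n_unassigned` genes without a peak, `n_zero_variance` pairs).
#' @export
cluster_trajectory_correlation <- function(expr_log2fc, clusters, signal_fom,
                                           assignments) {
  asg <- assignments[!is.na(assignments$gene_id), , drop = FALSE]
  asg <- asg[asg$gene_id %in% names(clusters) &
               asg$gene_id %in% rownames(expr_log2fc) &
               asg$peak_id %in% rownames(signal_fom), , drop = FALSE]
  n_unassigned <- sum(!names(clusters) %in% asg$gene_id)
  r <- numeric(nrow(asg))
  for (i in seq_len(nrow(asg))) {
    r[i] <- pearson_r(expr_log2fc[asg$gene_id[i], ],
                      signal_fom[asg$peak_id[i], ])
  }
  pairs <- data.frame(gene_id = asg$gene_id, peak_id = asg$peak_id,
                      cluster = unname(clusters[asg$gene_id]), r = r,
                      stringsAsFactors = FALSE)
  n_zero_variance <- sum(is.na(pairs$r))
  ok <- pairs[!is.na(pairs$r), , drop = FALSE]
  summ <- do.call(rbind, lapply(split(ok, ok$cluster), function(d) {
    cl <- d$cluster[1]
    genes <- names(clusters)[clusters == cl]
    genes <- intersect(genes, rownames(expr_log2fc))
    gmean <- colMeans(expr_log2fc[genes, , drop = FALSE])
    pmean <- colMeans(signal_fom[unique(d$peak_id), , drop = FALSE])
    q <- stats::quantile(d$r, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(cluster = cl, n = nrow(d), q1 = q[1], median = q[2],
               q3 = q[3], mean_trajectory_r = pearson_r(gmean, pmean),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(pairs = pairs, summary = summ,
       n_unassigned = n_unassigned, n_zero_variance = n_zero_variance)
}

#' Mann-Whitney U test (two-sided)
#'
#' U is the number of (x, y) pairs with x > y (ties counted half). The
#' p-value is exact (null permutation distribution) when
#' `n_x + n_y <= 20` and there are no ties, otherwise a normal approximation
#' with tie and continuity corrections. An all-tied comparison returns p = 1.
#'
#' @param x,y Non-empty numeric samples.
#' @param mode `"auto"` (default), `"exact"` or `"approx"`.
#' @return List with `U` (for `x`) and `p` (two-sided, `2*min(tail)` capped
#'   at 1 in exact mode).
#' @export
mannwhitney_u <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  nx <- length(x)
  ny <- length(y)
  rk <- rank(c(x, y))
  u <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (length(unique(c(x, y))) == 1) {
    return(list(U = u, p = 1))
  }
  exact <- switch(mode,
                  auto = !ties && (nx + ny) <= 20,
                  exact = TRUE,
                  approx = FALSE)
  if (exact && ties) {
    stop("exact mode requires tie-free data", call. = FALSE)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided")
  )
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # degenerate normal approximation (zero variance)
  list(U = unname(u), p = min(unname(p), 1))
}

#' Gene-set accessibility profile with per-stage rank-sum tests
#'
#' Averages the accessibility of all peaks assigned to genes in the set at
#' each stage and compares every stage's per-peak signal distribution with
#' the reference stage by a two-sided Mann-Whitney U test.
#'
#' @param signal Peaks-by-stages matrix.
#' @param assignments Peak-to-gene assignment.
#' @param geneset Character vector of gene ids.
#' @param reference_stage Stage compared against (default first column).
#' @return `data.frame` per stage: `stage`, `n_peaks`, `mean_signal`,
#'   `U`, `p` (`NA` for the reference stage itself).
#' @export
geneset_profile <- function(signal, assignments, geneset,
                            reference_stage = colnames(signal)[1]) {
  peaks <- assignments$peak_id[!is.na(assignments$gene_id) &
                                 assignments$gene_id %in% geneset]
  peaks <- intersect(peaks, rownames(signal))
  if (length(peaks) == 0) {
    stop("gene set has no assigned peaks in the signal matrix", call. = FALSE)
  }
  sub <- signal[peaks, , drop = FALSE]
  ref <- sub[, reference_stage]
  out <- data.frame(stage = colnames(sub), n_peaks = length(peaks),
                    mean_signal = unname(colMeans(sub)),
                    U = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(sub))) {
    if (colnames(sub)[i] == reference_stage) next
    mw <- mannwhitney_u(sub[, i], ref)
    out$U[i] <- mw$U
    out$p[i] <- mw$p
  }
  out
}

#' Upper-tail hypergeometric enrichment
#'
#' `P(X >= hits_in_set)` for drawing `set_size` items from a universe
#' containing `hits_total` marked items; the generic over-representation
#' test applied to gene sets.
#'
#' @param hits_in_set Marked items observed in the set.
#' @param set_size Size of the set drawn.
#' @param hits_total Marked items in the universe.
#' @param universe Universe size.
#' @return Upper-tail p-value.
#' @export
hypergeom_enrichment <- function(hits_in_set, set_size, hits_total, universe) {
  if (hits_in_set > min(set_size, hits_total) ||
      set_size > universe || hits_total > universe || hits_in_set < 0) {
    stop("inconsistent counts for hypergeometric test", call. = FALSE)
  }
  stats::phyper(hits_in_set - 1, hits_total, universe - hits_total, set_size,
                lower.tail = FALSE)
}

#' MA table of expression changes between two conditions
#'
#' Per gene, `A = 0.5 * log2((a + c) * (b + c))` (mean log expression) and
#' `M = log2((a + c) / (b + c))` (log ratio), condition over control.
#'
#' @param expr_condition,expr_control Named numeric vectors (same gene ids).
#' @param pseudocount Pseudocount `c`.
#' @return `data.frame` with `gene_id`, `A`, `M`.
#' @export
ma_table <- function(expr_condition, expr_control, pseudocount = 0.1) {
  if (is.null(names(expr_condition)) || is.null(names(expr_control)) ||
      !setequal(names(expr_condition), names(expr_control))) {
    extra <- union(setdiff(names(expr_condition), names(expr_control)),
                   setdiff(names(expr_control), names(expr_condition)))
    stop(sprintf("gene ids must match between conditions (e.g. %s)",
                 paste(utils::head(extra, 3), collapse = ", ")),
         call. = FALSE)
  }
  ids <- names(expr_condition)
  a <- expr_condition[ids] + pseudocount
  b <- expr_control[ids] + pseudocount
  data.frame(gene_id = ids, A = unname(0.5 * log2(a * b)),
             M = unname(log2(a / b)), stringsAsFactors = FALSE)
}
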