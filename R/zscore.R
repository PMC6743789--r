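#' Per-chromosome-arm Z-scores of accessibility
#'
#' Standardises each stage's signal within each chromosome arm:
#' `Z[i, s] = (x[i, s] - mean(arm, s)) / sd(arm, s)` using the population
#' standard deviation over the peaks of the arm. Arms with a single peak or
#' zero spread at a stage get Z = 0 there, with a warning.
#'
#' @param signal Peaks-by-stages numeric matrix (rownames are peak ids).
#' @param peaks Peak set supplying the arm label of every signal row.
#' @return Matrix of Z-scores with a `"provenance"` attribute holding the
#'   per-arm, per-stage mean and sd used.
#' @export
arm_zscores <- function(signal, peaks) {
  validate_signal_matrix(signal)
  idx <- match(rownames(signal), peaks$peak_id)
  if (anyNA(idx)) {
    stop("every signal row id must exist in the peak set", call. = FALSE)
  }
  arm <- peaks$chrom[idx]
  z <- signal
  prov <- list()
  degenerate <- character()
  for (a in unique(arm)) {
    rows <- which(arm == a)
    x <- signal[rows, , drop = FALSE]
    mu <- colMeans(x)
    # population sd: sqrt(mean((x - mu)^2))
    sdv <- sqrt(colMeans(sweep(x, 2, mu)^2))
    zed <- sweep(sweep(x, 2, mu), 2, ifelse(sdv > 0, sdv, 1), "/")
    zed[, sdv == 0] <- 0
    if (length(rows) == 1 || any(sdv == 0)) degenerate <- c(degenerate, a)
    z[rows, ] <- zed
    prov[[a]] <- list(mean = mu, sd = sdv)
  }
  if (length(degenerate)) {
    warning(sprintf("arm(s) with zero spread at some stage, Z set to 0: %s",
                    paste(unique(degenerate), collapse = ", ")), call. = FALSE)
  }
  attr(z, "provenance") <- prov
  z
}

#' High-fidelity peak filter
#'
#' Keeps a peak when its maximal Z-score across stages strictly exceeds
#' `z_threshold`. Input order is preserved.
#'
#' @param peaks Peak set.
#' @param z Z-score matrix from [arm_zscores()] (rows matched by peak id).
#' @param z_threshold Threshold (default 2); the comparison is strict (`>`).
#' @return The subset of `peaks` passing the filter.
#' @export
high_fidelity_filter <- function(peaks, z, z_threshold = 2) {
  if (nrow(peaks) == 0) return(peaks)
  if (any(!is.finite(z))) stop("Z-scores must be finite", call. = FALSE)
  zmax <- apply(z, 1, max)
  keep_ids <- rownames(z)[zmax > z_threshold]
  peaks[peaks$peak_id %in% keep_ids, , drop = FALSE]
}
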