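# Independent brute-force oracles used by the unit and acceptance tests.
# Each is a direct, unoptimised transcription of the definition and shares
# no code with the package implementation.

# per-arm, per-stage Z-scores by explicit loops (population sd)
oracle_arm_zscores <- function(signal, arms) {
  z <- signal
  for (a in unique(arms)) {
    rows <- which(arms == a)
    for (s in seq_len(ncol(signal))) {
      v <- signal[rows, s]
      mu <- sum(v) / length(v)
      sdv <- sqrt(sum((v - mu)^2) / length(v))
      z[rows, s] <- if (sdv > 0) (v - mu) / sdv else 0
    }
  }
  z
}

# static/dynamic by checking every stage pair explicitly
oracle_static_dynamic <- function(signal, fold, pc) {
  apply(signal, 1, function(x) {
    dynamic <- FALSE
    for (i in seq_along(x)) {
      for (j in seq_along(x)) {
        r <- (x[i] + pc) / (x[j] + pc)
        if (r >= fold) dynamic <- TRUE
      }
    }
    if (dynamic) "dynamic" else "static"
  })
}

# nearest TSS by exhaustive scan over all candidates
oracle_nearest_tss <- function(peaks, tss) {
  mids <- floor((peaks$start + peaks$end) / 2)
  out <- data.frame(peak_id = peaks$peak_id, gene_id = NA_character_,
                    signed_distance = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks))) {
    cand <- tss[tss$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    d <- abs(mids[i] - cand$tss)
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[order(cand$gene_id[best])[1]]
    out$gene_id[i] <- cand$gene_id[best]
    out$signed_distance[i] <- if (cand$strand[best] == "+") {
      mids[i] - cand$tss[best]
    } else {
      cand$tss[best] - mids[i]
    }
  }
  out
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mwu_exact <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">"))
  obs <- u_of(x, y)
  combs <- utils::combn(n, nx)
  us <- apply(combs, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  p_lo <- mean(us <= obs)
  p_hi <- mean(us >= obs)
  list(U = obs, p = min(1, 2 * min(p_lo, p_hi)))
}

# two-sided Fisher exact p by enumerating all 2x2 tables with fixed margins
oracle_fisher <- function(a, b, c, d) {
  m <- a + b        # marked (hit) total
  n <- c + d        # unmarked total
  k <- a + c        # foreground size
  probs <- stats::dhyper(0:min(m, k), m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# adjusted Rand index between two labelings (closed form over the
# contingency table)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_i * sum_j / n2
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}
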