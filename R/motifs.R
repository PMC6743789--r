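#' Build a position weight matrix from base counts
#'
#' `p[i, b] = (count[i, b] + pc) / (sum_b count[i, b] + 4 * pc)` per
#' position, over the alphabet A, C, G, T.
#'
#' @param count_matrix Positions x 4 non-negative count matrix (columns
#'   A, C, G, T).
#' @param pseudocount Per-base pseudocount (default 0.25).
#' @param background Length-4 background distribution (default uniform).
#' @param name Motif name.
#' @return List of class `pwm`: `name`, `prob` (positions x 4), `background`,
#'   `pseudocount`.
#' @export
build_pwm <- function(count_matrix, pseudocount = 0.25,
                      background = rep(0.25, 4), name = "motif") {
  count_matrix <- as.matrix(count_matrix)
  if (ncol(count_matrix) != 4 || nrow(count_matrix) < 1) {
    stop("count matrix must have >= 1 position and 4 columns (A,C,G,T)",
         call. = FALSE)
  }
  if (any(count_matrix < 0)) stop("counts must be >= 0", call. = FALSE)
  totals <- rowSums(count_matrix) + 4 * pseudocount
  if (any(totals == 0)) {
    stop("position with all-zero counts and zero pseudocount", call. = FALSE)
  }
  if (abs(sum(background) - 1) > 1e-9 || any(background <= 0)) {
    stop("background must be 4 positive probabilities summing to 1",
         call. = FALSE)
  }
  prob <- (count_matrix + pseudocount) / totals
  colnames(prob) <- c("A", "C", "G", "T")
  pwm <- list(name = name, prob = prob,
              background = stats::setNames(background, c("A", "C", "G", "T")),
              pseudocount = pseudocount)
  class(pwm) <- "pwm"
  pwm
}

#' Build a PWM from a consensus sequence
#'
#' Convenience constructor: `weight` pseudo-observations of the consensus
#' base per position, smoothed by `pseudocount`.
#'
#' @param consensus String over A/C/G/T.
#' @param weight Count given to the consensus base (default 10).
#' @inheritParams build_pwm
#' @return A `pwm` object.
#' @export
consensus_pwm <- function(consensus, weight = 10, pseudocount = 0.25,
                          background = rep(0.25, 4), name = consensus) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (any(!bases %in% c("A", "C", "G", "T"))) {
    stop("consensus must be over A, C, G, T", call. = FALSE)
  }
  cm <- matrix(0, length(bases), 4,
               dimnames = list(NULL, c("A", "C", "G", "T")))
  cm[cbind(seq_along(bases), match(bases, colnames(cm)))] <- weight
  build_pwm(cm, pseudocount = pseudocount, background = background,
            name = name)
}

#' Read motif count matrices from a text file
#'
#' Simple format: a `#name` header line followed by one position per line
#' with 4 whitespace-separated counts (A C G T). Several motifs per file
#' allowed.
#'
#' @param path File path.
#' @param ... Passed to [build_pwm()].
#' @return Named list of `pwm` objects.
#' @export
read_pwms <- function(path, ...) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grepl("^#", lines)
  if (!heads[1]) stop("PWM file must start with a '#name' header",
                      call. = FALSE)
  idx <- cumsum(heads)
  out <- list()
  for (block in split(lines, idx)) {
    name <- sub("^#\\s*", "", block[1])
    rows <- lapply(strsplit(block[-1], "\\s+"), as.numeric)
    cm <- do.call(rbind, rows)
    out[[name]] <- build_pwm(cm, name = name, ...)
  }
  out
}

pwm_max_score <- function(pwm) {
  sum(apply(log2(pwm$prob / rep(pwm$background, each = nrow(pwm$prob))),
            1, max))
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(seq, function(s) paste(rev(strsplit(s, "")[[1]]),
                                       collapse = ""), ""))
}

scan_one_strand <- function(pwm, sequence) {
  w <- nrow(pwm$prob)
  bases <- strsplit(sequence, "")[[1]]
  n <- length(bases)
  if (n < w) {
    return(data.frame(offset = integer(), score = numeric()))
  }
  lods <- log2(pwm$prob / rep(pwm$background, each = w))
  code <- match(bases, c("A", "C", "G", "T"))  # N and others -> NA
  scores <- numeric(n - w + 1)
  for (o in seq_len(n - w + 1)) {
    idx <- code[o:(o + w - 1)]
    if (anyNA(idx)) {
      scores[o] <- NA_real_  # window contains N: skipped
    } else {
      scores[o] <- sum(lods[cbind(seq_len(w), idx)])
    }
  }
  keep <- which(!is.na(scores))
  data.frame(offset = keep - 1L, score = scores[keep])
}

#' Scan a sequence with a PWM
#'
#' Slides the motif's log2-odds score over the sequence (both strands by
#' default; windows containing N are skipped) and reports windows whose
#' score reaches `threshold_fraction` of the maximal attainable score.
#' Offsets are 0-based on the forward strand. When the maximal attainable
#' score is not positive (degenerate motif) no hits are reported.
#'
#' @param pwm A `pwm` object.
#' @param sequence DNA string over A/C/G/T/N.
#' @param threshold_fraction Hit threshold as a fraction of the maximum
#'   score (default 0.8).
#' @param both_strands Scan the reverse complement too (default TRUE).
#' @return `data.frame` with `offset`, `strand`, `score`, `score_fraction`.
#' @export
scan_sequence <- function(pwm, sequence, threshold_fraction = 0.8,
                          both_strands = TRUE) {
  sequence <- toupper(sequence)
  maxs <- pwm_max_score(pwm)
  fwd <- scan_one_strand(pwm, sequence)
  fwd$strand <- rep("+", nrow(fwd))
  hits <- fwd
  if (both_strands) {
    rev <- scan_one_strand(pwm, revcomp(sequence))
    # reflect offsets back to forward-strand coordinates
    rev$offset <- nchar(sequence) - nrow(pwm$prob) - rev$offset
    rev$strand <- rep("-", nrow(rev))
    hits <- rbind(hits, rev)
  }
  if (maxs <= 0) {
    hits <- hits[0, , drop = FALSE]
  } else {
    hits$score_fraction <- hits$score / maxs
    hits <- hits[hits$score_fraction >= threshold_fraction, , drop = FALSE]
  }
  if (is.null(hits$score_fraction)) hits$score_fraction <- numeric(0)
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("offset", "strand", "score", "score_fraction")]
}

#' Scan many peak sequences with a PWM
#'
#' @param pwm A `pwm` object.
#' @param seqs Named character vector of per-peak sequences.
#' @inheritParams scan_sequence
#' @return `data.frame` of hits with a leading `peak_id` column.
#' @export
scan_sequences <- function(pwm, seqs, threshold_fraction = 0.8,
                           both_strands = TRUE) {
  out <- lapply(names(seqs), function(id) {
    h <- scan_sequence(pwm, seqs[[id]], threshold_fraction, both_strands)
    if (nrow(h)) cbind(peak_id = id, h, stringsAsFactors = FALSE) else NULL
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(peak_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      score_fraction = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Motif enrichment in foreground vs background peaks
#'
#' Counts peaks with at least one hit in each set, forms the 2x2 table and
#' tests it with Fisher's exact test (two-sided: sum of table probabilities
#' not exceeding the observed one). The odds ratio is the sample odds ratio,
#' with a Haldane correction of 0.5 per cell when any cell is zero.
#'
#' @param pwm A `pwm` object.
#' @param fg_seqs,bg_seqs Named character vectors of peak sequences.
#' @param threshold_fraction Hit threshold fraction.
#' @return List: `odds_ratio`, `p` (two-sided Fisher), `fg_hits`, `fg_total`,
#'   `bg_hits`, `bg_total`.
#' @export
motif_enrichment <- function(pwm, fg_seqs, bg_seqs,
                             threshold_fraction = 0.8) {
  if (length(fg_seqs) == 0 || length(bg_seqs) == 0) {
    stop("foreground and background must be non-empty", call. = FALSE)
  }
  fg_hit <- length(unique(scan_sequences(pwm, fg_seqs,
                                         threshold_fraction)$peak_id))
  bg_hit <- length(unique(scan_sequences(pwm, bg_seqs,
                                         threshold_fraction)$peak_id))
  tab <- matrix(c(fg_hit, length(fg_seqs) - fg_hit,
                  bg_hit, length(bg_seqs) - bg_hit), 2, 2)
  p <- stats::fisher.test(tab)$p.value
  ct <- tab + if (any(tab == 0)) 0.5 else 0
  odds_ratio <- (ct[1, 1] * ct[2, 2]) / (ct[2, 1] * ct[1, 2])
  list(odds_ratio = odds_ratio, p = p,
       fg_hits = fg_hit, fg_total = length(fg_seqs),
       bg_hits = bg_hit, bg_total = length(bg_seqs))
}
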