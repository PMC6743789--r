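#' Simulation configuration for a synthetic accessibility time course
#'
#' Defines the statistical structure the pipeline assumes: six developmental
#' stages, peaks spread over chromosome arms, a static class plus sharp,
#' broad and oscillating dynamic classes with a multiplicative on/off
#' amplitude, log-normal baselines and log-scale multiplicative noise, genes
#' coupled to peaks by activation/repression/decoupled relations, replicate
#' samples, and peak sequences carrying a planted motif at class-dependent
#' rates.
#'
#' @param n_peaks Total number of peaks (default 2000).
#' @param stages Ordered stage labels.
#' @param arms Chromosome-arm labels.
#' @param arm_length Length of each arm in bp.
#' @param peak_width Peak width in bp.
#' @param frac_static Fraction of static peaks (default 0.25); the dynamic
#'   remainder is split over six sharp classes (one per stage), two broad
#'   classes and one oscillating class with weights `2:2:2:2:2:2:2:2:2`
#'   rescaled so sharp classes take half of it.
#' @param amplitude On/off accessibility ratio of dynamic classes (default 4).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline RPKM
#'   parameters (defaults 2 and 0.5).
#' @param noise_sigma SD of the log-scale multiplicative noise (default 0.15).
#' @param n_genes Number of genes, each coupled to a distinct peak
#'   (default `n_peaks %/% 2`).
#' @param coupling Named fractions for `activation`, `repression`,
#'   `decoupled` gene-peak relations (default 0.6/0.2/0.2).
#' @param gene_meanlog,gene_sdlog Log-normal baseline for gene RPKM
#'   (defaults 2.5, 0.5).
#' @param nc_frac Fraction of genes emitted as non-coding (gene span only).
#' @param n_replicates Replicate samples per stage (default 2).
#' @param replicate_sigma Log-scale replicate noise SD (default 0.1).
#' @param motif_consensus Consensus planted in peak sequences.
#' @param motif_rate_fg,motif_rate_bg Planting rate in dynamic (foreground)
#'   and static (background) peaks (defaults 0.3, 0.05).
#' @param rng_seed Integer seed; all randomness derives from it.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_peaks = 2000L,
                              stages = default_stages(),
                              arms = c("2L", "2R", "3L", "3R", "X"),
                              arm_length = 2e6,
                              peak_width = 200L,
                              frac_static = 0.25,
                              amplitude = 4,
                              baseline_meanlog = 2,
                              baseline_sdlog = 0.5,
                              noise_sigma = 0.15,
                              n_genes = NULL,
                              coupling = c(activation = 0.6,
                                           repression = 0.2,
                                           decoupled = 0.2),
                              gene_meanlog = 2.5,
                              gene_sdlog = 0.5,
                              nc_frac = 0.02,
                              n_replicates = 2L,
                              replicate_sigma = 0.1,
                              motif_consensus = "TGACGTCA",
                              motif_rate_fg = 0.3,
                              motif_rate_bg = 0.05,
                              rng_seed = 1L) {
  if (is.null(n_genes)) n_genes <- n_peaks %/% 2L
  if (abs(sum(coupling) - 1) > 1e-9 || any(coupling < 0)) {
    stop("coupling fractions must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (amplitude <= 1) stop("amplitude must exceed 1", call. = FALSE)
  cfg <- list(n_peaks = as.integer(n_peaks), stages = stages, arms = arms,
              arm_length = arm_length, peak_width = as.integer(peak_width),
              frac_static = frac_static, amplitude = amplitude,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              noise_sigma = noise_sigma, n_genes = as.integer(n_genes),
              coupling = coupling, gene_meanlog = gene_meanlog,
              gene_sdlog = gene_sdlog, nc_frac = nc_frac,
              n_replicates = as.integer(n_replicates),
              replicate_sigma = replicate_sigma,
              motif_consensus = toupper(motif_consensus),
              motif_rate_fg = motif_rate_fg, motif_rate_bg = motif_rate_bg,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Multiplicative class profiles of a simulation
#'
#' Static peaks sit at 1 across stages; a sharp class carries the amplitude
#' at one stage; the two broad classes at three sequential mid/late stages;
#' the oscillating class at alternating stages.
#'
#' @param config A `simulation_config`.
#' @return Named list of per-stage multiplier vectors, one per class.
#' @export
class_profiles <- function(config) {
  ns <- length(config$stages)
  a <- config$amplitude
  profs <- list(static = rep(1, ns))
  for (s in seq_len(ns)) {
    p <- rep(1, ns)
    p[s] <- a
    profs[[paste0("sharp_", config$stages[s])]] <- p
  }
  if (ns >= 5) {
    b1 <- rep(1, ns); b1[3:5] <- a
    b2 <- rep(1, ns); b2[(ns - 2):ns] <- a
    profs$broad_mid <- b1
    profs$broad_late <- b2
  }
  osc <- rep(1, ns)
  osc[seq(1, ns, by = 2)] <- a
  profs$oscillating <- osc
  lapply(profs, function(p) stats::setNames(p, config$stages))
}

class_counts <- function(config) {
  profs <- class_profiles(config)
  classes <- names(profs)
  dyn_classes <- setdiff(classes, "static")
  n_static <- round(config$n_peaks * config$frac_static)
  n_dyn <- config$n_peaks - n_static
  base <- n_dyn %/% length(dyn_classes)
  counts <- stats::setNames(rep(base, length(dyn_classes)), dyn_classes)
  rem <- n_dyn - base * length(dyn_classes)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  c(static = n_static, counts)
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  }, "")
}

#' Plant a motif consensus into sequences
#'
#' Selects each sequence independently with probability `rate` and overwrites
#' one uniformly placed window with the consensus (length preserved);
#' insertions are recorded. Sequences shorter than the consensus are skipped
#' with a warning.
#'
#' @param sequences Named character vector.
#' @param consensus Motif string over A/C/G/T.
#' @param rate Planting probability per sequence.
#' @param seed Optional integer seed (omit to use the current RNG stream).
#' @return List with `sequences` (modified) and `records`
#'   (`data.frame`: seq_id, offset).
#' @export
plant_motif <- function(sequences, consensus, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  consensus <- toupper(consensus)
  if (grepl("[^ACGT]", consensus)) {
    stop("consensus must be over A, C, G, T", call. = FALSE)
  }
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]", call. = FALSE)
  w <- nchar(consensus)
  ids <- names(sequences)
  selected <- stats::runif(length(sequences)) < rate
  too_short <- nchar(sequences) < w
  if (any(selected & too_short)) {
    warning(sprintf("%d sequence(s) shorter than the consensus, skipped",
                    sum(selected & too_short)), call. = FALSE)
  }
  selected <- selected & !too_short
  offsets <- integer(0)
  rec_ids <- character(0)
  for (i in which(selected)) {
    max_off <- nchar(sequences[i]) - w
    off <- if (max_off > 0) sample.int(max_off + 1L, 1L) - 1L else 0L
    substr(sequences[i], off + 1L, off + w) <- consensus
    offsets <- c(offsets, off)
    rec_ids <- c(rec_ids, ids[i])
  }
  list(sequences = sequences,
       records = data.frame(seq_id = rec_ids, offset = offsets,
                            stringsAsFactors = FALSE))
}

#' Simulate a complete synthetic time-course dataset
#'
#' Generates peaks placed without overlap on chromosome arms, a
#' peaks-by-stages accessibility matrix (`baseline x class profile x
#' exp(N(0, sigma^2))`), replicate samples, gene expression coupled to
#' partner peaks (activation: proportional; repression: inverted;
#' decoupled: independent), a TSS table placed so each gene's partner peak
#' finds it as nearest TSS, simple gene models, per-peak sequences with the
#' motif planted at class-dependent rates, and the full ground truth. All
#' randomness derives from `config$rng_seed`.
#'
#' @param config A `simulation_config`.
#' @return List with `peaks`, `signal`, `replicates` (peaks x
#'   stage-replicate samples), `expr`, `tss`, `gene_models`, `sequences`,
#'   `truth` (list `peaks`, `genes`, `motif`) and `config`.
#' @export
simulate_dataset <- function(config) {
  set.seed(config$rng_seed)
  ns <- length(config$stages)
  profs <- class_profiles(config)
  counts <- class_counts(config)

  # peak classes, shuffled so class and genomic position are independent
  cls <- sample(rep(names(counts), counts))
  n <- length(cls)
  peak_id <- sprintf("peak_%05d", seq_len(n))

  # non-overlapping placement: round-robin arms, jittered regular spacing
  arm <- rep(config$arms, length.out = n)
  start <- integer(n)
  for (a in config$arms) {
    rows <- which(arm == a)
    slot <- floor(config$arm_length / length(rows))
    if (slot <= config$peak_width) {
      stop(sprintf("arm %s too short for %d peaks of width %d", a,
                   length(rows), config$peak_width), call. = FALSE)
    }
    jitter <- sample.int(slot - config$peak_width, length(rows),
                         replace = TRUE) - 1L
    start[rows] <- as.integer((seq_along(rows) - 1L) * slot + jitter)
  }
  peaks <- new_peak_set(peak_id, arm, start, start + config$peak_width)

  # accessibility: baseline x class profile x multiplicative noise
  baseline <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  profile_mat <- do.call(rbind, profs[cls])
  noise <- matrix(stats::rnorm(n * ns, 0, config$noise_sigma), n, ns)
  signal <- baseline * profile_mat * exp(noise)
  dimnames(signal) <- list(peak_id, config$stages)

  # replicate samples around the stage signal
  reps <- NULL
  if (config$n_replicates > 0) {
    cols <- list()
    for (r in seq_len(config$n_replicates)) {
      rn <- matrix(stats::rnorm(n * ns, 0, config$replicate_sigma), n, ns)
      m <- signal * exp(rn)
      colnames(m) <- paste0(config$stages, "_rep", r)
      cols[[r]] <- m
    }
    reps <- do.call(cbind, cols)
    reps <- reps[, paste0(rep(config$stages, each = config$n_replicates),
                          "_rep", seq_len(config$n_replicates)),
                 drop = FALSE]
    rownames(reps) <- peak_id
  }

  # genes: each coupled to a distinct peak
  n_genes <- min(config$n_genes, n)
  partner <- sample.int(n, n_genes)
  gene_id <- sprintf("gene_%05d", seq_len(n_genes))
  pool <- rep(names(config$coupling), times = round(config$coupling * n_genes))
  if (length(pool) < n_genes) {
    pool <- c(pool, rep(names(config$coupling)[1], n_genes - length(pool)))
  }
  coupling <- sample(pool[seq_len(n_genes)])
  gene_base <- stats::rlnorm(n_genes, config$gene_meanlog, config$gene_sdlog)
  expr <- matrix(0, n_genes, ns, dimnames = list(gene_id, config$stages))
  class_names <- names(profs)
  for (g in seq_len(n_genes)) {
    prof <- profs[[cls[partner[g]]]]
    shape <- switch(coupling[g],
                    activation = prof,
                    repression = max(prof) / prof,
                    decoupled = profs[[sample(class_names, 1)]])
    gnoise <- stats::rnorm(ns, 0, config$noise_sigma)
    expr[g, ] <- gene_base[g] * shape * exp(gnoise)
  }

  # TSS: just downstream of the partner peak so nearest-TSS recovers it
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  mid <- peak_midpoint(peaks)[partner]
  tss_pos <- mid + ifelse(strand == "+", 150L, -150L)
  tss_pos <- pmax(tss_pos, 2001L)
  tss <- data.frame(gene_id = gene_id, chrom = arm[partner],
                    tss = as.integer(tss_pos), strand = strand,
                    stringsAsFactors = FALSE)

  gene_models <- build_gene_models(tss, nc_frac = config$nc_frac)

  # sequences with planted motif: dynamic peaks are foreground
  seqs <- stats::setNames(random_dna(n, config$peak_width), peak_id)
  is_dyn <- cls != "static"
  fg <- plant_motif(seqs[is_dyn], config$motif_consensus,
                    config$motif_rate_fg)
  bg <- plant_motif(seqs[!is_dyn], config$motif_consensus,
                    config$motif_rate_bg)
  seqs[is_dyn] <- fg$sequences
  seqs[!is_dyn] <- bg$sequences
  motif_records <- rbind(fg$records, bg$records)

  truth_peaks <- data.frame(
    peak_id = peak_id, class = cls,
    label = ifelse(is_dyn, "dynamic", "static"),
    category = ifelse(cls == "static", "static",
                      sub("_.*$", "", sub("sharp_.*", "sharp", cls))),
    motif_planted = peak_id %in% motif_records$seq_id,
    stringsAsFactors = FALSE)
  truth_genes <- data.frame(gene_id = gene_id,
                            peak_id = peak_id[partner],
                            coupling = coupling,
                            stringsAsFactors = FALSE)

  list(peaks = peaks, signal = signal, replicates = reps, expr = expr,
       tss = tss, gene_models = gene_models, sequences = seqs,
       truth = list(peaks = truth_peaks, genes = truth_genes,
                    motif = motif_records),
       config = config)
}

# simple two-exon gene models downstream of each TSS (strand-aware):
# 5'UTR 200 bp, CDS 500 + 500 bp split by a 300 bp intron, 3'UTR 500 bp
build_gene_models <- function(tss, nc_frac = 0) {
  n <- nrow(tss)
  nc <- rep(FALSE, n)
  if (nc_frac > 0 && n > 0) {
    nc[sample.int(n, round(nc_frac * n))] <- TRUE
  }
  segs <- rbind(c("five_prime_utr", 0, 200),
                c("cds", 200, 700),
                c("intron", 700, 1000),
                c("cds", 1000, 1500),
                c("three_prime_utr", 1500, 2000))
  rows <- vector("list", n)
  for (g in seq_len(n)) {
    t0 <- tss$tss[g]
    plus <- tss$strand[g] == "+"
    span <- if (plus) c(t0, t0 + 2000L) else c(t0 - 2000L + 1L, t0 + 1L)
    out <- data.frame(gene_id = tss$gene_id[g], chrom = tss$chrom[g],
                      start = span[1], end = span[2],
                      strand = tss$strand[g], feature = "gene",
                      nc_gene = nc[g], stringsAsFactors = FALSE)
    if (!nc[g]) {
      off <- as.integer(segs[, 2])
      off2 <- as.integer(segs[, 3])
      if (plus) {
        fs <- t0 + off
        fe <- t0 + off2
      } else {
        fs <- t0 + 1L - off2
        fe <- t0 + 1L - off
      }
      out <- rbind(out, data.frame(gene_id = tss$gene_id[g],
                                   chrom = tss$chrom[g],
                                   start = fs, end = fe,
                                   strand = tss$strand[g],
                                   feature = segs[, 1], nc_gene = FALSE,
                                   stringsAsFactors = FALSE))
    }
    rows[[g]] <- out
  }
  models <- do.call(rbind, rows)
  rownames(models) <- NULL
  models
}

#' Write a simulated dataset to a directory
#'
#' Emits exactly the plain-text formats the pipeline reads: peaks BED,
#' signal/replicate/expression TSV matrices, TSS TSV, gene-model TSV,
#' FASTA sequences and ground-truth TSVs.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_peaks(dataset$peaks, file.path(dir, "peaks.bed"))
  write_matrix(dataset$signal, file.path(dir, "signal.tsv"), "peak_id")
  if (!is.null(dataset$replicates)) {
    write_matrix(dataset$replicates, file.path(dir, "replicates.tsv"),
                 "peak_id")
  }
  write_matrix(dataset$expr, file.path(dir, "expression.tsv"), "gene_id")
  utils::write.table(dataset$tss, file.path(dir, "tss.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$gene_models, file.path(dir, "gene_models.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_sequences(dataset$sequences, file.path(dir, "peaks.fa"))
  utils::write.table(dataset$truth$peaks, file.path(dir, "truth_peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
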