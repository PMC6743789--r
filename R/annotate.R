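peak_midpoint <- function(peaks) {
  as.integer(floor((peaks$start + peaks$end) / 2))
}

#' Assign peaks to the nearest transcription start site
#'
#' For each peak the gene whose TSS minimises the absolute distance to the
#' peak midpoint (integer floor of `(start + end) / 2`) on the same
#' chromosome is chosen; equidistant ties go to the lexicographically
#' smallest `gene_id`. The signed distance is the strand-aware offset of the
#' midpoint from the TSS: positive downstream of the TSS in the gene's
#' orientation (`midpoint - tss` on `+`, `tss - midpoint` on `-`), negative
#' upstream. Peaks on chromosomes without any TSS are reported unassigned
#' with a warning.
#'
#' @param peaks Peak set.
#' @param tss TSS table (`gene_id`, `chrom`, `tss`, `strand`).
#' @return `data.frame` with `peak_id`, `gene_id` (NA when unassigned),
#'   `midpoint`, `signed_distance`, `strand`.
#' @export
assign_nearest_tss <- function(peaks, tss) {
  validate_peak_set(peaks)
  validate_tss_table(tss)
  mid <- peak_midpoint(peaks)
  gene_id <- rep(NA_character_, nrow(peaks))
  signed <- rep(NA_integer_, nrow(peaks))
  strand <- rep(NA_character_, nrow(peaks))
  orphan <- character()
  for (chr in unique(peaks$chrom)) {
    prows <- which(peaks$chrom == chr)
    cand <- tss[tss$chrom == chr, , drop = FALSE]
    if (nrow(cand) == 0) {
      orphan <- c(orphan, chr)
      next
    }
    # sort candidates so which.min resolves distance ties to the
    # lexicographically smallest gene id
    cand <- cand[order(cand$gene_id), , drop = FALSE]
    for (i in prows) {
      d <- abs(mid[i] - cand$tss)
      j <- which.min(d)
      gene_id[i] <- cand$gene_id[j]
      strand[i] <- cand$strand[j]
      signed[i] <- if (cand$strand[j] == "+") mid[i] - cand$tss[j]
                   else cand$tss[j] - mid[i]
    }
  }
  if (length(orphan)) {
    warning(sprintf("no TSS on chromosome(s) %s; peaks left unassigned",
                    paste(orphan, collapse = ", ")), call. = FALSE)
  }
  data.frame(peak_id = peaks$peak_id, gene_id = gene_id, midpoint = mid,
             signed_distance = signed, strand = strand,
             stringsAsFactors = FALSE)
}

#' Classify peaks into genomic feature categories
#'
#' Categorises each assigned peak midpoint by priority
#' `proximal_promoter > five_prime_utr > cds > intron > three_prime_utr >
#' nc_gene > intergenic`. The proximal promoter is the strand-aware window
#' (default -500..+150 bp) around the assigned TSS; other categories come
#' from the gene-model feature spans containing the midpoint.
#'
#' @param assignments Output of [assign_nearest_tss()].
#' @param gene_models Gene-model `data.frame` with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `feature` (one of `gene`,
#'   `five_prime_utr`, `cds`, `intron`, `three_prime_utr`) and logical
#'   `nc_gene` on the `gene` rows. Coordinates 0-based half-open.
#' @param peaks Peak set (for midpoints/chromosomes).
#' @param promoter_window Integer c(upstream, downstream) window, default
#'   c(-500, 150).
#' @return `assignments` with an added `feature_category` column.
#' @export
classify_features <- function(assignments, gene_models, peaks,
                              promoter_window = c(-500L, 150L)) {
  mid <- assignments$midpoint
  chrom <- peaks$chrom[match(assignments$peak_id, peaks$peak_id)]
  genes <- gene_models[gene_models$feature == "gene", , drop = FALSE]
  feats <- gene_models[gene_models$feature != "gene", , drop = FALSE]
  priority <- c("five_prime_utr", "cds", "intron", "three_prime_utr")
  category <- character(nrow(assignments))
  for (i in seq_len(nrow(assignments))) {
    d <- assignments$signed_distance[i]
    if (!is.na(d) && d >= promoter_window[1] && d <= promoter_window[2]) {
      category[i] <- "proximal_promoter"
      next
    }
    hit <- feats$chrom == chrom[i] & feats$start <= mid[i] & mid[i] < feats$end
    if (any(hit)) {
      have <- feats$feature[hit]
      category[i] <- priority[min(match(have, priority))]
      next
    }
    g <- genes$chrom == chrom[i] & genes$start <= mid[i] & mid[i] < genes$end
    if (any(g) && any(genes$nc_gene[g])) {
      category[i] <- "nc_gene"
    } else {
      category[i] <- "intergenic"
    }
  }
  assignments$feature_category <- category
  assignments
}

#' Histogram of TSS distances over kb bins
#'
#' Bins `|signed_distance|` into half-open intervals `[0, 0.5)`, `[0.5, 1)`,
#' `[1, 5)`, `[5, 10)`, `[10, Inf)` kb by default, optionally stratified by a
#' per-peak label (e.g. static/dynamic).
#'
#' @param assignments Output of [assign_nearest_tss()].
#' @param edges_kb Strictly increasing interior bin edges in kb.
#' @param labels Optional character vector of peak classes, aligned with
#'   `assignments` rows.
#' @return `data.frame` of counts per bin (per class when `labels` given).
#' @export
distance_bins <- function(assignments, edges_kb = c(0.5, 1, 5, 10),
                          labels = NULL) {
  breaks <- c(0, edges_kb * 1000, Inf)
  bin_names <- paste0("[", breaks[-length(breaks)] / 1000, ",",
                      c(edges_kb, Inf), ")kb")
  d <- abs(assignments$signed_distance)
  keep <- !is.na(d)
  bin <- cut(d[keep], breaks = breaks, right = FALSE, labels = bin_names)
  if (is.null(labels)) {
    counts <- table(bin)
    data.frame(bin = names(counts), count = as.integer(counts),
               stringsAsFactors = FALSE)
  } else {
    tab <- table(bin, class = labels[keep])
    out <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(out) <- c("bin", "class", "count")
    out
  }
}

#' Count overlapping peaks between two peak sets
#'
#' A peak of `a` is counted once when at least one peak of `b` intersects it
#' by at least `min_bp` (half-open interval intersection).
#'
#' @param a,b Peak sets on the same assembly.
#' @param min_bp Minimum overlap in bp (default 1).
#' @return List with `count` (peaks of `a` overlapped) and `pairs`
#'   (`data.frame` of overlapping `peak_a`, `peak_b`).
#' @export
overlap_peaksets <- function(a, b, min_bp = 1L) {
  validate_peak_set(a)
  validate_peak_set(b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(list(count = 0L,
                pairs = data.frame(peak_a = character(), peak_b = character(),
                                   stringsAsFactors = FALSE)))
  }
  gr_a <- GenomicRanges::GRanges(a$chrom,
                                 IRanges::IRanges(a$start + 1L, a$end))
  gr_b <- GenomicRanges::GRanges(b$chrom,
                                 IRanges::IRanges(b$start + 1L, b$end))
  hits <- GenomicRanges::findOverlaps(gr_a, gr_b, minoverlap = min_bp)
  pairs <- data.frame(peak_a = a$peak_id[S4Vectors::queryHits(hits)],
                      peak_b = b$peak_id[S4Vectors::subjectHits(hits)],
                      stringsAsFactors = FALSE)
  list(count = length(unique(pairs$peak_a)), pairs = pairs)
}

#' Gene-structure length statistics per gene set
#'
#' Computes element lengths (introns, 5' and 3' UTRs, whole gene spans) for
#' each provided gene set and summarises them (n, quartiles, median). Genes
#' absent from the models are skipped with a warning.
#'
#' @param gene_models Gene-model table (see [classify_features()]).
#' @param gene_sets Named list of gene-id character vectors.
#' @return List with `lengths` (long `data.frame`: set, gene_id, element,
#'   length) and `summary` (per set and element: n, q1, median, q3).
#' @export
gene_structure_stats <- function(gene_models, gene_sets) {
  genes <- gene_models[gene_models$feature == "gene", , drop = FALSE]
  feats <- gene_models[gene_models$feature != "gene", , drop = FALSE]
  rows <- list()
  for (set_name in names(gene_sets)) {
    ids <- gene_sets[[set_name]]
    missing <- setdiff(ids, genes$gene_id)
    if (length(missing)) {
      warning(sprintf("set '%s': %d gene(s) absent from models, skipped",
                      set_name, length(missing)), call. = FALSE)
      ids <- setdiff(ids, missing)
    }
    g <- genes[genes$gene_id %in% ids, , drop = FALSE]
    if (nrow(g)) {
      rows[[length(rows) + 1L]] <- data.frame(
        set = set_name, gene_id = g$gene_id, element = "gene",
        length = g$end - g$start, stringsAsFactors = FALSE)
    }
    f <- feats[feats$gene_id %in% ids &
                 feats$feature %in% c("intron", "five_prime_utr",
                                      "three_prime_utr"), , drop = FALSE]
    if (nrow(f)) {
      rows[[length(rows) + 1L]] <- data.frame(
        set = set_name, gene_id = f$gene_id, element = f$feature,
        length = f$end - f$start, stringsAsFactors = FALSE)
    }
  }
  lengths <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(), gene_id = character(),
               element = character(), length = integer(),
               stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(
    split(lengths, list(lengths$set, lengths$element), drop = TRUE),
    function(d) {
      q <- stats::quantile(d$length, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(set = d$set[1], element = d$element[1], n = nrow(d),
                 q1 = q[1], median = q[2], q3 = q[3],
                 stringsAsFactors = FALSE)
    }))
  rownames(summ) <- NULL
  list(lengths = lengths, summary = summ)
}
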