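#' Read a peak set from a BED-like file
#'
#' Accepts BED3 (chrom, start, end) or BED4+ (plus name). Coordinates are
#' 0-based half-open, the convention used throughout the package. When the
#' name column is absent, ids `peak_00001`, `peak_00002`, ... are generated.
#'
#' @param path Path to a tab-separated BED-like file (no header).
#' @return A `data.frame` with columns `peak_id`, `chrom`, `start`, `end`.
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(new_peak_set(character(), character(), integer(), integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  bad <- which(nfield < 3)
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: fewer than 3 tab-separated fields",
                 bad[1]), call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: non-numeric coordinates", bad[1]),
         call. = FALSE)
  }
  if (all(nfield >= 4)) {
    peak_id <- vapply(fields, `[[`, "", 4)
  } else {
    peak_id <- sprintf("peak_%05d", seq_along(chrom))
  }
  new_peak_set(peak_id, chrom, start, end)
}

new_peak_set <- function(peak_id, chrom, start, end) {
  ps <- data.frame(peak_id = peak_id, chrom = chrom,
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  validate_peak_set(ps)
}

#' Validate a peak set
#'
#' Enforces the internal contract: 0-based half-open intervals with
#' `start < end`, unique ids, non-empty chromosome-arm labels.
#'
#' @param peaks A peak-set `data.frame`.
#' @return The validated `data.frame`, invisibly unchanged.
#' @export
validate_peak_set <- function(peaks) {
  req <- c("peak_id", "chrom", "start", "end")
  if (!all(req %in% names(peaks))) {
    stop("peak set must have columns peak_id, chrom, start, end", call. = FALSE)
  }
  if (nrow(peaks) == 0) return(peaks)
  bad <- which(peaks$start >= peaks$end)
  if (length(bad)) {
    stop(sprintf("invalid interval for peak '%s': start (%d) >= end (%d)",
                 peaks$peak_id[bad[1]], peaks$start[bad[1]], peaks$end[bad[1]]),
         call. = FALSE)
  }
  if (anyDuplicated(peaks$peak_id)) {
    stop("peak ids must be unique", call. = FALSE)
  }
  if (any(!nzchar(peaks$chrom))) {
    stop("chromosome labels must be non-empty", call. = FALSE)
  }
  peaks
}

#' Write a peak set as BED4
#'
#' @param peaks Peak-set `data.frame`.
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  validate_peak_set(peaks)
  out <- peaks[, c("chrom", "start", "end", "peak_id")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a signal or expression matrix from TSV
#'
#' The file must have a header row of stage/sample names and row ids in the
#' first column. When `expected_stages` is given, columns are reordered to
#' that developmental order and missing stages are an error.
#'
#' @param path Path to a tab-separated matrix.
#' @param expected_stages Optional ordered character vector of column names.
#' @return Numeric matrix with row ids as rownames and ordered stage columns.
#' @export
read_matrix <- function(path, expected_stages = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (!is.null(expected_stages)) {
    missing <- setdiff(expected_stages, colnames(m))
    if (length(missing)) {
      stop(sprintf("matrix is missing stage column(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    m <- m[, expected_stages, drop = FALSE]
  }
  validate_signal_matrix(m)
}

#' Validate a signal matrix
#'
#' @param m Numeric matrix, rows are peaks/genes, columns stages/samples.
#' @return The matrix, if valid.
#' @export
validate_signal_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("signal matrix must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(m)) stop("signal matrix contains missing values", call. = FALSE)
  if (any(m < 0)) {
    stop("signal matrix contains negative values; RPKM must be >= 0",
         call. = FALSE)
  }
  if (is.null(rownames(m))) stop("signal matrix must have row ids", call. = FALSE)
  m
}

#' Write a matrix as TSV (row ids in first column)
#'
#' @param m Numeric matrix with rownames.
#' @param path Output path.
#' @param id_col Name for the row-id column in the header.
#' @export
write_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSS table
#'
#' Two input forms are supported. A plain TSV with columns
#' `gene_id, chrom, tss, strand` is taken as already 0-based. A GTF/GFF file
#' (recognised by extension, parsed with rtracklayer) uses 1-based closed
#' coordinates; the TSS is `start - 1` for `+` strand genes and `end - 1`
#' for `-` strand genes, converted to 0-based. For genes with several
#' transcripts the 5'-most TSS on the gene strand is kept.
#'
#' @param path Path to the annotation file.
#' @return `data.frame` with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff3")) {
    gr <- rtracklayer::import(path)
    meta <- S4Vectors::mcols(gr)
    gene_id <- if ("gene_id" %in% names(meta)) as.character(meta$gene_id)
               else as.character(meta$ID)
    strand <- as.character(GenomicRanges::strand(gr))
    if (any(!strand %in% c("+", "-"))) {
      stop("unknown strand symbol in annotation (must be + or -)",
           call. = FALSE)
    }
    tss <- ifelse(strand == "+",
                  GenomicRanges::start(gr) - 1L,
                  GenomicRanges::end(gr) - 1L)
    tab <- data.frame(gene_id = gene_id,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      tss = as.integer(tss),
                      strand = strand,
                      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    req <- c("gene_id", "chrom", "tss", "strand")
    if (!all(req %in% names(tab))) {
      stop("TSS TSV must have columns gene_id, chrom, tss, strand",
           call. = FALSE)
    }
    tab <- tab[, req]
  }
  validate_tss_table(primary_tss(tab))
}

# one record per gene: the 5'-most TSS on the gene strand
primary_tss <- function(tab) {
  if (anyDuplicated(tab$gene_id)) {
    parts <- split(tab, tab$gene_id)
    rows <- lapply(parts, function(d) {
      if (d$strand[1] == "+") d[which.min(d$tss), ] else d[which.max(d$tss), ]
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
  }
  tab
}

#' Validate a TSS table
#' @param tab `data.frame` with `gene_id`, `chrom`, `tss`, `strand`.
#' @return The validated table.
#' @export
validate_tss_table <- function(tab) {
  if (any(!tab$strand %in% c("+", "-"))) {
    stop("unknown strand symbol (must be + or -)", call. = FALSE)
  }
  if (anyDuplicated(tab$gene_id)) {
    stop("TSS table must contain one record per gene", call. = FALSE)
  }
  tab
}

#' RPKM from raw counts
#'
#' reads per kilobase of feature per million mapped reads:
#' `rpkm_i = counts_i * 1e9 / (lengths_i * library_size)`.
#'
#' @param counts Integer read counts per feature.
#' @param lengths Feature lengths in bp (> 0).
#' @param library_size Total mapped reads (> 0).
#' @return Numeric RPKM vector.
#' @export
rpkm_from_counts <- function(counts, lengths, library_size) {
  if (any(lengths <= 0)) stop("feature lengths must be > 0", call. = FALSE)
  if (length(library_size) != 1 || library_size <= 0) {
    stop("library_size must be a single value > 0", call. = FALSE)
  }
  counts * 1e9 / (lengths * library_size)
}

#' Read per-peak sequences from FASTA
#'
#' @param path FASTA path; record names must match peak ids.
#' @return Named character vector of upper-case sequences.
#' @export
read_sequences <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write per-peak sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_sequences <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
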