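# Small in-code fixtures shared across test files.

stage6 <- function() c("L3", "6h", "18h", "24h", "36h", "44h")

# a tiny signal matrix with named rows and the six standard stages
tiny_signal <- function(rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- stage6()
  m
}

write_tsv_matrix <- function(m, path, id_col = "peak_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

random_peaks <- function(n, chroms = c("2L", "2R"), width = 100L) {
  start <- sample.int(1e6, n)
  data.frame(peak_id = sprintf("p%03d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             stringsAsFactors = FALSE)
}

random_tss <- function(n, chroms = c("2L", "2R")) {
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             tss = sample.int(1e6, n),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}
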