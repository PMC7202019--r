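# shared fixture builders and independent oracles

# aligned-read table, vectorised over start
make_reads <- function(start, chrom = "chr1", strand = "+", mapq = 60L,
                       sample = "S1", read_length = 150L,
                       read_id = NULL) {
  n <- length(start)
  if (is.null(read_id)) read_id <- sprintf("r%04d", seq_len(n))
  data.frame(chrom = rep_len(chrom, n), start = as.integer(start),
             end = as.integer(start + read_length),
             strand = rep_len(strand, n),
             mapq = as.integer(rep_len(mapq, n)),
             sample = rep_len(sample, n), read_id = read_id,
             stringsAsFactors = FALSE)
}

# random read set for clustering properties
random_reads <- function(n, span = 3000L, chroms = c("chr1", "chr2"),
                         samples = c("S1", "S2", "S3")) {
  make_reads(sample.int(span, n, replace = TRUE),
             chrom = sample(chroms, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             mapq = sample(30:60, n, replace = TRUE),
             sample = sample(samples, n, replace = TRUE))
}

# independent clustering oracle: connected components (igraph) of the
# graph joining same-chrom same-strand reads with |start_i - start_j| <= w
oracle_cluster_summary <- function(reads, window) {
  parts <- split(reads, paste(reads$chrom, reads$strand))
  rows <- lapply(parts, function(p) {
    n <- nrow(p)
    adj <- abs(outer(p$start, p$start, "-")) <= window
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    do.call(rbind, lapply(split(seq_len(n), comp), function(idx) {
      data.frame(chrom = p$chrom[1], start = min(p$start[idx]),
                 end = max(p$end[idx]), strand = p$strand[1],
                 n_reads_total = length(idx), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force poly(T) window finder: test every window start
brute_polyt <- function(seq, k = 11L, max_mismatch = 1L) {
  n <- nchar(seq)
  if (n < k) return(NA_integer_)
  for (i in seq_len(n - k + 1L)) {
    win <- strsplit(substr(seq, i, i + k - 1L), "")[[1]]
    if (sum(win != "T") <= max_mismatch) return(i - 1L)
  }
  NA_integer_
}

random_acgtn_read <- function(len, t_rich = FALSE) {
  prob <- if (t_rich) c(0.1, 0.1, 0.1, 0.65, 0.05) else
    c(0.24, 0.24, 0.24, 0.24, 0.04)
  paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
               prob = prob), collapse = "")
}

# minimal peak table built directly (bypassing call_peaks), one sample
# count column per element of `counts`'s columns
make_peak_table <- function(mean_mapq, counts, class = "reference",
                            chrom = "chr1", strand = "+") {
  counts <- as.data.frame(counts)
  n <- nrow(counts)
  mean_mapq <- rep_len(mean_mapq, n)
  start <- as.integer(seq_len(n) * 1000L)
  peaks <- data.frame(chrom = rep_len(chrom, n), start = start,
                      end = start + 300L, strand = rep_len(strand, n),
                      n_reads_total = as.integer(rowSums(counts)),
                      n_unique_reads = as.integer(rowSums(counts > 0)),
                      mean_mapq = mean_mapq,
                      avg_reads_per_person = NA_real_,
                      annotation_class = rep_len(class, n),
                      annotation_name = NA_character_,
                      stringsAsFactors = FALSE)
  peaks <- cbind(peaks, counts)
  attr(peaks, "samples") <- colnames(counts)
  peaks
}

# SAM text writer for format tests
write_test_sam <- function(records, path,
                           header = c("@HD\tVN:1.6",
                                      "@SQ\tSN:chr1\tLN:1000000",
                                      "@RG\tID:rg1\tSM:sampleA",
                                      "@RG\tID:rg2\tSM:sampleB")) {
  writeLines(c(header, records), path)
  path
}

# the in-study validation-experiment counts shipped with the package
validation_fixture <- function() {
  read_validation_tsv(system.file("extdata", "table1_validation_counts.tsv",
                                  package = "rebelkit"))
}
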