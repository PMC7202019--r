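#' Remove low mapping-quality alignments
#'
#' Keeps exactly the reads with `mapq >= min_mapq` (the boundary value is
#' retained), preserving input order.
#'
#' @param reads aligned-read table from [read_sam()].
#' @param min_mapq minimum mapping quality (default 30).
#' @return the filtered read table.
#' @export
filter_mapq <- function(reads, min_mapq = 30) {
  reads[reads$mapq >= min_mapq, , drop = FALSE]
}

#' Cluster aligned reads into strand-aware peaks
#'
#' The core junction caller.  Reads are partitioned by chromosome and
#' strand; within each partition they are sorted by start and chained by
#' single linkage: a read joins the open peak if its start is within
#' `window` bp of the largest start already in the peak, otherwise a new
#' peak opens.  This equals the connected components of the graph
#' linking same-chromosome, same-strand reads whose starts differ by at
#' most `window` bp, so the result is independent of input order.  Every
#' read belongs to exactly one peak; each peak is a putative L1Hs 3'
#' insertion junction.
#'
#' Clustering is on read *starts*, not full intervals: the amplicon
#' chemistry anchors every supporting read near the junction, so starts
#' carry the signal while read lengths do not.
#'
#' Single-read peaks are emitted; all filtering is a later, explicit
#' stage.  "Unique reads" are distinct (sample, start) pairs within a
#' peak — a PCR-duplicate-insensitive count (strand is constant within a
#' peak).
#'
#' @param reads aligned-read table, already MapQ-filtered.
#' @param window clustering distance in bp (default 150).
#' @param samples sample universe for the per-sample count columns;
#'   defaults to the sorted set of samples present in `reads`.
#' @return a peak table: one row per peak, columns `chrom`, `start`
#'   (min member start), `end` (max member end), `strand`,
#'   `n_reads_total`, `n_unique_reads`, `mean_mapq`,
#'   `avg_reads_per_person` (`NA` until filters run),
#'   `annotation_class` (`"unset"`), `annotation_name`, then one count
#'   column per sample.  Rows sorted by (chrom, start, strand).
#' @export
call_peaks <- function(reads, window = 150, samples = NULL) {
  stopifnot(window > 0)
  if (is.null(samples)) samples <- sort(unique(reads$sample))
  if (nrow(reads) == 0L) return(.empty_peaks(samples))

  dt <- data.table::as.data.table(reads)
  data.table::setnames(dt, "sample", "sample_id")
  data.table::setorder(dt, chrom, strand, start, end, sample_id, read_id)
  dt[, new_peak := c(TRUE, diff(start) > window), by = .(chrom, strand)]
  dt[, peak_id := cumsum(new_peak)]

  core <- dt[, .(
    chrom = chrom[1L],
    start = min(start),
    end = max(end),
    strand = strand[1L],
    n_reads_total = .N,
    n_unique_reads = data.table::uniqueN(paste(sample_id, start)),
    mean_mapq = mean(mapq)
  ), by = peak_id]

  counts <- data.table::dcast(dt[, .N, by = .(peak_id, sample_id)],
                              peak_id ~ sample_id, value.var = "N",
                              fill = 0L)
  core <- merge(core, counts, by = "peak_id")
  for (s in setdiff(samples, colnames(core))) core[[s]] <- 0L
  data.table::setorder(core, chrom, start, strand)

  peaks <- as.data.frame(core)[, c("chrom", "start", "end", "strand",
                                   "n_reads_total", "n_unique_reads",
                                   "mean_mapq", samples), drop = FALSE]
  peaks$avg_reads_per_person <- NA_real_
  peaks$annotation_class <- "unset"
  peaks$annotation_name <- NA_character_
  peaks <- peaks[, c(.peak_fixed_cols, samples), drop = FALSE]
  rownames(peaks) <- NULL
  attr(peaks, "samples") <- samples
  peaks
}

#' Summarise one cluster of reads as a peak
#'
#' @param members non-empty aligned-read table on a single chromosome
#'   and strand.
#' @param samples sample universe (defaults to samples present).
#' @return a one-row peak table.
#' @export
summarize_peak <- function(members, samples = NULL) {
  if (nrow(members) == 0L) stop("cannot summarise an empty member set")
  if (length(unique(members$chrom)) != 1L ||
      length(unique(members$strand)) != 1L) {
    stop("peak members must share one chromosome and strand")
  }
  call_peaks(members, window = .Machine$integer.max, samples = samples)
}

.empty_peaks <- function(samples) {
  peaks <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_reads_total = integer(), n_unique_reads = integer(),
                      mean_mapq = numeric(), avg_reads_per_person = numeric(),
                      annotation_class = character(),
                      annotation_name = character(),
                      stringsAsFactors = FALSE)
  for (s in samples) peaks[[s]] <- integer()
  attr(peaks, "samples") <- samples
  peaks
}
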