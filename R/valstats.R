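#' Read-depth bin labels
#'
#' @param edges sorted lower bin edges, e.g. `c(100, 250, 500, 1000)`.
#' @return labels, lowest bin first: `"100-249"`, ..., `">=1,000"` (the top label uses the Unicode \u2265 sign).
#' @export
bin_labels <- function(edges = c(100, 250, 500, 1000)) {
  if (is.unsorted(edges, strictly = TRUE)) stop("bin edges must be sorted")
  n <- length(edges)
  c(sprintf("%d-%d", edges[-n], edges[-1] - 1),
    paste0("\u2265", format(edges[n], big.mark = ",", trim = TRUE)))
}

#' Bin peaks by average reads per carrier
#'
#' Bins are half-open on the depth metric: `[100, 250)`, `[250, 500)`,
#' `[500, 1000)`, `[1000, Inf)` with the default edges.  Peaks below the
#' first edge failed the read-depth cutoff and are excluded.
#'
#' @param peaks peak table with `avg_reads_per_person` and
#'   `annotation_class` set.
#' @param edges sorted lower bin edges.
#' @return data.frame, lowest bin first: `bin`, `detected_novel`,
#'   `detected_known`, `detected_ref`.
#' @export
bin_peaks <- function(peaks, edges = c(100, 250, 500, 1000)) {
  labels <- bin_labels(edges)
  avg <- peaks$avg_reads_per_person
  if (nrow(peaks) && anyNA(avg)) {
    stop("avg_reads_per_person not computed; run add_avg_reads_per_person()")
  }
  idx <- findInterval(avg, edges)          # 0 = below the first edge
  keep <- idx >= 1L
  idx <- idx[keep]
  cls <- peaks$annotation_class[keep]
  tab <- function(cl) {
    as.integer(tabulate(idx[cls == cl], nbins = length(labels)))
  }
  data.frame(bin = labels,
             detected_novel = tab("novel_nonref"),
             detected_known = tab("known_nonref"),
             detected_ref = tab("reference"),
             stringsAsFactors = FALSE)
}

#' Validation-rate table over read-depth bins
#'
#' From per-bin validation-experiment counts (successful / attempted PCR
#' validations of novel non-reference insertions) and per-bin detected
#' counts, computes:
#'
#' * `pct_validated` — `100 * validated / attempted`, 1 decimal;
#' * `predicted_tp_novel` — `detected_novel * pct_validated / 100`
#'   using the *rounded* percentage, rounded half away from zero to an
#'   integer;
#' * `total_tp` — `predicted_tp_novel + detected_known + detected_ref`
#'   (known and reference insertions count as true positives outright);
#' * `pct_tp` — `100 * total_tp / (novel + known + ref)`, 1 decimal;
#' * `cumulative_pct_tp` — the same ratio accumulated over the bin and
#'   all deeper bins (integer `total_tp` sums), 1 decimal.
#'
#' All percentage rounding is half away from zero.
#'
#' @param bins data.frame with columns `bin`, `validated`, `attempted`,
#'   `detected_novel`, `detected_known`, `detected_ref`; rows in depth
#'   order (either direction).  The last row in increasing-depth order
#'   is the top (unbounded) bin.
#' @param deepest_first if `TRUE` (default), rows of `bins` are deepest
#'   bin first (presentation order); otherwise lowest first.
#' @return the input with the derived columns appended, deepest bin
#'   first.
#' @export
validation_table <- function(bins, deepest_first = TRUE) {
  stopifnot(all(c("bin", "validated", "attempted", "detected_novel",
                  "detected_known", "detected_ref") %in% colnames(bins)))
  if (any(bins$attempted == 0L)) {
    stop("bin '", bins$bin[which(bins$attempted == 0L)[1]],
         "' has no validation attempts")
  }
  if (any(bins$validated > bins$attempted)) {
    stop("validated exceeds attempted")
  }
  x <- bins
  if (!deepest_first) x <- x[rev(seq_len(nrow(x))), , drop = FALSE]

  x$pct_validated <- round_half_away(100 * x$validated / x$attempted, 1L)
  x$predicted_tp_novel <- as.integer(
    round_half_away(x$detected_novel * x$pct_validated / 100, 0L))
  x$total_tp <- x$predicted_tp_novel + x$detected_known + x$detected_ref
  detected <- x$detected_novel + x$detected_known + x$detected_ref
  x$pct_tp <- round_half_away(100 * x$total_tp / detected, 1L)
  x$cumulative_pct_tp <- round_half_away(
    100 * cumsum(x$total_tp) / cumsum(detected), 1L)
  rownames(x) <- NULL
  x
}

#' Read a validation-experiment count table
#'
#' Tab-delimited with header: `bin`, `validated`, `attempted`, and
#' optionally `detected_novel`, `detected_known`, `detected_ref`
#' (otherwise supplied by [bin_peaks()]).
#'
#' @param path TSV path.
#' @return a data.frame.
#' @export
read_validation_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Genomic distribution of peaks in fixed windows
#'
#' Counts peaks per `window`-bp bin of each chromosome (bin index
#' `floor(start / window)`), split into the known group (reference plus
#' known non-reference) and the novel group.
#'
#' @param peaks annotated peak table.
#' @param window window width in bp (default 10 Mb).
#' @return data.frame: `chrom`, `window` (0-based index), `window_start`
#'   (bp), `n_known`, `n_novel`; one row per non-empty window.
#' @export
genomic_distribution <- function(peaks, window = 1e7) {
  stopifnot(window > 0)
  if (nrow(peaks) == 0L) {
    return(data.frame(chrom = character(), window = integer(),
                      window_start = numeric(), n_known = integer(),
                      n_novel = integer(), stringsAsFactors = FALSE))
  }
  w <- floor(peaks$start / window)
  known <- peaks$annotation_class %in% c("reference", "known_nonref")
  key <- paste(peaks$chrom, w, sep = "\r")
  uk <- sort(unique(key))
  nk <- as.integer(table(factor(key[known], levels = uk)))
  nn <- as.integer(table(factor(key[!known], levels = uk)))
  parts <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
  out <- data.frame(chrom = parts[, 1],
                    window = as.integer(parts[, 2]),
                    n_known = nk, n_novel = nn,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$window), , drop = FALSE]
  out$window_start <- out$window * window
  rownames(out) <- NULL
  out[, c("chrom", "window", "window_start", "n_known", "n_novel")]
}

#' Carrier-count histogram
#'
#' How many peaks are carried by exactly `k` individuals, for each
#' observed `k` — the sharing spectrum of insertions across the cohort.
#'
#' @param peaks peak table with remediated counts.
#' @return data.frame `carriers`, `n_peaks`; `sum(n_peaks) == nrow(peaks)`.
#' @export
carrier_histogram <- function(peaks) {
  if (nrow(peaks) == 0L) {
    return(data.frame(carriers = integer(), n_peaks = integer()))
  }
  k <- peak_carriers(peaks)
  tb <- table(k)
  data.frame(carriers = as.integer(names(tb)),
             n_peaks = as.integer(tb))
}
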