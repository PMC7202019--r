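#' Poly(T) trimming configuration
#'
#' The amplicon protocol reads from the L1Hs 3' end into downstream
#' genomic DNA; reads that run through the junction the other way carry a
#' poly(A)-derived poly(T) stretch after the genomic portion and fail to
#' align.  Such reads are rescued by k-mer trimming the poly(T) suffix
#' and realigning the retained genomic prefix.
#'
#' @param k k-mer length of the all-T probe window (bp).
#' @param max_mismatch non-T bases tolerated per window (the Hamming
#'   distance); `N` counts as a mismatch.
#' @param min_keep minimum retained read length (bp) for a trimmed read
#'   to be emitted for realignment.
#' @return a list of class `polyt_config`.
#' @export
polyt_config <- function(k = 11L, max_mismatch = 1L, min_keep = 25L) {
  k <- as.integer(k); max_mismatch <- as.integer(max_mismatch)
  min_keep <- as.integer(min_keep)
  stopifnot(k >= 1L, max_mismatch >= 0L, max_mismatch < k, min_keep >= 1L)
  structure(list(k = k, max_mismatch = max_mismatch, min_keep = min_keep),
            class = "polyt_config")
}

#' Locate the leftmost poly(T)-like window in a read
#'
#' Scans every window of `cfg$k` consecutive bases and returns the
#' 0-based start of the leftmost window containing at most
#' `cfg$max_mismatch` bases other than `T`.  Vectorised over reads.
#'
#' @param seq character vector of uppercase `ACGTN` sequences.
#' @param cfg a [polyt_config()].
#' @return integer vector, 0-based window start per read; `NA` where no
#'   window qualifies (including reads shorter than `k`).
#' @export
find_polyt <- function(seq, cfg = polyt_config()) {
  vapply(seq, function(s) {
    n <- nchar(s)
    if (n < cfg$k) return(NA_integer_)
    nonT <- cumsum(strsplit(s, "", fixed = TRUE)[[1]] != "T")
    # mismatches in window starting at i (1-based): nonT[i+k-1] - nonT[i-1]
    mm <- nonT[cfg$k:n] - c(0L, nonT[seq_len(n - cfg$k)])
    hit <- which(mm <= cfg$max_mismatch)
    if (length(hit)) hit[1] - 1L else NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

#' k-trim poly(T) stretches from the 3' end of reads
#'
#' Right-trims each read at the leftmost qualifying poly(T) window
#' (everything from the window start to the read end is removed, i.e.
#' the retained read is the prefix before the window).  Reads whose
#' retained length falls below `cfg$min_keep` are rejected; reads with
#' no qualifying window pass through unchanged.  Trimming is not
#' guaranteed idempotent: a trimmed prefix may itself contain a
#' qualifying window, so a second pass may trim further.
#'
#' @param reads FASTQ table from [read_fastq()] (`read_id`, `sequence`,
#'   `quality`).
#' @param cfg a [polyt_config()].
#' @return a list with elements `reads` (the emitted table: trimmed plus
#'   passed-through reads), `rejected` (reads removed for falling below
#'   `min_keep`), and `summary` (counts: `n_in`, `n_trimmed`,
#'   `n_rejected`, `n_passed`).
#' @export
trim_polyt <- function(reads, cfg = polyt_config()) {
  idx <- find_polyt(reads$sequence, cfg)     # retained length == idx
  trim <- !is.na(idx)
  reject <- trim & idx < cfg$min_keep
  out <- reads
  do <- trim & !reject
  out$sequence[do] <- substr(out$sequence[do], 1L, idx[do])
  out$quality[do]  <- substr(out$quality[do], 1L, idx[do])
  list(
    reads    = out[!reject, , drop = FALSE],
    rejected = reads[reject, , drop = FALSE],
    summary  = list(n_in = nrow(reads), n_trimmed = sum(do),
                    n_rejected = sum(reject),
                    n_passed = sum(!trim))
  )
}

#' File-level poly(T) trimming
#'
#' Reads a FASTQ of unaligned reads, applies [trim_polyt()], writes the
#' emitted reads and prints a one-line summary.
#'
#' @param infile,outfile FASTQ paths.
#' @param cfg a [polyt_config()].
#' @return the summary list, invisibly.
#' @export
trim_polyt_fastq <- function(infile, outfile, cfg = polyt_config()) {
  res <- trim_polyt(read_fastq(infile), cfg)
  write_fastq(res$reads, outfile)
  s <- res$summary
  message(sprintf("poly(T) trim: %d in / %d trimmed / %d rejected / %d passed through",
                  s$n_in, s$n_trimmed, s$n_rejected, s$n_passed))
  invisible(s)
}
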