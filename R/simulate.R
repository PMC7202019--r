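#' Simulation configuration
#'
#' Defines a synthetic cohort: a toy multi-chromosome genome with
#' planted L1Hs 3' insertion junctions of three classes (reference,
#' known non-reference, novel non-reference), per-sample genotypes,
#' junction-anchored flank reads with MapQ noise, residual poly(T)
#' read tails, and index hopping between pooled samples.
#'
#' Junction geometry: supporting reads align on `peak_strand` with
#' starts jittered within `jitter_bp` of the junction, pointing away
#' from the element; the element itself lies downstream of the peak (in
#' peak-strand orientation), on the opposite strand, starting
#' `element_gap` bp beyond the junction.  The annotator's downstream
#' extension therefore reaches cataloged elements, and
#' `min_separation` is large enough (with the defaults) that
#' neighbouring insertions can never capture each other's catalog
#' features.
#'
#' @param seed integer seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @param n_chroms,chrom_length genome shape (default 2 x 10 Mb).
#' @param n_ref,n_known,n_novel insertion counts per class.
#' @param n_samples,pool_size cohort size and multiplex pool size
#'   (default pools of 6).
#' @param reads_per_carrier mean supporting reads per carrier
#'   (Poisson).
#' @param read_length read length in bp (read 1 only; the protocol
#'   discards read 2).
#' @param jitter_bp reads start uniformly within `[0, jitter_bp)` of
#'   the junction (default 150, one clustering window).
#' @param mapq_mean,mapq_sd MapQ sampled from a rounded normal clamped
#'   to `[0, 60]`; defaults (39, 4.1) put a small tail below the MapQ-30
#'   alignment filter, as observed for reference insertions.
#' @param polyt_rate fraction of non-reference-supporting reads emitted
#'   unaligned with a poly(T) suffix instead of appearing in the SAM
#'   (default 0.10).
#' @param hop_rate per-read probability of index hopping to a random
#'   pool-mate (default 0.01).
#' @param af_range range of the per-insertion carrier allele frequency
#'   for non-reference insertions; reference insertions are carried by
#'   every sample.
#' @param element_length,element_gap length of the cataloged element
#'   interval and its gap downstream of the junction (bp).
#' @param min_separation minimum distance between planted junctions
#'   (default 2 kb).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_length = 1e7,
                       n_ref = 30L, n_known = 15L, n_novel = 15L,
                       n_samples = 12L, pool_size = 6L,
                       reads_per_carrier = 300, read_length = 150L,
                       jitter_bp = 150L, mapq_mean = 39, mapq_sd = 4.1,
                       polyt_rate = 0.10, hop_rate = 0.01,
                       af_range = c(0.1, 0.9),
                       element_length = 500L, element_gap = 300L,
                       min_separation = 2000L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = chrom_length, n_ref = as.integer(n_ref),
              n_known = as.integer(n_known), n_novel = as.integer(n_novel),
              n_samples = as.integer(n_samples),
              pool_size = as.integer(pool_size),
              reads_per_carrier = reads_per_carrier,
              read_length = as.integer(read_length),
              jitter_bp = as.integer(jitter_bp),
              mapq_mean = mapq_mean, mapq_sd = mapq_sd,
              polyt_rate = polyt_rate, hop_rate = hop_rate,
              af_range = af_range,
              element_length = as.integer(element_length),
              element_gap = as.integer(element_gap),
              min_separation = as.integer(min_separation))
  stopifnot(cfg$n_chroms >= 1L, cfg$chrom_length > 0,
            cfg$n_ref >= 0L, cfg$n_known >= 0L, cfg$n_novel >= 0L,
            cfg$n_samples >= 1L, cfg$pool_size >= 1L,
            cfg$reads_per_carrier >= 0, cfg$read_length >= 1L,
            cfg$jitter_bp >= 1L,
            cfg$polyt_rate >= 0, cfg$polyt_rate <= 1,
            cfg$hop_rate >= 0, cfg$hop_rate <= 1,
            length(cfg$af_range) == 2L, all(cfg$af_range > 0),
            all(cfg$af_range <= 1), cfg$min_separation >= 1L)
  class(cfg) <- "sim_config"
  cfg
}

.sim_samples <- function(cfg) sprintf("S%02d", seq_len(cfg$n_samples))

.sim_manifest <- function(cfg) {
  samples <- .sim_samples(cfg)
  pool_of <- ceiling(seq_along(samples) / cfg$pool_size)
  split(samples, sprintf("P%02d", pool_of))
}

#' Generate the simulation truth set and catalogs
#'
#' Places insertions uniformly at random with at least
#' `cfg$min_separation` bp between junctions, assigns classes, strands
#' and carriers, and builds the two BED catalogs (reference-class
#' elements in the repeat-masker-style catalog, known non-reference
#' elements in the known-insertion catalog; novel insertions are in
#' neither).  Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list: `truth` (data.frame `insertion_id`, `chrom`,
#'   `junction`, `peak_strand`, `element_strand`, `class`,
#'   `allele_frequency`, `carriers` — comma-joined sample ids),
#'   `ref_features`, `known_features` (BED-style feature tables),
#'   `manifest`, `chrom_lengths`, `config`.
#' @export
make_truth <- function(cfg) {
  set.seed(cfg$seed)
  n_total <- cfg$n_ref + cfg$n_known + cfg$n_novel
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  chrom_lengths <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                                   chroms)
  margin <- cfg$element_gap + cfg$element_length + cfg$jitter_bp +
    cfg$read_length + 100L

  chrom_of <- sample(chroms, n_total, replace = TRUE)
  junction <- integer(n_total)
  for (ch in chroms) {
    idx <- which(chrom_of == ch)
    k <- length(idx)
    if (k == 0L) next
    usable <- cfg$chrom_length - 2 * margin -
      (k - 1) * cfg$min_separation
    if (usable < 0) {
      stop("chromosome too small for ", k, " insertions at ",
           cfg$min_separation, " bp separation")
    }
    u <- sort(runif(k, 0, usable))
    junction[idx] <- as.integer(floor(margin + u +
                                        (seq_len(k) - 1L) * cfg$min_separation))
  }

  cls <- sample(rep(c("reference", "known_nonref", "novel_nonref"),
                    times = c(cfg$n_ref, cfg$n_known, cfg$n_novel)))
  peak_strand <- sample(c("+", "-"), n_total, replace = TRUE)
  element_strand <- ifelse(peak_strand == "+", "-", "+")

  samples <- .sim_samples(cfg)
  af <- numeric(n_total)
  carriers <- character(n_total)
  for (i in seq_len(n_total)) {
    if (cls[i] == "reference") {
      af[i] <- 1
      carriers[i] <- paste(samples, collapse = ",")
    } else {
      af[i] <- runif(1, cfg$af_range[1], cfg$af_range[2])
      is_carrier <- rbinom(cfg$n_samples, 1L, af[i]) == 1L
      if (!any(is_carrier)) is_carrier[sample.int(cfg$n_samples, 1L)] <- TRUE
      carriers[i] <- paste(samples[is_carrier], collapse = ",")
    }
  }

  truth <- data.frame(
    insertion_id = sprintf("INS_%04d", seq_len(n_total)),
    chrom = chrom_of, junction = junction,
    peak_strand = peak_strand, element_strand = element_strand,
    class = cls, allele_frequency = af, carriers = carriers,
    stringsAsFactors = FALSE)
  truth <- truth[order(truth$chrom, truth$junction), , drop = FALSE]
  rownames(truth) <- NULL

  feat <- function(rows, source) {
    if (nrow(rows) == 0L) {
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), name = character(),
                        strand = character(), source = character(),
                        stringsAsFactors = FALSE))
    }
    plus <- rows$peak_strand == "+"
    start <- ifelse(plus, rows$junction + cfg$element_gap,
                    rows$junction - cfg$element_gap - cfg$element_length)
    data.frame(chrom = rows$chrom, start = as.integer(start),
               end = as.integer(start + cfg$element_length),
               name = rows$insertion_id, strand = rows$element_strand,
               source = source, stringsAsFactors = FALSE)
  }

  list(truth = truth,
       ref_features = feat(truth[truth$class == "reference", , drop = FALSE],
                           "repeatmasker_l1hs"),
       known_features = feat(truth[truth$class == "known_nonref", ,
                                   drop = FALSE], "known_nonref"),
       manifest = .sim_manifest(cfg),
       chrom_lengths = chrom_lengths,
       config = cfg)
}

#' Simulate junction-anchored reads from a truth set
#'
#' For each carrier x insertion, draws a Poisson number of supporting
#' reads with starts jittered within one clustering window of the
#' junction on the peak strand and MapQ from the configured rounded
#' normal.  A Bernoulli `polyt_rate` subset of reads supporting
#' *non-reference* insertions is diverted to the unaligned FASTQ with a
#' poly(T) suffix appended after a shortened genomic portion (emulating
#' reads that ran through the junction into the element's poly(A) tail
#' and failed to align).  Each aligned read is independently relabeled
#' to a uniformly chosen pool-mate with probability `hop_rate` (index
#' hopping).  Deterministic under `cfg$seed` (the generator reseeds with
#' `cfg$seed + 1` so truth and reads come from documented, separate
#' stream positions).
#'
#' @param truth_set output of [make_truth()].
#' @param cfg the same [sim_config()].
#' @return list: `reads` (aligned-read table as from [read_sam()]),
#'   `polyt` (FASTQ table of diverted reads), `polyt_truth` (where each
#'   diverted read's genomic portion truly aligns: `read_id`, `chrom`,
#'   `start`, `end`, `strand`, `mapq`, `sample`).
#' @export
simulate_reads <- function(truth_set, cfg) {
  set.seed(cfg$seed + 1L)
  truth <- truth_set$truth
  samples <- .sim_samples(cfg)
  manifest <- truth_set$manifest

  recs <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    carr <- strsplit(truth$carriers[i], ",", fixed = TRUE)[[1]]
    n_per <- rpois(length(carr), cfg$reads_per_carrier)
    n <- sum(n_per)
    if (n == 0L) next
    jitter <- sample.int(cfg$jitter_bp, n, replace = TRUE) - 1L
    if (truth$peak_strand[i] == "+") {
      start <- truth$junction[i] + jitter
      end <- start + cfg$read_length
    } else {
      end <- truth$junction[i] - jitter
      start <- end - cfg$read_length
    }
    recs[[i]] <- data.frame(
      chrom = truth$chrom[i], start = start, end = end,
      strand = truth$peak_strand[i],
      mapq = as.integer(pmin(60, pmax(0, round(rnorm(n, cfg$mapq_mean,
                                                     cfg$mapq_sd))))),
      sample = rep(carr, times = n_per),
      nonref = truth$class[i] != "reference",
      stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, recs)
  if (is.null(reads)) {
    reads <- data.frame(chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        mapq = integer(), sample = character(),
                        nonref = logical(), stringsAsFactors = FALSE)
  }
  reads$read_id <- sprintf("read%07d", seq_len(nrow(reads)))

  # divert a polyt_rate fraction of non-reference-supporting reads
  divert <- reads$nonref & runif(nrow(reads)) < cfg$polyt_rate
  diverted <- reads[divert, , drop = FALSE]
  reads <- reads[!divert, , drop = FALSE]
  reads$nonref <- NULL

  polyt <- data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE)
  polyt_truth <- diverted[, c("read_id", "chrom", "start", "end",
                              "strand", "mapq", "sample"), drop = FALSE]
  if (nrow(diverted)) {
    tail_len <- sample(15:60, nrow(diverted), replace = TRUE)
    genomic_len <- cfg$read_length - tail_len
    seqs <- vapply(seq_len(nrow(diverted)), function(j) {
      paste0(paste(sample(c("A", "C", "G"), genomic_len[j],
                          replace = TRUE), collapse = ""),
             strrep("T", tail_len[j]))
    }, character(1))
    polyt <- data.frame(read_id = diverted$read_id, sequence = seqs,
                        quality = strrep("I", cfg$read_length),
                        stringsAsFactors = FALSE)
    # where the genomic portion truly aligns after poly(T) trimming:
    # the read's 3' end (genomic-low side on '-' alignments) is cut back
    minus <- polyt_truth$strand == "-"
    polyt_truth$start[minus] <- polyt_truth$end[minus] - genomic_len[minus]
    polyt_truth$end[!minus] <- polyt_truth$start[!minus] + genomic_len[!minus]
  }
  rownames(polyt) <- rownames(polyt_truth) <- NULL

  # index hopping: relabel reads to a random same-pool sample
  if (cfg$hop_rate > 0 && nrow(reads)) {
    pool_of <- stats::setNames(rep(names(manifest),
                                   lengths(manifest)),
                               unlist(manifest, use.names = FALSE))
    hop <- which(runif(nrow(reads)) < cfg$hop_rate)
    for (j in hop) {
      mates <- setdiff(manifest[[pool_of[[reads$sample[j]]]]],
                       reads$sample[j])
      if (length(mates)) reads$sample[j] <- mates[sample.int(length(mates), 1L)]
    }
  }
  rownames(reads) <- NULL
  list(reads = reads[, c("chrom", "start", "end", "strand", "mapq",
                         "sample", "read_id"), drop = FALSE],
       polyt = polyt, polyt_truth = polyt_truth)
}

#' Generate a complete synthetic dataset
#'
#' @param cfg a [sim_config()].
#' @return the combined [make_truth()] and [simulate_reads()] output.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  truth_set <- make_truth(cfg)
  c(truth_set, simulate_reads(truth_set, cfg))
}

#' Write a simulated dataset to disk
#'
#' Emits `reads.sam` (RG-tagged), `unaligned.fastq`, `ref_l1hs.bed`,
#' `known_l1.bed`, `truth.tsv`, `polyt_truth.tsv` and `pools.yaml`
#' under `dir`.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return named vector of the paths written, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(sam = file.path(dir, "reads.sam"),
         fastq = file.path(dir, "unaligned.fastq"),
         ref_bed = file.path(dir, "ref_l1hs.bed"),
         known_bed = file.path(dir, "known_l1.bed"),
         truth = file.path(dir, "truth.tsv"),
         polyt_truth = file.path(dir, "polyt_truth.tsv"),
         pools = file.path(dir, "pools.yaml"))
  write_sim_sam(sim$reads, sim$chrom_lengths,
                .sim_samples(sim$config), p["sam"])
  write_fastq(sim$polyt, p["fastq"])
  write_bed(sim$ref_features, p["ref_bed"])
  write_bed(sim$known_features, p["known_bed"])
  write.table(sim$truth, p["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$polyt_truth, p["polyt_truth"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_pool_manifest(sim$manifest, p["pools"])
  invisible(p)
}

#' Write an aligned-read table as SAM
#'
#' Minimal valid SAM with `@SQ` lines from `chrom_lengths` and one
#' `@RG` line per sample (`ID` == `SM`); sequences are omitted (`*`),
#' which alignment consumers accept.
#'
#' @param reads aligned-read table.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param samples sample universe for the `@RG` header lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_sam <- function(reads, chrom_lengths, samples, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)),
           sprintf("@RG\tID:%s\tSM:%s", samples, samples))
  body <- if (nrow(reads)) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*\tRG:Z:%s",
            reads$read_id, ifelse(reads$strand == "-", 16L, 0L),
            reads$chrom, reads$start + 1L, reads$mapq,
            reads$end - reads$start, reads$sample)
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}
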