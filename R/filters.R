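#' Remediate index hopping between multiplexed samples
#'
#' Free adapter exchange on the flow cell mis-assigns a small fraction
#' of reads between samples sharing a lane, producing spurious low-count
#' carriers.  For each peak and each multiplex pool independently, let
#' `m` be the maximum read count among that pool's samples: samples with
#' count strictly less than `hop_fraction * m` are zeroed (counts
#' exactly at the threshold are kept).  `n_reads_total` is recomputed;
#' peaks whose every count is zeroed are dropped (their number is
#' attached as attribute `n_dropped` and messaged).  `n_unique_reads`
#' and `mean_mapq` retain their calling-stage values, as read-level
#' information is no longer available.
#'
#' The filter is idempotent: the pool maximum can never be zeroed
#' (`m < hop_fraction * m` is impossible for `hop_fraction < 1`), so the
#' threshold is unchanged on a second application.
#'
#' @param peaks a peak table.
#' @param manifest pool manifest from [read_pool_manifest()]: named
#'   list, pool id -> sample ids.
#' @param hop_fraction threshold fraction of the pool maximum
#'   (default 0.06).
#' @return the remediated peak table; `avg_reads_per_person` is reset to
#'   `NA` (recompute with [add_avg_reads_per_person()]).
#' @export
index_hop_filter <- function(peaks, manifest, hop_fraction = 0.06) {
  stopifnot(hop_fraction >= 0, hop_fraction < 1)
  .validate_manifest(manifest)
  samples <- peak_samples(peaks)
  pooled <- unlist(manifest, use.names = FALSE)
  missing <- setdiff(samples, pooled)
  if (length(missing)) {
    stop("sample(s) absent from the pool manifest: ",
         paste(missing, collapse = ", "))
  }
  if (nrow(peaks) == 0L) return(peaks)

  cnt <- as.matrix(peaks[, samples, drop = FALSE])
  for (pool in manifest) {
    cols <- intersect(pool, samples)
    if (length(cols) == 0L) next
    sub <- cnt[, cols, drop = FALSE]
    m <- apply(sub, 1L, max)
    sub[sub < hop_fraction * m] <- 0L
    cnt[, cols] <- sub
  }
  peaks[, samples] <- cnt
  peaks$n_reads_total <- as.integer(rowSums(cnt))
  peaks$avg_reads_per_person <- NA_real_
  drop <- peaks$n_reads_total == 0L
  if (any(drop)) {
    message(sum(drop), " peak(s) dropped: all sample counts zeroed by ",
            "index-hop remediation")
  }
  out <- peaks[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Carriers of each peak
#'
#' @param peaks a peak table (counts remediated).
#' @return integer vector: per peak, the number of samples with a
#'   positive read count.
#' @export
peak_carriers <- function(peaks) {
  samples <- peak_samples(peaks)
  as.integer(rowSums(peaks[, samples, drop = FALSE] > 0L))
}

#' Average sequencing reads per carrier
#'
#' Total supporting reads for the insertion divided by the number of
#' individuals reported as carriers — the depth metric used for binning
#' and the read-depth cutoff.
#'
#' @param peaks a peak table with remediated counts.
#' @return numeric vector of averages, one per peak.
#' @export
avg_reads_per_person <- function(peaks) {
  k <- peak_carriers(peaks)
  if (any(k == 0L)) {
    stop("peak with zero carriers at row ", which(k == 0L)[1],
         "; such peaks must be dropped before this step")
  }
  peaks$n_reads_total / k
}

#' @rdname avg_reads_per_person
#' @return `add_avg_reads_per_person`: the peak table with its
#'   `avg_reads_per_person` column filled in.
#' @export
add_avg_reads_per_person <- function(peaks) {
  peaks$avg_reads_per_person <- if (nrow(peaks)) avg_reads_per_person(peaks) else numeric()
  peaks
}

#' Mean-MapQ cutoff derived from reference-class peaks
#'
#' Reference-genome insertions are detected with high confidence, so the
#' distribution of their per-peak mean MapQ anchors an empirical
#' quality cutoff: mean minus `sd_mult` sample standard deviations
#' (n - 1 denominator).
#'
#' @param ref_peaks peak table rows classed `reference` (at least 2),
#'   or any peak table — non-reference rows are ignored unless none are
#'   classed.
#' @param sd_mult standard-deviation multiplier (default 2).
#' @return the cutoff value.
#' @export
derive_mapq_cutoff <- function(ref_peaks, sd_mult = 2) {
  if ("annotation_class" %in% colnames(ref_peaks) &&
      any(ref_peaks$annotation_class == "reference")) {
    ref_peaks <- ref_peaks[ref_peaks$annotation_class == "reference", ,
                           drop = FALSE]
  }
  if (nrow(ref_peaks) < 2L) {
    stop("need at least 2 reference-class peaks to derive a MapQ cutoff")
  }
  mapq_cutoff_from_stats(mean(ref_peaks$mean_mapq),
                         stats::sd(ref_peaks$mean_mapq), sd_mult)
}

#' @rdname derive_mapq_cutoff
#' @param mean_mapq,sd_mapq summary statistics of reference-peak mean
#'   MapQ values.
#' @export
mapq_cutoff_from_stats <- function(mean_mapq, sd_mapq, sd_mult = 2) {
  stopifnot(sd_mult >= 0, sd_mapq >= 0)
  mean_mapq - sd_mult * sd_mapq
}

# percentage retained, rounded to 2 decimals (half away from zero)
retention_pct <- function(n_after, n_before) {
  ifelse(n_before == 0L, NA_real_,
         round_half_away(100 * n_after / n_before, 2L))
}

#' Apply the empirical cutoffs and report retention per class
#'
#' Sequential application: first the mean-MapQ cutoff, then the average
#' reads-per-carrier cutoff on the surviving peaks.  A peak is retained
#' iff `mean_mapq >= mapq_cutoff` and `avg_reads_per_person >=
#' min_avg_reads`.  Retention percentages are relative to the pre-cutoff
#' count of each class, rounded to 2 decimals.
#'
#' @param peaks annotated, remediated peak table.
#' @param mapq_cutoff mean-MapQ threshold (e.g. from
#'   [derive_mapq_cutoff()]).
#' @param min_avg_reads reads-per-carrier threshold (default 100).
#' @return list with `peaks` (retained rows, `avg_reads_per_person`
#'   filled) and `report` (per class: `n_input`, `n_after_mapq`,
#'   `pct_after_mapq`, `n_retained`, `pct_retained`).
#' @export
apply_cutoffs <- function(peaks, mapq_cutoff, min_avg_reads = 100) {
  peaks <- add_avg_reads_per_person(peaks)
  pass_mapq <- peaks$mean_mapq >= mapq_cutoff
  pass_both <- pass_mapq & peaks$avg_reads_per_person >= min_avg_reads

  classes <- c("reference", "known_nonref", "novel_nonref")
  classes <- c(classes, setdiff(unique(peaks$annotation_class), classes))
  report <- do.call(rbind, lapply(classes, function(cl) {
    in_cl <- peaks$annotation_class == cl
    data.frame(class = cl,
               n_input = sum(in_cl),
               n_after_mapq = sum(in_cl & pass_mapq),
               pct_after_mapq = retention_pct(sum(in_cl & pass_mapq),
                                              sum(in_cl)),
               n_retained = sum(in_cl & pass_both),
               pct_retained = retention_pct(sum(in_cl & pass_both),
                                            sum(in_cl)),
               stringsAsFactors = FALSE)
  }))
  report <- report[report$n_input > 0L | report$class %in%
                     c("reference", "known_nonref", "novel_nonref"), ,
                   drop = FALSE]
  rownames(report) <- NULL
  out <- peaks[pass_both, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- peak_samples(peaks)
  list(peaks = out, report = report)
}

# round half away from zero (base round() is round-half-even)
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
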