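#' Run the full calling/annotation/filtering pipeline
#'
#' Executes the published stage order on a merged, RG-tagged SAM/BAM:
#' MapQ filtering, strand-aware peak calling, catalog annotation,
#' index-hop remediation, the mean-MapQ and reads-per-carrier cutoffs,
#' and (if a validation count table is supplied) the validation-rate
#' table, plus the genomic-distribution and carrier-histogram reports.
#' An unaligned FASTQ may additionally be poly(T)-trimmed for external
#' realignment (alignment itself is out of process; the pipeline
#' consumes alignments).
#'
#' All outputs carry `##` provenance comments: package version, a
#' configuration digest and input checksums.  Nothing is written until
#' every computing stage has completed, so a failing stage leaves no
#' partial peak table behind.
#'
#' @param sam merged SAM/BAM path.
#' @param ref_bed,known_bed catalog BED paths.
#' @param pools pool-manifest YAML path (required for index-hop
#'   remediation; `NULL` skips remediation).
#' @param out_dir output directory.
#' @param fastq optional unaligned FASTQ to poly(T)-trim.
#' @param validation optional validation-count TSV (columns `bin`,
#'   `validated`, `attempted`) to build the validation-rate table from
#'   the binned peaks.
#' @param sample optional single-sample override for files without RG
#'   tags.
#' @param window,min_mapq peak-calling parameters.
#' @param downstream_bp annotation extension.
#' @param hop_fraction index-hop threshold.
#' @param mapq_cutoff mean-MapQ cutoff; `NULL` derives it from the
#'   reference-class peaks (mean minus `mapq_sd_mult` SD).
#' @param mapq_sd_mult SD multiplier for the derived cutoff.
#' @param min_avg_reads reads-per-carrier cutoff.
#' @param polyt poly(T) trimming configuration ([polyt_config()]).
#' @return invisibly, a list: `peaks` (retained), `report`,
#'   `mapq_cutoff`, `n_peaks_called`, and the output paths.
#' @export
run_pipeline <- function(sam, ref_bed, known_bed, pools = NULL,
                         out_dir = ".", fastq = NULL, validation = NULL,
                         sample = NULL, window = 150, min_mapq = 30,
                         downstream_bp = 500, hop_fraction = 0.06,
                         mapq_cutoff = NULL, mapq_sd_mult = 2,
                         min_avg_reads = 100,
                         polyt = polyt_config()) {
  inputs <- c(sam = sam, ref_bed = ref_bed, known_bed = known_bed,
              pools = pools, fastq = fastq, validation = validation)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg <- list(window = window, min_mapq = min_mapq,
              downstream_bp = downstream_bp, hop_fraction = hop_fraction,
              mapq_cutoff = mapq_cutoff, mapq_sd_mult = mapq_sd_mult,
              min_avg_reads = min_avg_reads, polyt = unclass(polyt))
  prov <- .provenance(cfg, inputs)

  if (!is.null(fastq)) {
    trimmed <- file.path(out_dir, "trimmed.fastq")
    trim_polyt_fastq(fastq, trimmed, polyt)
  }

  reads <- read_sam(sam, sample = sample)
  reads <- filter_mapq(reads, min_mapq)
  peaks <- call_peaks(reads, window = window)
  n_called <- nrow(peaks)
  peaks <- annotate_peaks(peaks, read_bed(ref_bed, "repeatmasker_l1hs"),
                          read_bed(known_bed, "known_nonref"),
                          downstream_bp = downstream_bp)
  if (!is.null(pools)) {
    peaks <- index_hop_filter(peaks, read_pool_manifest(pools),
                              hop_fraction)
  }
  if (is.null(mapq_cutoff)) {
    mapq_cutoff <- derive_mapq_cutoff(peaks, mapq_sd_mult)
  }
  res <- apply_cutoffs(peaks, mapq_cutoff, min_avg_reads)

  paths <- c(peaks = file.path(out_dir, "peaks.filtered.tsv"),
             report = file.path(out_dir, "retention_report.tsv"),
             distribution = file.path(out_dir, "genomic_distribution.tsv"),
             carriers = file.path(out_dir, "carrier_histogram.tsv"))
  write_peaks_tsv(res$peaks, paths["peaks"], provenance = prov)
  .write_report_tsv(res$report, paths["report"], prov)
  .write_report_tsv(genomic_distribution(res$peaks),
                    paths["distribution"], prov)
  .write_report_tsv(carrier_histogram(res$peaks), paths["carriers"], prov)

  out <- list(peaks = res$peaks, report = res$report,
              mapq_cutoff = mapq_cutoff, n_peaks_called = n_called,
              paths = paths)
  if (!is.null(validation)) {
    val <- read_validation_tsv(validation)
    det <- bin_peaks(res$peaks)
    tab <- validation_table(merge(val, det, by = "bin", sort = FALSE),
                            deepest_first = FALSE)
    paths["validation"] <- file.path(out_dir, "validation_table.tsv")
    .write_report_tsv(tab, paths["validation"], prov)
    out$validation <- tab
    out$paths <- paths
  }
  invisible(out)
}

# provenance comment lines: version, config digest, input checksums
.provenance <- function(cfg, inputs) {
  tmp <- tempfile()
  writeLines(yaml::as.yaml(cfg), tmp)
  on.exit(unlink(tmp))
  c(sprintf("rebelkit %s",
            as.character(utils::packageVersion("rebelkit"))),
    sprintf("config md5=%s", unname(tools::md5sum(tmp))),
    sprintf("input %s md5=%s", names(inputs),
            unname(tools::md5sum(unname(inputs)))))
}

.write_report_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(provenance)) writeLines(paste0("## ", provenance), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
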