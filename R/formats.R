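#' Read aligned reads from a SAM or BAM file
#'
#' Parses a coordinate-addressable alignment file into the package's
#' aligned-read table.  SAM 1-based positions are converted to 0-based
#' half-open intervals (`start = POS - 1`, `end = start +` reference bases
#' consumed by the CIGAR).  Unmapped, secondary and supplementary records
#' are skipped: the pipeline keeps one alignment per read and relies on
#' MapQ filtering downstream.  Sample identity is taken from the record's
#' read-group (`RG`) tag, resolved to a sample name through the `@RG`
#' header lines (`SM` field, falling back to the `ID` field).
#'
#' @param path path to a SAM (text) or BAM file.
#' @param sample optional single sample name overriding read-group
#'   resolution, for unmerged per-sample files without `RG` tags.
#' @return a `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"`/`"-"`), `mapq`, `sample`, `read_id`.
#' @export
read_sam <- function(path, sample = NULL) {
  stopifnot(file.exists(path))
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "strand"),
    tag = "RG")
  x <- Rsamtools::scanBam(bam, param = param)[[1]]

  flag <- x$flag
  keep <- !bitwAnd(flag, 4L) & !bitwAnd(flag, 256L) & !bitwAnd(flag, 2048L)
  if (!any(keep)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      mapq = integer(), sample = character(),
                      read_id = character(), stringsAsFactors = FALSE))
  }

  rg <- x$tag$RG
  if (is.null(rg)) rg <- rep(NA_character_, length(flag))
  if (is.null(sample)) {
    rg_map <- .sam_rg_map(bam)
    missing_rg <- keep & is.na(rg)
    if (any(missing_rg)) {
      stop("record '", x$qname[which(missing_rg)[1]],
           "' has no RG tag and no --sample override was given")
    }
    unknown <- keep & !(rg %in% names(rg_map))
    if (any(unknown)) {
      stop("record '", x$qname[which(unknown)[1]],
           "' carries RG '", rg[which(unknown)[1]],
           "' absent from the SAM header")
    }
    smp <- unname(rg_map[rg])
  } else {
    stopifnot(is.character(sample), length(sample) == 1L)
    smp <- rep(sample, length(flag))
  }

  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(x$cigar[keep])
  start0 <- x$pos[keep] - 1L
  data.frame(
    chrom   = as.character(x$rname[keep]),
    start   = start0,
    end     = start0 + width,
    strand  = ifelse(bitwAnd(flag[keep], 16L) > 0L, "-", "+"),
    mapq    = as.integer(x$mapq[keep]),
    sample  = smp[keep],
    read_id = x$qname[keep],
    stringsAsFactors = FALSE
  )
}

# @RG header lines -> named vector ID -> sample name (SM, else ID)
.sam_rg_map <- function(bam) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$text
  rg_lines <- hdr[names(hdr) == "@RG"]
  if (length(rg_lines) == 0L) return(character())
  ids <- vapply(rg_lines, function(f) {
    id <- sub("^ID:", "", grep("^ID:", f, value = TRUE)[1])
    id
  }, character(1), USE.NAMES = FALSE)
  sms <- vapply(rg_lines, function(f) {
    sm <- grep("^SM:", f, value = TRUE)
    if (length(sm)) sub("^SM:", "", sm[1]) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  sms[is.na(sms)] <- ids[is.na(sms)]
  stats::setNames(sms, ids)
}

#' Read an annotation catalog in BED format
#'
#' BED intervals are 0-based half-open and pass through unchanged.
#' BED3 files get strand `"."`; a missing name becomes `"."`.
#'
#' @param path path to a BED3+ file.
#' @param source short tag recording which catalog this is, e.g.
#'   `"repeatmasker_l1hs"` or `"known_nonref"`.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `strand`, `source`.
#' @export
read_bed <- function(path, source = NA_character_) {
  stopifnot(file.exists(path))
  raw <- tryCatch(
    read.delim(path, header = FALSE, comment.char = "#",
               stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      strand = character(), source = character(),
                      stringsAsFactors = FALSE))
  }
  if (ncol(raw) < 3L) stop("BED file must have at least 3 columns: ", path)
  start <- as.integer(raw[[2]]); end <- as.integer(raw[[3]])
  bad <- which(!(start < end))
  if (length(bad)) {
    stop("BED interval with start >= end at line ", bad[1], " of ", path)
  }
  name <- if (ncol(raw) >= 4L) as.character(raw[[4]]) else rep(".", nrow(raw))
  name[is.na(name) | name == ""] <- "."
  strand <- if (ncol(raw) >= 6L) as.character(raw[[6]]) else rep(".", nrow(raw))
  strand[!strand %in% c("+", "-")] <- "."
  data.frame(chrom = as.character(raw[[1]]), start = start, end = end,
             name = name, strand = strand,
             source = rep(source, nrow(raw)), stringsAsFactors = FALSE)
}

#' Write features to a BED6 file
#'
#' @param features data.frame as returned by [read_bed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(features, path) {
  df <- data.frame(features$chrom, features$start, features$end,
                   features$name, 0L, features$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write FASTQ
#'
#' 4-line FASTQ records, round-trip safe: `read_fastq(write_fastq(x))`
#' reproduces the records exactly (ids, sequences incl. `N`, qualities).
#'
#' @param path file path.
#' @return `read_fastq`: a `data.frame` with columns `read_id`,
#'   `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) {
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id  = names(x),
             sequence = as.character(x),
             quality  = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fastq
#' @param reads data.frame with columns `read_id`, `sequence`, `quality`.
#' @export
write_fastq <- function(reads, path) {
  bad <- nchar(reads$sequence) != nchar(reads$quality)
  if (any(bad)) {
    stop("sequence/quality length mismatch for read '",
         reads$read_id[which(bad)[1]], "'")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                      reads$quality), con, sep = "\n")
  }
  invisible(path)
}

# fixed (non-sample) columns of a peak table, in on-disk order
.peak_fixed_cols <- c("chrom", "start", "end", "strand", "n_reads_total",
                      "n_unique_reads", "mean_mapq", "avg_reads_per_person",
                      "annotation_class", "annotation_name")

#' Peak-table TSV input/output
#'
#' Tab-delimited UTF-8 with a single `#`-prefixed header line.  Fixed
#' columns come first, then one read-count column per sample; the reader
#' recovers the sample set from the header.  Round trip is lossless
#' (`mean_mapq` is written with full precision).
#'
#' Lines beginning `##` before the column header are provenance
#' comments (tool version, configuration hash, input checksums) and are
#' skipped by the reader.
#'
#' @param peaks a peak table as produced by [call_peaks()].
#' @param path file path.
#' @param provenance optional character vector written as `##` comment
#'   lines before the header.
#' @return `read_peaks_tsv`: the peak table; `write_peaks_tsv`: `path`,
#'   invisibly.
#' @export
write_peaks_tsv <- function(peaks, path, provenance = NULL) {
  samples <- peak_samples(peaks)
  cols <- c(.peak_fixed_cols, samples)
  out <- peaks[, cols, drop = FALSE]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(provenance)) writeLines(paste0("## ", provenance), con)
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  if (nrow(out)) {
    num <- vapply(out, is.double, logical(1))
    for (j in which(num)) out[[j]] <- format(out[[j]], digits = 15)
    write.table(out, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' @rdname write_peaks_tsv
#' @export
read_peaks_tsv <- function(path) {
  stopifnot(file.exists(path))
  top <- readLines(path, n = 100L)
  skip <- 0L
  while (skip < length(top) && startsWith(top[skip + 1L], "##")) {
    skip <- skip + 1L
  }
  header <- top[skip + 1L]
  if (is.na(header) || !startsWith(header, "#")) {
    stop("peak TSV must have a '#'-prefixed column header")
  }
  skip <- skip + 1L
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  samples <- setdiff(cols, .peak_fixed_cols)
  if (length(readLines(path)) <= skip) {
    body <- as.data.frame(stats::setNames(
      rep(list(character()), length(cols)), cols), check.names = FALSE)
  } else {
    body <- read.delim(path, header = FALSE, skip = skip, col.names = cols,
                       stringsAsFactors = FALSE, check.names = FALSE,
                       colClasses = "character")
  }
  for (cc in c("start", "end", "n_reads_total", "n_unique_reads", samples)) {
    body[[cc]] <- as.integer(body[[cc]])
  }
  for (cc in c("mean_mapq", "avg_reads_per_person")) {
    body[[cc]] <- as.numeric(body[[cc]])
  }
  attr(body, "samples") <- samples
  body
}

#' Sample columns of a peak table
#'
#' @param peaks a peak table.
#' @return character vector of sample ids (the per-sample count columns).
#' @export
peak_samples <- function(peaks) {
  s <- attr(peaks, "samples")
  if (is.null(s)) s <- setdiff(colnames(peaks), .peak_fixed_cols)
  s
}

#' Read / write a multiplex-pool manifest
#'
#' A YAML mapping from pool id to the ordered list of sample ids
#' multiplexed in that pool (nominally six per pool).  Each sample must
#' appear in exactly one pool.
#'
#' @param path YAML file path.
#' @return `read_pool_manifest`: a named list, pool id -> character
#'   vector of sample ids.
#' @export
read_pool_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  m <- lapply(m, as.character)
  .validate_manifest(m)
  m
}

#' @rdname read_pool_manifest
#' @param manifest named list, pool id -> sample ids.
#' @export
write_pool_manifest <- function(manifest, path) {
  .validate_manifest(manifest)
  yaml::write_yaml(manifest, path)
  invisible(path)
}

.validate_manifest <- function(manifest) {
  all_samples <- unlist(manifest, use.names = FALSE)
  dup <- unique(all_samples[duplicated(all_samples)])
  if (length(dup)) {
    stop("sample(s) in more than one pool: ", paste(dup, collapse = ", "))
  }
  invisible(manifest)
}
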