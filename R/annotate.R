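#' Extend peak intervals downstream with respect to strand
#'
#' A `+` peak `[s, e)` becomes `[s, e + downstream_bp)`; a `-` peak
#' becomes `[max(0, s - downstream_bp), e)`.
#'
#' @param peaks a peak table.
#' @param downstream_bp extension distance in bp.
#' @return data.frame with columns `ext_start`, `ext_end` (0-based
#'   half-open), one row per peak.
#' @export
extend_downstream <- function(peaks, downstream_bp = 500) {
  stopifnot(downstream_bp >= 0)
  plus <- peaks$strand == "+"
  data.frame(
    ext_start = ifelse(plus, peaks$start,
                       pmax(0L, peaks$start - as.integer(downstream_bp))),
    ext_end   = ifelse(plus, peaks$end + as.integer(downstream_bp),
                       peaks$end)
  )
}

#' Classify peaks against reference and known-insertion catalogs
#'
#' Each peak's interval is extended `downstream_bp` bp downstream with
#' respect to its strand; if the extended interval overlaps (half-open
#' intersection non-empty) any feature of the reference L1Hs catalog the
#' peak is classed `reference`; otherwise if it overlaps any known
#' non-reference insertion it is classed `known_nonref`; otherwise
#' `novel_nonref`.  Extension by `downstream_bp` makes a feature whose
#' nearest base lies exactly `downstream_bp` bp beyond the peak edge
#' overlap after extension (gap of `downstream_bp - 1` in half-open
#' arithmetic), so "within `downstream_bp` bp downstream" is inclusive.
#'
#' Feature strand is ignored by default: the junction geometry places
#' supporting reads antisense to the element, so peak strand and element
#' strand are systematically opposite and no strand match is required.
#' `require_feature_strand_match = TRUE` restricts hits to features on
#' the same strand as the peak (features with strand `"."` always
#' match).
#'
#' Among several overlapping features of the winning catalog, the
#' annotation name is the feature nearest the peak's downstream edge
#' (distance 0 if it overlaps the edge), ties broken by lexicographic
#' name.
#'
#' @param peaks a peak table.
#' @param ref_features reference (repeat-masker-style) catalog from
#'   [read_bed()].
#' @param known_features known non-reference insertion catalog.
#' @param downstream_bp extension distance (default 500).
#' @param require_feature_strand_match see above (default `FALSE`).
#' @return the peak table with `annotation_class` and `annotation_name`
#'   set; every peak gets exactly one class.
#' @export
annotate_peaks <- function(peaks, ref_features, known_features,
                           downstream_bp = 500,
                           require_feature_strand_match = FALSE) {
  if (nrow(peaks) == 0L) return(peaks)
  ext <- extend_downstream(peaks, downstream_bp)
  # downstream edge: the peak boundary the extension grows from
  edge <- ifelse(peaks$strand == "+", peaks$end, peaks$start)

  hit_ref <- .best_feature(peaks, ext, edge, ref_features,
                           require_feature_strand_match)
  hit_known <- .best_feature(peaks, ext, edge, known_features,
                             require_feature_strand_match)

  cls <- ifelse(!is.na(hit_ref), "reference",
                ifelse(!is.na(hit_known), "known_nonref", "novel_nonref"))
  nm <- ifelse(!is.na(hit_ref), hit_ref, hit_known)
  peaks$annotation_class <- cls
  peaks$annotation_name <- nm
  peaks
}

# per peak, name of the nearest overlapping feature or NA
.best_feature <- function(peaks, ext, edge, features, strand_match) {
  if (is.null(features) || nrow(features) == 0L) {
    return(rep(NA_character_, nrow(peaks)))
  }
  pk <- GenomicRanges::GRanges(
    peaks$chrom,
    IRanges::IRanges(ext$ext_start + 1L, ext$ext_end),
    strand = peaks$strand)
  ft <- GenomicRanges::GRanges(
    features$chrom,
    IRanges::IRanges(features$start + 1L, features$end),
    strand = ifelse(features$strand %in% c("+", "-"), features$strand, "*"))
  ov <- GenomicRanges::findOverlaps(pk, ft, ignore.strand = !strand_match)
  out <- rep(NA_character_, nrow(peaks))
  if (length(ov) == 0L) return(out)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  # gap from the downstream edge coordinate to the feature (0 if spanning)
  d <- pmax(features$start[sh] - edge[qh], edge[qh] - features$end[sh], 0L)
  nm <- features$name[sh]
  o <- order(qh, d, nm)
  first <- !duplicated(qh[o])
  out[qh[o][first]] <- nm[o][first]
  out
}
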