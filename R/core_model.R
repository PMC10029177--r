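#' @keywords internal
"_PACKAGE"

## Coordinate convention: 0-based half-open internally (BED semantics), so
## length == end - start exactly. 1-based inclusive sources (GFF3-like CNV
## tables) are converted at parse time with start - 1.

#' Pathogenicity label levels, benign to pathogenic
#'
#' The ACMG five-tier clinical-significance scale in increasing order of
#' pathogenicity, as used throughout for label encoding and prediction
#' tie-breaking.
#' @export
PATHOGENICITY_LEVELS <- c("benign", "likely_benign", "uncertain_significance",
                          "likely_pathogenic", "pathogenic")

#' Normalize a chromosome name
#'
#' Strips a leading "chr" prefix so that resources mixing "chr1"/"1"
#' conventions compare equal.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector of normalized names.
#' @export
norm_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

#' Construct a validated genomic-interval data frame
#'
#' Intervals are 0-based half-open. Empty intervals (end <= start) and
#' negative starts are rejected.
#'
#' @param chrom,start,end vectors (recycled to common length).
#' @return data.frame with columns chrom, start, end.
#' @export
genomic_interval <- function(chrom, start, end) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(norm_chrom(chrom), n)
  start <- rep_len(as.numeric(start), n)
  end <- rep_len(as.numeric(end), n)
  if (anyNA(chrom) || anyNA(start) || anyNA(end))
    stop("genomic_interval: NA coordinates are not allowed")
  if (any(start < 0))
    stop("genomic_interval: start must be >= 0")
  if (any(end <= start))
    stop("genomic_interval: empty or inverted interval (end must be > start)")
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Interval length in base pairs
#'
#' @param iv data.frame with chrom/start/end columns (0-based half-open).
#' @return numeric vector of span in bp (end - start).
#' @export
interval_length <- function(iv) {
  stopifnot(all(c("start", "end") %in% names(iv)))
  if (any(iv$end <= iv$start)) stop("interval_length: empty interval")
  iv$end - iv$start
}

#' Overlap between two intervals in base pairs
#'
#' Vectorized over rows; recycles the shorter input. Returns 0 for
#' different chromosomes or disjoint intervals (half-open adjacency is
#' disjoint).
#'
#' @param a,b interval data.frames (chrom/start/end).
#' @return numeric vector of shared base pairs.
#' @export
overlap_bp <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  ov[norm_chrom(a$chrom[ai]) != norm_chrom(b$chrom[bi])] <- 0
  pmax(ov, 0)
}

#' Reciprocal overlap of two intervals
#'
#' The overlap length divided by each interval's own length; the pair's
#' reciprocal overlap is the minimum of the two fractions. Symmetric, in
#' [0, 1], and 1 only for identical intervals on the same chromosome.
#' Cross-chromosome pairs score 0 (not an error).
#'
#' @param a,b interval data.frames (chrom/start/end).
#' @return numeric vector of fractions in [0, 1].
#' @export
reciprocal_overlap <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  ov <- overlap_bp(a, b)
  pmin(ov / (a$end[ai] - a$start[ai]), ov / (b$end[bi] - b$start[bi]))
}

## -- CNV records --------------------------------------------------------

normalize_cnv_type <- function(x) {
  x <- tolower(as.character(x))
  map <- c("loss" = "loss", "gain" = "gain",
           "deletion" = "loss", "duplication" = "gain",
           "del" = "loss", "dup" = "gain",
           "copy number loss" = "loss", "copy number gain" = "gain",
           "copy_number_loss" = "loss", "copy_number_gain" = "gain")
  out <- unname(map[x])
  out
}

normalize_label <- function(x) {
  x <- tolower(gsub("[ /]+", "_", trimws(as.character(x))))
  map <- c("benign" = "benign", "likely_benign" = "likely_benign",
           "uncertain_significance" = "uncertain_significance",
           "vus" = "uncertain_significance",
           "likely_pathogenic" = "likely_pathogenic",
           "pathogenic" = "pathogenic",
           "pathogenic_likely_pathogenic" = "pathogenic",
           "unknown" = "unknown")
  out <- unname(map[x])
  out[is.na(out)] <- "unknown"
  out
}

#' Construct a validated CNV record set
#'
#' A CNV record is a genomic interval plus CNV type (loss/gain), a five-tier
#' pathogenicity label (or "unknown"), a source-database identifier and a
#' record id unique within the set. Deletion/duplication synonyms are
#' normalized to loss/gain.
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param cnv_type "loss"/"gain" (synonyms deletion/DEL, duplication/DUP
#'   accepted).
#' @param label five-tier label, "unknown" if unlabelled.
#' @param source source-database name.
#' @param record_id unique identifiers; generated if missing.
#' @return data.frame of class \code{cnv_records}.
#' @export
cnv_records <- function(chrom, start, end, cnv_type,
                        label = "unknown", source = "unknown",
                        record_id = NULL) {
  iv <- genomic_interval(chrom, start, end)
  n <- nrow(iv)
  cnv_type <- normalize_cnv_type(rep_len(cnv_type, n))
  if (anyNA(cnv_type))
    stop("cnv_records: cnv_type must normalize to 'loss' or 'gain'")
  label <- normalize_label(rep_len(label, n))
  if (is.null(record_id)) record_id <- sprintf("cnv%06d", seq_len(n))
  record_id <- as.character(rep_len(record_id, n))
  if (anyDuplicated(record_id))
    stop("cnv_records: record_id must be unique within a record set")
  out <- cbind(iv, data.frame(cnv_type = cnv_type, label = label,
                              source = rep_len(as.character(source), n),
                              record_id = record_id,
                              stringsAsFactors = FALSE))
  class(out) <- c("cnv_records", "data.frame")
  out
}

#' @export
print.cnv_records <- function(x, ...) {
  cat(sprintf("CNV record set: %d records (%d loss, %d gain)\n",
              nrow(x), sum(x$cnv_type == "loss"), sum(x$cnv_type == "gain")))
  NextMethod()
}

as_granges_ivs <- function(df) {
  GenomicRanges::GRanges(
    seqnames = norm_chrom(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
}
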