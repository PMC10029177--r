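## Multi-source CNV curation: per-database inclusion filters, dosage-score
## label mapping, non-redundant merge and validation-set deduplication.
## Length bounds and the 70%/90% reciprocal-overlap rules follow the
## training-corpus construction rules; "conflicting pathogenicity" is one
## member in {benign, likely_benign} versus one in {pathogenic,
## likely_pathogenic} (uncertain significance conflicts with neither).

MIN_CNV_LENGTH <- 50
MAX_CNV_LENGTH <- 5e6
CONFLICT_RO <- 0.70
DEDUP_RO <- 0.90

CLINVAR_REVIEW_STATUS <- c(
  "criteria provided, multiple submitters, no conflicts",
  "criteria provided, single submitter",
  "reviewed by expert panel",
  "practice guideline")

benign_side <- function(label) label %in% c("benign", "likely_benign")
patho_side <- function(label) label %in% c("pathogenic", "likely_pathogenic")

new_curation_report <- function(source, n_in, rule_counts, n_retained) {
  out <- list(source = source, n_in = n_in, excluded_by = rule_counts,
              n_retained = n_retained)
  stopifnot(n_in == n_retained + sum(unlist(rule_counts)))
  class(out) <- "curation_report"
  out
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("Curation report [%s]: %d in, %d retained\n",
              x$source, x$n_in, x$n_retained))
  for (rule in names(x$excluded_by))
    cat(sprintf("  - excluded by %s: %d\n", rule, x$excluded_by[[rule]]))
  invisible(x)
}

## Ordered named list of predicates per source; a row is excluded by the
## first rule it fails so that counts conserve exactly.
source_predicates <- function(records, source) {
  switch(source,
    clinvar = list(
      labelled_five_tier = records$label %in% PATHOGENICITY_LEVELS,
      review_status = !is.na(records$review_status) &
        records$review_status %in% CLINVAR_REVIEW_STATUS),
    dbvar = list(
      pathogenic_label = records$label %in% c("pathogenic", "likely_pathogenic")),
    dgv = list(
      sample_size = !is.na(records$sample_size) & records$sample_size >= 2000),
    decipher = list(
      observations = !is.na(records$observations) & records$observations > 0,
      frequency = !is.na(records$frequency) & records$frequency > 0.01),
    gnomad = list(
      filter_pass = !is.na(records$FILTER) & records$FILTER == "PASS",
      allele_frequency = !is.na(records$AF) & records$AF > 0.01,
      allele_number = !is.na(records$AN) & records$AN > 2000),
    stop("unknown curation source: ", source))
}

#' Apply a source database's inclusion filter and label map
#'
#' Retains exactly the rows passing every predicate for that source:
#' ClinVar needs a five-tier label and an accepted review status; dbVar
#' keeps pathogenic/likely-pathogenic records; DGV keeps records with at
#' least 2000 samples tested; DECIPHER needs observations > 0 and
#' population frequency > 1\%; gnomAD needs FILTER PASS, AF > 1\% and
#' AN > 2000. DGV/DECIPHER/gnomAD survivors are labelled benign. ClinGen
#' dosage regions map haploinsufficiency/triplosensitivity score 3 to a
#' pathogenic CNV of the corresponding type (loss for HI, gain for TS) and
#' score 40 to a benign CNV; other scores are excluded.
#'
#' @param records \code{cnv_records} parsed with the matching dialect.
#' @param source one of clinvar, dbvar, clingen_region, dgv, decipher, gnomad.
#' @return list with \code{records} (retained, labelled) and \code{report}
#'   (a \code{curation_report}).
#' @export
apply_source_filter <- function(records, source) {
  n_in <- nrow(records)
  if (source == "clingen_region") {
    emitted <- list()
    for (side in c("hi", "ts")) {
      sc <- as.character(records[[paste0(side, "_score")]])
      type <- if (side == "hi") "loss" else "gain"
      for (code in c("3", "40")) {
        sel <- !is.na(sc) & sc == code
        if (!any(sel)) next
        sub <- records[sel, , drop = FALSE]
        sub$cnv_type <- type
        sub$label <- if (code == "3") "pathogenic" else "benign"
        sub$record_id <- paste0(sub$record_id, ":", type)
        emitted[[length(emitted) + 1]] <- sub
      }
    }
    retained <- if (length(emitted)) do.call(rbind, emitted) else records[0, ]
    hi <- as.character(records$hi_score); ts <- as.character(records$ts_score)
    qualifies <- (!is.na(hi) & hi %in% c("3", "40")) |
                 (!is.na(ts) & ts %in% c("3", "40"))
    report <- new_curation_report(
      source, n_in, list(no_dosage_call = sum(!qualifies)), sum(qualifies))
    # retained may exceed qualifying regions (a region can emit loss and gain)
    class(retained) <- c("cnv_records", "data.frame")
    return(list(records = retained, report = report))
  }
  preds <- source_predicates(records, source)
  keep <- rep(TRUE, n_in)
  rule_counts <- list()
  for (rule in names(preds)) {
    fails_here <- keep & !preds[[rule]]
    rule_counts[[rule]] <- sum(fails_here)
    keep <- keep & preds[[rule]]
  }
  retained <- records[keep, , drop = FALSE]
  if (source %in% c("dgv", "decipher", "gnomad") && nrow(retained))
    retained$label <- "benign"
  report <- new_curation_report(source, n_in, rule_counts, nrow(retained))
  list(records = retained, report = report)
}

## All same-type pairs with reciprocal overlap >= threshold, as index pairs
## into `records`. Decided over the given set once (no cascading).
ro_pairs <- function(records, threshold) {
  if (nrow(records) < 2)
    return(data.frame(i = integer(), j = integer(), ro = numeric()))
  gr <- as_granges_ivs(records)
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  sel <- i < j & records$cnv_type[i] == records$cnv_type[j]
  i <- i[sel]; j <- j[sel]
  if (!length(i)) return(data.frame(i = integer(), j = integer(), ro = numeric()))
  ro <- reciprocal_overlap(records[i, c("chrom", "start", "end")],
                           records[j, c("chrom", "start", "end")])
  sel <- ro >= threshold
  data.frame(i = i[sel], j = j[sel], ro = ro[sel])
}

#' Merge per-source CNV sets into a non-redundant labelled corpus
#'
#' Applies, in order: (1) length filter, retaining spans in [50, 5e6] bp;
#' (2) removal of both members of every same-type pair with reciprocal
#' overlap >= 70\% and conflicting pathogenicity (benign-side vs
#' pathogenic-side label), decided over the post-length set in one pass;
#' (3) removal of identical-coordinate same-type CNVs carrying more than
#' one distinct label. Record ids are prefixed with their source to stay
#' unique across databases.
#'
#' @param record_sets list of labelled \code{cnv_records} (one per source).
#' @return list with \code{records} (merged, non-redundant) and
#'   \code{report}.
#' @export
merge_nonredundant <- function(record_sets) {
  if (inherits(record_sets, "cnv_records")) record_sets <- list(record_sets)
  cols <- c("chrom", "start", "end", "cnv_type", "label", "source", "record_id")
  merged <- do.call(rbind, lapply(record_sets, function(r)
    as.data.frame(r)[, cols, drop = FALSE]))
  n_in <- nrow(merged)
  merged$record_id <- paste0(merged$source, ":", merged$record_id)
  if (anyDuplicated(merged$record_id))
    stop("merge_nonredundant: duplicate record ids after source prefixing")
  # deterministic base order regardless of input order
  merged <- merged[order(merged$chrom, merged$start, merged$end,
                         merged$cnv_type, merged$record_id), , drop = FALSE]

  len <- merged$end - merged$start
  keep_len <- len >= MIN_CNV_LENGTH & len <= MAX_CNV_LENGTH
  n_length <- sum(!keep_len)
  merged <- merged[keep_len, , drop = FALSE]

  pairs <- ro_pairs(merged, CONFLICT_RO)
  conflict <- (benign_side(merged$label[pairs$i]) & patho_side(merged$label[pairs$j])) |
              (patho_side(merged$label[pairs$i]) & benign_side(merged$label[pairs$j]))
  drop_idx <- unique(c(pairs$i[conflict], pairs$j[conflict]))
  n_conflict <- length(drop_idx)
  if (n_conflict) merged <- merged[-drop_idx, , drop = FALSE]

  key <- paste(merged$chrom, merged$start, merged$end, merged$cnv_type)
  n_labels <- tapply(merged$label, key, function(l) length(unique(l)))
  multi <- names(n_labels)[n_labels > 1]
  drop_multi <- key %in% multi
  n_multi <- sum(drop_multi)
  merged <- merged[!drop_multi, , drop = FALSE]

  rownames(merged) <- NULL
  class(merged) <- c("cnv_records", "data.frame")
  report <- new_curation_report(
    "merge", n_in,
    list(length_filter = n_length, conflicting_70pct = n_conflict,
         multiple_significance = n_multi),
    nrow(merged))
  list(records = merged, report = report)
}

#' Deduplicate a validation CNV set
#'
#' Applies, in order: the 70\% conflicting-pathogenicity rule (both members
#' of an offending pair removed); then, for every same-type pair with
#' reciprocal overlap >= 90\%, removal of the longer member (keep the
#' shorter; equal lengths keep the lexicographically smaller record_id);
#' then the [50, 5e6] bp length filter. Pair decisions are made over each
#' stage's input set in a single pass.
#'
#' @param records labelled \code{cnv_records}.
#' @return list with \code{records} (retained) and \code{report}.
#' @export
dedup_validation <- function(records) {
  n_in <- nrow(records)
  recs <- as.data.frame(records)
  recs <- recs[order(recs$chrom, recs$start, recs$end, recs$record_id), ,
               drop = FALSE]

  pairs <- ro_pairs(recs, CONFLICT_RO)
  conflict <- (benign_side(recs$label[pairs$i]) & patho_side(recs$label[pairs$j])) |
              (patho_side(recs$label[pairs$i]) & benign_side(recs$label[pairs$j]))
  drop_idx <- unique(c(pairs$i[conflict], pairs$j[conflict]))
  n_conflict <- length(drop_idx)
  if (n_conflict) recs <- recs[-drop_idx, , drop = FALSE]

  pairs <- ro_pairs(recs, DEDUP_RO)
  len <- recs$end - recs$start
  drop_longer <- integer()
  if (nrow(pairs)) {
    li <- len[pairs$i]; lj <- len[pairs$j]
    loser <- ifelse(li < lj, pairs$j,
             ifelse(lj < li, pairs$i,
                    ifelse(recs$record_id[pairs$i] < recs$record_id[pairs$j],
                           pairs$j, pairs$i)))
    drop_longer <- unique(loser)
  }
  n_dedup <- length(drop_longer)
  if (n_dedup) recs <- recs[-drop_longer, , drop = FALSE]

  len <- recs$end - recs$start
  keep_len <- len >= MIN_CNV_LENGTH & len <= MAX_CNV_LENGTH
  n_length <- sum(!keep_len)
  recs <- recs[keep_len, , drop = FALSE]

  rownames(recs) <- NULL
  class(recs) <- c("cnv_records", "data.frame")
  report <- new_curation_report(
    "dedup_validation", n_in,
    list(conflicting_70pct = n_conflict, longer_of_90pct_pair = n_dedup,
         length_filter = n_length),
    nrow(recs))
  list(records = recs, report = report)
}
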