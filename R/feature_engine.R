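## Direction-aware feature annotation: one numeric vector per CNV, computed
## from a ResourceBundle under a FeatureRegistry. Overlap queries go through
## GenomicRanges::findOverlaps; aggregation semantics (max for
## higher-is-worse scores, min for lower-is-worse, mean for direction-less,
## count for attribute features) are declared per feature in the registry.

#' Construct a feature matrix
#' @param registry the \code{feature_registry} defining column order.
#' @param values numeric matrix, rows = CNVs (rownames = record ids),
#'   columns = registry features; NA marks missing (not yet imputed).
#' @param medians named numeric vector of fitted imputation medians, or
#'   NULL before fitting.
#' @return list of class \code{cnv_feature_matrix}.
#' @export
new_feature_matrix <- function(registry, values, medians = NULL) {
  stopifnot(inherits(registry, "feature_registry"),
            is.matrix(values), ncol(values) == nrow(registry))
  colnames(values) <- registry$name
  out <- list(registry = registry, values = values,
              missing_mask = is.na(values), medians = medians)
  class(out) <- "cnv_feature_matrix"
  out
}

#' @export
print.cnv_feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d CNVs x %d features (%d missing cells%s)\n",
              nrow(x$values), ncol(x$values), sum(x$missing_mask),
              if (is.null(x$medians)) "" else ", imputation fitted"))
  invisible(x)
}

#' Aggregate score values by direction-aware method
#'
#' An empty input yields missing (NA), never silently 0: a CNV overlapping
#' no scored record is distinct from one overlapping a record scored 0, and
#' is filled later by median imputation.
#'
#' @param values numeric vector (finite; may be empty).
#' @param method "max", "min" or "mean".
#' @return scalar numeric, or NA if \code{values} is empty.
#' @export
aggregate_score <- function(values, method) {
  if (!method %in% c("max", "min", "mean"))
    stop("aggregate_score: unknown method '", method, "'")
  values <- values[!is.na(values)]
  if (length(values) == 0) return(NA_real_)
  if (any(!is.finite(values))) stop("aggregate_score: non-finite values")
  switch(method, max = max(values), min = min(values), mean = mean(values))
}

## Overlap machinery: hits between CNVs and one track, as (query, subject)
## index pairs. Site records are width-1 points.
track_hits <- function(cnv_gr, track, point = FALSE) {
  if (nrow(track) == 0)
    return(list(q = integer(), s = integer()))
  gr <- if (point)
    GenomicRanges::GRanges(norm_chrom(track$chrom),
                           IRanges::IRanges(track$pos + 1, width = 1))
  else
    GenomicRanges::GRanges(norm_chrom(track$chrom),
                           IRanges::IRanges(track$start + 1, track$end))
  # disjoint seqlevels (a CNV on a chromosome with no annotation) are a
  # legitimate no-hit case, not a warning
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(cnv_gr, gr, ignore.strand = TRUE))
  list(q = S4Vectors::queryHits(hits), s = S4Vectors::subjectHits(hits))
}

## Aggregate vals (indexed by hit subject) per query; NA when no usable hit.
agg_by_query <- function(n_query, hits, vals, method) {
  out <- rep(NA_real_, n_query)
  keep <- !is.na(vals[hits$s])
  if (!any(keep)) return(out)
  q <- hits$q[keep]; v <- vals[hits$s[keep]]
  fun <- switch(method, max = max, min = min, mean = mean)
  agg <- tapply(v, q, fun)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

count_by_query <- function(n_query, hits, mask) {
  tabulate(hits$q[mask[hits$s]], nbins = n_query)
}

require_column <- function(track, col, src) {
  if (nrow(track) > 0 && !col %in% names(track))
    stop(sprintf("feature registry selector '%s' not present in bundle %s track",
                 col, src))
  if (col %in% names(track)) track[[col]] else rep(NA, nrow(track))
}

#' Annotate a set of CNVs with the registry's feature vector
#'
#' For each CNV and each feature definition: \code{length} features return
#' the CNV span in bp; max/min/mean features aggregate the selected score
#' over overlapping genes (gene-level scores, once per overlapping gene) or
#' overlapping sites (site-level scores, once per site); count features
#' count overlapping records of the selected biotype, UTR kind, cCRE class,
#' dosage-score bucket, OMIM/Morbid flag, or sites whose categorical
#' predictor call equals the declared category. Overlap is any shared base
#' pair. A CNV overlapping nothing gets its length, missing (NA) for every
#' aggregation, and 0 for every count.
#'
#' @param cnvs \code{cnv_records}.
#' @param bundle \code{cnv_bundle}.
#' @param registry \code{feature_registry} (default: the built-in 79 features).
#' @return a \code{cnv_feature_matrix} with one row per CNV.
#' @export
annotate_cnvs <- function(cnvs, bundle, registry = default_feature_registry()) {
  stopifnot(inherits(bundle, "cnv_bundle"), inherits(registry, "feature_registry"))
  n <- nrow(cnvs)
  cnv_gr <- as_granges_ivs(cnvs)
  gh <- track_hits(cnv_gr, bundle$genes)
  uh <- track_hits(cnv_gr, bundle$utrs)
  sh <- track_hits(cnv_gr, bundle$sites, point = TRUE)
  rh <- track_hits(cnv_gr, bundle$regions)

  values <- matrix(NA_real_, nrow = n, ncol = nrow(registry),
                   dimnames = list(cnvs$record_id, registry$name))
  for (i in seq_len(nrow(registry))) {
    def <- registry[i, ]
    values[, i] <- switch(def$source,
      cnv_itself = cnvs$end - cnvs$start,
      gene_scores = agg_by_query(
        n, gh, as.numeric(require_column(bundle$genes, def$selector, "gene")),
        def$kind),
      site_numeric = agg_by_query(
        n, sh, as.numeric(require_column(bundle$sites, def$selector, "site")),
        def$kind),
      site_categorical = {
        calls <- as.character(require_column(bundle$sites, def$selector, "site"))
        count_by_query(n, sh, !is.na(calls) & calls == def$category)
      },
      genes = count_by_query(
        n, gh, !is.na(bundle$genes$biotype) &
          bundle$genes$biotype == def$selector),
      utr = count_by_query(
        n, uh, !is.na(bundle$utrs$utr_kind) &
          bundle$utrs$utr_kind == def$selector),
      regions = count_by_query(
        n, rh, !is.na(bundle$regions$region_class) &
          bundle$regions$region_class == def$selector),
      dosage = {
        parts <- strsplit(def$selector, ":", fixed = TRUE)[[1]]
        col <- if (parts[1] == "HI") "hi_score" else "ts_score"
        sc <- as.character(bundle$genes[[col]])
        mask <- if (parts[2] == "NA") is.na(sc) | sc == "NA"
                else !is.na(sc) & sc == parts[2]
        count_by_query(n, gh, mask)
      },
      omim_morbid = {
        flag <- if (def$selector == "omim") bundle$genes$is_omim
                else bundle$genes$is_morbid
        count_by_query(n, gh, !is.na(flag) & flag)
      },
      stop("unknown feature source: ", def$source))
  }
  new_feature_matrix(registry, values)
}

#' Annotate a single CNV record
#' @param cnv a one-row \code{cnv_records}.
#' @param bundle \code{cnv_bundle}.
#' @param registry \code{feature_registry}.
#' @return named list: record_id, values (named numeric), missing_mask.
#' @export
annotate_cnv <- function(cnv, bundle, registry = default_feature_registry()) {
  stopifnot(nrow(cnv) == 1)
  fm <- annotate_cnvs(cnv, bundle, registry)
  list(record_id = cnv$record_id, values = fm$values[1, ],
       missing_mask = fm$missing_mask[1, ])
}

#' Count records of one feature definition overlapping a CNV
#' @param cnv a one-row \code{cnv_records}.
#' @param bundle \code{cnv_bundle}.
#' @param def a one-row count-kind \code{feature_registry} slice.
#' @return integer count.
#' @export
count_overlapping <- function(cnv, bundle, def) {
  stopifnot(def$kind == "count")
  reg <- feature_registry(def)
  unname(annotate_cnv(cnv, bundle, reg)$values[1])
}

#' Fit median imputation on a (training) feature matrix
#'
#' Per-feature medians over non-missing values. A feature entirely missing
#' in training imputes to 0 and is flagged by a warning and the
#' \code{all_missing} attribute. Fit on the training partition only; apply
#' the fitted medians to held-out data.
#'
#' @param fm a \code{cnv_feature_matrix}.
#' @return named numeric vector of medians.
#' @export
fit_impute <- function(fm) {
  stopifnot(inherits(fm, "cnv_feature_matrix"))
  med <- apply(fm$values, 2, function(col) stats::median(col, na.rm = TRUE))
  all_missing <- names(med)[is.na(med)]
  if (length(all_missing)) {
    warning("fit_impute: feature(s) entirely missing in training, imputing 0: ",
            paste(all_missing, collapse = ", "))
    med[is.na(med)] <- 0
  }
  attr(med, "all_missing") <- all_missing
  med
}

#' Apply fitted medians to a feature matrix
#' @param fm a \code{cnv_feature_matrix}.
#' @param medians named vector from \code{fit_impute} (train medians, also
#'   for test data).
#' @return imputed \code{cnv_feature_matrix} (no missing cells).
#' @export
apply_impute <- function(fm, medians) {
  stopifnot(inherits(fm, "cnv_feature_matrix"))
  missing_med <- setdiff(colnames(fm$values), names(medians))
  if (length(missing_med))
    stop("apply_impute: no median for feature(s): ",
         paste(missing_med, collapse = ", "))
  values <- fm$values
  for (j in seq_len(ncol(values))) {
    nas <- is.na(values[, j])
    if (any(nas)) values[nas, j] <- medians[[colnames(values)[j]]]
  }
  new_feature_matrix(fm$registry, values, medians = medians)
}
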