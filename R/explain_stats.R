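## Model interpretation (TreeSHAP attributions via xgboost's exact
## predcontrib) and nonparametric feature-distribution statistics
## (Mann-Whitney U with exact small-sample p, Kruskal-Wallis with
## Bonferroni post hoc, genomic-element proportions, differential
## top-feature selection for heat maps).

#' Exact TreeSHAP attributions for a fitted model
#'
#' Per-row, per-feature additive attributions of the model's margin output.
#' For each row, attributions plus the base value equal the margin exactly
#' (binary: log-odds; multiclass: per-class raw score).
#'
#' @param model a \code{cnv_model}.
#' @param x imputed feature matrix compatible with the model.
#' @return list of class \code{cnv_shap}: \code{values} (binary: matrix
#'   rows x features; multiclass: array rows x classes x features),
#'   \code{base} (per-row base value, or rows x classes), \code{features},
#'   \code{classes}.
#' @export
shap_attributions <- function(model, x) {
  vals <- feature_values(x)
  fp <- paste(colnames(vals), collapse = "|")
  if (!identical(fp, model$fingerprint))
    stop("shap_attributions: feature columns do not match the model")
  if (anyNA(vals)) stop("shap_attributions: impute the matrix first")
  contrib <- predict(model$booster, vals, predcontrib = TRUE)
  features <- colnames(vals)
  nf <- length(features)  # bias term is the trailing slice
  if (model$task$task == "binary") {
    values <- contrib[, seq_len(nf), drop = FALSE]
    colnames(values) <- features
    base <- contrib[, nf + 1]
  } else {
    values <- contrib[, , seq_len(nf), drop = FALSE]
    dimnames(values)[[3]] <- features
    base <- contrib[, , nf + 1]
  }
  out <- list(values = values, base = base, features = features,
              classes = model$task$classes, task = model$task)
  class(out) <- "cnv_shap"
  out
}

abs_attr_by_feature <- function(attr) {
  if (length(dim(attr$values)) == 3)
    apply(abs(attr$values), 3, sum)
  else
    colSums(abs(attr$values))
}

#' Rank features by total absolute SHAP attribution
#'
#' Features sorted descending by the sum of absolute attributions over all
#' rows (and classes, for multiclass models); ties break by registry
#' (column) order.
#'
#' @param attr a \code{cnv_shap}.
#' @param top_k how many features to return (all if larger than the count).
#' @return character vector of feature names.
#' @export
rank_features_by_shap <- function(attr, top_k = 20) {
  sums <- abs_attr_by_feature(attr)
  ord <- order(-sums, seq_along(sums))
  attr$features[ord][seq_len(min(top_k, length(sums)))]
}

running_median <- function(x, window = 51) {
  n <- length(x)
  if (n == 0) return(x)
  window <- min(window, if (n %% 2 == 1) n else n - 1)
  if (window < 3) return(x)
  as.numeric(stats::runmed(x, k = window))
}

#' SHAP dependence data for one feature
#'
#' (feature value, attribution) pairs for plotting, plus an estimate of the
#' feature value at which the attribution changes sign: attributions are
#' ordered by feature value, smoothed with a running median (window 51),
#' and the first zero crossing is located by linear interpolation. NA if
#' the smoothed attribution never changes sign.
#'
#' @param attr a \code{cnv_shap}.
#' @param x the feature matrix the attributions were computed on.
#' @param feature feature name.
#' @param class for multiclass models, which class's attribution to use
#'   (default: the most pathogenic class).
#' @param window running-median window for the threshold estimate.
#' @return list with \code{data} (data.frame value/attribution) and
#'   \code{threshold} (numeric or NA).
#' @export
shap_dependence <- function(attr, x, feature,
                            class = attr$classes[length(attr$classes)],
                            window = 51) {
  if (!feature %in% attr$features)
    stop("shap_dependence: unknown feature '", feature, "'")
  vals <- feature_values(x)
  fv <- vals[, feature]
  a <- if (length(dim(attr$values)) == 3)
    attr$values[, match(class, attr$classes), match(feature, attr$features)]
  else attr$values[, feature]
  ord <- order(fv)
  sm <- running_median(a[ord], window)
  sgn <- sign(sm)
  cross <- which(sgn[-1] != sgn[-length(sgn)] & sgn[-1] != 0 &
                 sgn[-length(sgn)] != 0)
  threshold <- NA_real_
  if (length(cross)) {
    k <- cross[1]
    x0 <- fv[ord][k]; x1 <- fv[ord][k + 1]
    y0 <- sm[k]; y1 <- sm[k + 1]
    threshold <- if (y1 == y0) (x0 + x1) / 2 else x0 - y0 * (x1 - x0) / (y1 - y0)
  } else if (any(sgn == 0) && any(sgn != 0)) {
    threshold <- fv[ord][which(sgn == 0)[1]]
  }
  list(data = data.frame(value = fv, attribution = a),
       threshold = threshold)
}

## -- Nonparametric statistics --------------------------------------------

mw_u_stat <- function(x, y) {
  r <- rank(c(x, y), ties.method = "average")
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test (two-sided)
#'
#' U computed from midranks. For small samples (n_x + n_y <= exact_limit)
#' the p-value is exact by full enumeration of all assignments of the
#' pooled values to the two groups (valid under ties); otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples (both non-empty).
#' @param exact_limit maximum pooled size for exact enumeration.
#' @return list with \code{U} (for the first sample) and \code{p.value}.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 12) {
  if (length(x) == 0 || length(y) == 0)
    stop("mann_whitney_u: both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  u_obs <- mw_u_stat(x, y)
  if (n <= exact_limit) {
    pooled <- c(x, y)
    combos <- utils::combn(n, nx)
    u_all <- apply(combos, 2, function(idx)
      mw_u_stat(pooled[idx], pooled[-idx]))
    p_le <- mean(u_all <= u_obs + 1e-9)
    p_ge <- mean(u_all >= u_obs - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    r <- rank(c(x, y), ties.method = "average")
    mu <- nx * ny / 2
    ties <- table(r)
    sigma2 <- (nx * ny / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = u_obs, p.value = 1))
    z <- u_obs - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = u_obs, p.value = p)
}

#' Kruskal-Wallis H test across groups
#'
#' Tie-corrected H with a chi-square p-value on k-1 degrees of freedom
#' (delegates to \code{stats::kruskal.test}).
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return list with \code{H} and \code{p.value}.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("kruskal_wallis: need at least 2 groups")
  if (any(lengths(groups) == 0)) stop("kruskal_wallis: empty group")
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p.value = kt$p.value)
}

#' Bonferroni-adjusted pairwise rank comparisons
#'
#' All k(k-1)/2 pairwise Mann-Whitney tests with each p multiplied by the
#' number of comparisons, capped at 1.
#'
#' @param groups named list of numeric vectors.
#' @return data.frame with group pair, U, raw and adjusted p.
#' @export
pairwise_posthoc <- function(groups) {
  if (length(groups) < 2) stop("pairwise_posthoc: need at least 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  pairs <- utils::combn(names(groups), 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    res <- mann_whitney_u(groups[[a]], groups[[b]])
    data.frame(group_a = a, group_b = b, U = res$U, p = res$p.value,
               p_adjusted = min(1, res$p.value * m))
  })
  do.call(rbind, rows)
}

#' Feature-distribution statistics per pathogenicity group
#'
#' For each requested feature: the Mann-Whitney test of every non-benign
#' group against the benign reference group (two-sided), and the
#' Kruskal-Wallis test across all groups with Bonferroni-adjusted post hoc
#' pairwise comparisons.
#'
#' @param fm \code{cnv_feature_matrix} (values may be raw or imputed; NA
#'   cells are dropped per group).
#' @param labels five-tier label per row.
#' @param features feature names to analyse.
#' @param reference reference group label.
#' @return named list per feature: \code{vs_reference} (data.frame),
#'   \code{kruskal} and \code{posthoc}.
#' @export
feature_distribution_stats <- function(fm, labels, features,
                                       reference = "benign") {
  labels <- as.character(labels)
  out <- list()
  for (f in features) {
    v <- fm$values[, f]
    groups <- split(v, labels)
    groups <- lapply(groups, function(g) g[!is.na(g)])
    groups <- groups[lengths(groups) > 0]
    if (!reference %in% names(groups))
      stop("feature_distribution_stats: reference group '", reference,
           "' absent")
    others <- setdiff(names(groups), reference)
    vs_ref <- do.call(rbind, lapply(others, function(g) {
      res <- mann_whitney_u(groups[[g]], groups[[reference]])
      data.frame(group = g, U = res$U, p = res$p.value)
    }))
    out[[f]] <- list(vs_reference = vs_ref,
                     kruskal = kruskal_wallis(groups),
                     posthoc = pairwise_posthoc(groups))
  }
  out
}

## -- Genomic-element proportions (stacked-bar data) -----------------------

ELEMENT_CATEGORIES <- c("pseudogene", "OMIM_gene", "Morbid_gene", "RNA_gene",
                        "protein_coding_gene")

#' Genomic-element proportions per CNV group
#'
#' For each CNV group, counts overlapped gene elements in the categories
#' pseudogene, OMIM gene, Morbid gene, RNA (non-coding) gene and
#' protein-coding gene, normalized to fractions summing to 1 over the five
#' categories. A gene contributes to every category it satisfies (an OMIM
#' protein-coding gene counts in both). Groups overlapping no elements get
#' NA proportions and are flagged.
#'
#' @param cnvs \code{cnv_records}.
#' @param bundle \code{cnv_bundle} with gene biotype and OMIM/Morbid flags.
#' @param group grouping label per CNV (default: pathogenicity label).
#' @return data.frame: group, one column per category, \code{defined} flag.
#' @export
element_proportions <- function(cnvs, bundle, group = cnvs$label) {
  gh <- track_hits(as_granges_ivs(cnvs), bundle$genes)
  g <- bundle$genes
  cat_mask <- cbind(
    pseudogene = g$biotype == "pseudogene",
    OMIM_gene = g$is_omim,
    Morbid_gene = g$is_morbid,
    RNA_gene = g$biotype == "ncRNA",
    protein_coding_gene = g$biotype == "protein_coding")
  group <- as.character(group)
  out <- lapply(sort(unique(group)), function(gr) {
    rows <- which(group == gr)
    sel <- gh$q %in% rows
    counts <- if (any(sel))
      colSums(cat_mask[gh$s[sel], , drop = FALSE], na.rm = TRUE)
    else stats::setNames(rep(0, length(ELEMENT_CATEGORIES)), ELEMENT_CATEGORIES)
    total <- sum(counts)
    props <- if (total > 0) counts / total else rep(NA_real_, length(counts))
    data.frame(group = gr, t(props), defined = total > 0,
               check.names = FALSE)
  })
  do.call(rbind, out)
}

#' Differential top-feature selection for heat-map rendering
#'
#' Feature values are transformed with the signed offset log,
#' sign(x) * log10(|x| + 1): count features are legitimately 0 (the offset
#' keeps the transform defined and maps 0 to 0) and several deleteriousness
#' scores are legitimately negative (GERP++ RS, PROVEAN), which the signed
#' form preserves. Features are ranked by the two-sided Mann-Whitney p-value between
#' the benign and pathogenic groups (constant features rank last); the top
#' k are selected, rows whose selected-feature values are all 0 are
#' removed, and the transformed sub-matrix is returned.
#'
#' @param fm imputed \code{cnv_feature_matrix}.
#' @param labels binary labels ("benign"/"pathogenic").
#' @param top_k number of features to select.
#' @param rank_by "p" (Mann-Whitney p) or "median_diff" (absolute
#'   difference of group medians on the transformed scale).
#' @return list: \code{features}, \code{p} (named), \code{matrix}
#'   (transformed, selected features, all-zero rows removed),
#'   \code{labels} (for the retained rows).
#' @export
differential_top_features <- function(fm, labels, top_k = 10,
                                      rank_by = c("p", "median_diff")) {
  rank_by <- match.arg(rank_by)
  labels <- as.character(labels)
  if (!all(labels %in% c("benign", "pathogenic")))
    stop("differential_top_features: labels must be benign/pathogenic")
  if (anyNA(fm$values))
    stop("differential_top_features: impute the matrix first")
  tv <- sign(fm$values) * log10(abs(fm$values) + 1)
  is_b <- labels == "benign"
  score <- vapply(seq_len(ncol(tv)), function(j) {
    xb <- tv[is_b, j]; xp <- tv[!is_b, j]
    if (length(unique(c(xb, xp))) < 2) return(Inf)  # constant feature: last
    if (rank_by == "p") mann_whitney_u(xp, xb)$p.value
    else -abs(stats::median(xp) - stats::median(xb))
  }, numeric(1))
  ord <- order(score, seq_along(score))
  sel <- ord[seq_len(min(top_k, ncol(tv)))]
  features <- colnames(tv)[sel]
  sub <- tv[, sel, drop = FALSE]
  keep <- rowSums(sub != 0) > 0
  list(features = features,
       p = stats::setNames(score[sel], features),
       matrix = sub[keep, , drop = FALSE],
       labels = labels[keep])
}
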