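## Readers/writers for annotation resources, CNV tables, the feature
## registry and feature matrices. All coordinates are converted to the
## internal 0-based half-open convention at parse time.

FEATURE_KINDS <- c("max", "min", "mean", "count", "length")
FEATURE_SOURCES <- c("gene_scores", "site_numeric", "site_categorical",
                     "genes", "utr", "regions", "dosage", "omim_morbid",
                     "cnv_itself")
CCRE_CLASSES <- c("CTCF_bound", "CTCF_only", "dELS", "DNase_H3K4me3",
                  "pELS", "PLS")
DOSAGE_SCORES <- c("0", "1", "2", "3", "40", "NA")
GENE_BIOTYPES <- c("protein_coding", "pseudogene", "ncRNA", "other")

#' Construct a feature registry
#'
#' A feature registry is an ordered table of feature definitions; its order
#' fixes the feature-matrix column order. Each definition has a unique
#' \code{name}, an aggregation \code{kind} (max/min/mean for numeric scores,
#' count for countable records, length for the CNV span itself), a
#' \code{source} track, a \code{selector} naming the score column, biotype,
#' region class or predictor, and an optional \code{category} code for
#' categorical-prediction counts.
#'
#' @param df data.frame with columns name, kind, source, selector, category.
#' @return data.frame of class \code{feature_registry}.
#' @export
feature_registry <- function(df) {
  required <- c("name", "kind", "source", "selector", "category")
  for (col in setdiff(required, names(df)))
    df[[col]] <- rep(NA_character_, nrow(df))
  df <- df[, required]
  for (col in required) df[[col]] <- as.character(df[[col]])
  if (nrow(df) > 0) {
    if (anyDuplicated(df$name))
      stop("feature_registry: duplicate feature name(s): ",
           paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
    bad <- !df$kind %in% FEATURE_KINDS
    if (any(bad)) stop("feature_registry: unknown kind: ", df$kind[bad][1])
    bad <- !df$source %in% FEATURE_SOURCES
    if (any(bad)) stop("feature_registry: unknown source: ", df$source[bad][1])
    numeric_src <- df$source %in% c("gene_scores", "site_numeric")
    agg <- df$kind %in% c("max", "min", "mean")
    if (any(agg & !numeric_src))
      stop("feature_registry: kind max/min/mean requires a numeric source (",
           df$name[agg & !numeric_src][1], ")")
    countable <- df$source %in% c("site_categorical", "genes", "utr",
                                  "regions", "dosage", "omim_morbid")
    if (any(df$kind == "count" & !countable))
      stop("feature_registry: kind count requires a countable source (",
           df$name[df$kind == "count" & !countable][1], ")")
    if (any(df$kind == "length" & df$source != "cnv_itself"))
      stop("feature_registry: kind length requires source cnv_itself")
  }
  rownames(df) <- NULL
  class(df) <- c("feature_registry", "data.frame")
  df
}

reg_entry <- function(name, kind, source, selector = NA, category = NA) {
  data.frame(name = name, kind = kind, source = source,
             selector = as.character(selector),
             category = as.character(category), stringsAsFactors = FALSE)
}

#' The built-in 79-entry feature registry
#'
#' The default deleteriousness-direction-aware feature scheme: 1 CNV length
#' feature; 24 max-aggregated scores (higher is more deleterious: pLI,
#' Episcore at gene level; REVEL, GERP++ RS, CADD, conservation scores and
#' further site-level scores); 10 min-aggregated scores (lower is more
#' deleterious: LOEUF, RVIS and further gene-level constraint scores; SIFT,
#' FATHMM, PROVEAN, CDTS and further site-level scores); 2 mean-aggregated
#' direction-less scores (GHIS, GDI); 7 genomic-element counts (gene
#' biotypes, UTRs, OMIM/Morbid genes); 6 candidate cis-regulatory element
#' class counts; 12 dosage-sensitivity counts (haploinsufficiency and
#' triplosensitivity genes at scores 0/1/2/3/40/NA); and 17
#' categorical-prediction counts (deleterious/benign/tolerated calls of
#' SIFT, LRT, PolyPhen2 HDIV/HVAR, MutationTaster, FATHMM, MetaSVM).
#' The aggregation direction of every score is declared here, never
#' inferred. The exact score roster beyond the named anchors is a package
#' default and fully user-overridable via a registry config file.
#'
#' @return a \code{feature_registry} with exactly 79 entries.
#' @export
default_feature_registry <- function() {
  gene_max <- c("pLI", "Episcore")
  site_max <- c("REVEL", "GERP_RS", "CADD_phred", "DANN", "MetaSVM_score",
                "MetaLR_score", "M_CAP", "MutationAssessor",
                "MutationTaster_score", "VEST3", "GenoCanyon",
                "integrated_fitCons", "GM12878_fitCons", "H1_hESC_fitCons",
                "HUVEC_fitCons", "phyloP100way", "phyloP20way",
                "phastCons100way", "phastCons20way", "SiPhy_29way",
                "Eigen", "fathmm_MKL")
  gene_min <- c("LOEUF", "RVIS", "LoFtool", "oe_lof")
  site_min <- c("SIFT", "SIFT4G", "PROVEAN", "FATHMM", "CDTS", "MTR")
  gene_mean <- c("GHIS", "GDI")
  cat_defs <- list(
    SIFT_pred = c("D", "T"),
    LRT_pred = c("D", "N", "U"),
    Polyphen2_HDIV_pred = c("D", "P", "B"),
    Polyphen2_HVAR_pred = c("D", "P", "B"),
    MutationTaster_pred = c("D", "N"),
    FATHMM_pred = c("D", "T"),
    MetaSVM_pred = c("D", "T"))

  rows <- list(reg_entry("length", "length", "cnv_itself"))
  for (s in gene_max)
    rows[[length(rows) + 1]] <- reg_entry(paste0(s, "_max"), "max", "gene_scores", s)
  for (s in site_max)
    rows[[length(rows) + 1]] <- reg_entry(paste0(s, "_max"), "max", "site_numeric", s)
  for (s in gene_min)
    rows[[length(rows) + 1]] <- reg_entry(paste0(s, "_min"), "min", "gene_scores", s)
  for (s in site_min)
    rows[[length(rows) + 1]] <- reg_entry(paste0(s, "_min"), "min", "site_numeric", s)
  for (s in gene_mean)
    rows[[length(rows) + 1]] <- reg_entry(paste0(s, "_mean"), "mean", "gene_scores", s)
  biotype_counts <- c(protein_coding = "protein_coding_gene_num",
                      pseudogene = "pseudogene_num", ncRNA = "ncRNA_num")
  for (b in names(biotype_counts))
    rows[[length(rows) + 1]] <- reg_entry(biotype_counts[[b]], "count", "genes", b)
  rows[[length(rows) + 1]] <- reg_entry("three_prime_UTR_num", "count", "utr", "three_prime")
  rows[[length(rows) + 1]] <- reg_entry("five_prime_UTR_num", "count", "utr", "five_prime")
  rows[[length(rows) + 1]] <- reg_entry("OMIM_gene_num", "count", "omim_morbid", "omim")
  rows[[length(rows) + 1]] <- reg_entry("Morbid_gene_num", "count", "omim_morbid", "morbid")
  for (cl in CCRE_CLASSES)
    rows[[length(rows) + 1]] <- reg_entry(paste0(cl, "_num"), "count", "regions", cl)
  for (side in c("HI", "TS")) for (sc in DOSAGE_SCORES)
    rows[[length(rows) + 1]] <- reg_entry(
      paste0(side, "_", sc, "_num"), "count", "dosage", paste0(side, ":", sc))
  for (pred in names(cat_defs)) for (code in cat_defs[[pred]])
    rows[[length(rows) + 1]] <- reg_entry(
      paste0(pred, "_", code), "count", "site_categorical", pred, code)

  feature_registry(do.call(rbind, rows))
}

#' Load a feature registry from a config file or the built-in default
#'
#' Config format: one feature per line, whitespace-separated fields
#' \code{name kind source selector [category]}; blank lines and lines
#' starting with \code{#} are ignored.
#'
#' @param path path to a registry config file, or \code{"default"} for the
#'   built-in 79-entry registry.
#' @return a \code{feature_registry}.
#' @export
load_feature_registry <- function(path = "default") {
  if (identical(path, "default")) return(default_feature_registry())
  if (!file.exists(path)) stop("registry config not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(feature_registry(data.frame()))
  parts <- strsplit(lines, "[ \t]+")
  bad <- vapply(parts, length, 1L) < 3
  if (any(bad))
    stop("registry config line ", which(bad)[1], ": need at least ",
         "'name kind source'")
  field <- function(p, i) {
    if (length(p) < i || p[i] == "-") NA else p[i]
  }
  df <- do.call(rbind, lapply(parts, function(p)
    reg_entry(p[1], p[2], p[3], field(p, 4), field(p, 5))))
  feature_registry(df)
}

#' Write a feature registry to a config file
#' @param registry a \code{feature_registry}.
#' @param path output path.
#' @export
write_feature_registry <- function(registry, path) {
  lines <- apply(registry, 1, function(r) {
    fields <- c(r[["name"]], r[["kind"]], r[["source"]],
                if (!is.na(r[["selector"]])) r[["selector"]] else "-",
                if (!is.na(r[["category"]])) r[["category"]])
    paste(fields, collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

## -- CNV table reading ---------------------------------------------------

CNV_DIALECTS <- c("clinvar", "dbvar", "clingen_region", "dgv", "decipher",
                  "gnomad", "generic_bed")

read_tsv_checked <- function(path, header) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = header, sep = "\t",
                    stringsAsFactors = FALSE, quote = "",
                    comment.char = "#", na.strings = c("NA", "."))
}

check_coords <- function(start, end, path) {
  s <- suppressWarnings(as.numeric(start)); e <- suppressWarnings(as.numeric(end))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad))
    stop(sprintf("%s: unparsable coordinate at data line %d", path, bad[1]))
  list(start = s, end = e)
}

#' Read a CNV call table in a source-database dialect
#'
#' Supported dialects: \code{generic_bed} (headerless BED-like TSV:
#' chrom, start, end, type, label, [id]; 0-based half-open) and header TSVs
#' for \code{clinvar}, \code{dbvar}, \code{clingen_region}, \code{dgv},
#' \code{decipher}, \code{gnomad} (1-based inclusive coordinates, converted
#' internally). Dialect-specific columns needed by the curation filters
#' (review status, AF, AN, FILTER, observations, frequency, sample counts,
#' dosage scores) are retained on the returned records. Rows missing
#' mandatory fields are reported via warning and skipped; an unparsable
#' coordinate is a row-level error naming the line.
#'
#' @param path input file.
#' @param dialect one of the supported source-database names.
#' @return \code{cnv_records} data.frame (with extra dialect columns).
#' @export
read_cnv_table <- function(path, dialect) {
  if (!dialect %in% CNV_DIALECTS)
    stop("unknown CNV table dialect: ", dialect,
         " (expected one of ", paste(CNV_DIALECTS, collapse = ", "), ")")
  if (dialect == "generic_bed") {
    df <- read_tsv_checked(path, header = FALSE)
    if (ncol(df) < 5)
      stop(path, ": generic_bed needs >= 5 columns (chrom start end type label)")
    names(df)[1:5] <- c("chrom", "start", "end", "type", "label")
    co <- check_coords(df$start, df$end, path)
    rec <- cnv_records(df$chrom, co$start, co$end, df$type, df$label,
                       source = "generic_bed",
                       record_id = if (ncol(df) >= 6) df[[6]] else NULL)
    return(rec)
  }
  df <- read_tsv_checked(path, header = TRUE)
  mandatory <- switch(dialect,
    clinvar = c("chrom", "start", "end", "type", "clinical_significance",
                "review_status"),
    dbvar = c("chrom", "start", "end", "type", "clinical_significance"),
    clingen_region = c("chrom", "start", "end", "hi_score", "ts_score"),
    dgv = c("chrom", "start", "end", "type", "sample_size"),
    decipher = c("chrom", "start", "end", "type", "observations", "frequency"),
    gnomad = c("chrom", "start", "end", "SVTYPE", "FILTER", "AF", "AN"))
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols))
    stop(path, ": dialect '", dialect, "' requires column(s): ",
         paste(missing_cols, collapse = ", "))
  co <- check_coords(df$start, df$end, path)
  df$start <- co$start - 1  # 1-based inclusive -> 0-based half-open
  df$end <- co$end
  # hi/ts dosage scores use "NA" as a real level, so they are exempt from
  # the missing-field skip
  key_cols <- setdiff(mandatory, c("chrom", "start", "end",
                                   "hi_score", "ts_score"))
  incomplete <- rowSums(is.na(df[, key_cols, drop = FALSE])) > 0
  if (any(incomplete)) {
    warning(sprintf("%s: skipped %d row(s) with missing mandatory fields",
                    path, sum(incomplete)))
    df <- df[!incomplete, , drop = FALSE]
  }
  if (dialect == "clingen_region") {
    type <- rep("loss", nrow(df))   # placeholder; curation assigns per score
    label <- rep("unknown", nrow(df))
  } else {
    type_col <- if (dialect == "gnomad") df$SVTYPE else df$type
    type <- normalize_cnv_type(type_col)
    keep <- !is.na(type)
    if (any(!keep)) {
      df <- df[keep, , drop = FALSE]; type <- type[keep]
    }
    label <- if (dialect %in% c("clinvar", "dbvar"))
      normalize_label(df$clinical_significance) else rep("unknown", nrow(df))
  }
  if (nrow(df) == 0)
    return(cnv_records(character(), numeric(), numeric(), character())[0, ])
  rec <- cnv_records(df$chrom, df$start, df$end, type, label,
                     source = dialect,
                     record_id = if ("record_id" %in% names(df))
                       df$record_id else paste0(dialect, "_", seq_len(nrow(df))))
  extra <- setdiff(names(df), c("chrom", "start", "end", "type", "SVTYPE",
                                "clinical_significance", "record_id"))
  for (col in extra) rec[[col]] <- df[[col]]
  rec
}

#' Write CNV records as a generic BED-like TSV
#' @param records \code{cnv_records}.
#' @param path output path.
#' @export
write_cnv_table <- function(records, path) {
  out <- data.frame(chrom = records$chrom, start = records$start,
                    end = records$end, type = records$cnv_type,
                    label = records$label, record_id = records$record_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## -- Annotation track readers -------------------------------------------

#' Read a gene track
#'
#' TSV format (header): chrom, start, end (1-based inclusive), gene_id,
#' biotype, is_omim, is_morbid, hi_score, ts_score, then any number of
#' numeric gene-score columns (pLI, LOEUF, ...). GFF3 format: gene lines
#' with \code{ID} and \code{biotype} attributes (no scores). Missing score
#' cells (\code{.} or NA) stay missing, never 0.
#'
#' @param path input file.
#' @param format "tsv" or "gff3".
#' @return data.frame of gene records (0-based half-open coordinates).
#' @export
read_gene_track <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "gff3") {
    df <- read_tsv_checked(path, header = FALSE)
    if (ncol(df) < 9) stop(path, ": not a GFF3 file (9 columns required)")
    df <- df[df[[3]] == "gene", , drop = FALSE]
    attr_get <- function(attrs, key) {
      m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
      out <- sub(paste0("^(;)?", key, "="), "", m)
      ifelse(lengths(regmatches(attrs, gregexpr(paste0(key, "="), attrs))) > 0,
             out, NA_character_)
    }
    attrs <- df[[9]]
    gene_id <- sub(".*ID=([^;]*).*", "\\1", attrs)
    biotype <- ifelse(grepl("biotype=", attrs),
                      sub(".*biotype=([^;]*).*", "\\1", attrs), "other")
    biotype[!biotype %in% GENE_BIOTYPES] <- "other"
    co <- check_coords(df[[4]], df[[5]], path)
    out <- data.frame(chrom = norm_chrom(df[[1]]), start = co$start - 1,
                      end = co$end, gene_id = gene_id, biotype = biotype,
                      is_omim = FALSE, is_morbid = FALSE,
                      hi_score = NA_character_, ts_score = NA_character_,
                      stringsAsFactors = FALSE)
    return(out)
  }
  df <- read_tsv_checked(path, header = TRUE)
  needed <- c("chrom", "start", "end", "gene_id", "biotype")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop(path, ": gene track missing column(s): ",
         paste(missing_cols, collapse = ", "))
  co <- check_coords(df$start, df$end, path)
  df$chrom <- norm_chrom(df$chrom)
  df$start <- co$start - 1; df$end <- co$end
  for (flag in c("is_omim", "is_morbid"))
    df[[flag]] <- if (flag %in% names(df)) as.logical(df[[flag]]) else FALSE
  for (sc in c("hi_score", "ts_score"))
    df[[sc]] <- if (sc %in% names(df)) as.character(df[[sc]]) else NA_character_
  df
}

#' Read a UTR track (TSV: chrom, start, end 1-based, utr_kind, parent_gene)
#' @param path input file.
#' @return data.frame of UTR records (0-based half-open).
#' @export
read_utr_track <- function(path) {
  df <- read_tsv_checked(path, header = TRUE)
  needed <- c("chrom", "start", "end", "utr_kind")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop(path, ": UTR track missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!all(df$utr_kind %in% c("three_prime", "five_prime")))
    stop(path, ": utr_kind must be 'three_prime' or 'five_prime'")
  co <- check_coords(df$start, df$end, path)
  df$chrom <- norm_chrom(df$chrom); df$start <- co$start - 1; df$end <- co$end
  df
}

#' Read a site-level score table
#'
#' TSV with header: chrom, pos (1-based), then numeric score columns and
#' categorical predictor columns (names ending in \code{_pred}, letter
#' codes such as D/B/T/N). \code{.} cells become explicit missing values.
#'
#' @param path input file.
#' @return data.frame of site records (0-based positions).
#' @export
read_site_scores <- function(path) {
  df <- read_tsv_checked(path, header = TRUE)
  if (!all(c("chrom", "pos") %in% names(df)))
    stop(path, ": site table needs 'chrom' and 'pos' columns")
  pos <- suppressWarnings(as.numeric(df$pos))
  if (anyNA(pos))
    stop(sprintf("%s: unparsable position at data line %d", path,
                 which(is.na(pos))[1]))
  df$chrom <- norm_chrom(df$chrom)
  df$pos <- pos - 1
  for (col in setdiff(names(df), c("chrom", "pos")))
    if (!grepl("_pred$", col)) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Read a region track (4-column BED: chrom, start, end, region class)
#' @param path input file.
#' @return data.frame of region records (0-based half-open).
#' @export
read_region_track <- function(path) {
  df <- read_tsv_checked(path, header = FALSE)
  if (ncol(df) < 4) stop(path, ": region BED needs 4 columns")
  names(df)[1:4] <- c("chrom", "start", "end", "region_class")
  co <- check_coords(df$start, df$end, path)
  bad <- !df$region_class %in% CCRE_CLASSES
  if (any(bad))
    stop(path, ": unknown region class '", df$region_class[bad][1], "'")
  data.frame(chrom = norm_chrom(df$chrom), start = co$start, end = co$end,
             region_class = df$region_class, stringsAsFactors = FALSE)
}

#' Assemble a resource bundle
#'
#' A resource bundle holds every annotation track the feature engine needs:
#' gene records (with biotype, OMIM/Morbid flags, dosage-sensitivity scores
#' and gene-level numeric scores), UTR records, site-level score records
#' and cCRE region records. Tracks may be empty.
#'
#' @param genes,utrs,sites,regions track data.frames as returned by the
#'   corresponding readers.
#' @param provenance named list describing where each track came from.
#' @return list of class \code{cnv_bundle}.
#' @export
resource_bundle <- function(genes = NULL, utrs = NULL, sites = NULL,
                            regions = NULL, provenance = list()) {
  empty_iv <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), stringsAsFactors = FALSE)
  if (is.null(genes)) genes <- cbind(empty_iv, gene_id = character(),
                                     biotype = character(),
                                     is_omim = logical(), is_morbid = logical(),
                                     hi_score = character(), ts_score = character())
  if (is.null(utrs)) utrs <- cbind(empty_iv, utr_kind = character())
  if (is.null(sites)) sites <- data.frame(chrom = character(), pos = numeric())
  if (is.null(regions)) regions <- cbind(empty_iv, region_class = character())
  for (tr in list(genes, utrs, regions))
    if (nrow(tr) && any(tr$end <= tr$start))
      stop("resource_bundle: invalid interval in track")
  if (nrow(sites) && any(sites$pos < 0))
    stop("resource_bundle: negative site position")
  out <- list(genes = genes, utrs = utrs, sites = sites, regions = regions,
              provenance = provenance)
  class(out) <- "cnv_bundle"
  out
}

#' @export
print.cnv_bundle <- function(x, ...) {
  cat(sprintf(
    "Resource bundle: %d genes, %d UTRs, %d sites, %d regions\n",
    nrow(x$genes), nrow(x$utrs), nrow(x$sites), nrow(x$regions)))
  invisible(x)
}

#' Write/load a resource bundle as a directory of plain-text tracks
#' @param bundle a \code{cnv_bundle}.
#' @param dir directory path.
#' @rdname bundle_io
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- bundle$genes; g$start <- g$start + 1
  utils::write.table(g, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  u <- bundle$utrs; u$start <- u$start + 1
  utils::write.table(u, file.path(dir, "utrs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  s <- bundle$sites; s$pos <- s$pos + 1
  utils::write.table(s, file.path(dir, "sites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$regions, file.path(dir, "regions.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(dir)
}

#' @rdname bundle_io
#' @export
load_bundle <- function(dir) {
  resource_bundle(
    genes = read_gene_track(file.path(dir, "genes.tsv")),
    utrs = read_utr_track(file.path(dir, "utrs.tsv")),
    sites = read_site_scores(file.path(dir, "sites.tsv")),
    regions = read_region_track(file.path(dir, "regions.bed")),
    provenance = list(dir = dir))
}

## -- Feature matrix I/O --------------------------------------------------

#' Write a feature matrix to TSV
#'
#' Columns are \code{record_id} plus one column per registry feature, in
#' registry order. If the matrix carries fitted imputation medians, a
#' sidecar file \code{<path>.medians.tsv} records them.
#'
#' @param fm a \code{cnv_feature_matrix}.
#' @param path output TSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "cnv_feature_matrix"))
  df <- data.frame(record_id = rownames(fm$values), fm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fm$medians)) {
    med <- data.frame(feature = names(fm$medians), median = unname(fm$medians))
    utils::write.table(med, paste0(path, ".medians.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a feature matrix written by \code{write_feature_matrix}
#' @param path TSV path.
#' @param registry the registry the matrix was computed with; column order
#'   must match.
#' @return a \code{cnv_feature_matrix}.
#' @export
read_feature_matrix <- function(path, registry) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!identical(names(df)[-1], registry$name))
    stop(path, ": feature columns do not match the registry order")
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$record_id
  medians <- NULL
  med_path <- paste0(path, ".medians.tsv")
  if (file.exists(med_path)) {
    med <- utils::read.table(med_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    medians <- stats::setNames(med$median, med$feature)
  }
  new_feature_matrix(registry, values, medians = medians)
}
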