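## Synthetic toy genomes, annotation bundles, labelled CNV sets with
## planted pathogenicity signal, and raw per-database tables exercising
## every curation rule path. Everything is reproducible from one seed:
## each track draws from its own derived stream (seed combined with a
## track-name hash), so adding records to one track never shifts another.

derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * (7 + seq_along(utf8ToInt(stream))))
  (as.integer(seed) * 2654435L + h * 40503L) %% 2147483647L
}

#' Specification for the synthetic fixture generator
#'
#' Defaults emulate the statistical structure the classifier assumes:
#' pathogenic CNVs are longer and enriched for morbid/dosage-sensitive
#' gene overlap, with monotone effects across the five tiers (benign <
#' likely benign < uncertain < likely pathogenic < pathogenic), and
#' deleterious site calls cluster in morbid genes.
#'
#' @param seed mandatory integer seed.
#' @param genome named numeric vector: chromosome lengths in bp.
#' @param n_genes,n_sites,n_regions track sizes.
#' @param class_counts named vector: CNVs per five-tier label (per CNV type).
#' @param length_ratio pathogenic/benign mean length multiplier (> 0).
#' @param morbid_enrichment extra probability that a pathogenic CNV is
#'   centred on a morbid gene (0 disables the planted overlap signal).
#' @param site_D_rate_shift increase in deleterious-call density and
#'   deleterious-score shift inside morbid genes.
#' @param noise sd of multiplicative length jitter.
#' @return list of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed,
                         genome = c("1" = 1e7, "2" = 1e7),
                         n_genes = 300, n_sites = 3000, n_regions = 300,
                         class_counts = c(benign = 400, likely_benign = 100,
                                          uncertain_significance = 150,
                                          likely_pathogenic = 150,
                                          pathogenic = 400),
                         length_ratio = 4, morbid_enrichment = 0.8,
                         site_D_rate_shift = 0.3, noise = 0.3) {
  if (missing(seed)) stop("fixture_spec: seed is mandatory")
  stopifnot(all(genome > 0), n_genes >= 0, n_sites >= 0, n_regions >= 0,
            all(class_counts >= 0), length_ratio > 0,
            morbid_enrichment >= 0, morbid_enrichment <= 1)
  out <- list(seed = as.integer(seed), genome = genome, n_genes = n_genes,
              n_sites = n_sites, n_regions = n_regions,
              class_counts = class_counts, length_ratio = length_ratio,
              morbid_enrichment = morbid_enrichment,
              site_D_rate_shift = site_D_rate_shift, noise = noise)
  class(out) <- "fixture_spec"
  out
}

sample_positions <- function(n, genome) {
  chrom <- sample(names(genome), n, replace = TRUE,
                  prob = genome / sum(genome))
  pos <- floor(stats::runif(n) * genome[chrom])
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

## Score roster matching the default registry. Ranges follow each score's
## documented scale (pLI/REVEL/SIFT in [0,1], LOEUF in [0,9], GERP++ RS in
## [-5,6], CADD phred in [0,40], ...).
GENE_SCORE_RANGES <- list(
  pLI = c(0, 1), Episcore = c(0, 1), LOEUF = c(0, 9), RVIS = c(-4, 4),
  LoFtool = c(0, 1), oe_lof = c(0, 2), GHIS = c(0, 1), GDI = c(0, 30))
GENE_SCORE_DIRECTION <- c(pLI = 1, Episcore = 1, LOEUF = -1, RVIS = -1,
                          LoFtool = -1, oe_lof = -1, GHIS = 0, GDI = 0)
SITE_MAX_RANGES <- list(
  REVEL = c(0, 1), GERP_RS = c(-5, 6), CADD_phred = c(0, 40),
  DANN = c(0, 1), MetaSVM_score = c(-2, 2), MetaLR_score = c(0, 1),
  M_CAP = c(0, 1), MutationAssessor = c(-4, 6),
  MutationTaster_score = c(0, 1), VEST3 = c(0, 1), GenoCanyon = c(0, 1),
  integrated_fitCons = c(0, 1), GM12878_fitCons = c(0, 1),
  H1_hESC_fitCons = c(0, 1), HUVEC_fitCons = c(0, 1),
  phyloP100way = c(-5, 10), phyloP20way = c(-5, 10),
  phastCons100way = c(0, 1), phastCons20way = c(0, 1),
  SiPhy_29way = c(0, 30), Eigen = c(-4, 4), fathmm_MKL = c(0, 1))
SITE_MIN_RANGES <- list(
  SIFT = c(0, 1), SIFT4G = c(0, 1), PROVEAN = c(-13, 4),
  FATHMM = c(-16, 10), CDTS = c(-20, 10), MTR = c(0, 2))
SITE_PRED_ALPHABETS <- list(
  SIFT_pred = c("D", "T"), LRT_pred = c("D", "N", "U"),
  Polyphen2_HDIV_pred = c("D", "P", "B"),
  Polyphen2_HVAR_pred = c("D", "P", "B"),
  MutationTaster_pred = c("D", "N"), FATHMM_pred = c("D", "T"),
  MetaSVM_pred = c("D", "T"))

scaled <- function(u, range) range[1] + u * (range[2] - range[1])

#' Generate a synthetic resource bundle
#'
#' Genes (biotypes, OMIM/Morbid flags, dosage scores, gene-level scores
#' uniform in their documented ranges), UTRs on protein-coding genes,
#' site-level numeric scores (uniform in their documented ranges) and
#' categorical calls (deleterious-call density enriched inside morbid
#' genes by \code{site_D_rate_shift}), and cCRE regions across the six
#' classes. Reproducible for a fixed seed.
#'
#' @param spec a \code{fixture_spec}.
#' @return a \code{cnv_bundle}.
#' @export
generate_bundle <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  genome <- spec$genome
  if (spec$n_genes > 0 && min(genome) < 1e5)
    stop("generate_bundle: genome too small to place gene records")

  genes <- with_seed(derive_seed(spec$seed, "genes"), {
    if (spec$n_genes == 0) NULL else {
      p <- sample_positions(spec$n_genes, genome)
      len <- floor(stats::runif(spec$n_genes, 5e3, 5e4))
      start <- pmin(p$pos, genome[p$chrom] - len - 1)
      biotype <- sample(GENE_BIOTYPES, spec$n_genes, replace = TRUE,
                        prob = c(0.5, 0.2, 0.2, 0.1))
      # independent flags: keeps the morbid-overlap signal attributable to
      # the morbid count rather than an OMIM proxy (toy simplification)
      is_morbid <- biotype == "protein_coding" &
        stats::runif(spec$n_genes) < 0.3
      is_omim <- biotype == "protein_coding" &
        stats::runif(spec$n_genes) < 0.25
      hi <- sample(DOSAGE_SCORES, spec$n_genes, replace = TRUE,
                   prob = c(.3, .15, .1, .1, .05, .3))
      ts <- sample(DOSAGE_SCORES, spec$n_genes, replace = TRUE,
                   prob = c(.3, .15, .1, .1, .05, .3))
      g <- data.frame(chrom = p$chrom, start = start, end = start + len,
                      gene_id = sprintf("G%04d", seq_len(spec$n_genes)),
                      biotype = biotype, is_omim = is_omim,
                      is_morbid = is_morbid, hi_score = hi, ts_score = ts,
                      stringsAsFactors = FALSE)
      for (sc in names(GENE_SCORE_RANGES))
        g[[sc]] <- scaled(stats::runif(spec$n_genes), GENE_SCORE_RANGES[[sc]])
      g
    }
  })

  utrs <- with_seed(derive_seed(spec$seed, "utrs"), {
    if (is.null(genes)) NULL else {
      pc <- genes[genes$biotype == "protein_coding", , drop = FALSE]
      keep <- stats::runif(max(nrow(pc), 0)) < 0.9
      pc <- pc[keep, , drop = FALSE]
      if (nrow(pc) == 0) NULL else rbind(
        data.frame(chrom = pc$chrom, start = pc$start,
                   end = pc$start + 400, utr_kind = "five_prime",
                   parent_gene = pc$gene_id, stringsAsFactors = FALSE),
        data.frame(chrom = pc$chrom, start = pc$end - 600,
                   end = pc$end, utr_kind = "three_prime",
                   parent_gene = pc$gene_id, stringsAsFactors = FALSE))
    }
  })

  in_morbid <- function(chrom, pos) {
    if (is.null(genes)) return(rep(FALSE, length(pos)))
    mg <- genes[genes$is_morbid, , drop = FALSE]
    if (nrow(mg) == 0) return(rep(FALSE, length(pos)))
    gr_sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1, width = 1))
    gr_mg <- GenomicRanges::GRanges(mg$chrom, IRanges::IRanges(mg$start + 1, mg$end))
    IRanges::overlapsAny(gr_sites, gr_mg)
  }

  sites <- with_seed(derive_seed(spec$seed, "sites"), {
    if (spec$n_sites == 0) NULL else {
      p <- sample_positions(spec$n_sites, genome)
      hot <- in_morbid(p$chrom, p$pos)
      s <- data.frame(chrom = p$chrom, pos = p$pos, stringsAsFactors = FALSE)
      shift <- spec$site_D_rate_shift
      for (sc in names(SITE_MAX_RANGES))
        s[[sc]] <- scaled(stats::runif(spec$n_sites), SITE_MAX_RANGES[[sc]])
      for (sc in names(SITE_MIN_RANGES))
        s[[sc]] <- scaled(stats::runif(spec$n_sites), SITE_MIN_RANGES[[sc]])
      for (pred in names(SITE_PRED_ALPHABETS)) {
        alpha <- SITE_PRED_ALPHABETS[[pred]]
        p_del <- ifelse(hot, pmin(1, 0.15 + shift), 0.15)
        is_d <- stats::runif(spec$n_sites) < p_del
        other <- sample(alpha[-1], spec$n_sites, replace = TRUE)
        s[[pred]] <- ifelse(is_d, alpha[1], other)
      }
      s
    }
  })

  regions <- with_seed(derive_seed(spec$seed, "regions"), {
    if (spec$n_regions == 0) NULL else {
      p <- sample_positions(spec$n_regions, genome)
      len <- floor(stats::runif(spec$n_regions, 200, 3000))
      start <- pmin(p$pos, genome[p$chrom] - len - 1)
      data.frame(chrom = p$chrom, start = start, end = start + len,
                 region_class = sample(CCRE_CLASSES, spec$n_regions,
                                       replace = TRUE),
                 stringsAsFactors = FALSE)
    }
  })

  resource_bundle(genes = genes, utrs = utrs, sites = sites,
                  regions = regions,
                  provenance = list(generator = "synthetic",
                                    seed = spec$seed))
}

#' Generate a labelled CNV set with planted pathogenicity signal
#'
#' Per five-tier class and CNV type: base lengths are log-normal around
#' 20 kb, multiplied by \code{length_ratio^(rank/4)} where rank runs 0
#' (benign) to 4 (pathogenic); with probability
#' \code{morbid_enrichment * rank/4} a CNV is centred on a random morbid
#' gene instead of placed uniformly. Lengths are clipped to [50, 5e6] bp.
#' Loss and gain sets are generated independently from separate streams.
#' With neutral effects (\code{length_ratio = 1},
#' \code{morbid_enrichment = 0}) classes are exchangeable by construction.
#'
#' @param spec a \code{fixture_spec}.
#' @param bundle the bundle generated from the same spec.
#' @return \code{cnv_records} with five-tier labels.
#' @export
generate_cnv_set <- function(spec, bundle) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(bundle, "cnv_bundle"))
  counts <- spec$class_counts[spec$class_counts > 0]
  if (length(counts) == 0) stop("generate_cnv_set: class_counts is empty")
  genome <- spec$genome
  morbid <- bundle$genes[bundle$genes$is_morbid, , drop = FALSE]
  out <- list()
  for (type in c("loss", "gain")) {
    recs <- with_seed(derive_seed(spec$seed, paste0("cnv_", type)), {
      chunks <- list()
      for (label in names(counts)) {
        n <- counts[[label]]
        rank <- match(label, PATHOGENICITY_LEVELS) - 1L
        mult <- spec$length_ratio^(rank / 4)
        len <- stats::rlnorm(n, meanlog = log(2e4 * mult),
                             sdlog = spec$noise)
        len <- pmax(MIN_CNV_LENGTH, pmin(MAX_CNV_LENGTH, floor(len)))
        targeted <- nrow(morbid) > 0 &
          stats::runif(n) < spec$morbid_enrichment * rank / 4
        p <- sample_positions(n, genome)
        chrom <- p$chrom; start <- p$pos
        if (any(targeted)) {
          gi <- sample(nrow(morbid), sum(targeted), replace = TRUE)
          centre <- floor((morbid$start[gi] + morbid$end[gi]) / 2)
          chrom[targeted] <- morbid$chrom[gi]
          start[targeted] <- centre - floor(len[targeted] / 2)
        }
        start <- pmax(0, pmin(start, genome[chrom] - len - 1))
        chunks[[label]] <- data.frame(
          chrom = chrom, start = start, end = start + len,
          label = label, stringsAsFactors = FALSE)
      }
      df <- do.call(rbind, chunks)
      cnv_records(df$chrom, df$start, df$end, type, df$label,
                  source = "synthetic",
                  record_id = sprintf("%s_%05d", type, seq_len(nrow(df))))
    })
    out[[type]] <- recs
  }
  merged <- rbind(as.data.frame(out$loss), as.data.frame(out$gain))
  rownames(merged) <- NULL
  class(merged) <- c("cnv_records", "data.frame")
  merged
}

## -- Raw per-database tables with known curation outcomes -----------------

#' Generate raw per-database CNV tables with a ground-truth manifest
#'
#' Writes one table per source dialect into \code{dir}, containing by
#' construction known numbers of rows passing and failing every curation
#' predicate (gnomAD rows straddling the AF/AN cutoffs, DGV rows straddling
#' 2000 samples, ClinGen regions at dosage scores 3/40/other, a conflicting
#' 75--90\% overlap pair, an identical-coordinate multi-significance pair,
#' out-of-bounds lengths) plus a validation table with a planted concordant
#' >= 90\% pair. Seeded filler rows that pass all rules are added to the
#' frequency databases. Expected per-rule counts are recorded in the
#' returned manifest.
#'
#' @param seed integer seed for the filler rows.
#' @param dir output directory (created).
#' @return list: \code{dir}, \code{files} (named paths per dialect),
#'   \code{manifest} (expected counts).
#' @export
generate_raw_db_tables <- function(seed, dir = tempfile("rawdb")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ok_review <- "criteria provided, multiple submitters, no conflicts"
  # coordinates below are 1-based inclusive as in the source files
  clinvar <- data.frame(
    chrom = "1",
    start = c(10001, 30001, 50001, 70001, 90001, 200001, 300001, 400001,
              500001, 600001, 620001),
    end = c(20000, 40000, 60000, 80000, 95000, 210000, 301000, 7400000,
            500040, 610000, 630000),
    type = c("loss", "gain", "loss", "loss", "gain", "loss", "loss", "loss",
             "gain", "loss", "gain"),
    clinical_significance = c("pathogenic", "benign",
                              "uncertain significance", "pathogenic",
                              "drug response", "pathogenic", "pathogenic",
                              "pathogenic", "benign", "likely benign",
                              "likely pathogenic"),
    review_status = c(ok_review, "criteria provided, single submitter",
                      "reviewed by expert panel",
                      "no assertion criteria provided", ok_review,
                      ok_review, ok_review, ok_review,
                      "criteria provided, single submitter", ok_review,
                      ok_review),
    stringsAsFactors = FALSE)
  dbvar <- data.frame(
    chrom = "1",
    start = c(240001, 260001, 280001, 290001, 300001),
    end = c(250000, 270000, 285000, 295000, 301000),
    type = c("loss", "gain", "loss", "gain", "loss"),
    clinical_significance = c("Pathogenic", "Likely pathogenic", "Benign",
                              "pathogenic/likely pathogenic",
                              "Likely pathogenic"),
    stringsAsFactors = FALSE)
  clingen <- data.frame(
    chrom = "1",
    start = c(1000001, 1100001, 1200001, 1300001),
    end = c(1050000, 1150000, 1250000, 1350000),
    hi_score = c("3", NA, "40", "1"),
    ts_score = c(NA, "3", "40", "2"),
    stringsAsFactors = FALSE)
  dgv <- data.frame(
    chrom = "1",
    start = c(201001, 1400001, 1420001, 1440001),
    end = c(210000, 1410000, 1430000, 1450000),
    type = c("loss", "loss", "gain", "gain"),
    sample_size = c(3000, 2500, 1500, 2000),
    frequency = c(0.02, 0.02, 0.02, 0.02),
    stringsAsFactors = FALSE)
  decipher <- data.frame(
    chrom = "1",
    start = c(1500001, 1520001, 1540001),
    end = c(1510000, 1530000, 1550000),
    type = c("loss", "gain", "loss"),
    observations = c(5, 0, 3),
    frequency = c(0.05, 0.05, 0.005),
    stringsAsFactors = FALSE)
  gnomad <- data.frame(
    chrom = "1",
    start = c(1600001, 1620001, 1640001, 1660001, 1680001),
    end = c(1610000, 1630000, 1650000, 1670000, 1690000),
    SVTYPE = c("DEL", "DUP", "DEL", "DEL", "INS"),
    FILTER = c("PASS", "PASS", "LowQual", "PASS", "PASS"),
    AF = c(0.05, 0.005, 0.05, 0.05, 0.05),
    AN = c(5000, 5000, 5000, 1000, 5000),
    stringsAsFactors = FALSE)
  # seeded filler: guaranteed-pass benign rows in disjoint 200 kb slots
  n_filler <- 5L
  filler <- with_seed(derive_seed(seed, "filler"), {
    len <- floor(stats::runif(2 * n_filler, 1e4, 5e4))
    start <- 3e6 + (seq_len(2 * n_filler) - 1) * 2e5 + 1
    data.frame(start = start, end = start + len - 1,
               type = sample(c("loss", "gain"), 2 * n_filler, TRUE))
  })
  dgv <- rbind(dgv, data.frame(
    chrom = "1", start = filler$start[1:n_filler],
    end = filler$end[1:n_filler], type = filler$type[1:n_filler],
    sample_size = 4000, frequency = 0.02))
  gnomad <- rbind(gnomad, data.frame(
    chrom = "1", start = filler$start[n_filler + 1:n_filler],
    end = filler$end[n_filler + 1:n_filler],
    SVTYPE = toupper(substr(filler$type[n_filler + 1:n_filler], 1, 3)),
    FILTER = "PASS", AF = 0.05, AN = 5000))
  gnomad$SVTYPE <- sub("LOS", "DEL", sub("GAI", "DUP", gnomad$SVTYPE))

  # validation set (generic BED, 0-based half-open)
  validation <- data.frame(
    chrom = "1",
    start = c(100000, 100000, 120000, 121000, 140000, 143000, 160000, 170000),
    end = c(101000, 101100, 130000, 130000, 150000, 150000, 160040, 180000),
    type = "loss",
    label = c("pathogenic", "pathogenic", "benign", "pathogenic", "benign",
              "benign", "benign", "pathogenic"),
    record_id = sprintf("val%02d", 1:8),
    stringsAsFactors = FALSE)

  files <- list()
  for (nm in c("clinvar", "dbvar", "clingen", "dgv", "decipher", "gnomad")) {
    df <- get(nm)
    if (nm == "clingen") nm <- "clingen_region"
    path <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[nm]] <- path
  }
  files$validation <- file.path(dir, "validation.bed")
  utils::write.table(validation, files$validation, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  manifest <- list(
    source_retained = c(clinvar = 9, dbvar = 4, clingen_region = 3,
                        dgv = 3 + n_filler, decipher = 1, gnomad = 1 + n_filler),
    clingen_emitted_records = 4,
    source_excluded = list(
      clinvar = c(labelled_five_tier = 1, review_status = 1),
      dbvar = c(pathogenic_label = 1),
      clingen_region = c(no_dosage_call = 1),
      dgv = c(sample_size = 1),
      decipher = c(observations = 1, frequency = 1),
      gnomad = c(filter_pass = 1, allele_frequency = 1, allele_number = 1)),
    gnomad_parsed_rows = 4 + n_filler,  # the INS row drops at parse time
    merge = list(n_in = 9 + 4 + 4 + (3 + n_filler) + 1 + (1 + n_filler),
                 length_filter = 2, conflicting_70pct = 2,
                 multiple_significance = 2,
                 retained = 16 + 2 * n_filler),
    validation = list(n_in = 8, conflicting_70pct = 2,
                      longer_of_90pct_pair = 1, length_filter = 1,
                      retained = 4, kept_shorter_id = "val01",
                      removed_longer_id = "val02"))
  list(dir = dir, files = files, manifest = manifest)
}
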