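test_that("default registry has 79 uniquely named, well-typed entries", {
  reg <- default_feature_registry()
  expect_equal(nrow(reg), 79)
  expect_false(anyDuplicated(reg$name) > 0)
  # features named in the model's headline analyses are all present
  expect_true(all(c("length", "pLI_max", "LOEUF_min", "GHIS_mean",
                    "Episcore_max", "GERP_RS_max", "REVEL_max", "SIFT_min",
                    "FATHMM_min", "three_prime_UTR_num", "LRT_pred_D",
                    "SIFT_pred_D", "Polyphen2_HDIV_pred_D",
                    "Polyphen2_HVAR_pred_D", "dELS_num", "OMIM_gene_num",
                    "Morbid_gene_num") %in% reg$name))
  # declared composition: 1 length + 24 max + 10 min + 2 mean + 42 counts
  expect_equal(as.integer(table(reg$kind)[c("length", "max", "min", "mean",
                                            "count")]),
               c(1L, 24L, 10L, 2L, 42L))
  # dosage counts cover HI/TS at each score level
  expect_equal(sum(reg$source == "dosage"), 12)
  expect_equal(sum(reg$source == "regions"), 6)
  expect_equal(sum(reg$source == "site_categorical"), 17)
})

test_that("registry config round-trips and invalid configs are rejected", {
  reg <- default_feature_registry()
  path <- withr::local_tempfile(fileext = ".cfg")
  write_feature_registry(reg, path)
  expect_equal(load_feature_registry(path), reg)

  empty <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# only a comment", ""), empty)
  expect_equal(nrow(load_feature_registry(empty)), 0)

  dup <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("pLI_max max gene_scores pLI", "pLI_max max gene_scores pLI"), dup)
  expect_error(load_feature_registry(dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".cfg")
  writeLines("foo max genes protein_coding", bad)
  expect_error(load_feature_registry(bad), "numeric source")
  bad2 <- withr::local_tempfile(fileext = ".cfg")
  writeLines("bar length site_numeric REVEL", bad2)
  expect_error(load_feature_registry(bad2), "cnv_itself")
})

test_that("CNV tables parse per dialect with normalization and skip rules", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t1000\t5000\tDEL\tpathogenic", bed)
  r <- read_cnv_table(bed, "generic_bed")
  expect_equal(r$cnv_type, "loss")
  expect_equal(r$label, "pathogenic")
  expect_equal(c(r$start, r$end), c(1000, 5000))

  gn <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tSVTYPE\tFILTER\tAF\tAN",
               "1\t1001\t2000\tINS\tPASS\t0.5\t3000",
               "1\t3001\t4000\tDUP\tPASS\t0.5\t3000"), gn)
  r <- read_cnv_table(gn, "gnomad")
  expect_equal(nrow(r), 1)        # the INS row is skipped
  expect_equal(r$cnv_type, "gain")
  expect_equal(r$start, 3000)     # 1-based inclusive converted to 0-based

  cv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\ttype\tclinical_significance\treview_status",
               "1\t101\t900\tduplication\tLikely benign\tpractice guideline"), cv)
  r <- read_cnv_table(cv, "clinvar")
  expect_equal(r$cnv_type, "gain")
  expect_equal(r$label, "likely_benign")

  expect_error(read_cnv_table(bed, "ucsc"), "dialect")
  badco <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\ttype\tclinical_significance\treview_status",
               "1\tx\t900\tloss\tbenign\tpractice guideline"), badco)
  expect_error(read_cnv_table(badco, "clinvar"), "line 1")
})

test_that("annotation track readers convert conventions and keep missing explicit", {
  st <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tREVEL\tLRT_pred",
               "chr1\t100\t.\tD",
               "1\t200\t0.5\t."), st)
  s <- read_site_scores(st)
  expect_true(is.na(s$REVEL[1]))   # "." is missing, not 0
  expect_equal(s$pos, c(99, 199))
  expect_equal(s$chrom, c("1", "1"))
  expect_true(is.na(s$LRT_pred[2]))

  rg <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t100\t500\tdELS", "2\t700\t900\tPLS"), rg)
  r <- read_region_track(rg)
  expect_equal(r$region_class, c("dELS", "PLS"))
  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("1\t100\t500\tTAD", bad)
  expect_error(read_region_track(bad), "region class")

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(paste0("1\tensembl\tgene\t1001\t5000\t.\t+\t.\t",
                    "ID=ENSG1;biotype=protein_coding"), gff)
  g <- read_gene_track(gff, format = "gff3")
  expect_equal(g$biotype, "protein_coding")
  expect_equal(g$start, 1000)
  expect_equal(g$gene_id, "ENSG1")
})

test_that("feature matrix I/O round-trips including imputation medians", {
  bundle <- make_tiny_bundle()
  reg <- make_tiny_registry()
  cnvs <- cnv_records("1", c(0, 10000), c(10000, 40000), "loss", "benign")
  fm <- annotate_cnvs(cnvs, bundle, reg)
  med <- suppressWarnings(fit_impute(fm))
  fmi <- apply_impute(fm, med)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fmi, path)
  header <- strsplit(readLines(path, 1), "\t")[[1]]
  expect_equal(length(header), nrow(reg) + 1)  # id column + features
  expect_true(file.exists(paste0(path, ".medians.tsv")))
  back <- read_feature_matrix(path, reg)
  expect_equal(back$values, fmi$values)
  expect_equal(back$medians, med, ignore_attr = TRUE)

  # empty matrix still writes a header-only file
  fm0 <- new_feature_matrix(reg, fmi$values[0, , drop = FALSE])
  p0 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm0, p0)
  expect_equal(length(readLines(p0)), 1)
})

test_that("bundle directory round-trip preserves every track", {
  b <- make_tiny_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  b2 <- load_bundle(dir)
  expect_equal(b2$genes$start, b$genes$start)
  expect_equal(b2$genes$pLI, b$genes$pLI)
  expect_equal(b2$sites$pos, b$sites$pos)
  expect_equal(b2$sites$LRT_pred, b$sites$LRT_pred)
  expect_equal(b2$regions$region_class, b$regions$region_class)
  expect_equal(b2$utrs$utr_kind, b$utrs$utr_kind)
})
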