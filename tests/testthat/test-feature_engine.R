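test_that("aggregate_score applies direction-aware methods and keeps empty missing", {
  expect_equal(aggregate_score(c(0.1, 0.9, 0.5), "max"), 0.9)
  expect_equal(aggregate_score(c(0.1, 0.9, 0.5), "min"), 0.1)
  expect_equal(aggregate_score(c(0.2, 0.4), "mean"), 0.3)
  expect_true(is.na(aggregate_score(numeric(), "mean")))
  expect_error(aggregate_score(1:3, "median"), "unknown method")
})

test_that("count features count overlapping records of the selected kind", {
  bundle <- make_tiny_bundle()
  reg <- make_tiny_registry()
  # spans genes G1..G5: 3 protein-coding, 1 pseudogene, 1 ncRNA
  cnv <- cnv_records("1", 0, 40000, "loss", "pathogenic")
  def <- reg[reg$name == "protein_coding_gene_num", ]
  expect_equal(count_overlapping(cnv, bundle, def), 3)
  # LRT_pred D calls among overlapped sites at pos 1500..31000: D at 1500, 6000
  def <- reg[reg$name == "LRT_pred_D", ]
  expect_equal(count_overlapping(cnv, bundle, def), 2)
  far <- cnv_records("2", 0, 1000, "loss", "benign")
  expect_equal(count_overlapping(far, bundle, reg[reg$name == "PLS_num", ]), 0)
})

test_that("annotation yields the full registry vector with correct edge semantics", {
  full <- generate_bundle(fixture_spec(seed = 71, n_genes = 30, n_sites = 150,
                                       n_regions = 20))
  fv <- annotate_cnv(cnv_records("1", 0, 40000, "loss", "benign"),
                     full, default_feature_registry())
  expect_length(fv$values, 79)
  # a selector the bundle does not declare is a configuration error
  tiny_reg <- feature_registry(data.frame(
    name = "CADD_phred_max", kind = "max", source = "site_numeric",
    selector = "CADD_phred", category = NA))
  expect_error(
    annotate_cnvs(cnv_records("1", 0, 100, "loss", "benign"),
                  make_tiny_bundle(), tiny_reg),
    "not present in bundle")

  bundle <- make_tiny_bundle()
  cnvs <- cnv_records("1", c(0, 60000), c(40000, 70000), "loss", "benign",
                      record_id = c("covered", "desert"))
  reg <- make_tiny_registry()
  fm <- annotate_cnvs(cnvs, bundle, reg)
  desert <- fm$values["desert", ]
  expect_equal(unname(desert["length"]), 10000)
  agg <- reg$name[reg$kind %in% c("max", "min", "mean")]
  cnt <- reg$name[reg$kind == "count"]
  expect_true(all(is.na(desert[agg])))
  expect_true(all(desert[cnt] == 0))

  # determinism: identical coordinates give identical vectors
  twin <- cnv_records("1", c(0, 0), c(40000, 40000), "loss", "benign",
                      record_id = c("a", "b"))
  fm2 <- annotate_cnvs(twin, bundle, reg)
  expect_equal(unname(fm2$values[1, ]), unname(fm2$values[2, ]))
})

test_that("a zero score is distinct from no overlapping record", {
  bundle <- resource_bundle(
    sites = data.frame(chrom = "1", pos = 500, REVEL = 0))
  reg <- feature_registry(data.frame(name = "REVEL_max", kind = "max",
                                     source = "site_numeric",
                                     selector = "REVEL", category = NA))
  cnvs <- cnv_records("1", c(0, 2000), c(1000, 3000), "loss", "benign",
                      record_id = c("hit", "miss"))
  fm <- annotate_cnvs(cnvs, bundle, reg)
  expect_equal(unname(fm$values["hit", 1]), 0)
  expect_true(is.na(fm$values["miss", 1]))
})

test_that("extending a CNV never decreases max/count features nor increases min features", {
  spec <- fixture_spec(seed = 19, n_genes = 80, n_sites = 400, n_regions = 60,
                       genome = c("1" = 1e6))
  bundle <- generate_bundle(spec)
  reg <- default_feature_registry()
  set.seed(23)
  for (i in 1:20) {
    s <- sample(0:8e5, 1); w <- sample(1e3:5e4, 1)
    ext <- sample(1e3:5e4, 1)
    nested <- cnv_records("1", c(s, max(0, s - ext)), c(s + w, s + w + ext),
                          "loss", "benign", record_id = c("inner", "outer"))
    fm <- annotate_cnvs(nested, bundle, reg)
    inner <- fm$values["inner", ]; outer <- fm$values["outer", ]
    up <- reg$kind %in% c("max", "count", "length")
    dn <- reg$kind == "min"
    both <- !is.na(inner) & !is.na(outer)
    expect_true(all(outer[up & both] >= inner[up & both]))
    expect_true(all(outer[dn & both] <= inner[dn & both]))
    # an aggregation defined on the inner interval is defined on the outer
    expect_true(all(!is.na(outer[!is.na(inner)])))
  }
})

test_that("annotation matches the naive per-record oracle and ignores record order", {
  bundle <- make_tiny_bundle()
  reg <- make_tiny_registry()
  set.seed(77)
  starts <- sample(0:49000, 30)
  widths <- sample(500:20000, 30, replace = TRUE)
  cnvs <- cnv_records("1", starts, starts + widths, "loss", "benign")
  fm <- annotate_cnvs(cnvs, bundle, reg)
  for (i in seq_len(nrow(cnvs)))
    expect_equal(unname(fm$values[i, ]),
                 unname(oracle_annotate(cnvs[i, ], bundle, reg)))

  shuf <- bundle
  set.seed(3)
  shuf$genes <- shuf$genes[sample(nrow(shuf$genes)), ]
  shuf$sites <- shuf$sites[sample(nrow(shuf$sites)), ]
  shuf$regions <- shuf$regions[sample(nrow(shuf$regions)), ]
  shuf$utrs <- shuf$utrs[sample(nrow(shuf$utrs)), ]
  fm2 <- annotate_cnvs(cnvs, bundle, reg)
  fm3 <- annotate_cnvs(cnvs, shuf, reg)
  expect_equal(fm3$values, fm2$values)
})

test_that("median imputation fits on train and applies train medians to test", {
  reg <- feature_registry(data.frame(name = c("REVEL_max", "SIFT_min"),
                                     kind = c("max", "min"),
                                     source = "site_numeric",
                                     selector = c("REVEL", "SIFT"),
                                     category = NA))
  train_vals <- matrix(c(1, 2, NA, 4, 5, 5, 5, 5), ncol = 2,
                       dimnames = list(paste0("t", 1:4), reg$name))
  train <- new_feature_matrix(reg, train_vals)
  med <- fit_impute(train)
  expect_equal(unname(med["REVEL_max"]), 2)  # median of {1,2,4}
  filled <- apply_impute(train, med)
  expect_equal(unname(filled$values[3, 1]), 2)
  expect_false(any(filled$missing_mask))
  # untouched where observed
  expect_equal(filled$values[, 2], train_vals[, 2])

  test_vals <- matrix(c(100, NA, 200, 7, 8, 9), ncol = 2,
                      dimnames = list(paste0("s", 1:3), reg$name))
  testm <- apply_impute(new_feature_matrix(reg, test_vals), med)
  expect_equal(unname(testm$values[2, 1]), 2)  # train median, not test's 150

  all_na <- matrix(c(NA, NA, 1, 2), ncol = 2,
                   dimnames = list(NULL, reg$name))
  expect_warning(m2 <- fit_impute(new_feature_matrix(reg, all_na)),
                 "entirely missing")
  expect_equal(unname(m2["REVEL_max"]), 0)
  expect_error(apply_impute(train, med[1]), "no median")
})
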