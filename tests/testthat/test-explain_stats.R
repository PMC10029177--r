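test_that("Mann-Whitney U matches enumeration, symmetry and the AUC identity", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p.value, 2 / 6)

  x <- c(1, 2, 3, 4)
  res <- mann_whitney_u(x, x)
  expect_equal(res$U, length(x)^2 / 2)
  expect_equal(res$p.value, 1)

  set.seed(17)
  for (i in 1:15) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- sample(1:6, nx, replace = TRUE)   # ties likely
    y <- sample(1:6, ny, replace = TRUE)
    res <- mann_whitney_u(x, y)
    expect_equal(res$p.value, oracle_mw_p(x, y))
    expect_equal(res$U, mann_whitney_u(y, x)$U * -1 + nx * ny)
    expect_equal(res$U / (nx * ny),
                 roc_auc(c(x, y), c(rep(1, nx), rep(0, ny))))
  }
  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
})

test_that("large-sample Mann-Whitney approximation matches the standard test", {
  set.seed(29)
  x <- rnorm(40); y <- rnorm(45, 0.4)   # no ties: wilcox.test is exact-free
  ours <- mann_whitney_u(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$U, unname(ref$statistic))
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("Kruskal-Wallis and Bonferroni post hoc behave per definition", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  kw <- kruskal_wallis(g)
  expect_equal(kw$H, 0)
  expect_error(kruskal_wallis(list(1:3)), "at least 2")

  set.seed(5)
  g <- list(a = rnorm(10), b = rnorm(10, 1), c = rnorm(10, 2))
  ph <- pairwise_posthoc(g)
  expect_equal(nrow(ph), 3)   # k(k-1)/2 comparisons
  expect_true(all(ph$p_adjusted <= 1))
  expect_true(all(ph$p_adjusted >= ph$p))
  expect_equal(ph$p_adjusted, pmin(1, ph$p * 3))
})

test_that("SHAP attributions are additive and localize to the informative feature", {
  toy <- make_toy_binary()
  task <- task_spec("binary", "loss")
  m <- train_model(toy$x, toy$y, default_hp(), task, seed = 9)
  attr <- shap_attributions(m, toy$x)
  margin <- model_margin(m, toy$x)
  expect_lt(max(abs(rowSums(attr$values) + attr$base - margin)),
            1e-6 * max(1, max(abs(margin))))

  # single tree with one split: the split feature carries the whole
  # margin deviation
  stump <- train_model(toy$x, toy$y,
                       list(eta = 1, gamma = 0, max_depth = 1,
                            min_child_weight = 1, subsample = 1, nrounds = 1),
                       task, seed = 9)
  a1 <- shap_attributions(stump, toy$x)
  expect_true(all(abs(a1$values[, c("f2", "f3")]) < 1e-12))
  expect_true(any(abs(a1$values[, "f1"]) > 0))
  expect_equal(rank_features_by_shap(a1, top_k = 1), "f1")

  # multiclass additivity per class
  set.seed(11)
  x5 <- cbind(f1 = rnorm(150), f2 = rnorm(150))
  y5 <- PATHOGENICITY_LEVELS[cut(x5[, 1], c(-Inf, -1, -0.3, 0.3, 1, Inf),
                                 labels = FALSE)]
  t5 <- task_spec("five_tier", "gain")
  m5 <- train_model(x5, y5, default_hp(), t5, seed = 2)
  a5 <- shap_attributions(m5, x5)
  m5_margin <- model_margin(m5, x5)
  recon <- apply(a5$values, c(1, 2), sum) + a5$base
  expect_lt(max(abs(recon - m5_margin)),
            1e-6 * max(1, max(abs(m5_margin))))
})

test_that("SHAP ranking is row-order invariant with registry-order tie-break", {
  toy <- make_toy_binary()
  task <- task_spec("binary", "loss")
  m <- train_model(toy$x, toy$y, default_hp(), task, seed = 9)
  a <- shap_attributions(m, toy$x)
  perm <- sample(nrow(toy$x))
  a2 <- shap_attributions(m, toy$x[perm, ])
  expect_equal(rank_features_by_shap(a), rank_features_by_shap(a2))
  expect_length(rank_features_by_shap(a, top_k = 2), 2)
  expect_length(rank_features_by_shap(a, top_k = 99), 3)

  zero <- a
  zero$values[] <- 0
  expect_equal(rank_features_by_shap(zero), colnames(toy$x))
})

test_that("SHAP dependence recovers a planted monotone effect and its threshold", {
  set.seed(41)
  n <- 400
  x <- cbind(signal = runif(n, 0, 10), noise = rnorm(n))
  y <- ifelse(x[, "signal"] + rnorm(n, 0, 0.8) > 5, "pathogenic", "benign")
  task <- task_spec("binary", "loss")
  m <- train_model(x, y, default_hp(), task, seed = 3)
  a <- shap_attributions(m, x)
  dep <- shap_dependence(a, x, "signal")
  expect_gt(cor(dep$data$value, dep$data$attribution, method = "spearman"),
            0.8)
  expect_false(is.na(dep$threshold))
  expect_gt(dep$threshold, 3); expect_lt(dep$threshold, 7)

  dep_n <- shap_dependence(a, x, "noise")
  expect_lt(sum(abs(dep_n$data$attribution)),
            sum(abs(dep$data$attribution)) * 0.2)
  expect_error(shap_dependence(a, x, "absent"), "unknown feature")
})

test_that("element proportions normalize per group and reflect planted enrichment", {
  bundle <- make_tiny_bundle()
  # G3 is the only pseudogene; a CNV over just G3 is 100% pseudogene
  cnvs <- cnv_records("1", c(12500, 0), c(17000, 40000), "loss",
                      c("benign", "pathogenic"))
  pr <- element_proportions(cnvs, bundle)
  ps <- pr[pr$group == "benign", ]
  expect_equal(ps$pseudogene, 1)
  rowsums <- rowSums(pr[, ELEMENT_CATEGORIES <- c("pseudogene", "OMIM_gene",
                                                  "Morbid_gene", "RNA_gene",
                                                  "protein_coding_gene")])
  expect_true(all(abs(rowsums[pr$defined] - 1) < 1e-9))

  # a group overlapping nothing is flagged undefined
  lone <- cnv_records("2", 0, 100, "loss", "benign")
  pr0 <- element_proportions(lone, bundle)
  expect_false(pr0$defined)

  spec <- fixture_spec(seed = 53, class_counts = c(benign = 150,
                                                   pathogenic = 150))
  b <- generate_bundle(spec)
  cn <- generate_cnv_set(spec, b)
  pr <- element_proportions(cn[cn$cnv_type == "loss", ], b)
  expect_gt(pr$Morbid_gene[pr$group == "pathogenic"],
            pr$Morbid_gene[pr$group == "benign"])
})

test_that("differential analysis selects planted features and drops all-zero rows", {
  spec <- fixture_spec(seed = 67, class_counts = c(benign = 200,
                                                   pathogenic = 200))
  b <- generate_bundle(spec)
  cn <- generate_cnv_set(spec, b)
  cn <- cn[cn$cnv_type == "loss", ]
  fm <- annotate_cnvs(cn, b)
  fm <- apply_impute(fm, suppressWarnings(fit_impute(fm)))
  res <- differential_top_features(fm, cn$label, top_k = 10)
  expect_length(res$features, 10)
  expect_true(all(c("length", "Morbid_gene_num") %in% res$features))
  expect_true(all(rowSums(res$matrix != 0) > 0))
  expect_equal(nrow(res$matrix), length(res$labels))
  # the signed offset log is defined everywhere (negative scores included)
  # and maps 0 to exactly 0
  expect_true(all(is.finite(res$matrix)))
  reg0 <- feature_registry(data.frame(name = "GERP_RS_max", kind = "max",
                                      source = "site_numeric",
                                      selector = "GERP_RS", category = NA))
  fm0 <- new_feature_matrix(reg0, matrix(c(0, -3, 99), ncol = 1,
                                         dimnames = list(NULL, "GERP_RS_max")))
  r0 <- differential_top_features(
    fm0, c("benign", "benign", "pathogenic"), top_k = 1)
  expect_equal(unname(r0$matrix[, 1]), c(-log10(4), 2))  # all-zero row dropped
})

test_that("distribution statistics compare every group against the benign reference", {
  spec <- fixture_spec(seed = 83, n_genes = 150, n_sites = 800,
                       class_counts = c(benign = 80, likely_benign = 40,
                                        uncertain_significance = 40,
                                        likely_pathogenic = 40,
                                        pathogenic = 80))
  b <- generate_bundle(spec)
  cn <- generate_cnv_set(spec, b)
  cn <- cn[cn$cnv_type == "loss", ]
  fm <- annotate_cnvs(cn, b)
  st <- feature_distribution_stats(fm, cn$label, c("length", "LOEUF_min"))
  expect_setequal(st$length$vs_reference$group,
                  setdiff(PATHOGENICITY_LEVELS, "benign"))
  expect_true(all(st$length$vs_reference$p >= 0 &
                  st$length$vs_reference$p <= 1))
  # the planted length effect separates pathogenic from benign
  expect_lt(st$length$vs_reference$p[
    st$length$vs_reference$group == "pathogenic"], 0.001)
  expect_equal(nrow(st$length$posthoc), choose(5, 2))
})
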