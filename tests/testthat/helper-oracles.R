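# Independent brute-force oracles, deliberately naive: they share no code
# with the implementation paths they check.

# Shared integer positions of two 0-based half-open intervals.
oracle_overlap_bp <- function(a, b) {
  if (cnvpatho::norm_chrom(a$chrom) != cnvpatho::norm_chrom(b$chrom)) return(0)
  length(intersect(seq(a$start, a$end - 1), seq(b$start, b$end - 1)))
}

# All-pairs concordance AUC with half credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Exact two-sided Mann-Whitney p by bitmask enumeration of every assignment
# of the pooled values to the two groups (handles ties).
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  u_of <- function(xs, ys) {
    u <- 0
    for (a in xs) for (b in ys)
      u <- u + if (a > b) 1 else if (a == b) 0.5 else 0
    u
  }
  u_obs <- u_of(x, y)
  us <- c()
  for (mask in 0:(2^n - 1)) {
    sel <- which(intToBits(mask)[1:n] == 1)
    if (length(sel) != nx) next
    us <- c(us, u_of(pooled[sel], pooled[-sel]))
  }
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# Naive per-record annotation of one CNV: plain loops and arithmetic, no
# interval index. Mirrors the registry semantics feature by feature.
oracle_annotate <- function(cnv, bundle, registry) {
  hits_iv <- function(track) {
    if (nrow(track) == 0) return(integer())
    which(vapply(seq_len(nrow(track)), function(i)
      track$chrom[i] == cnv$chrom &&
        min(cnv$end, track$end[i]) > max(cnv$start, track$start[i]),
      logical(1)))
  }
  hits_pos <- function(track) {
    if (nrow(track) == 0) return(integer())
    which(track$chrom == cnv$chrom & track$pos >= cnv$start &
          track$pos < cnv$end)
  }
  g <- hits_iv(bundle$genes); u <- hits_iv(bundle$utrs)
  r <- hits_iv(bundle$regions); s <- hits_pos(bundle$sites)
  out <- numeric(nrow(registry)); names(out) <- registry$name
  for (i in seq_len(nrow(registry))) {
    def <- registry[i, ]
    out[i] <- switch(def$source,
      cnv_itself = cnv$end - cnv$start,
      gene_scores = {
        v <- bundle$genes[g, def$selector]; v <- v[!is.na(v)]
        if (!length(v)) NA_real_
        else switch(def$kind, max = max(v), min = min(v), mean = mean(v))
      },
      site_numeric = {
        v <- bundle$sites[s, def$selector]; v <- v[!is.na(v)]
        if (!length(v)) NA_real_
        else switch(def$kind, max = max(v), min = min(v), mean = mean(v))
      },
      site_categorical = {
        v <- bundle$sites[s, def$selector]
        sum(!is.na(v) & v == def$category)
      },
      genes = sum(bundle$genes$biotype[g] == def$selector),
      utr = sum(bundle$utrs$utr_kind[u] == def$selector),
      regions = sum(bundle$regions$region_class[r] == def$selector),
      dosage = {
        parts <- strsplit(def$selector, ":")[[1]]
        col <- if (parts[1] == "HI") "hi_score" else "ts_score"
        v <- as.character(bundle$genes[g, col])
        if (parts[2] == "NA") sum(is.na(v) | v == "NA")
        else sum(!is.na(v) & v == parts[2])
      },
      omim_morbid = {
        fl <- if (def$selector == "omim") bundle$genes$is_omim[g]
              else bundle$genes$is_morbid[g]
        sum(fl, na.rm = TRUE)
      })
  }
  out
}

# Small deterministic bundle used across tests: a 100 kb toy genome.
make_tiny_bundle <- function() {
  genes <- data.frame(
    chrom = "1",
    start = c(1000, 5000, 12000, 20000, 30000, 42000),
    end = c(4000, 9000, 18000, 26000, 36000, 50000),
    gene_id = paste0("G", 1:6),
    biotype = c("protein_coding", "protein_coding", "pseudogene",
                "ncRNA", "protein_coding", "other"),
    is_omim = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
    is_morbid = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    hi_score = c("3", "0", "NA", "40", "1", "2"),
    ts_score = c("40", "NA", "3", "0", "2", "1"),
    pLI = c(0.99, 0.1, NA, 0.5, 0.8, 0.2),
    Episcore = c(0.9, 0.2, 0.4, NA, 0.6, 0.3),
    LOEUF = c(0.1, 2.5, 8, 4, 1, NA),
    GHIS = c(0.7, 0.3, 0.5, 0.4, NA, 0.6),
    stringsAsFactors = FALSE)
  utrs <- data.frame(
    chrom = "1", start = c(1000, 3500, 5000, 8500),
    end = c(1400, 4000, 5400, 9000),
    utr_kind = c("five_prime", "three_prime", "five_prime", "three_prime"),
    parent_gene = c("G1", "G1", "G2", "G2"), stringsAsFactors = FALSE)
  sites <- data.frame(
    chrom = "1", pos = c(1500, 2500, 6000, 13000, 21000, 31000, 45000),
    REVEL = c(0.9, 0.2, NA, 0.5, 0.7, 0.1, 0.4),
    GERP_RS = c(5.5, -2, 3, 1, NA, 4, 2),
    SIFT = c(0.01, 0.6, 0.3, NA, 0.05, 0.9, 0.5),
    LRT_pred = c("D", "N", "D", "U", NA, "N", "D"),
    SIFT_pred = c("D", "T", "T", "D", "T", NA, "D"),
    stringsAsFactors = FALSE)
  regions <- data.frame(
    chrom = "1", start = c(2000, 7000, 14000, 22000, 33000),
    end = c(2500, 7600, 14800, 23000, 33900),
    region_class = c("PLS", "dELS", "CTCF_bound", "pELS", "DNase_H3K4me3"),
    stringsAsFactors = FALSE)
  cnvpatho::resource_bundle(genes = genes, utrs = utrs, sites = sites,
                            regions = regions)
}

# Registry restricted to selectors available in the tiny bundle.
make_tiny_registry <- function() {
  reg <- cnvpatho::default_feature_registry()
  keep <- reg$source %in% c("cnv_itself", "genes", "utr", "regions",
                            "dosage", "omim_morbid") |
    (reg$source == "gene_scores" &
       reg$selector %in% c("pLI", "Episcore", "LOEUF", "GHIS")) |
    (reg$source == "site_numeric" &
       reg$selector %in% c("REVEL", "GERP_RS", "SIFT")) |
    (reg$source == "site_categorical" &
       reg$selector %in% c("LRT_pred", "SIFT_pred"))
  cnvpatho::feature_registry(reg[keep, ])
}

# Tiny separable training set for classifier/SHAP tests.
make_toy_binary <- function(n = 120, seed = 5, sep = TRUE) {
  set.seed(seed)
  x <- cbind(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  y <- if (sep) ifelse(x[, "f1"] > 0, "pathogenic", "benign")
       else sample(c("benign", "pathogenic"), n, replace = TRUE)
  rownames(x) <- sprintf("r%03d", seq_len(n))
  list(x = x, y = y)
}

default_hp <- function(nrounds = 50)
  list(eta = 0.3, gamma = 0, max_depth = 4, min_child_weight = 1,
       subsample = 1, nrounds = nrounds)
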