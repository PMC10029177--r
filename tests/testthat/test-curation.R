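test_that("per-database filters retain exactly the qualifying rows", {
  raw <- generate_raw_db_tables(seed = 5)
  m <- raw$manifest
  for (src in names(m$source_retained)) {
    recs <- read_cnv_table(raw$files[[src]], src)
    res <- apply_source_filter(recs, src)
    if (src == "clingen_region") {
      expect_equal(res$report$n_retained,
                   unname(m$source_retained[[src]]))
      expect_equal(nrow(res$records), m$clingen_emitted_records)
      # HI score 3 region becomes a pathogenic loss; 40 becomes benign
      expect_true(any(res$records$cnv_type == "loss" &
                      res$records$label == "pathogenic"))
      expect_true(any(res$records$cnv_type == "gain" &
                      res$records$label == "pathogenic"))
      expect_true(all(res$records$label %in% c("pathogenic", "benign")))
    } else {
      expect_equal(nrow(res$records), unname(m$source_retained[[src]]))
    }
    expect_equal(unlist(res$report$excluded_by)[names(m$source_excluded[[src]])],
                 m$source_excluded[[src]])
    # conservation: every input row accounted for exactly once
    expect_equal(res$report$n_in,
                 res$report$n_retained + sum(unlist(res$report$excluded_by)))
    if (src %in% c("dgv", "decipher", "gnomad"))
      expect_true(all(res$records$label == "benign"))
  }
  gn <- read_cnv_table(raw$files$gnomad, "gnomad")
  expect_equal(nrow(gn), m$gnomad_parsed_rows)  # INS dropped at parse
})

test_that("non-redundant merge applies length, conflict and multi-significance rules", {
  raw <- generate_raw_db_tables(seed = 5)
  m <- raw$manifest$merge
  sets <- lapply(setdiff(names(raw$manifest$source_retained), "validation"),
                 function(src) {
    apply_source_filter(read_cnv_table(raw$files[[src]], src), src)$records
  })
  res <- merge_nonredundant(sets)
  expect_equal(res$report$n_in, m$n_in)
  expect_equal(res$report$excluded_by$length_filter, m$length_filter)
  expect_equal(res$report$excluded_by$conflicting_70pct, m$conflicting_70pct)
  expect_equal(res$report$excluded_by$multiple_significance,
               m$multiple_significance)
  expect_equal(nrow(res$records), m$retained)

  # exhaustive pair scan: no surviving same-type pair conflicts at >= 70%
  r <- res$records
  for (i in seq_len(nrow(r) - 1)) for (j in (i + 1):nrow(r)) {
    if (r$cnv_type[i] != r$cnv_type[j]) next
    ro <- reciprocal_overlap(r[i, c("chrom", "start", "end")],
                             r[j, c("chrom", "start", "end")])
    conflicting <-
      (r$label[i] %in% c("benign", "likely_benign") &&
       r$label[j] %in% c("pathogenic", "likely_pathogenic")) ||
      (r$label[j] %in% c("benign", "likely_benign") &&
       r$label[i] %in% c("pathogenic", "likely_pathogenic"))
    expect_false(ro >= 0.70 && conflicting)
  }

  # order independence: shuffled inputs give the same retained set
  set.seed(8)
  sets_shuf <- lapply(rev(sets), function(s) s[sample(nrow(s)), ])
  res2 <- merge_nonredundant(sets_shuf)
  expect_equal(sort(res2$records$record_id), sort(res$records$record_id))
})

test_that("conflicting pairs remove both members; concordant pairs survive", {
  mk <- function(start, end, label, id)
    cnv_records("1", start, end, "loss", label, source = "t", record_id = id)
  conflict <- rbind(mk(0, 1000, "benign", "b1"),
                    mk(100, 1000, "pathogenic", "p1"))
  class(conflict) <- c("cnv_records", "data.frame")
  expect_equal(reciprocal_overlap(conflict[1, 1:3], conflict[2, 1:3]), 0.9)
  res <- merge_nonredundant(list(conflict))
  expect_equal(nrow(res$records), 0)
  expect_equal(res$report$excluded_by$conflicting_70pct, 2)

  concordant <- rbind(mk(0, 1000, "benign", "b1"),
                      mk(100, 1000, "benign", "b2"))
  class(concordant) <- c("cnv_records", "data.frame")
  res <- merge_nonredundant(list(concordant))
  expect_equal(nrow(res$records), 2)

  # VUS conflicts with neither side
  vus <- rbind(mk(0, 1000, "uncertain_significance", "v1"),
               mk(100, 1000, "pathogenic", "p1"))
  class(vus) <- c("cnv_records", "data.frame")
  expect_equal(nrow(merge_nonredundant(list(vus))$records), 2)

  # cross-type pairs are never compared
  cross <- rbind(mk(0, 1000, "benign", "b1"),
                 cnv_records("1", 0, 1000, "gain", "pathogenic",
                             source = "t", record_id = "g1"))
  class(cross) <- c("cnv_records", "data.frame")
  expect_equal(nrow(merge_nonredundant(list(cross))$records), 2)

  short <- mk(0, 40, "benign", "s1")
  res <- merge_nonredundant(list(short))
  expect_equal(res$report$excluded_by$length_filter, 1)
})

test_that("validation dedup keeps the shorter of concordant >=90% pairs", {
  raw <- generate_raw_db_tables(seed = 5)
  v <- raw$manifest$validation
  recs <- read_cnv_table(raw$files$validation, "generic_bed")
  res <- dedup_validation(recs)
  expect_equal(res$report$excluded_by$conflicting_70pct, v$conflicting_70pct)
  expect_equal(res$report$excluded_by$longer_of_90pct_pair,
               v$longer_of_90pct_pair)
  expect_equal(res$report$excluded_by$length_filter, v$length_filter)
  expect_equal(nrow(res$records), v$retained)
  expect_true(v$kept_shorter_id %in% res$records$record_id)
  expect_false(v$removed_longer_id %in% res$records$record_id)

  # pair at 0.8 overlap with the same label: both kept
  pair <- cnv_records("1", c(0, 2000), c(10000, 10000), "loss", "benign",
                      record_id = c("a", "b"))
  expect_equal(nrow(dedup_validation(pair)$records), 2)

  # equal-length tie at >= 0.90 overlap: keep the smaller record_id
  tie <- cnv_records("1", c(0, 500), c(10000, 10500), "loss", "pathogenic",
                     record_id = c("idB", "idA"))
  res <- dedup_validation(tie)
  expect_equal(res$records$record_id, "idA")
})
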