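test_that("rt_outlier_filter removes IQR outliers per glycopeptide, bounds inclusive", {
  rec <- make_records(sample_id = paste0("S", 1:5), glycan = "N4H5",
                      auc = 2000, rt = c(10.0, 10.1, 10.2, 10.3, 50.0))
  r <- rt_outlier_filter(rec)
  expect_equal(nrow(r$removed), 1)
  expect_equal(r$removed$rt, 50.0)
  # identical RTs: IQR 0, every point sits on the (inclusive) bound
  same <- make_records(paste0("S", 1:6), "N4H5", 2000, rt = 20)
  expect_equal(nrow(rt_outlier_filter(same)$removed), 0)
  # groups below the minimum size pass through
  small <- make_records(paste0("S", 1:3), "N4H5", 2000, rt = c(10, 11, 99))
  expect_equal(nrow(rt_outlier_filter(small)$removed), 0)
  # filtering is per glycopeptide
  two <- rbind(rec, make_records(paste0("S", 1:5), "N2H7", 2000,
                                 rt = c(49.8, 50, 50.2, 50.4, 50.6)))
  expect_equal(rt_outlier_filter(two)$removed$glycan, "N4H5")
  # idempotent
  once <- rt_outlier_filter(rec)$kept
  expect_identical(rt_outlier_filter(once)$kept, once)
})

test_that("auc_filter drops strictly below the threshold", {
  rec <- make_records(paste0("S", 1:10), "N4H5",
                      auc = c(999.9, 1000, 1000.1, 500, 0, 1e6, 2000, 1, 5000, 999))
  kept <- auc_filter(rec)
  expect_equal(nrow(kept), sum(rec$auc >= 1000))  # enumeration oracle: 5 kept
  expect_equal(nrow(kept), 5)
  expect_true(all(kept$auc >= 1000))
  expect_true(1000 %in% kept$auc)
  expect_identical(auc_filter(kept), kept)  # idempotent
})

test_that("glyco_matrix pivots records and resolves duplicates by max AUC", {
  rec <- rbind(make_records(c("S1", "S2"), "N4H5", c(10, 20)),
               make_records("S1", "N4H5", 99),      # duplicate, higher AUC
               make_records("S1", "N2H7", 5))
  gm <- glyco_matrix(rec)
  expect_equal(dim(gm$abundance), c(2, 2))
  expect_equal(gm$abundance["P1|N100|N4H5", "S1"], 99)
  expect_true(is.na(gm$abundance["P1|N100|N2H7", "S2"]))
  expect_equal(gm$provenance[[1]]$duplicates_resolved_keep_max_auc, 1)
})

test_that("presence_filter drops rows then columns, once, in order", {
  # 12 glycopeptides x 8 samples with a designed pattern; brute-force
  # enumeration oracle computed in-line
  set.seed(21)
  m <- matrix(rpois(96, 5000), nrow = 12,
              dimnames = list(sprintf("P1|N1|G%02d", 1:12), paste0("S", 1:8)))
  m[1, 1:4] <- NA       # row 1 present in 4 -> dropped (threshold 5)
  m[2, 1:5] <- NA       # row 2 present in 3 -> dropped
  m[5:12, 8] <- NA      # sample 8 keeps rows 1:4 minus dropped -> 2 left
  rec <- data.frame(sample_id = rep(colnames(m), each = 12),
                    protein = "P1", glycosite = "N1",
                    glycan = rep(sprintf("G%02d", 1:12)),
                    rt = 30, auc = as.vector(m))
  rec <- rec[!is.na(rec$auc), ]
  gm <- glyco_matrix(rec)
  out <- presence_filter(gm, min_samples = 5, min_glycopeptides = 3)
  keep_rows <- rowSums(!is.na(m)) >= 5
  keep_cols <- colSums(!is.na(m[keep_rows, ])) >= 3
  expect_setequal(rownames(out$abundance), rownames(m)[keep_rows])
  expect_setequal(colnames(out$abundance), colnames(m)[keep_cols])
  # no-op on dense data
  dense <- glyco_matrix(make_records(rep(paste0("S", 1:20), each = 20),
                                     rep(sprintf("G%02d", 1:20), times = 20),
                                     auc = 5000))
  out2 <- presence_filter(dense, 5, 10)
  expect_equal(dim(out2$abundance), c(20, 20))
  # once-through idempotence
  out3 <- presence_filter(out, min_samples = 5, min_glycopeptides = 3)
  expect_equal(out3$abundance, out$abundance)
  # everything removed -> explicit error
  sparse <- glyco_matrix(make_records(paste0("S", 1:3), "N4H5", 2000))
  expect_error(presence_filter(sparse, 5, 10), "review")
})

test_that("quotient total-area normalization equalizes proportional columns", {
  base <- c(1000, 4000, 2500, 8000)
  rec <- do.call(rbind, lapply(1:3, function(i) {
    make_records(paste0("S", i), sprintf("G%d", 1:4), auc = base * c(1, 2, 0.5)[i])
  }))
  gm <- qta_normalize(glyco_matrix(rec))
  m <- gm$abundance
  expect_lt(max(abs(m[, 1] - m[, 2])), 1e-10)
  expect_lt(max(abs(m[, 1] - m[, 3])), 1e-10)
  # single sample: identity
  one <- glyco_matrix(make_records("S1", sprintf("G%d", 1:4), auc = base))
  expect_equal(qta_normalize(one)$abundance, one$abundance)
  # all-missing sample is impossible by construction, but zero totals error
  rec0 <- make_records(c("S1", "S2"), c("G1", "G1"), auc = c(0, 100))
  expect_error(qta_normalize(glyco_matrix(rec0)), "non-positive total")
})

test_that("log_transform is exact, keeps missing, and names bad cells", {
  rec <- rbind(make_records(c("S1", "S2"), "N4H5", c(8, 1024)),
               make_records("S1", "N2H7", 2))
  gm <- log_transform(glyco_matrix(rec), base = 2)
  expect_equal(gm$abundance["P1|N100|N4H5", "S1"], 3)
  expect_true(is.na(gm$abundance["P1|N100|N2H7", "S2"]))
  expect_true(gm$log_scale)
  # round trip
  expect_equal(2^gm$abundance["P1|N100|N4H5", "S2"], 1024, tolerance = 1e-12)
  bad <- glyco_matrix(make_records(c("S1", "S2"), "N4H5", c(-5, 10)))
  expect_error(log_transform(bad), "non-positive abundance.*N4H5.*S1")
})

test_that("site metric degrees match hand computation", {
  # fucosylation 300:100 -> 0.75
  rec <- make_records("S1", c("N4H5F1", "N4H5"), auc = c(300, 100))
  smt <- site_metric_degrees(glyco_matrix(rec))
  expect_equal(smt$fucosylation, 0.75, tolerance = 1e-12)
  # sialylation: biantennary S1 (100) + S0 (100) -> 100 / 400 = 0.25
  rec <- make_records("S1", c("N4H5S1", "N4H5"), auc = c(100, 100))
  smt <- site_metric_degrees(glyco_matrix(rec))
  expect_equal(smt$sialylation, 0.25, tolerance = 1e-12)
  # single fully sialylated biantennary glycoform
  rec <- make_records("S1", "N4H5S2", auc = 500)
  expect_equal(site_metric_degrees(glyco_matrix(rec))$sialylation, 1,
               tolerance = 1e-12)
  # galactosylation: N4H5 (2 gal / 2 ant, 100) + N4H3 (0 gal, 300) -> 0.25
  rec <- make_records("S1", c("N4H5", "N4H3"), auc = c(100, 300))
  expect_equal(site_metric_degrees(glyco_matrix(rec))$galactosylation, 0.25,
               tolerance = 1e-12)
  # oligomannose-only site: no antennae -> sialylation NA, fucosylation 0
  rec <- make_records("S1", "N2H7", auc = 100)
  smt <- site_metric_degrees(glyco_matrix(rec))
  expect_true(is.na(smt$sialylation))
  expect_equal(smt$fucosylation, 0)
})

test_that("degrees are invariant to per-sample rescaling", {
  set.seed(8)
  glycans <- c("N4H5F1", "N4H5S1", "N4H4", "N5H6S2F1", "N2H6")
  rec <- do.call(rbind, lapply(1:6, function(i) {
    make_records(paste0("S", i), glycans, auc = runif(5, 1e3, 1e5))
  }))
  smt1 <- site_metric_degrees(glyco_matrix(rec))
  rec2 <- rec
  scale_by <- setNames(runif(6, 0.1, 10), paste0("S", 1:6))
  rec2$auc <- rec2$auc * scale_by[rec2$sample_id]
  smt2 <- site_metric_degrees(glyco_matrix(rec2))
  for (m in c("fucosylation", "sialylation", "galactosylation")) {
    expect_equal(smt1[[m]], smt2[[m]], tolerance = 1e-12)
  }
})

test_that("dataset descriptors normalize correctly", {
  rec <- make_records("S1", c("N4H5", "N4H5F1", "N5H6"), auc = c(100, 200, 700))
  d <- dataset_descriptors(glyco_matrix(rec))
  expect_equal(unname(d$glycan_type_ratio["complex"]), 1)
  expect_equal(sum(d$glycan_type_ratio), 1)
  expect_equal(sum(d$branching), 1)
  expect_equal(d$avg_fucosylation, 0.2)
  expect_equal(d$complex_glycopeptide_fraction, 1)
  # no sialylated glycoforms -> antenna sialylation 0
  expect_equal(d$avg_antenna_sialylation, 0)
  expect_equal(d$sialylated_antennary_fraction, 0)
})

test_that("glyco_differential flags spiked features and logs degenerate ones", {
  set.seed(12)
  groups <- rep(c("Normal", "G1", "G2", "G3"), times = c(20, 4, 8, 8))
  n <- length(groups)
  mat <- rbind(
    spiked = ifelse(groups == "Normal", 0.4, 0.8) + rnorm(n, 0, 0.05),
    null1 = rnorm(n, 0.5, 0.05),
    null2 = rnorm(n, 0.5, 0.05),
    flat = rep(0.3, n))
  res <- glyco_differential(mat, groups, "two_group")
  expect_true(res$significant[res$feature == "spiked"])
  expect_false("flat" %in% res$feature)
  skipped <- attr(res, "skipped")
  expect_equal(skipped$feature, "flat")
  expect_match(skipped$reason, "zero variance")
  # multi-group route returns a Tukey table for significant features
  resm <- glyco_differential(mat, groups, "multi_group")
  tk <- attr(resm, "tukey")
  expect_true(all(tk$feature %in% resm$feature[resm$significant]))
  expect_equal(nrow(tk[tk$feature == "spiked", ]), 6)
  # a group with < 2 non-missing values skips the feature with a reason
  mat2 <- mat[1:2, ]
  mat2[1, which(groups == "G1")[-1]] <- NA
  mat2[1, which(groups == "G1")[1]] <- NA
  res2 <- glyco_differential(mat2, groups, "multi_group")
  expect_match(attr(res2, "skipped")$reason, "fewer than 2 non-missing")
})
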