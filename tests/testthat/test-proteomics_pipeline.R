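test_that("group_presence_filter implements both readings of the 60% rule", {
  groups <- factor(rep(c("Normal", "G1", "G2", "G3"), each = 3))
  m <- matrix(1, nrow = 4, ncol = 12,
              dimnames = list(paste0("P", 1:4), paste0("S", 1:12)))
  m[1, 4:12] <- NA                      # 100% in Normal, 0% elsewhere
  m[2, c(1, 4, 7, 10)] <- NA            # ~67% in every group
  m[3, c(1:2, 4:5, 7:8, 10:11)] <- NA   # 33% in every group
  f_any <- group_presence_filter(m, groups, 0.6, mode = "any")
  expect_setequal(rownames(f_any), c("P1", "P2", "P4"))
  f_all <- group_presence_filter(m, groups, 0.6, mode = "all")
  expect_setequal(rownames(f_all), c("P2", "P4"))
  expect_equal(attr(f_any, "removed"), 1)
  # brute-force enumeration oracle on a designed 10 x 12 pattern
  set.seed(31)
  m2 <- matrix(rnorm(120), nrow = 10,
               dimnames = list(paste0("Q", 1:10), paste0("S", 1:12)))
  m2[sample(length(m2), 55)] <- NA
  keep <- vapply(seq_len(10), function(i) {
    any(vapply(levels(groups), function(g) {
      mean(!is.na(m2[i, groups == g])) >= 0.6
    }, logical(1)))
  }, logical(1))
  if (any(keep)) {
    expect_setequal(rownames(group_presence_filter(m2, groups, 0.6)),
                    rownames(m2)[keep])
  }
  # idempotent
  expect_equal(group_presence_filter(f_any, groups, 0.6), f_any,
               ignore_attr = TRUE)
})

test_that("impute_missing draws from the down-shifted normal, reproducibly", {
  set.seed(2)
  m <- matrix(rnorm(2000, 25, 2), nrow = 50)
  miss <- sample(length(m), 300)
  m[miss] <- NA
  a <- impute_missing(m, seed = 123)
  b <- impute_missing(m, seed = 123)
  expect_identical(a, b)
  expect_false(identical(a, impute_missing(m, seed = 124)))
  # observed cells never change
  expect_equal(a[-miss], m[-miss])
  expect_false(anyNA(a))
  expect_equal(which(attr(a, "imputed")), sort(miss))
  # moments: larger matrix for a law-of-large-numbers check
  set.seed(3)
  big <- matrix(rnorm(3e4, 25, 2), nrow = 200)
  bmiss <- sample(length(big), 4000)
  big[bmiss] <- NA
  mu <- mean(big, na.rm = TRUE); sdv <- sd(as.vector(big), na.rm = TRUE)
  imp <- impute_missing(big, seed = 9)[bmiss]
  expect_lt(abs(mean(imp) - (mu - 1.8 * sdv)), 0.03 * sdv)
  expect_lt(abs(sd(imp) - 0.3 * sdv), 0.03 * sdv)
  # no missing cells -> identity
  full <- matrix(1:6, 2)
  expect_equal(impute_missing(full, seed = 1), full, ignore_attr = TRUE)
  expect_error(impute_missing(m), "seed")
})

test_that("two_group_volcano classes partition and respect strict bounds", {
  set.seed(13)
  groups <- rep(c("Normal", "G1", "G2", "G3"), times = c(20, 4, 8, 8))
  n <- length(groups)
  pca <- groups != "Normal"
  mat <- rbind(
    up4 = 25 + 2 * pca + rnorm(n, 0, 0.3),       # fold 4
    down4 = 25 - 2 * pca + rnorm(n, 0, 0.3),
    nullp = rnorm(n, 25, 0.3),
    # exactly fold 2 with tiny within-group spread -> significant_only
    exact2 = 25 + 1 * pca + rep(c(0, 1e-6), length.out = n))
  rownames(mat) <- c("up4", "down4", "nullp", "exact2")
  v <- two_group_volcano(mat, groups)
  expect_equal(v$class[v$protein == "up4"], "over2x")
  expect_equal(v$class[v$protein == "down4"], "under0.5x")
  expect_equal(v$class[v$protein == "exact2"], "significant_only")
  expect_equal(sum(table(v$class)), nrow(v))   # partition
  expect_equal(v$fold_change[v$protein == "exact2"], 2, tolerance = 1e-9)
})

test_that("multigroup_anova_tukey recovers a monotone spike and degenerate certainty", {
  set.seed(14)
  groups <- rep(c("Normal", "G1", "G2", "G3"), times = c(12, 6, 8, 8))
  shift <- c(Normal = 0, G1 = 1, G2 = 2, G3 = 3)[groups]
  mat <- rbind(spiked = 25 + shift + rnorm(length(groups), 0, 0.5),
               nullp = rnorm(length(groups), 25, 0.5))
  res <- multigroup_anova_tukey(mat, groups)
  expect_true(res$significant[res$feature == "spiked"])
  tk <- attr(res, "tukey")
  pair_ng3 <- tk$feature == "spiked" &
    ((tk$group1 == "Normal" & tk$group2 == "G3") |
       (tk$group1 == "G3" & tk$group2 == "Normal"))
  expect_lt(tk$p_adj[pair_ng3], 1e-6)
  # zero within-group variance, distinct means
  g2 <- rep(c("a", "b", "c", "d"), each = 2)
  m2 <- matrix(rep(1:4, each = 2), nrow = 1, dimnames = list("x", NULL))
  r2 <- multigroup_anova_tukey(m2, g2)
  expect_lt(r2$p, 1e-12)
  expect_true(all(attr(r2, "tukey")$p_adj < 1e-9))
  expect_error(multigroup_anova_tukey(mat, rep(c("a", "b"), c(33, 1))),
               "at least 2 samples")
})

test_that("cluster_significant separates up from down regulation", {
  set.seed(15)
  groups <- rep(c("Normal", "G1", "G2", "G3"), times = c(12, 4, 6, 6))
  shift <- c(Normal = 0, G1 = 0.4, G2 = 0.8, G3 = 1.2)[groups]
  n <- length(groups)
  up <- t(replicate(8, 25 + shift + rnorm(n, 0, 0.3)))
  dn <- t(replicate(6, 25 - shift + rnorm(n, 0, 0.3)))
  mat <- rbind(up, dn)
  rownames(mat) <- c(paste0("UP", 1:8), paste0("DN", 1:6))
  cl <- cluster_significant(mat, groups, rownames(mat))
  expect_true(all(cl$direction[1:8] == "up"))
  expect_true(all(cl$direction[9:14] == "down"))
  # two anti-correlated proteins end up apart
  two <- rbind(a = 25 + shift, b = 25 - shift)
  cl2 <- cluster_significant(two, groups, c("a", "b"))
  expect_true(cl2$cluster[1] != cl2$cluster[2])
  # identical rows: degenerate tie-break, with a warning from the
  # undefined-correlation handler
  same <- rbind(x = rep(1, n), y = rep(1, n))
  expect_warning(cluster_significant(same, groups, c("x", "y")))
  expect_error(cluster_significant(mat, groups, "UP1"), "at least 2")
})

test_that("grade_scheme_correlation is 1 for identical schemes, ~0 for random", {
  set.seed(16)
  groups <- factor(rep(c("G1", "G2", "G3"), each = 8))
  mat <- matrix(rnorm(40 * 24, 25, 1), nrow = 40,
                dimnames = list(paste0("P", 1:40), paste0("S", 1:24)))
  pairs <- data.frame(group_a = c("G1", "G2", "G3"),
                      group_b = c("G1", "G2", "G3"))
  r <- grade_scheme_correlation(mat, groups, groups, pairs)
  expect_equal(r$pearson_r, rep(1, 3), tolerance = 1e-12)
  # independent random labels on independent data -> near zero on average
  groups_b <- sample(groups)
  r2 <- grade_scheme_correlation(mat, groups, groups_b, pairs)
  expect_true(all(abs(r2$pearson_r) < 0.9))
  # zero-variance vector reported missing
  cm <- matrix(1, nrow = 5, ncol = 24,
               dimnames = list(paste0("C", 1:5), colnames(mat)))
  expect_true(all(is.na(grade_scheme_correlation(cm, groups, groups, pairs)$pearson_r)))
})

test_that("gleason_regroup maps GG grades and normals", {
  g <- gleason_regroup(c(NA, "GG2", "GG3", "GG4", "GG5"))
  expect_equal(as.character(g), c("Normal", "GG2", "GG3_4", "GG3_4", "GG5"))
  expect_error(gleason_regroup("GG7"), "unknown")
})

test_that("zscore_rows standardizes and is affine invariant", {
  set.seed(17)
  m <- matrix(rnorm(60, 10, 3), nrow = 5)
  z <- zscore_rows(m)
  expect_equal(unname(rowMeans(z)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 5), tolerance = 1e-12)
  expect_equal(zscore_rows(3 * m + 7), z, tolerance = 1e-12)
  expect_warning(zc <- zscore_rows(rbind(m, rep(2, 12))), "constant")
  expect_equal(unname(zc[6, ]), rep(0, 12))
})
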