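# Protein-level analysis: group-presence filtering, left-censored
# shifted-normal imputation, two-group volcano statistics, multi-group
# ANOVA/Tukey, up/down clustering of significant proteins and the
# grade-scheme correlation comparison.

.group_means <- function(mat, groups) {
  groups <- droplevels(factor(groups))
  vapply(levels(groups), function(l) {
    rowMeans(mat[, groups == l, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(mat)))
}

#' Group-presence filter for the protein matrix
#'
#' Keeps a protein when its non-missing fraction reaches `fraction` in at
#' least one sample group (`mode = "any"`, the valid-values-in-at-least-one-
#' group convention) or in every group (`mode = "all"`).
#'
#' @param mat proteins x samples log-intensity matrix with `NA` for missing.
#' @param groups group label per sample column.
#' @param fraction required presence fraction (default 0.6).
#' @param mode `"any"` (default) or `"all"`.
#' @return the filtered matrix; the number of removed proteins is attached
#'   as attribute `"removed"`.
#' @export
group_presence_filter <- function(mat, groups, fraction = 0.6,
                                  mode = c("any", "all")) {
  mode <- match.arg(mode)
  groups <- droplevels(factor(groups))
  if (length(groups) != ncol(mat)) {
    stop("`groups` must have one label per sample column")
  }
  frac <- vapply(levels(groups), function(l) {
    rowMeans(!is.na(mat[, groups == l, drop = FALSE]))
  }, numeric(nrow(mat)))
  frac <- matrix(frac, nrow = nrow(mat))
  hit <- frac >= fraction
  keep <- if (mode == "any") rowSums(hit) >= 1 else rowSums(hit) == ncol(hit)
  if (!any(keep)) stop("no proteins pass the group-presence filter")
  out <- mat[keep, , drop = FALSE]
  attr(out, "removed") <- sum(!keep)
  attr(out, "presence") <- list(fraction = fraction, mode = mode)
  out
}

#' Impute missing values from a down-shifted normal distribution
#'
#' Whole-matrix imputation for left-censored missingness: with mu and sigma
#' the mean and standard deviation of all observed values, each missing cell
#' is drawn independently from `Normal(mu - down_shift * sigma,
#' (width * sigma)^2)`. Observed cells are never changed; the imputed-cell
#' mask is attached as attribute `"imputed"`.
#'
#' @param mat log-scale matrix with `NA` for missing values.
#' @param down_shift shift of the imputation distribution in observed-sd
#'   units (default 1.8).
#' @param width spread of the imputation distribution in observed-sd units
#'   (default 0.3).
#' @param seed mandatory RNG seed; the same seed reproduces the imputed
#'   matrix bit-identically.
#' @return the completed matrix.
#' @export
impute_missing <- function(mat, down_shift = 1.8, width = 0.3, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required so the imputation is reproducible")
  }
  miss <- is.na(mat)
  out <- mat
  if (any(miss)) {
    obs <- mat[!miss]
    if (!length(obs)) stop("matrix has no observed values to estimate from")
    mu <- mean(obs)
    sdv <- stats::sd(obs)
    if (is.na(sdv) || sdv == 0) {
      warning("observed values have zero spread; imputing the constant mean")
      sdv <- 0
    }
    set.seed(as.integer(seed))
    out[miss] <- stats::rnorm(sum(miss), mu - down_shift * sdv, width * sdv)
  }
  attr(out, "imputed") <- miss
  attr(out, "imputation") <- list(down_shift = down_shift, width = width,
                                  seed = as.integer(seed))
  out
}

#' Two-group volcano statistics
#'
#' Student's t-test per protein between Normal and cancerous (PCa) samples,
#' Benjamini-Hochberg q-values, and fold changes as the exponentiated
#' difference of group mean log intensities. Direction classes: `over2x`
#' (significant and fold change strictly above `fc_over`), `under0.5x`
#' (significant and strictly below `fc_under`), `significant_only`, `ns`.
#'
#' @param mat imputed proteins x samples log-intensity matrix.
#' @param groups grade labels per column; non-Normal grades are pooled as
#'   PCa.
#' @param alpha FDR level.
#' @param fc_over,fc_under fold-change class bounds (default 2 and 0.5).
#' @param log_base base of the log intensities (default 2).
#' @param var_equal pooled-variance t statistic?
#' @return data frame with one row per tested protein: means, `log_fc`,
#'   `fold_change`, `p`, `q`, `significant`, `class`.
#' @export
two_group_volcano <- function(mat, groups, alpha = 0.05, fc_over = 2,
                              fc_under = 0.5, log_base = 2, var_equal = TRUE) {
  g <- two_group_labels(groups)
  res <- .differential_engine(as.matrix(mat), g, alpha = alpha,
                              two_group = TRUE, var_equal = var_equal)
  lfc <- res$mean_PCa - res$mean_Normal
  fc <- log_base^lfc
  cls <- ifelse(res$significant & fc > fc_over, "over2x",
         ifelse(res$significant & fc < fc_under, "under0.5x",
         ifelse(res$significant, "significant_only", "ns")))
  out <- data.frame(protein = res$feature,
                    mean_Normal = res$mean_Normal, mean_PCa = res$mean_PCa,
                    log_fc = lfc, fold_change = fc,
                    p = res$p, q = res$q, significant = res$significant,
                    class = cls, stringsAsFactors = FALSE)
  attr(out, "skipped") <- attr(res, "skipped")
  out
}

#' Multi-group ANOVA with Tukey HSD post-hoc
#'
#' One-way ANOVA per protein across the supplied groups with BH adjustment
#' across proteins; significant proteins get an all-pairs Tukey HSD table
#' (attribute `"tukey"`).
#'
#' @inheritParams two_group_volcano
#' @param groups multi-level group labels (e.g. Normal/G1/G2/G3 or a Gleason
#'   regrouping), at least 2 samples per group.
#' @param tukey run the post-hoc test?
#' @return data frame of per-protein ANOVA results; see
#'   [glyco_differential()] for the attached attributes.
#' @export
multigroup_anova_tukey <- function(mat, groups, alpha = 0.05, tukey = TRUE) {
  groups <- droplevels(factor(groups))
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  .differential_engine(as.matrix(mat), groups, alpha = alpha,
                       two_group = FALSE, tukey = tukey)
}

#' Split significant proteins into up/down clusters
#'
#' Average-linkage hierarchical clustering of the significant proteins with
#' distance 1 - Spearman correlation, cut at 2 clusters. By default proteins
#' are represented by their per-group mean profiles. The cluster whose mean
#' PCa-minus-Normal intensity difference is larger is labelled `"up"`, the
#' other `"down"`.
#'
#' @param mat imputed log-intensity matrix (all proteins).
#' @param groups grade labels per column (must contain `"Normal"`).
#' @param proteins character vector of significant proteins to cluster
#'   (>= 2).
#' @param profile `"group_means"` (default) or `"samples"` for full
#'   per-sample profiles.
#' @return data frame with `protein`, `cluster` (1/2) and `direction`
#'   (`"up"`/`"down"`).
#' @export
cluster_significant <- function(mat, groups, proteins,
                                profile = c("group_means", "samples")) {
  profile <- match.arg(profile)
  proteins <- intersect(proteins, rownames(mat))
  if (length(proteins) < 2) stop("need at least 2 significant proteins to cluster")
  sub <- mat[proteins, , drop = FALSE]
  prof <- if (profile == "group_means") .group_means(sub, groups) else sub
  cl <- hier_cluster(prof, k = 2, method = "spearman", linkage = "average")
  is_norm <- as.character(groups) == "Normal"
  shift <- rowMeans(sub[, !is_norm, drop = FALSE]) -
    rowMeans(sub[, is_norm, drop = FALSE])
  s1 <- mean(shift[cl == 1]); s2 <- mean(shift[cl == 2])
  up_cluster <- if (isTRUE(s1 >= s2)) 1L else 2L
  data.frame(protein = proteins, cluster = as.integer(cl),
             direction = ifelse(cl == up_cluster, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Correlation of group means between two grading schemes
#'
#' For each declared pair of groups (one from each scheme), the Pearson
#' correlation between the two group-mean intensity vectors across the
#' common proteins. Zero-variance vectors yield `NA`.
#'
#' @param mat log-intensity matrix.
#' @param groups_a,groups_b group labels per column under scheme A and B
#'   (`NA` labels are ignored for that scheme).
#' @param pairs data frame with columns `group_a` and `group_b` naming the
#'   group pairs to correlate.
#' @param proteins optional protein subset (default: all rows).
#' @return `pairs` with an added `pearson_r` column.
#' @export
grade_scheme_correlation <- function(mat, groups_a, groups_b, pairs,
                                     proteins = NULL) {
  proteins <- proteins %||% rownames(mat)
  proteins <- intersect(proteins, rownames(mat))
  if (!length(proteins)) stop("empty protein list")
  sub <- mat[proteins, , drop = FALSE]
  ga <- as.character(groups_a); gb <- as.character(groups_b)
  pairs$pearson_r <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$group_a[i]; b <- pairs$group_b[i]
    ia <- which(!is.na(ga) & ga == a); ib <- which(!is.na(gb) & gb == b)
    if (!length(ia) || !length(ib)) next
    va <- rowMeans(sub[, ia, drop = FALSE], na.rm = TRUE)
    vb <- rowMeans(sub[, ib, drop = FALSE], na.rm = TRUE)
    pairs$pearson_r[i] <- cor_coef(va, vb, "pearson")
  }
  pairs
}

#' Regroup Gleason grades to match the pathological-grade resolution
#'
#' Cancer samples are regrouped as GG2, GG3+GG4 (`"GG3_4"`) and GG5; samples
#' without a Gleason grade (normals) are labelled `"Normal"`.
#'
#' @param gleason character vector of Gleason grade labels (GG2-GG5) with
#'   `NA` for normal samples.
#' @return factor with levels `Normal`, `GG2`, `GG3_4`, `GG5`.
#' @export
gleason_regroup <- function(gleason) {
  g <- as.character(gleason)
  out <- ifelse(is.na(g) | g == "", "Normal",
         ifelse(g == "GG2", "GG2",
         ifelse(g %in% c("GG3", "GG4"), "GG3_4",
         ifelse(g == "GG5", "GG5", NA_character_))))
  if (anyNA(out)) {
    stop("unknown Gleason label(s): ",
         paste(unique(g[is.na(out)]), collapse = ", "))
  }
  factor(out, levels = c("Normal", "GG2", "GG3_4", "GG5"))
}

#' Row-wise Z-scores
#'
#' Subtracts the row mean and divides by the row standard deviation;
#' constant rows become all zeros with a warning.
#'
#' @param mat numeric matrix without missing values.
#' @return the transformed matrix.
#' @export
zscore_rows <- function(mat) {
  if (anyNA(mat)) stop("Z-scoring expects a complete (imputed) matrix")
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  if (any(sdv == 0)) {
    warning(sum(sdv == 0), " constant row(s) set to zero")
  }
  out <- (mat - mu) / ifelse(sdv == 0, 1, sdv)
  out[sdv == 0, ] <- 0
  out
}
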