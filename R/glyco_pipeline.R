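# Glycopeptide quantification pipeline: record-level filters, the glycopeptide
# x sample abundance matrix, quotient total-area normalization, per-glycosite
# metric degrees and cohort-level descriptors.

.GLYCO_RECORD_COLS <- c("sample_id", "protein", "glycosite", "glycan", "rt", "auc")

.peptide_id <- function(records) {
  paste(records$protein, records$glycosite, records$glycan, sep = "|")
}

.check_glyco_records <- function(records, need_rt = FALSE) {
  need <- setdiff(.GLYCO_RECORD_COLS, if (need_rt) character(0) else "rt")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("glycopeptide records are missing column(s): ",
         paste(miss, collapse = ", "))
  }
  invisible(records)
}

#' Retention-time IQR outlier filter
#'
#' Per unique glycopeptide (protein, glycosite, glycan) across all samples,
#' observations with retention time outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`
#' are removed. Quartiles use linear interpolation (quantile type 7) and the
#' bounds are inclusive. Glycopeptides observed fewer than `min_group` times
#' pass through unfiltered, as quartiles are not meaningful there.
#'
#' @param records long-format data frame with columns `sample_id`, `protein`,
#'   `glycosite`, `glycan`, `rt`, `auc`.
#' @param min_group smallest per-glycopeptide group size that is filtered.
#' @return list with data frames `kept` and `removed`.
#' @export
rt_outlier_filter <- function(records, min_group = 4) {
  .check_glyco_records(records, need_rt = TRUE)
  keep <- rep(TRUE, nrow(records))
  for (ids in split(seq_len(nrow(records)), .peptide_id(records))) {
    if (length(ids) < min_group) next
    rt <- records$rt[ids]
    qs <- stats::quantile(rt, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- qs[2] - qs[1]
    keep[ids] <- rt >= qs[1] - 1.5 * iqr & rt <= qs[2] + 1.5 * iqr
  }
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

#' Minimum-area filter
#'
#' Drops records whose chromatographic peak area is strictly below
#' `min_auc`; the boundary value is kept.
#'
#' @inheritParams rt_outlier_filter
#' @param min_auc area threshold (default 1000).
#' @return the kept records.
#' @export
auc_filter <- function(records, min_auc = 1000) {
  .check_glyco_records(records)
  records[records$auc >= min_auc, , drop = FALSE]
}

#' Build a glycopeptide abundance matrix
#'
#' Pivots long-format records into a glycopeptides x samples matrix of peak
#' areas with `NA` for unobserved cells. Duplicate (sample, glycopeptide)
#' records are resolved by keeping the maximum area; the resolution is
#' recorded in the provenance log.
#'
#' @inheritParams rt_outlier_filter
#' @param samples optional character vector fixing the sample columns (and
#'   their order); defaults to the sorted samples present in `records`.
#' @param groups optional named vector of group labels for the samples.
#' @return an object of class `glyco_matrix`: a list with `abundance`
#'   (matrix), `peptides` (annotation data frame aligned with the rows),
#'   `samples`, `groups`, `log_scale` flag and a `provenance` list.
#' @export
glyco_matrix <- function(records, samples = NULL, groups = NULL) {
  .check_glyco_records(records)
  if (!nrow(records)) stop("no glycopeptide records supplied")
  pid <- .peptide_id(records)
  samples <- samples %||% sort(unique(records$sample_id))
  pep_levels <- sort(unique(pid))
  n_cells <- nrow(unique(data.frame(pid, records$sample_id)))
  n_dup <- nrow(records) - n_cells
  m <- tapply(records$auc,
              list(factor(pid, levels = pep_levels),
                   factor(records$sample_id, levels = samples)),
              max)
  m <- matrix(as.numeric(m), nrow = length(pep_levels),
              dimnames = list(pep_levels, samples))
  pep <- unique(records[, c("protein", "glycosite", "glycan")])
  pep$peptide_id <- paste(pep$protein, pep$glycosite, pep$glycan, sep = "|")
  pep <- pep[match(pep_levels, pep$peptide_id), , drop = FALSE]
  pep$site_id <- paste(pep$protein, pep$glycosite, sep = "|")
  rownames(pep) <- NULL
  gm <- structure(
    list(abundance = m, peptides = pep, samples = samples,
         groups = groups, log_scale = FALSE,
         provenance = list(list(
           step = "build_matrix", n_glycopeptides = nrow(m),
           n_samples = ncol(m), duplicates_resolved_keep_max_auc = n_dup))),
    class = "glyco_matrix")
  gm
}

#' @export
print.glyco_matrix <- function(x, ...) {
  cat(sprintf("glyco_matrix: %d glycopeptides x %d samples (%s scale)\n",
              nrow(x$abundance), ncol(x$abundance),
              if (isTRUE(x$log_scale)) "log" else "raw"))
  cat(sprintf("  %d glycosites, %d glycans, %d provenance steps\n",
              length(unique(x$peptides$site_id)),
              length(unique(x$peptides$glycan)), length(x$provenance)))
  invisible(x)
}

.gm_log <- function(gm, entry) {
  gm$provenance <- c(gm$provenance, list(entry))
  gm
}

.gm_subset <- function(gm, rows = NULL, cols = NULL) {
  if (!is.null(rows)) {
    gm$abundance <- gm$abundance[rows, , drop = FALSE]
    gm$peptides <- gm$peptides[rows, , drop = FALSE]
    rownames(gm$peptides) <- NULL
  }
  if (!is.null(cols)) {
    gm$abundance <- gm$abundance[, cols, drop = FALSE]
    gm$samples <- colnames(gm$abundance)
    if (!is.null(gm$groups)) gm$groups <- gm$groups[gm$samples]
  }
  gm
}

#' Presence filter for the glycopeptide matrix
#'
#' Applied once, in order: first glycopeptide rows observed in fewer than
#' `min_samples` samples are dropped, then sample columns with fewer than
#' `min_glycopeptides` observed glycopeptides are dropped (no iteration to a
#' fixpoint). Counts removed at each step go to the provenance log.
#'
#' @param gm a [glyco_matrix()].
#' @param min_samples minimum samples a glycopeptide must be observed in.
#' @param min_glycopeptides minimum glycopeptides a sample must carry.
#' @return the filtered `glyco_matrix`.
#' @export
presence_filter <- function(gm, min_samples = 5, min_glycopeptides = 10) {
  stopifnot(inherits(gm, "glyco_matrix"))
  keep_r <- rowSums(!is.na(gm$abundance)) >= min_samples
  gm2 <- .gm_subset(gm, rows = which(keep_r))
  keep_c <- colSums(!is.na(gm2$abundance)) >= min_glycopeptides
  gm2 <- .gm_subset(gm2, cols = which(keep_c))
  if (!nrow(gm2$abundance) || !ncol(gm2$abundance)) {
    stop("presence filtering removed everything; review the `min_samples` ",
         "and `min_glycopeptides` thresholds for this dataset")
  }
  .gm_log(gm2, list(step = "presence_filter",
                    min_samples = min_samples,
                    min_glycopeptides = min_glycopeptides,
                    glycopeptides_removed = sum(!keep_r),
                    samples_removed = sum(!keep_c)))
}

#' Quotient total-area normalization
#'
#' Two-step normalization of the raw abundance matrix. Step 1 (total-area):
#' every sample column is scaled so its total observed abundance equals the
#' cohort-median total. Step 2 (probabilistic quotient): the reference
#' profile is the per-glycopeptide median across samples of the step-1
#' matrix; each sample is divided by the median of its value/reference
#' quotients over its observed glycopeptides.
#'
#' @param gm a raw-scale [glyco_matrix()].
#' @return the normalized `glyco_matrix` (still on the raw scale; follow
#'   with [log_transform()]).
#' @export
qta_normalize <- function(gm) {
  stopifnot(inherits(gm, "glyco_matrix"))
  if (isTRUE(gm$log_scale)) stop("normalization expects raw-scale abundances")
  m <- gm$abundance
  n_obs <- colSums(!is.na(m))
  if (any(n_obs == 0)) {
    stop("sample(s) with no observed values: ",
         paste(colnames(m)[n_obs == 0], collapse = ", "))
  }
  tot <- colSums(m, na.rm = TRUE)
  if (any(tot <= 0)) {
    stop("sample(s) with non-positive total abundance: ",
         paste(colnames(m)[tot <= 0], collapse = ", "))
  }
  m1 <- sweep(m, 2, tot / stats::median(tot), "/")
  ref <- apply(m1, 1, stats::median, na.rm = TRUE)
  quo <- apply(sweep(m1, 1, ref, "/"), 2, stats::median, na.rm = TRUE)
  gm$abundance <- sweep(m1, 2, quo, "/")
  .gm_log(gm, list(step = "quotient_total_area_normalization",
                   target_total = stats::median(tot),
                   reference = "per-glycopeptide median profile"))
}

#' Logarithmic transformation
#'
#' @param gm a [glyco_matrix()] with strictly positive observed values.
#' @param base logarithm base (default 2).
#' @return the log-scale `glyco_matrix`; missing values stay missing.
#' @export
log_transform <- function(gm, base = 2) {
  stopifnot(inherits(gm, "glyco_matrix"))
  m <- gm$abundance
  bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive abundance at glycopeptide '%s', sample '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  gm$abundance <- log(m, base = base)
  gm$log_scale <- TRUE
  .gm_log(gm, list(step = "log_transform", base = base))
}

#' Glycosite-specific metric degrees
#'
#' Abundance-weighted degrees per (glycosite, sample), computed from the raw
#' (pre-log) filtered abundances:
#' * fucosylation: signal of fucosylated glycoforms over total signal;
#' * sialylation: sialylated antennae over all antennae, abundance-weighted,
#'   over antenna-bearing glycoforms;
#' * galactosylation: galactosylated antennae over all antennae over
#'   complex-type glycoforms.
#'
#' A degree is `NA` where the corresponding denominator is zero (no eligible
#' glycoform quantified at that site in that sample). All degrees lie in
#' \[0, 1\] and are invariant to rescaling a sample's abundances.
#'
#' @param gm a raw-scale [glyco_matrix()].
#' @param features optional precomputed [glycan_features()] data frame
#'   aligned with `gm$peptides`; derived from the glycan strings if omitted.
#' @return long data frame: `site`, `sample_id`, `fucosylation`,
#'   `sialylation`, `galactosylation`.
#' @export
site_metric_degrees <- function(gm, features = NULL) {
  stopifnot(inherits(gm, "glyco_matrix"))
  if (isTRUE(gm$log_scale)) {
    stop("site metric degrees must be computed on the raw abundance scale")
  }
  feats <- features %||% glycan_features(parse_glycan(gm$peptides$glycan))
  if (nrow(feats) != nrow(gm$abundance) ||
      !all(c("antennae", "sialic_antennae", "galactoses", "is_fucosylated",
             "glycan_class") %in% names(feats))) {
    stop("unknown glycopeptide annotation: `features` must align with the ",
         "matrix rows and carry the glycan_features columns")
  }
  m <- gm$abundance
  site <- gm$peptides$site_id
  wsum <- function(w) rowsum(m * w, site, na.rm = TRUE)
  deg <- function(num, den) {
    r <- num / den
    r[den == 0] <- NA_real_
    r
  }
  ones <- rep(1, nrow(m))
  gal_w <- as.numeric(feats$glycan_class == "complex")
  fuc <- deg(wsum(as.numeric(feats$is_fucosylated)), wsum(ones))
  sia <- deg(wsum(feats$sialic_antennae), wsum(feats$antennae))
  gal <- deg(wsum(feats$galactoses * gal_w), wsum(feats$antennae * gal_w))
  sites <- rownames(fuc)
  data.frame(
    site = rep(sites, times = ncol(m)),
    sample_id = rep(colnames(m), each = length(sites)),
    fucosylation = as.vector(fuc),
    sialylation = as.vector(sia),
    galactosylation = as.vector(gal),
    stringsAsFactors = FALSE
  )
}

#' Reshape a site metric table into a sites x samples matrix
#'
#' @param smt output of [site_metric_degrees()].
#' @param metric one of `"fucosylation"`, `"sialylation"`,
#'   `"galactosylation"`.
#' @return numeric matrix, sites in rows and samples in columns.
#' @export
site_metric_matrix <- function(smt, metric = c("fucosylation", "sialylation",
                                               "galactosylation")) {
  metric <- match.arg(metric)
  sites <- unique(smt$site); samples <- unique(smt$sample_id)
  m <- matrix(NA_real_, length(sites), length(samples),
              dimnames = list(sites, samples))
  m[cbind(match(smt$site, sites), match(smt$sample_id, samples))] <- smt[[metric]]
  m
}

#' Cohort-level glycosylation descriptors
#'
#' Dataset-wide summaries of the filtered matrix: the fraction of
#' glycopeptides carrying complex-type glycans (count-based, over
#' identifications), the abundance-weighted glycan class ratio, the average
#' antenna sialylation, the abundance fraction of antenna-containing
#' structures carrying at least one sialic acid, the average fucosylation
#' and the abundance-weighted branching (antenna count) distribution.
#'
#' @inheritParams site_metric_degrees
#' @return a list of descriptors; all fractions lie in \[0, 1\] and the
#'   class ratio and branching distribution each sum to 1.
#' @export
dataset_descriptors <- function(gm, features = NULL) {
  stopifnot(inherits(gm, "glyco_matrix"))
  if (isTRUE(gm$log_scale)) {
    stop("descriptors are abundance-weighted and need the raw scale")
  }
  feats <- features %||% glycan_features(parse_glycan(gm$peptides$glycan))
  rs <- rowSums(gm$abundance, na.rm = TRUE)
  total <- sum(rs)
  cls <- factor(feats$glycan_class, levels = .GLYCAN_CLASSES)
  type_ratio <- tapply(rs, cls, sum, default = 0) / total
  ant_w <- rs * feats$antennae
  has_ant <- feats$antennae >= 1
  branching <- tapply(rs, factor(feats$antennae, levels = 0:4), sum,
                      default = 0) / total
  list(
    complex_glycopeptide_fraction = mean(feats$glycan_class == "complex"),
    glycan_type_ratio = as.numeric(type_ratio) |>
      stats::setNames(levels(cls)),
    avg_antenna_sialylation =
      if (sum(ant_w) > 0) sum(rs * feats$sialic_antennae) / sum(ant_w) else NA_real_,
    sialylated_antennary_fraction =
      if (any(has_ant)) sum(rs[has_ant & feats$is_sialylated]) / sum(rs[has_ant]) else NA_real_,
    avg_fucosylation = sum(rs[feats$is_fucosylated]) / total,
    branching = as.numeric(branching) |> stats::setNames(paste0("antennae_", 0:4))
  )
}

#' Collapse grade labels to the two-group design
#'
#' Every cancerous grade (anything other than `"Normal"`) is labelled
#' `"PCa"`.
#'
#' @param grade character or factor vector of grade labels.
#' @return factor with levels `c("Normal", "PCa")`.
#' @export
two_group_labels <- function(grade) {
  factor(ifelse(as.character(grade) == "Normal", "Normal", "PCa"),
         levels = c("Normal", "PCa"))
}

#' Differential testing of glyco features
#'
#' Per-feature two-sided Student's t-test (two-group design) or one-way
#' ANOVA (multi-group design) with Benjamini-Hochberg adjustment across the
#' tested features, on log glycopeptide abundances or per-sample site metric
#' degrees. Features where some group has fewer than 2 non-missing values,
#' or with zero overall variance, are skipped with a logged reason
#' (attribute `"skipped"`). For ANOVA-significant features a Tukey HSD
#' pairwise table is attached as attribute `"tukey"`.
#'
#' @param x numeric matrix, features in rows and samples in columns.
#' @param groups group label per column.
#' @param design `"two_group"` or `"multi_group"`.
#' @param alpha FDR level.
#' @param tukey run Tukey HSD on significant multi-group features?
#' @param var_equal use the pooled-variance t statistic?
#' @return data frame with group means, test statistic, `p`, `q` and
#'   `significant` per tested feature.
#' @export
glyco_differential <- function(x, groups,
                               design = c("two_group", "multi_group"),
                               alpha = 0.05, tukey = TRUE, var_equal = TRUE) {
  design <- match.arg(design)
  g <- if (design == "two_group") two_group_labels(groups) else factor(groups)
  .differential_engine(as.matrix(x), g, alpha = alpha,
                       two_group = design == "two_group",
                       tukey = tukey && design == "multi_group",
                       var_equal = var_equal)
}
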