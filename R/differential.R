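# Shared per-feature differential testing engine used by both analysis arms.

.differential_engine <- function(mat, groups, alpha = 0.05, two_group = TRUE,
                                 tukey = FALSE, var_equal = TRUE) {
  if (is.null(rownames(mat))) rownames(mat) <- paste0("feature_", seq_len(nrow(mat)))
  groups <- droplevels(factor(groups))
  if (length(groups) != ncol(mat)) {
    stop("`groups` must have one label per column of the matrix")
  }
  lv <- levels(groups)
  if (two_group && length(lv) != 2) stop("two-group design needs exactly 2 groups")
  if (!two_group && length(lv) < 2) stop("need at least 2 groups")

  feats <- rownames(mat)
  n_f <- nrow(mat)
  means <- matrix(NA_real_, n_f, length(lv), dimnames = list(feats, lv))
  stat <- p <- rep(NA_real_, n_f)
  skipped <- character(0); skip_reason <- character(0)
  group_values <- vector("list", n_f)

  for (i in seq_len(n_f)) {
    v <- mat[i, ]
    ok <- !is.na(v)
    gl <- split(v[ok], groups[ok])
    sizes <- lengths(gl)
    if (any(sizes < 2)) {
      skipped <- c(skipped, feats[i])
      skip_reason <- c(skip_reason,
                       sprintf("group '%s' has fewer than 2 non-missing values",
                               lv[which(sizes < 2)[1]]))
      next
    }
    if (max(v[ok]) == min(v[ok])) {
      skipped <- c(skipped, feats[i])
      skip_reason <- c(skip_reason, "zero variance across all groups")
      next
    }
    means[i, ] <- vapply(gl, mean, numeric(1))
    if (two_group) {
      tt <- student_t_test(gl[[1]], gl[[2]], var_equal = var_equal)
      stat[i] <- tt$statistic; p[i] <- tt$p.value
    } else {
      aa <- one_way_anova(gl)
      stat[i] <- aa$statistic; p[i] <- aa$p.value
    }
    group_values[[i]] <- gl
  }

  tested <- which(!is.na(p))
  q <- rep(NA_real_, n_f); sig <- rep(NA, n_f)
  if (length(tested)) {
    fdr <- bh_fdr(p[tested], alpha = alpha)
    q[tested] <- fdr$q
    sig[tested] <- fdr$significant
  }

  out <- data.frame(feature = feats, stringsAsFactors = FALSE)
  for (l in lv) out[[paste0("mean_", l)]] <- means[, l]
  out$statistic <- stat
  out$p <- p
  out$q <- q
  out$significant <- sig
  out <- out[!(out$feature %in% skipped), , drop = FALSE]
  rownames(out) <- NULL

  attr(out, "skipped") <- data.frame(feature = skipped, reason = skip_reason,
                                     stringsAsFactors = FALSE)
  attr(out, "design") <- if (two_group) "two_group" else "multi_group"
  attr(out, "alpha") <- alpha

  if (tukey && !two_group) {
    tk <- list()
    for (i in tested) {
      if (!isTRUE(sig[i])) next
      tab <- tukey_hsd(group_values[[i]])
      tab <- cbind(feature = feats[i], tab, stringsAsFactors = FALSE)
      tk[[length(tk) + 1]] <- tab
    }
    attr(out, "tukey") <- if (length(tk)) do.call(rbind, tk) else
      data.frame(feature = character(0), group1 = character(0),
                 group2 = character(0), diff = numeric(0), se = numeric(0),
                 q = numeric(0), p_adj = numeric(0))
  }
  out
}
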