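# Self-contained statistical primitives shared by the proteomics and
# glycoproteomics pipelines. Each has an independent brute-force oracle in
# the test suite; the studentized-range CDF is computed by numerical
# integration rather than delegated to stats::ptukey.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-sample Student's t-test
#'
#' Pooled-variance two-sided t-test (Welch's correction available via
#' `var_equal = FALSE`). With zero pooled variance the convention is p = 1
#' for equal means and p = 0 otherwise; the `note` field records the
#' degenerate case.
#'
#' @param x,y numeric vectors, at least 2 non-missing values each.
#' @param var_equal assume equal variances (classic Student test)?
#' @return list with `statistic`, `df`, `p.value`, and `note` (NULL unless a
#'   degenerate convention was applied).
#' @export
student_t_test <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each sample needs at least 2 non-missing values")
  vx <- stats::var(x); vy <- stats::var(y)
  d <- mean(x) - mean(y)
  if (var_equal) {
    df <- nx + ny - 2
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / df
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- if (se > 0) {
      (vx / nx + vy / ny)^2 /
        ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    } else nx + ny - 2
  }
  if (se == 0) {
    if (d == 0) {
      return(list(statistic = 0, df = df, p.value = 1,
                  note = "zero pooled variance with equal means; p = 1 by convention"))
    }
    return(list(statistic = sign(d) * Inf, df = df, p.value = 0,
                note = "zero pooled variance with unequal means"))
  }
  tval <- d / se
  list(statistic = tval, df = df,
       p.value = 2 * stats::pt(-abs(tval), df), note = NULL)
}

#' One-way analysis of variance
#'
#' @param groups list of numeric vectors (>= 2 groups, each with >= 2
#'   non-missing values).
#' @return list with `statistic` (F), `df1`, `df2`, `p.value`, `note`.
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) {
    stop("every group needs at least 2 non-missing values")
  }
  n <- lengths(groups); N <- sum(n); k <- length(groups)
  m <- vapply(groups, mean, numeric(1))
  gm <- sum(n * m) / N
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1; df2 <- N - k
  if (ssw == 0) {
    if (ssb == 0) {
      return(list(statistic = 0, df1 = df1, df2 = df2, p.value = 1,
                  note = "zero between- and within-group variance; p = 1 by convention"))
    }
    return(list(statistic = Inf, df1 = df1, df2 = df2, p.value = 0,
                note = "zero within-group variance with distinct means"))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, df1 = df1, df2 = df2,
       p.value = stats::pf(f, df1, df2, lower.tail = FALSE), note = NULL)
}

# Cached Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch).
.gl_env <- new.env(parent = emptyenv())
.gl_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_env[[key]])) {
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    .gl_env[[key]] <- list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
  }
  .gl_env[[key]]
}

# P(range of k iid standard normals <= x), vectorized over x.
# 128-node quadrature over z in [-9, 9] (the normal density is negligible
# beyond); accurate to well under 1e-8.
.prange_std <- function(x, k) {
  gl <- .gl_nodes(128)
  z <- 9 * gl$x
  wz <- 9 * gl$w * stats::dnorm(z)
  Phi <- stats::pnorm(z)
  out <- numeric(length(x))
  pos <- which(x > 0)
  if (length(pos)) {
    D <- Phi - stats::pnorm(outer(z, x[pos], "-"))
    D[D < 0] <- 0
    out[pos] <- pmin(1, k * colSums(wz * D^(k - 1)))
  }
  out
}

#' Studentized range distribution function
#'
#' CDF of the studentized range statistic with `k` groups and `df` error
#' degrees of freedom, computed by two-dimensional numerical integration:
#' the normal-range probability (inner integral over the common order
#' statistic) against the scaled-chi density of the pooled standard
#' deviation (outer integral), each on fixed Gauss-Legendre grids. Accurate
#' to about 1e-6; used by [tukey_hsd()] so the package does not depend on
#' any particular library's tabulation of the distribution.
#'
#' @param q quantile(s), non-negative.
#' @param k number of groups (>= 2).
#' @param df error degrees of freedom; `Inf` gives the plain normal range.
#' @return numeric vector of probabilities.
#' @export
psrange <- function(q, k, df = Inf) {
  if (k < 2) stop("`k` must be at least 2")
  if (!is.finite(df)) {
    out <- rep(NA_real_, length(q))
    ok <- !is.na(q)
    out[ok] <- .prange_std(pmax(q[ok], 0), k)
    return(out)
  }
  if (df < 1) stop("`df` must be at least 1")
  # s = pooled sd / sigma has density c * s^(df-1) * exp(-df s^2 / 2),
  # concentrated around 1 with spread ~ 1/sqrt(2 df)
  gl <- .gl_nodes(160)
  half <- 12 / sqrt(2 * df)
  a <- max(0, 1 - half); b <- 1 + half
  s <- (b - a) / 2 * gl$x + (a + b) / 2
  ws <- (b - a) / 2 * gl$w
  ln_c <- (df / 2) * log(df) - lgamma(df / 2) - (df / 2 - 1) * log(2)
  dens <- exp(ln_c + (df - 1) * log(s) - df * s^2 / 2)
  dens[!is.finite(dens)] <- 0
  vapply(q, function(qi) {
    if (is.na(qi)) return(NA_real_)
    if (qi <= 0) return(0)
    min(1, sum(ws * dens * .prange_std(qi * s, k)))
  }, numeric(1))
}

#' Critical value of the studentized range
#'
#' @param alpha family-wise error rate.
#' @inheritParams psrange
#' @return the quantile q with `psrange(q, k, df) == 1 - alpha`.
#' @export
tukey_critical <- function(alpha = 0.05, k = 3, df = 10) {
  stats::uniroot(function(q) psrange(q, k, df) - (1 - alpha),
                 interval = c(1e-3, 100), tol = 1e-8)$root
}

#' Tukey HSD all-pairs post-hoc test
#'
#' Tukey-Kramer adjusted p-values for all group pairs from the studentized
#' range distribution; unbalanced designs use the per-pair harmonic mean
#' sample size (the Tukey-Kramer standard error).
#'
#' @inheritParams one_way_anova
#' @return data frame with one row per pair: `group1`, `group2`, `diff`
#'   (mean of group1 minus mean of group2), `se`, `q` statistic, `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) {
    stop("every group needs at least 2 non-missing values")
  }
  nm <- names(groups) %||% paste0("g", seq_along(groups))
  nm[!nzchar(nm)] <- paste0("g", seq_along(groups))[!nzchar(nm)]
  n <- lengths(groups); k <- length(groups); N <- sum(n)
  m <- vapply(groups, mean, numeric(1))
  df2 <- N - k
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / df2
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
    diff = m[pairs[1, ]] - m[pairs[2, ]],
    se = NA_real_, q = NA_real_, p_adj = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    if (msw == 0) {
      out$se[j] <- 0
      out$q[j] <- if (out$diff[j] == 0) 0 else Inf
      out$p_adj[j] <- if (out$diff[j] == 0) 1 else 0
      next
    }
    se <- sqrt(msw / 2 * (1 / n[i1] + 1 / n[i2]))
    qs <- abs(out$diff[j]) / se
    out$se[j] <- se
    out$q[j] <- qs
    out$p_adj[j] <- min(1, max(0, 1 - psrange(qs, k, df2)))
  }
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values with enforced monotonicity; a feature is flagged
#' significant when its q-value is at or below `alpha`.
#'
#' @param p numeric vector of p-values in \[0, 1\], no missing values.
#' @param alpha FDR level for the significance flags.
#' @return list with `q` and logical `significant`, both aligned with `p`.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  if (!length(p)) return(list(q = numeric(0), significant = logical(0)))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * p[o]))[order(o)]
  list(q = q, significant = q <= alpha)
}

#' Pearson or Spearman correlation coefficient
#'
#' Spearman uses average (fractional) ranks for ties. Pairs with missing
#' values are dropped; a zero-variance vector yields `NA` (undefined
#' correlation reported as missing).
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @param method `"pearson"` or `"spearman"`.
#' @return correlation coefficient in \[-1, 1\], or `NA`.
#' @export
cor_coef <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Hierarchical clustering with correlation distance
#'
#' Agglomerative clustering of matrix rows with distance 1 - correlation and
#' the requested linkage, cut into `k` clusters. Undefined correlations from
#' zero-variance rows are replaced by distance 0 for identical rows and 1
#' otherwise (with a warning).
#'
#' @param mat numeric matrix, one observation per row.
#' @param k number of clusters.
#' @param method correlation flavor, `"spearman"` or `"pearson"`.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return integer vector of cluster labels, one per row of `mat`.
#' @export
hier_cluster <- function(mat, k = 2, method = c("spearman", "pearson"),
                         linkage = "average") {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  if (nrow(mat) < k) stop("fewer rows than requested clusters")
  d <- 1 - suppressWarnings(stats::cor(t(mat), method = method))
  if (anyNA(d)) {
    warning("undefined correlations (zero-variance rows); ",
            "identical rows get distance 0, others 1")
    idx <- which(is.na(d), arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      d[i, j] <- if (isTRUE(all.equal(mat[i, ], mat[j, ],
                                      check.attributes = FALSE))) 0 else 1
    }
  }
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  stats::cutree(hc, k = k)
}
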