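# Synthetic cohort generator. Emits the three tables the pipelines consume
# (protein log2-intensity matrix, long glycopeptide quantification table,
# sample metadata) with configurable spiked group effects and a ground-truth
# record for recovery tests. Randomness flows from one master seed split
# into named substreams so parts can be regenerated independently.

.SITE_METRICS <- c("fucosylation", "sialylation", "galactosylation")

# Canonical glycoproteins/glycosites with documented site-specific effects;
# used whenever the configured counts leave room for them.
.NAMED_GLYCOSITES <- data.frame(
  protein = c("PPAP", "POSTN", "CO6A2", "MFAP4", "MFAP4", "IGHG2", "THRB"),
  glycosite = c("N94", "N599", "N785", "N137", "N87", "N176", "N121"),
  stringsAsFactors = FALSE
)

# Biantennary glycoform panels whose metric hulls span the targets used in
# the presets: panel A moves sialylation and fucosylation across [0, 1],
# panel B moves galactosylation and sialylation.
.GLYCAN_PANEL_A <- c("N4H5", "N4H5S1", "N4H5S2", "N4H5F1", "N4H5S2F1")
.GLYCAN_PANEL_B <- c("N4H3", "N4H4", "N4H5", "N4H5S1", "N4H4S2")

.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1000003) * 2011 + 7919 * k) %% 2147483647L
}

#' Enumerate a composition-level N-glycan library
#'
#' All compositions with N in 2..6, H in 3..9, F in 0..1 and S from 0 up to
#' the antenna count of the (N, H, F) skeleton. Covers every glycan class.
#'
#' @return data frame with `glycan` strings and their [glycan_features()].
#' @export
enumerate_glycan_library <- function() {
  rows <- list()
  for (N in 2:6) for (H in 3:9) for (F_ in 0:1) {
    base <- data.frame(H = H, N = N, F = F_, S = 0L)
    smax <- glycan_features(as_glycan_composition(base))$antennae
    for (S in 0:smax) {
      rows[[length(rows) + 1]] <- data.frame(H = H, N = N, F = F_, S = S)
    }
  }
  comp <- as_glycan_composition(do.call(rbind, rows))
  out <- cbind(glycan = render_glycan(comp), glycan_features(comp),
               stringsAsFactors = FALSE)
  out
}

#' Cohort generator configuration
#'
#' The defaults encode the study design the generator emulates: 95 samples
#' (46 Normal, 9 G1, 16 G2, 24 G3; the 49 cancer samples relabelled
#' GG2/GG3/GG4/GG5 as 7/12/15/15), 653 quantified proteins with
#' intensity-dependent (MNAR) missingness, and 145 glycopeptides from 22
#' glycoproteins with 29 glycosites drawn from a 53-glycan pool. Cohort-wide
#' glycosylation is calibrated to an average fucosylation of 0.378 and an
#' average antenna sialylation of 0.201.
#'
#' @param group_sizes named sizes for Normal/G1/G2/G3 (each >= 2).
#' @param gleason_sizes named sizes for GG2/GG3/GG4/GG5; must sum to the
#'   number of cancer samples.
#' @param n_proteins,n_glycoproteins,n_glycosites,n_glycans,glycoforms_per_site
#'   dataset dimensions; glycopeptide count is
#'   `n_glycosites * glycoforms_per_site`.
#' @param baseline_mean,baseline_sd log2 protein intensity baseline.
#' @param within_sd within-group log2 intensity standard deviation.
#' @param spiked_baseline_mean,spiked_baseline_sd,spiked_baseline_min
#'   baseline distribution for spiked proteins and glycoproteins (kept high
#'   enough to survive presence filtering, as differential candidates in a
#'   real study are well quantified).
#' @param mnar enable intensity-dependent missingness; probability of
#'   missing is `plogis(-(intensity - mnar_threshold) / mnar_scale)`.
#' @param mnar_threshold,mnar_scale MNAR model parameters (log2 units).
#' @param site_log2_mean_range,site_log2_sd per-glycosite total-abundance
#'   model (log2 of summed peak area).
#' @param dirichlet_conc concentration of the per-sample Dirichlet draw of
#'   glycoform proportions (larger = less compositional noise).
#' @param auc_log_sd multiplicative log-normal measurement noise on areas.
#' @param glyco_detect_threshold,glyco_detect_scale MNAR detection model for
#'   glycoform observations: a record with area `a` is lost with probability
#'   `plogis(-(log2(a) - log2(threshold)) / scale)`, so missingness
#'   concentrates on records near or below the detection limit (matching
#'   the minimum-area filter's threshold) and abundant glycoforms are
#'   essentially always observed.
#' @param dropout_prob additional small intensity-independent probability
#'   that an observation is lost (random technical failure).
#' @param rt_range,rt_jitter_sd retention-time model (minutes).
#' @param rt_outlier_prob,rt_outlier_shift probability and shift range
#'   (minutes) of injected retention-time outliers.
#' @param global_targets cohort-level metric targets applied to every site
#'   whose glycoform panel can attain them.
#' @param protein_effects data frame (`protein`, `G1`, `G2`, `G3`) of log2
#'   fold shifts relative to Normal.
#' @param site_effects data frame (`protein`, `glycosite`, `metric`,
#'   `Normal`, `G1`, `G2`, `G3`) of per-group metric degree targets in
#'   \[0, 1\].
#' @param seed master seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(group_sizes = c(Normal = 46, G1 = 9, G2 = 16, G3 = 24),
                          gleason_sizes = c(GG2 = 7, GG3 = 12, GG4 = 15, GG5 = 15),
                          n_proteins = 653, n_glycoproteins = 22,
                          n_glycosites = 29, n_glycans = 53,
                          glycoforms_per_site = 5,
                          baseline_mean = 27, baseline_sd = 2, within_sd = 0.5,
                          spiked_baseline_mean = 27.5, spiked_baseline_sd = 1,
                          spiked_baseline_min = 26.5,
                          mnar = TRUE, mnar_threshold = 24, mnar_scale = 1,
                          site_log2_mean_range = c(16, 22), site_log2_sd = 1,
                          dirichlet_conc = 60, auc_log_sd = 0.2,
                          glyco_detect_threshold = 1000,
                          glyco_detect_scale = 0.5,
                          dropout_prob = 0.002,
                          rt_range = c(15, 85), rt_jitter_sd = 0.5,
                          rt_outlier_prob = 0.01, rt_outlier_shift = c(10, 30),
                          global_targets = list(fucosylation = 0.378,
                                                sialylation = 0.201),
                          protein_effects = NULL, site_effects = NULL,
                          seed = 1L) {
  if (!all(c("Normal", "G1", "G2", "G3") %in% names(group_sizes))) {
    stop("`group_sizes` must name Normal, G1, G2 and G3")
  }
  group_sizes <- group_sizes[c("Normal", "G1", "G2", "G3")]
  if (any(group_sizes < 2)) stop("every group needs at least 2 samples")
  n_cancer <- sum(group_sizes[c("G1", "G2", "G3")])
  if (!all(c("GG2", "GG3", "GG4", "GG5") %in% names(gleason_sizes))) {
    stop("`gleason_sizes` must name GG2..GG5")
  }
  gleason_sizes <- gleason_sizes[c("GG2", "GG3", "GG4", "GG5")]
  if (sum(gleason_sizes) != n_cancer) {
    stop("`gleason_sizes` must sum to the number of cancer samples (",
         n_cancer, ")")
  }
  probs <- c(rt_outlier_prob, dropout_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!is.null(global_targets)) {
    bad <- !names(global_targets) %in% .SITE_METRICS
    if (any(bad)) stop("unknown global target metric: ",
                       paste(names(global_targets)[bad], collapse = ", "))
    v <- unlist(global_targets)
    if (any(v < 0 | v > 1)) stop("metric targets must lie in [0, 1]")
  }
  if (!is.null(site_effects)) {
    need <- c("protein", "glycosite", "metric", "Normal", "G1", "G2", "G3")
    if (!all(need %in% names(site_effects))) {
      stop("`site_effects` needs columns ", paste(need, collapse = ", "))
    }
    if (!all(site_effects$metric %in% .SITE_METRICS)) {
      stop("site effect metrics must be among ",
           paste(.SITE_METRICS, collapse = ", "))
    }
    v <- unlist(site_effects[, c("Normal", "G1", "G2", "G3")])
    if (any(is.na(v)) || any(v < 0 | v > 1)) {
      stop("infeasible metric target: site effect targets must lie in [0, 1]")
    }
  }
  if (!is.null(protein_effects)) {
    need <- c("protein", "G1", "G2", "G3")
    if (!all(need %in% names(protein_effects))) {
      stop("`protein_effects` needs columns ", paste(need, collapse = ", "))
    }
  }
  structure(list(
    group_sizes = group_sizes, gleason_sizes = gleason_sizes,
    n_proteins = n_proteins, n_glycoproteins = n_glycoproteins,
    n_glycosites = n_glycosites, n_glycans = n_glycans,
    glycoforms_per_site = glycoforms_per_site,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    within_sd = within_sd,
    spiked_baseline_mean = spiked_baseline_mean,
    spiked_baseline_sd = spiked_baseline_sd,
    spiked_baseline_min = spiked_baseline_min,
    mnar = mnar, mnar_threshold = mnar_threshold, mnar_scale = mnar_scale,
    site_log2_mean_range = site_log2_mean_range, site_log2_sd = site_log2_sd,
    dirichlet_conc = dirichlet_conc, auc_log_sd = auc_log_sd,
    glyco_detect_threshold = glyco_detect_threshold,
    glyco_detect_scale = glyco_detect_scale,
    dropout_prob = dropout_prob,
    rt_range = rt_range, rt_jitter_sd = rt_jitter_sd,
    rt_outlier_prob = rt_outlier_prob, rt_outlier_shift = rt_outlier_shift,
    global_targets = global_targets,
    protein_effects = protein_effects, site_effects = site_effects,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# metric numerators/denominators per glycoform
.metric_parts <- function(feats, metric) {
  switch(metric,
    fucosylation = list(num = as.numeric(feats$is_fucosylated),
                        den = rep(1, nrow(feats))),
    sialylation = list(num = as.numeric(feats$sialic_antennae),
                       den = as.numeric(feats$antennae)),
    galactosylation = list(
      num = as.numeric(feats$galactoses) *
        (feats$glycan_class == "complex"),
      den = as.numeric(feats$antennae) *
        (feats$glycan_class == "complex")),
    stop("unknown metric ", metric))
}

.expected_degree <- function(w, feats, metric) {
  mp <- .metric_parts(feats, metric)
  den <- sum(w * mp$den)
  if (den == 0) return(NA_real_)
  sum(w * mp$num) / den
}

# Exponentially tilt glycoform weights so the expected abundance-weighted
# degrees match the targets (iterative proportional fitting across metrics).
# strict = TRUE turns an unattainable target into an error.
.tilt_weights <- function(w, feats, targets, strict = TRUE, label = "") {
  w <- w / sum(w)
  for (it in seq_len(200)) {
    w_prev <- w
    for (metric in names(targets)) {
      t <- targets[[metric]]
      mp <- .metric_parts(feats, metric)
      sub <- mp$den > 0
      if (!any(sub)) {
        if (strict) stop(sprintf(
          "infeasible metric target: no glycoform at %s contributes to %s",
          label, metric))
        next
      }
      f <- mp$num[sub] / mp$den[sub]
      if (max(f) - min(f) < 1e-9) {
        if (strict && abs(f[1] - t) > 1e-6) stop(sprintf(
          "infeasible metric target: %s at %s is fixed at %.3f by the glycoform panel",
          metric, label, f[1]))
        next
      }
      if (t < min(f) - 1e-9 || t > max(f) + 1e-9) {
        if (strict) stop(sprintf(
          "infeasible metric target: %s = %.3f at %s is outside the attainable range [%.3f, %.3f]",
          metric, t, label, min(f), max(f)))
        next
      }
      u <- w[sub] * mp$den[sub]
      fc <- f - mean(range(f))  # centred for numerical stability
      tc <- t - mean(range(f))
      g <- function(l) {
        e <- u * exp(l * fc)
        sum(e * fc) / sum(e) - tc
      }
      if (abs(g(0)) > 1e-12) {
        l <- tryCatch(
          stats::uniroot(g, interval = c(-80, 80), tol = 1e-13)$root,
          error = function(e) if (g(0) > 0) -80 else 80)
        w[sub] <- w[sub] * exp(l * fc)
        w <- w / sum(w)
      }
    }
    if (max(abs(w - w_prev)) < 1e-12) break
  }
  w
}

# Site/glycan design: which glycoprotein carries which glycosite, and the
# glycoform panel of each site. Uses the RNG (call under a substream seed).
.build_glyco_design <- function(cfg) {
  n_gp <- cfg$n_glycoproteins
  named <- .NAMED_GLYCOSITES
  use_named <- n_gp >= 6 && cfg$n_glycosites >= nrow(named)
  gp <- if (use_named) {
    c(unique(named$protein),
      if (n_gp > 6) sprintf("GLYP%02d", seq_len(n_gp - 6)))
  } else {
    sprintf("GLYP%02d", seq_len(n_gp))
  }
  sites <- if (use_named) named else named[0, ]
  n_more <- cfg$n_glycosites - nrow(sites)
  if (n_more > 0) {
    owner_pool <- setdiff(gp, unique(sites$protein))
    owners <- rep(c(owner_pool, gp), length.out = n_more)
    pos <- sample(setdiff(40:999, c(94, 599, 785, 137, 87, 176, 121)), n_more)
    sites <- rbind(sites, data.frame(protein = owners,
                                     glycosite = paste0("N", pos),
                                     stringsAsFactors = FALSE))
  }
  sites$site_id <- paste(sites$protein, sites$glycosite, sep = "|")

  lib <- enumerate_glycan_library()
  pool <- union(union(.GLYCAN_PANEL_A, .GLYCAN_PANEL_B), character(0))
  extra <- setdiff(lib$glycan, pool)
  n_extra <- max(0, cfg$n_glycans - length(pool))
  pool <- c(pool, sample(extra, min(n_extra, length(extra))))
  pool_feats <- glycan_features(parse_glycan(pool))

  eff_site <- if (!is.null(cfg$site_effects)) {
    paste(cfg$site_effects$protein, cfg$site_effects$glycosite, sep = "|")
  } else character(0)
  gal_site <- if (!is.null(cfg$site_effects)) {
    unique(eff_site[cfg$site_effects$metric == "galactosylation"])
  } else character(0)

  gt <- cfg$global_targets
  panel_ok <- function(glycans) {
    f <- pool_feats[match(glycans, pool), ]
    if (!is.null(gt$fucosylation) &&
        !(any(f$is_fucosylated) && any(!f$is_fucosylated))) return(FALSE)
    if (!is.null(gt$sialylation)) {
      sub <- f$antennae > 0
      if (!any(sub)) return(FALSE)
      fr <- f$sialic_antennae[sub] / f$antennae[sub]
      if (min(fr) > gt$sialylation || max(fr) < gt$sialylation) return(FALSE)
    }
    if (is.null(gt) || !length(gt)) return(TRUE)
    # marginal attainability is not enough: the targets must be JOINTLY
    # attainable, otherwise the alternating tilt diverges and polarizes
    # the profile; accept only panels where the tilt verifiably lands
    wt <- .tilt_weights(rep(1 / nrow(f), nrow(f)), f, gt, strict = FALSE)
    for (metric in names(gt)) {
      got <- .expected_degree(wt, f, metric)
      if (!is.na(got) && abs(got - gt[[metric]]) > 1e-6) return(FALSE)
    }
    # a target on the hull boundary is formally attainable but degenerates
    # the profile; demand an interior solution
    min(wt) >= 1e-3
  }

  panels <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    sid <- sites$site_id[i]
    if (sid %in% gal_site) {
      panels[[i]] <- .GLYCAN_PANEL_B
    } else if (sid %in% eff_site) {
      panels[[i]] <- .GLYCAN_PANEL_A
    } else {
      k <- min(cfg$glycoforms_per_site, length(pool))
      for (try in seq_len(500)) {
        cand <- sample(pool, k)
        if (panel_ok(cand)) break
        cand <- NULL
      }
      panels[[i]] <- cand %||% .GLYCAN_PANEL_A
    }
  }
  list(glycoproteins = gp, sites = sites, panels = panels, pool = pool)
}

#' Generate a synthetic cohort
#'
#' Draws a complete cohort under the configured model: sample metadata with
#' pathological and Gleason grades, a protein log2-intensity matrix with
#' MNAR missingness and optional spiked per-group fold changes, and a long
#' glycopeptide quantification table in which glycoform abundances are
#' allocated per site from a Dirichlet profile tilted per group so the
#' abundance-weighted site metric degrees hit the configured targets in
#' expectation. Retention-time outliers are injected at the configured rate
#' and flagged in the ground truth. Identical seeds give identical cohorts.
#'
#' @param config a [cohort_config()].
#' @param parts which tables to generate (`"proteins"`, `"glyco"`); the
#'   metadata is always produced.
#' @return list of class `glyco_cohort` with `metadata`, `proteins` (wide
#'   data frame), `glyco` (long records) and `truth` (spiked effects,
#'   expected per-group site degrees, injected outliers).
#' @export
generate_cohort <- function(config, parts = c("proteins", "glyco")) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config

  ## -- metadata substream ---------------------------------------------------
  set.seed(.sub_seed(cfg$seed, 1))
  grade <- rep(names(cfg$group_sizes), cfg$group_sizes)
  n <- length(grade)
  sample_id <- sprintf("S%03d", seq_len(n))
  cancer <- which(grade != "Normal")
  severity <- match(grade[cancer], c("G1", "G2", "G3")) +
    stats::runif(length(cancer), -0.35, 0.35)
  gleason <- rep(NA_character_, n)
  gleason[cancer[order(severity)]] <- rep(names(cfg$gleason_sizes),
                                          cfg$gleason_sizes)
  metadata <- data.frame(sample_id = sample_id, grade = grade,
                         gleason = gleason, stringsAsFactors = FALSE)

  truth <- list(protein_effects = cfg$protein_effects,
                site_effects = cfg$site_effects)
  out <- list(metadata = metadata, proteins = NULL, glyco = NULL)

  ## -- protein substream ----------------------------------------------------
  if ("proteins" %in% parts) {
    set.seed(.sub_seed(cfg$seed, 2))
    gp_names <- .build_design_names(cfg)
    n_generic <- cfg$n_proteins - length(gp_names)
    if (n_generic < 0) stop("`n_proteins` smaller than the glycoprotein count")
    prot <- c(gp_names, sprintf("PROT%04d", seq_len(n_generic)))
    pe <- cfg$protein_effects
    if (!is.null(pe) && !all(pe$protein %in% prot)) {
      stop("protein effect(s) reference unknown proteins: ",
           paste(setdiff(pe$protein, prot), collapse = ", "))
    }
    spiked <- union(gp_names, if (!is.null(pe)) pe$protein)
    baseline <- stats::rnorm(length(prot), cfg$baseline_mean, cfg$baseline_sd)
    is_spiked <- prot %in% spiked
    baseline[is_spiked] <- pmax(
      stats::rnorm(sum(is_spiked), cfg$spiked_baseline_mean,
                   cfg$spiked_baseline_sd),
      cfg$spiked_baseline_min)
    eff <- matrix(0, length(prot), 4,
                  dimnames = list(prot, c("Normal", "G1", "G2", "G3")))
    if (!is.null(pe)) {
      idx <- match(pe$protein, prot)
      eff[idx, "G1"] <- pe$G1; eff[idx, "G2"] <- pe$G2; eff[idx, "G3"] <- pe$G3
    }
    mat <- baseline + eff[, grade] +
      matrix(stats::rnorm(length(prot) * n, 0, cfg$within_sd),
             nrow = length(prot))
    dimnames(mat) <- list(prot, sample_id)
    if (isTRUE(cfg$mnar)) {
      pmiss <- stats::plogis(-(mat - cfg$mnar_threshold) / cfg$mnar_scale)
      mat[matrix(stats::runif(length(mat)), nrow = nrow(mat)) < pmiss] <- NA
    }
    out$proteins <- data.frame(protein = prot, mat, check.names = FALSE,
                               stringsAsFactors = FALSE, row.names = NULL)
  }

  ## -- glyco substream ------------------------------------------------------
  if ("glyco" %in% parts) {
    set.seed(.sub_seed(cfg$seed, 3))
    design <- .build_glyco_design(cfg)
    se <- cfg$site_effects
    if (!is.null(se)) {
      se$site_id <- paste(se$protein, se$glycosite, sep = "|")
      unknown <- setdiff(se$site_id, design$sites$site_id)
      if (length(unknown)) {
        stop("site effect(s) reference unknown glycosites: ",
             paste(unknown, collapse = ", "))
      }
    }
    groups4 <- c("Normal", "G1", "G2", "G3")
    grade_idx <- match(grade, groups4)
    recs <- list()
    expected <- list()
    outliers <- list()
    for (i in seq_len(nrow(design$sites))) {
      srow <- design$sites[i, ]
      glycans <- design$panels[[i]]
      has_effect <- !is.null(se) && design$sites$site_id[i] %in% se$site_id
      se_i <- if (has_effect) se[se$site_id == srow$site_id, , drop = FALSE]
      # global tilt for the cohort calibration, then group-specific tilts
      # for the spiked metric targets
      build_wg <- function(w0, feats) {
        w0 <- .tilt_weights(w0, feats, cfg$global_targets %||% list(),
                            strict = FALSE, label = srow$site_id)
        wg <- matrix(rep(w0, 4), nrow = 4, byrow = TRUE,
                     dimnames = list(groups4, NULL))
        if (has_effect) {
          for (g in groups4) {
            targets <- stats::setNames(as.list(se_i[[g]]), se_i$metric)
            wg[g, ] <- .tilt_weights(w0, feats, targets, strict = TRUE,
                                     label = srow$site_id)
          }
        }
        wg
      }
      # effect-bearing sites get an even base profile: their reported
      # glycoforms are all reliably quantified, so none sits at the
      # censoring edge where the minimum-area filter would distort degrees;
      # a uniform admixture keeps every designed glycoform detectable
      k <- length(glycans)
      feats <- glycan_features(parse_glycan(glycans))
      w <- stats::rgamma(k, shape = if (has_effect) 8 else 2) + 1e-6
      w <- 0.8 * w / sum(w) + 0.2 / k
      wg <- build_wg(w, feats)
      # a near-boundary joint target can degenerate the projection from a
      # skewed start; retry from uniform, then from the reference panel
      if (min(wg) < 1e-3) wg <- build_wg(rep(1 / k, k), feats)
      if (min(wg) < 1e-3 && !has_effect) {
        glycans <- .GLYCAN_PANEL_A
        k <- length(glycans)
        feats <- glycan_features(parse_glycan(glycans))
        wg <- build_wg(rep(1 / k, k), feats)
      }
      colnames(wg) <- glycans
      for (g in groups4) for (metric in .SITE_METRICS) {
        expected[[length(expected) + 1]] <- data.frame(
          site = srow$site_id, group = g, metric = metric,
          value = .expected_degree(wg[g, ], feats, metric),
          stringsAsFactors = FALSE)
      }
      # effect-bearing sites draw from the upper abundance range: reported
      # differential sites are well-quantified in every sample by
      # construction (they survived all filters in the study design)
      lo <- if (has_effect) {
        cfg$site_log2_mean_range[1] +
          0.67 * diff(cfg$site_log2_mean_range)
      } else cfg$site_log2_mean_range[1]
      site_mean <- stats::runif(1, lo, cfg$site_log2_mean_range[2])
      # every designed glycoform must be detectable: raise the site total
      # where a strongly tilted profile would push a form under the
      # detection limit (designed glycopeptides emulate the study's
      # post-filter universe of reliably quantified features)
      site_mean <- max(site_mean,
                       log2(8 * cfg$glyco_detect_threshold / min(wg)))
      alpha <- cfg$dirichlet_conc * wg[grade_idx, , drop = FALSE]
      gdraw <- matrix(stats::rgamma(n * k, shape = as.vector(alpha)),
                      nrow = n)
      props <- gdraw / rowSums(gdraw)
      tot <- 2^(site_mean + stats::rnorm(n, 0, cfg$site_log2_sd))
      auc <- props * tot * exp(matrix(stats::rnorm(n * k, 0, cfg$auc_log_sd),
                                      nrow = n))
      rt_mean <- stats::runif(k, cfg$rt_range[1], cfg$rt_range[2])
      rt <- matrix(rep(rt_mean, each = n), nrow = n) +
        matrix(stats::rnorm(n * k, 0, cfg$rt_jitter_sd), nrow = n)
      is_out <- matrix(stats::runif(n * k) < cfg$rt_outlier_prob, nrow = n)
      if (any(is_out)) {
        shift <- sample(c(-1, 1), sum(is_out), replace = TRUE) *
          stats::runif(sum(is_out), cfg$rt_outlier_shift[1],
                       cfg$rt_outlier_shift[2])
        rt[is_out] <- rt[is_out] + shift
      }
      rt <- pmax(rt, 0.5)
      # MNAR detection loss (logistic in log-area) plus a small uniform
      # technical dropout; abundant glycoforms are essentially always seen
      p_detect_loss <- stats::plogis(
        -(log2(auc) - log2(cfg$glyco_detect_threshold)) / cfg$glyco_detect_scale)
      keep <- matrix(stats::runif(n * k) >= p_detect_loss, nrow = n) &
        matrix(stats::runif(n * k) >= cfg$dropout_prob, nrow = n)
      idx <- which(keep, arr.ind = TRUE)
      recs[[i]] <- data.frame(
        sample_id = sample_id[idx[, 1]],
        protein = srow$protein, glycosite = srow$glycosite,
        glycan = glycans[idx[, 2]],
        rt = rt[keep], auc = auc[keep],
        stringsAsFactors = FALSE)
      oidx <- which(keep & is_out, arr.ind = TRUE)
      if (nrow(oidx)) {
        outliers[[length(outliers) + 1]] <- data.frame(
          sample_id = sample_id[oidx[, 1]],
          protein = srow$protein, glycosite = srow$glycosite,
          glycan = glycans[oidx[, 2]], stringsAsFactors = FALSE)
      }
    }
    glyco <- do.call(rbind, recs)
    rownames(glyco) <- NULL
    ord <- order(glyco$protein, glyco$glycosite, glyco$glycan, glyco$sample_id)
    out$glyco <- glyco[ord, , drop = FALSE]
    rownames(out$glyco) <- NULL
    truth$expected_site_degrees <- do.call(rbind, expected)
    truth$rt_outliers <- if (length(outliers)) do.call(rbind, outliers) else
      data.frame(sample_id = character(0), protein = character(0),
                 glycosite = character(0), glycan = character(0))
    truth$design <- design$sites
  }

  out$truth <- truth
  class(out) <- "glyco_cohort"
  out
}

# glycoprotein names for the current configuration (shared by the protein
# and glyco substreams; deterministic, no RNG).
.build_design_names <- function(cfg) {
  use_named <- cfg$n_glycoproteins >= 6 &&
    cfg$n_glycosites >= nrow(.NAMED_GLYCOSITES)
  if (use_named) {
    c(unique(.NAMED_GLYCOSITES$protein),
      if (cfg$n_glycoproteins > 6)
        sprintf("GLYP%02d", seq_len(cfg$n_glycoproteins - 6)))
  } else {
    sprintf("GLYP%02d", seq_len(cfg$n_glycoproteins))
  }
}

#' Named scenario presets
#'
#' * `null`: the default cohort with no group effects (error-control
#'   calibration).
#' * `paper_like`: 40 proteins spiked up and 35 down with monotone grade
#'   effects reaching +-1 log2 unit at G3, plus site-specific metric shifts
#'   at the documented glycosites (fucosylation 0.47 to 0.83 at PPAP N94,
#'   0.24 to 0.72 at POSTN N599; sialylation 0.83 to 0.44 at POSTN N599,
#'   down at THRB N121, IGHG2 N176 and MFAP4 N87, up at CO6A2 N785;
#'   galactosylation up at MFAP4 N137 and down at IGHG2 N176).
#' * `minimal`: 5 samples per group, 20 proteins, 10 glycopeptides, for
#'   fast smoke tests.
#'
#' @return named list of [cohort_config()] objects.
#' @export
scenario_presets <- function() {
  pe <- rbind(
    data.frame(protein = sprintf("PROT%04d", 1:40),
               G1 = 1 / 3, G2 = 2 / 3, G3 = 1),
    data.frame(protein = sprintf("PROT%04d", 41:75),
               G1 = -1 / 3, G2 = -2 / 3, G3 = -1)
  )
  se <- rbind(
    data.frame(protein = "PPAP", glycosite = "N94", metric = "fucosylation",
               Normal = 0.47, G1 = 0.83, G2 = 0.83, G3 = 0.83),
    data.frame(protein = "POSTN", glycosite = "N599", metric = "fucosylation",
               Normal = 0.24, G1 = 0.72, G2 = 0.72, G3 = 0.72),
    data.frame(protein = "POSTN", glycosite = "N599", metric = "sialylation",
               Normal = 0.83, G1 = 0.44, G2 = 0.44, G3 = 0.44),
    data.frame(protein = "CO6A2", glycosite = "N785", metric = "fucosylation",
               Normal = 0.30, G1 = 0.40, G2 = 0.65, G3 = 0.50),
    data.frame(protein = "CO6A2", glycosite = "N785", metric = "sialylation",
               Normal = 0.20, G1 = 0.25, G2 = 0.28, G3 = 0.30),
    data.frame(protein = "MFAP4", glycosite = "N137", metric = "galactosylation",
               Normal = 0.60, G1 = 0.71, G2 = 0.71, G3 = 0.71),
    data.frame(protein = "IGHG2", glycosite = "N176", metric = "galactosylation",
               Normal = 0.60, G1 = 0.513, G2 = 0.513, G3 = 0.513),
    data.frame(protein = "IGHG2", glycosite = "N176", metric = "sialylation",
               Normal = 0.10, G1 = 0.079, G2 = 0.079, G3 = 0.079),
    data.frame(protein = "THRB", glycosite = "N121", metric = "sialylation",
               Normal = 0.065, G1 = 0.019, G2 = 0.019, G3 = 0.019),
    data.frame(protein = "MFAP4", glycosite = "N87", metric = "sialylation",
               Normal = 0.30, G1 = 0.22, G2 = 0.22, G3 = 0.22)
  )
  list(
    null = cohort_config(),
    paper_like = cohort_config(protein_effects = pe, site_effects = se),
    minimal = cohort_config(
      group_sizes = c(Normal = 5, G1 = 5, G2 = 5, G3 = 5),
      gleason_sizes = c(GG2 = 3, GG3 = 4, GG4 = 4, GG5 = 4),
      n_proteins = 20, n_glycoproteins = 2, n_glycosites = 2,
      n_glycans = 10)
  )
}

#' Write a cohort to a directory of TSV files
#'
#' Emits `proteins.tsv` (wide, empty cell = missing), `glyco.tsv` (long),
#' `metadata.tsv` and `truth.json`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "glyco_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wt <- function(df, name, na = "") {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = na)
    p
  }
  if (!is.null(cohort$proteins)) paths <- c(paths, wt(cohort$proteins, "proteins.tsv"))
  if (!is.null(cohort$glyco)) paths <- c(paths, wt(cohort$glyco, "glyco.tsv"))
  paths <- c(paths, wt(cohort$metadata, "metadata.tsv", na = "NA"))
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(cohort$truth, tp, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", dataframe = "rows")
  invisible(c(paths, tp))
}

#' Read a wide protein-intensity TSV
#'
#' @param path TSV with a `protein` id column followed by one column per
#'   sample; empty cells are missing.
#' @return numeric matrix with protein rownames.
#' @export
read_protein_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("", "NA"),
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "protein") {
    stop("first column of the protein table must be named 'protein'")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$protein
  m
}

#' Read a long glycopeptide quantification TSV
#'
#' @param path TSV with columns `sample_id`, `protein`, `glycosite`,
#'   `glycan`, `rt`, `auc`.
#' @return data frame of quantification records.
#' @export
read_glyco_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(sample_id = "character",
                                         protein = "character",
                                         glycosite = "character",
                                         glycan = "character"))
  .check_glyco_records(df, need_rt = TRUE)
  df
}

#' Read the sample metadata TSV
#'
#' @param path TSV with columns `sample_id`, `grade` (Normal/G1/G2/G3) and
#'   `gleason` (GG2-GG5, `NA` for normals).
#' @return data frame of sample metadata.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  need <- c("sample_id", "grade", "gleason")
  if (!all(need %in% names(df))) {
    stop("metadata must have columns ", paste(need, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df
}
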