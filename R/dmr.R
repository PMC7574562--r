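#' Reference-normalized window features
#'
#' For each (sample, window): `norm_cov = log2(window_coverage + 1) -
#' log2(reference-chromosome total coverage)` (a log-ratio with pseudocount
#' 1) and `norm_frac = window_cg_fraction / reference-chromosome
#' cg_fraction`. Windows with no CG never enter (they are excluded by
#' [window_stats()]).
#'
#' @param ws a [window_stats()] object (typically 100-bp windows of the
#'   target chromosome).
#' @param cs the [chrom_stats()] of the same coverage matrix.
#' @param ref_chrom reference chromosome; every sample must have nonzero
#'   total coverage and CG-fraction there.
#' @return object of class `window_features`: list with `windows`,
#'   `norm_cov`, `norm_frac` (windows x samples), `raw_cov`, `raw_frac`,
#'   `sample_ids`, `ref_chrom`.
#' @examples
#' # window coverage 3 against a reference total of 1000:
#' # log2(3 + 1) - log2(1000) = -7.9658
#' @export
normalize_window_features <- function(ws, cs, ref_chrom) {
  stopifnot(inherits(ws, "window_stats"))
  ref <- cs[cs$chrom == ref_chrom, ]
  if (nrow(ref) == 0L) stop("reference chromosome missing from chrom stats", call. = FALSE)
  ref <- ref[match(ws$sample_ids, ref$sample_id), ]
  if (any(ref$total_coverage == 0)) {
    stop("zero reference-chromosome coverage for sample ",
         ref$sample_id[which(ref$total_coverage == 0)[1]], call. = FALSE)
  }
  if (any(ref$cg_fraction == 0)) {
    stop("zero reference-chromosome CG-fraction for sample ",
         ref$sample_id[which(ref$cg_fraction == 0)[1]], call. = FALSE)
  }
  norm_cov <- sweep(log2(ws$coverage + 1), 2L, log2(ref$total_coverage), "-")
  norm_frac <- sweep(ws$fraction, 2L, ref$cg_fraction, "/")
  structure(
    list(windows = ws$windows, norm_cov = norm_cov, norm_frac = norm_frac,
         raw_cov = ws$coverage, raw_frac = ws$fraction,
         sample_ids = ws$sample_ids, ref_chrom = ref_chrom),
    class = "window_features"
  )
}

#' Per-window logistic likelihood-ratio DMR test
#'
#' For every window a full logistic model `label ~ norm_cov + norm_frac
#' [+ fetal_sex + ff]` is compared against the null model carrying only
#' the covariates, by the chi-squared likelihood-ratio (analysis-of-
#' deviance) test with 2 degrees of freedom. Windows whose full model does
#' not converge are retried with fetal sex removed from both models (the
#' df stays 2); windows that still fail get `p = NA` and are excluded from
#' FDR adjustment downstream. Windows whose features are constant across
#' samples carry no information and return `p = 1`.
#'
#' Effect sizes are reported as `logFC_cov` and `logFC_frac`: log2 ratios
#' of (positive-group mean + eps) / (reference-group mean + eps) of the
#' linear-scale normalized coverage and fraction, with
#' `eps = 0.5 * min(positive mean)` per measure.
#'
#' @param features a [normalize_window_features()] object.
#' @param labels binary group labels aligned with the features' samples
#'   (factor, logical, or 0/1; the second level / `TRUE` is group B).
#' @param covariates optional data.frame with columns among `fetal_sex`
#'   and `ff`, one row per sample.
#' @param min_per_class minimum class size (default 3).
#' @return data.frame: window coordinates, `p`, `lrt_stat`, `df`,
#'   `logFC_cov`, `logFC_frac`, `delta_cov`, `delta_frac` (group-mean
#'   differences of the normalized features), `converged`.
#' @export
dmr_lrt <- function(features, labels, covariates = NULL, min_per_class = 3L) {
  stopifnot(inherits(features, "window_features"))
  y <- to_binary_label(labels)
  n <- length(y)
  if (n != length(features$sample_ids)) {
    stop("labels must match the feature samples", call. = FALSE)
  }
  if (min(table(y)) < min_per_class) {
    stop("fewer than ", min_per_class, " samples in a class", call. = FALSE)
  }
  cov_mat <- NULL
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == n)
    cov_mat <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  }

  W <- nrow(features$windows)
  p <- rep(NA_real_, W)
  stat <- rep(NA_real_, W)
  conv <- rep(TRUE, W)

  dev_null <- binom_deviance(cov_mat, y)
  dev_null_nosex <- if (!is.null(cov_mat) && "fetal_sexXY" %in% colnames(cov_mat)) {
    binom_deviance(cov_mat[, colnames(cov_mat) != "fetal_sexXY", drop = FALSE], y)
  } else NULL

  for (w in seq_len(W)) {
    x <- cbind(norm_cov = features$norm_cov[w, ], norm_frac = features$norm_frac[w, ])
    if (all(apply(x, 2L, function(v) length(unique(v)) == 1L))) {
      p[w] <- 1
      stat[w] <- 0
      next
    }
    full <- binom_deviance(cbind(x, cov_mat), y)
    if (!full$converged && !is.null(dev_null_nosex)) {
      # drop fetal sex from both models; df stays 2
      full <- binom_deviance(cbind(x, cov_mat[, colnames(cov_mat) != "fetal_sexXY",
                                              drop = FALSE]), y)
      nul <- dev_null_nosex
      conv[w] <- full$converged
    } else {
      nul <- dev_null
      conv[w] <- full$converged
    }
    s <- max(0, nul$deviance - full$deviance)
    stat[w] <- s
    p[w] <- stats::pchisq(s, df = 2L, lower.tail = FALSE)
  }

  # linear-scale effect sizes
  lin_cov <- 2^features$norm_cov
  grpB <- y == 1
  mB_cov <- rowMeans(lin_cov[, grpB, drop = FALSE])
  mA_cov <- rowMeans(lin_cov[, !grpB, drop = FALSE])
  mB_fr <- rowMeans(features$norm_frac[, grpB, drop = FALSE])
  mA_fr <- rowMeans(features$norm_frac[, !grpB, drop = FALSE])
  eps_cov <- 0.5 * min(c(mB_cov, mA_cov)[c(mB_cov, mA_cov) > 0], na.rm = TRUE)
  pos_fr <- c(mB_fr, mA_fr)[c(mB_fr, mA_fr) > 0]
  eps_fr <- if (length(pos_fr)) 0.5 * min(pos_fr) else 0.5

  out <- cbind(
    features$windows,
    data.frame(
      p = p, lrt_stat = stat, df = 2L,
      logFC_cov = log2((mB_cov + eps_cov) / (mA_cov + eps_cov)),
      logFC_frac = log2((mB_fr + eps_fr) / (mA_fr + eps_fr)),
      delta_cov = rowMeans(features$norm_cov[, grpB, drop = FALSE]) -
        rowMeans(features$norm_cov[, !grpB, drop = FALSE]),
      delta_frac = mB_fr - mA_fr,
      converged = conv
    )
  )
  rownames(out) <- NULL
  out
}

to_binary_label <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) return(as.integer(labels) - 1L)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
    return(as.integer(labels))
  }
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("labels must be binary", call. = FALSE)
  as.integer(f) - 1L
}

# logistic deviance via glm.fit on an explicit design (intercept added);
# returns deviance + convergence flag, NULL on hard failure
binom_deviance <- function(x, y) {
  X <- cbind(`(Intercept)` = rep(1, length(y)), x)
  warned <- FALSE
  fit <- withCallingHandlers(
    tryCatch(
      stats::glm.fit(X, y, family = stats::binomial(),
                     control = stats::glm.control(maxit = 100)),
      error = function(e) NULL
    ),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w))) warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (is.null(fit)) return(list(deviance = NA_real_, converged = FALSE))
  list(deviance = fit$deviance, converged = isTRUE(fit$converged) && !warned)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH q-values with monotonicity enforcement; `NA` p-values are
#' passed through untouched and do not count toward the number of tests.
#'
#' @param p p-values in `[0, 1]` (NA allowed).
#' @return q-values of the same length.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Overlap of two DMR sets with Fisher's exact test
#'
#' Builds the 2x2 table of window membership (in A x in B) over a stated
#' universe of tested windows, reports the sample odds ratio `ad / bc`
#' (with a Haldane correction of 0.5 per cell when any cell is zero,
#' flagged) and the two-sided Fisher exact p-value.
#'
#' @param set_a,set_b window identifiers (subsets of `universe`).
#' @param universe identifiers of all tested windows.
#' @return list: `overlap` (ids in both), `table` (2x2), `odds_ratio`,
#'   `haldane` (logical), `p`.
#' @export
intersect_dmr_sets <- function(set_a, set_b, universe) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("DMR sets must be subsets of the universe", call. = FALSE)
  }
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- table(factor(in_a, c(TRUE, FALSE)), factor(in_b, c(TRUE, FALSE)))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  haldane <- any(tab == 0)
  or <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else (a * d) / (b * c_)
  p <- stats::fisher.test(tab)$p.value
  list(overlap = intersect(set_a, set_b), table = tab,
       odds_ratio = unname(or), haldane = haldane, p = p)
}

#' Concordance of modification differences between two contrasts
#'
#' Pearson correlation between per-window group-mean differences observed
#' in two contrasts (e.g. pregnancy-specific vs CV-specific changes over
#' the shared placenta-specific DMRs).
#'
#' @param delta_a,delta_b aligned per-window effect vectors (>= 3 windows).
#' @return Pearson r.
#' @export
dmr_effect_concordance <- function(delta_a, delta_b) {
  if (length(delta_a) != length(delta_b) || length(delta_a) < 3L) {
    stop("need >= 3 aligned windows", call. = FALSE)
  }
  if (stats::sd(delta_a) == 0 || stats::sd(delta_b) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(delta_a, delta_b)
}

#' Two-sample Kolmogorov-Smirnov test of DMR positions
#'
#' Compares the positional distributions of two DMR sets along a
#' chromosome: `D = sup |ECDF_A - ECDF_B|` with the asymptotic p-value.
#'
#' @param positions_a,positions_b numeric positions (>= 5 each).
#' @return list `D`, `p`.
#' @export
dmr_positional_ks <- function(positions_a, positions_b) {
  if (length(positions_a) < 5L || length(positions_b) < 5L) {
    stop("need >= 5 positions per set", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(positions_a, positions_b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Per-window cross-validated classification AUC
#'
#' For each window, a leave-one-out logistic classifier on the window's
#' normalized coverage and fraction, fitted with a weakly-informative
#' Gaussian penalty (scale 2.5 on standardized coefficients, emulating a
#' Bayesian GLM with a weak prior) so that separable windows still yield
#' finite fits. AUC is computed over the held-out slope-only linear scores
#' `x %*% beta` — the per-fold intercept is excluded because it encodes
#' the fold's class base rate, which is not rank-comparable across folds
#' (see [loocv_classify()] for the same argument). Windows with AUC = 1
#' are the discriminatory ones.
#'
#' @param features a [normalize_window_features()] object.
#' @param karyotype binary labels (both classes >= 2 members).
#' @param windows optional integer subset of window rows to evaluate
#'   (default: all; restrict to significant windows for speed).
#' @param prior_scale scale of the Gaussian slope prior (default 2.5).
#' @return data.frame of window coordinates plus `cv_auc`.
#' @export
per_dmr_cv_auc <- function(features, karyotype, windows = NULL,
                           prior_scale = 2.5) {
  stopifnot(inherits(features, "window_features"))
  y <- to_binary_label(karyotype)
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stop("both classes need >= 2 members", call. = FALSE)
  }
  windows <- windows %||% seq_len(nrow(features$windows))
  lambda <- 1 / (2 * prior_scale^2)
  n <- length(y)
  cv_auc <- rep(NA_real_, length(windows))
  for (k in seq_along(windows)) {
    w <- windows[k]
    x <- cbind(features$norm_cov[w, ], features$norm_frac[w, ])
    score <- numeric(n)
    for (i in seq_len(n)) {
      fit <- penalized_logistic(x[-i, , drop = FALSE], y[-i], lambda = lambda)
      score[i] <- drop(x[i, , drop = FALSE] %*% fit$coefficients[-1])
    }
    cv_auc[k] <- auc(score, y)
  }
  out <- features$windows[windows, , drop = FALSE]
  out$cv_auc <- cv_auc
  rownames(out) <- NULL
  out
}
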