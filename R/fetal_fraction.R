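#' Bin-level read counts
#'
#' Totals reads in fixed-width, non-overlapping genomic bins (50 kb by
#' default), the representation used by count-based fetal-fraction
#' estimators. Unlike [window_stats()], the full tiling is returned —
#' bins without CG sites appear with zero counts — so that the bin layout
#' depends only on the genome, never on which sites happened to be
#' covered.
#'
#' @param cm a [coverage_matrix()].
#' @param width bin width in bp (default 50000).
#' @return list with `bins` (data.frame `chrom`, `start`, `end`) and
#'   `counts` (bins x samples matrix); column sums equal sample totals.
#' @export
bin_counts <- function(cm, width = 50000L) {
  stopifnot(inherits(cm, "coverage_matrix"))
  if (width <= 0) stop("`width` must be positive", call. = FALSE)
  chroms <- unique(cm$site_chrom)
  bins <- do.call(rbind, lapply(chroms, function(ch) {
    len <- as.numeric(cm$chrom_lengths[[ch]])
    starts <- seq(0, len - 1e-9, by = width)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + width, len)),
               stringsAsFactors = FALSE)
  }))
  key_all <- paste0(bins$chrom, ":", bins$start)
  site_key <- paste0(cm$site_chrom, ":",
                     (cm$site_pos %/% as.integer(width)) * as.integer(width))
  g <- factor(site_key, levels = key_all)
  counts <- rowsum(cm$counts, g, reorder = TRUE)
  # rowsum drops empty levels; rebuild the full tiling
  full <- matrix(0, nrow = length(key_all), ncol = ncol(cm$counts),
                 dimnames = list(key_all, cm$sample_ids))
  full[rownames(counts), ] <- counts
  list(bins = bins, counts = full[key_all, , drop = FALSE])
}

#' Fit a bin-regression fetal-fraction estimator
#'
#' Ridge-penalized linear regression of known fetal fractions on
#' depth-normalized bin proportions — a deliberately simple, deterministic
#' stand-in honoring the contract of count-based, fetal-sex-independent
#' estimators (SeqFF-like): fetal-derived reads redistribute coverage
#' toward placentally distinctive bins, so bin composition carries ff. It
#' is not a reimplementation of any published estimator and no published
#' weights are used; it must be trained on samples with known reference
#' fractions.
#'
#' @param bins a [bin_counts()] result for the training samples.
#' @param ff known fetal fractions, one per training sample (>= 10, not
#'   constant).
#' @param lambda ridge penalty on standardized bin proportions.
#' @param seed accepted for API symmetry; the fit is closed-form and
#'   deterministic.
#' @return object of class `ff_model`: bin layout, coefficients,
#'   intercept, training metadata.
#' @export
fit_ff <- function(bins, ff, lambda = 1, seed = NULL) {
  X <- prop_matrix(bins)
  n <- nrow(X)
  if (length(ff) != n) stop("one ff per training sample required", call. = FALSE)
  if (n < 10L) stop("need >= 10 training samples", call. = FALSE)
  if (stats::sd(ff) == 0) stop("constant ff in training set", call. = FALSE)

  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  use <- scl > 0
  Xs <- sweep(sweep(X[, use, drop = FALSE], 2L, ctr[use], "-"), 2L,
              scl[use], "/")
  ybar <- mean(ff)
  A <- crossprod(Xs) + diag(lambda, ncol(Xs))
  beta_s <- solve(A, crossprod(Xs, ff - ybar))
  beta <- numeric(ncol(X))
  beta[use] <- beta_s / scl[use]
  intercept <- ybar - sum(ctr * beta)
  structure(
    list(bins = bins$bins, width = bins$bins$end[1] - bins$bins$start[1],
         coefficients = beta, intercept = intercept,
         lambda = lambda, n_train = n, seed = seed),
    class = "ff_model"
  )
}

#' Predict fetal fraction from binned counts
#'
#' @param model an [fit_ff()] model.
#' @param bins a [bin_counts()] result with the same bin layout.
#' @return per-sample fetal-fraction estimates, clipped to `[0, 1]`.
#'   All-zero samples receive the clipped intercept.
#' @export
predict_ff <- function(model, bins) {
  stopifnot(inherits(model, "ff_model"))
  if (nrow(bins$bins) != nrow(model$bins) ||
      !all(bins$bins$chrom == model$bins$chrom &
             bins$bins$start == model$bins$start)) {
    stop("bin layout does not match the model", call. = FALSE)
  }
  X <- prop_matrix(bins, allow_zero = TRUE)
  est <- model$intercept + drop(X %*% model$coefficients)
  stats::setNames(pmin(1, pmax(0, est)), rownames(X))
}

# samples x bins row-normalized proportions
prop_matrix <- function(bins, allow_zero = FALSE) {
  X <- t(bins$counts)
  tot <- rowSums(X)
  if (any(tot == 0)) {
    if (!allow_zero) stop("sample with zero total count", call. = FALSE)
    tot[tot == 0] <- 1
  }
  X / tot
}
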