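#' Default reference chromosome for an assay
#'
#' The reference chromosome used to normalize the target-chromosome signal
#' is an analysis choice, and the pairings reported for these assays are
#' inconsistent (chr16/uCG with chr20/5hmCG, or the reverse). This helper
#' returns chr16 for uCG and chr20 for 5hmCG and (once per session) points
#' out that the choice is overridable.
#'
#' @param assay `"uCG"` or `"5hmCG"`.
#' @param quiet suppress the advisory message.
#' @return chromosome name.
#' @export
default_reference <- function(assay = c("uCG", "5hmCG"), quiet = FALSE) {
  assay <- match.arg(assay)
  if (!quiet && !isTRUE(getOption("epinipt.ref_note_shown"))) {
    message("Note: reported uCG/5hmCG reference-chromosome pairings are ",
            "ambiguous (chr16/chr20 vs chr20/chr16); using chr16 for uCG ",
            "and chr20 for 5hmCG. Override via `ref_chrom`.")
    options(epinipt.ref_note_shown = TRUE)
  }
  c(uCG = "chr16", `5hmCG` = "chr20")[[assay]]
}

#' Reference-normalized chromosome-ratio Z-scores
#'
#' For each sample i the statistic `X_i = S_target / S_ref` is the ratio of
#' the target-chromosome signal (CG-coverage or CG-fraction) to the same
#' signal on a reference chromosome. The healthy-pregnancy samples supply
#' the location and scale: `Z_i = (X_i - mu) / sigma` with `mu`, `sigma`
#' the mean and SD of X over `healthy_ids`. A trisomic fetus inflates the
#' fetal dosage of the target chromosome by 1.5, shifting X upward in
#' proportion to the effective fetal read share.
#'
#' The SD convention is the sample SD (n - 1) by default;
#' `sd_type = "population"` divides by n instead.
#'
#' @param cs a [chrom_stats()] data.frame.
#' @param target_chrom,ref_chrom target and reference chromosome names
#'   (must differ).
#' @param healthy_ids sample ids of the healthy-pregnancy training set
#'   (>= 3).
#' @param signal `"fraction"` (CG-fraction) or `"coverage"` (CG-coverage).
#' @param sd_type `"sample"` (n - 1, default) or `"population"` (n).
#' @return data.frame `sample_id`, `signal_kind`, `X`, `mu`, `sigma`, `Z`
#'   covering every sample in `cs`.
#' @examples
#' # healthy ratios 0.10, 0.11, 0.12 give mu = 0.11, sigma = 0.01 (sample
#' # SD); a test ratio of 0.14 scores Z = 3.
#' @export
chrom_ratio_zscores <- function(cs, target_chrom, ref_chrom, healthy_ids,
                                signal = c("fraction", "coverage"),
                                sd_type = c("sample", "population")) {
  signal <- match.arg(signal)
  sd_type <- match.arg(sd_type)
  if (identical(target_chrom, ref_chrom)) {
    stop("reference chromosome must differ from the target", call. = FALSE)
  }
  col <- if (signal == "coverage") "total_coverage" else "cg_fraction"
  X <- ratio_from_stats(cs, target_chrom, ref_chrom, col)
  if (length(healthy_ids) < 3L) stop("need >= 3 healthy training samples", call. = FALSE)
  if (!all(healthy_ids %in% names(X))) {
    stop("healthy_ids not all present in chrom stats", call. = FALSE)
  }
  mu <- mean(X[healthy_ids])
  sigma <- stats::sd(X[healthy_ids])
  if (sd_type == "population") {
    n <- length(healthy_ids)
    sigma <- sigma * sqrt((n - 1) / n)
  }
  if (!is.finite(sigma) || sigma == 0) {
    stop("degenerate training set: zero variance in healthy ratios", call. = FALSE)
  }
  data.frame(
    sample_id = names(X), signal_kind = signal,
    X = unname(X), mu = mu, sigma = sigma, Z = unname((X - mu) / sigma),
    stringsAsFactors = FALSE
  )
}

ratio_from_stats <- function(cs, target_chrom, ref_chrom, col) {
  tgt <- cs[cs$chrom == target_chrom, ]
  ref <- cs[cs$chrom == ref_chrom, ]
  if (nrow(tgt) == 0L || nrow(ref) == 0L) {
    stop("target or reference chromosome missing from chrom stats", call. = FALSE)
  }
  ref_v <- ref[[col]][match(tgt$sample_id, ref$sample_id)]
  if (any(ref_v == 0)) stop("zero reference-chromosome signal", call. = FALSE)
  stats::setNames(tgt[[col]] / ref_v, tgt$sample_id)
}

#' Leave-one-out cross-validated karyotype classification
#'
#' In every fold one sample is held out; `mu` and `sigma` are re-estimated
#' from the healthy training samples among the remainder (so a held-out
#' healthy sample never standardizes itself), Z-scores are recomputed, a
#' logistic regression of karyotype on Z is fitted to the retained samples
#' (ridge-stabilized, since the Z-scores separate the classes completely
#' when the assay works), and the held-out sample's class probability is
#' recorded.
#'
#' Accuracy uses the 0.5 probability cutoff. AUC is the rank statistic
#' (midrank ties) over the held-out *standardized Z-scores* rather than
#' the pooled fold probabilities: probabilities from different folds are
#' not rank-comparable (each fold carries its own base-rate calibration,
#' which under a null signal orders held-out negatives above held-out
#' positives and biases pooled-probability AUC far below 0.5), whereas the
#' held-out Z is an out-of-sample score on a common scale. With real
#' signal the two agree; under the null the Z-based AUC is correctly
#' centered at 0.5.
#'
#' @param x named vector of per-sample chromosome ratios X (from
#'   [chrom_ratio_zscores()]'s `X` column, or computed directly).
#' @param karyotype per-sample labels, `"euploid"` / `"T21"` (or a factor
#'   whose second level is the positive class); both classes need >= 2
#'   members.
#' @param healthy_ids ids used for mu/sigma estimation; defaults to the
#'   euploid samples.
#' @param sd_type SD convention, see [chrom_ratio_zscores()].
#' @param lambda ridge penalty of the per-fold logistic fit.
#' @return list with `prob` (held-out probabilities), `auc`, `accuracy`,
#'   `z_insample` (Z-scores from the full training set).
#' @export
loocv_classify <- function(x, karyotype, healthy_ids = NULL,
                           sd_type = c("sample", "population"),
                           lambda = 1e-4) {
  sd_type <- match.arg(sd_type)
  if (is.null(names(x))) names(x) <- paste0("sample_", seq_along(x))
  y <- karyotype_to_binary(karyotype)
  if (length(y) != length(x)) stop("labels must match samples", call. = FALSE)
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stop("both karyotype classes need >= 2 members", call. = FALSE)
  }
  healthy_ids <- healthy_ids %||% names(x)[y == 0]
  n <- length(x)
  prob <- stats::setNames(numeric(n), names(x))
  z_out <- stats::setNames(numeric(n), names(x))
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    h <- intersect(healthy_ids, names(x)[train])
    if (length(h) < 3L) stop("too few healthy samples in training fold", call. = FALSE)
    mu <- mean(x[h])
    sigma <- stats::sd(x[h])
    if (sd_type == "population") sigma <- sigma * sqrt((length(h) - 1) / length(h))
    if (sigma == 0) stop("degenerate training fold", call. = FALSE)
    z <- (x - mu) / sigma
    fit <- penalized_logistic(z[train], y[train], lambda = lambda)
    prob[i] <- predict(fit, z[i])
    z_out[i] <- z[i]
  }
  mu_all <- mean(x[intersect(healthy_ids, names(x))])
  sd_all <- stats::sd(x[intersect(healthy_ids, names(x))])
  list(
    prob = prob,
    z_heldout = z_out,
    auc = auc(z_out, y),
    accuracy = mean((prob > 0.5) == (y == 1)),
    z_insample = (x - mu_all) / sd_all
  )
}

karyotype_to_binary <- function(karyotype) {
  if (is.logical(karyotype)) return(as.integer(karyotype))
  if (is.factor(karyotype)) return(as.integer(karyotype) - 1L)
  if (is.numeric(karyotype)) {
    if (!all(karyotype %in% c(0, 1))) {
      stop("numeric karyotype labels must be 0/1", call. = FALSE)
    }
    return(as.integer(karyotype))
  }
  k <- as.character(karyotype)
  if (!all(k %in% c("euploid", "T21"))) {
    stop("karyotype labels must be 'euploid' or 'T21'", call. = FALSE)
  }
  as.integer(k == "T21")
}

#' Read-depth titration of classification performance
#'
#' For each depth and each of `n_reps` repetitions, every sample's library
#' is independently subsampled without replacement to the target depth,
#' chromosome statistics and reference-normalized Z-ratios are recomputed,
#' and leave-one-out classification is evaluated; the per-depth mean and SD
#' of AUC (and accuracy) summarize the curve. Optional natively shallow
#' samples (`extra`) are evaluated at their own depth alongside the
#' subsampled cohort, so natively shallow libraries can be evaluated
#' alongside downsampled deep ones.
#'
#' @param cm a [coverage_matrix()] restricted to the samples entering
#'   classification (healthy + T21).
#' @param karyotype labels aligned with `cm`'s samples.
#' @param target_chrom,ref_chrom chromosomes for the ratio.
#' @param depths read depths to titrate (strictly increasing).
#' @param n_reps subsampling repetitions per depth (default 30).
#' @param signal `"fraction"` or `"coverage"`.
#' @param healthy_ids mu/sigma training ids (default: euploid samples).
#' @param seed base RNG seed; repetition r at depth d uses a seed derived
#'   deterministically from `(seed, d, r)`.
#' @param extra optional list with `cm` and `karyotype` for natively
#'   shallow samples appended to every evaluation (their counts are used
#'   as-is, at their native depth).
#' @param sd_type SD convention.
#' @return object of class `titration_curve`: list with `results`
#'   (data.frame `depth`, `rep`, `auc`, `accuracy`) and `summary`
#'   (per-depth `mean_auc`, `sd_auc`, `min_auc`, `min_accuracy`).
#' @export
depth_titration <- function(cm, karyotype, target_chrom, ref_chrom, depths,
                            n_reps = 30L, signal = c("fraction", "coverage"),
                            healthy_ids = NULL, seed = 1L, extra = NULL,
                            sd_type = c("sample", "population")) {
  signal <- match.arg(signal)
  sd_type <- match.arg(sd_type)
  depths <- as.integer(depths)
  if (is.unsorted(depths, strictly = TRUE)) {
    stop("`depths` must be strictly increasing", call. = FALSE)
  }
  totals <- colSums(cm$counts)
  if (max(depths) > min(totals)) {
    stop("depth ", max(depths), " infeasible: sample ",
         cm$sample_ids[which.min(totals)], " has only ", min(totals),
         " reads", call. = FALSE)
  }
  y <- karyotype_to_binary(karyotype)
  healthy_ids <- healthy_ids %||% cm$sample_ids[y == 0]
  col <- if (signal == "coverage") "total_coverage" else "cg_fraction"

  extra_x <- NULL
  extra_y <- NULL
  if (!is.null(extra)) {
    ecs <- chrom_stats(extra$cm)
    extra_x <- ratio_from_stats(ecs, target_chrom, ref_chrom, col)
    extra_y <- karyotype_to_binary(extra$karyotype)
  }

  res <- expand.grid(depth = depths, rep = seq_len(n_reps))
  res$auc <- NA_real_
  res$accuracy <- NA_real_
  for (k in seq_len(nrow(res))) {
    d <- res$depth[k]
    r <- res$rep[k]
    sub <- subsample_counts(cm, d, seed = derive_seed(seed, match(d, depths), r))
    cs <- chrom_stats(sub)
    x <- ratio_from_stats(cs, target_chrom, ref_chrom, col)
    yy <- y
    if (!is.null(extra_x)) {
      x <- c(x, extra_x)
      yy <- c(y, extra_y)
    }
    cv <- loocv_classify(x, yy, healthy_ids = healthy_ids, sd_type = sd_type)
    res$auc[k] <- cv$auc
    res$accuracy[k] <- cv$accuracy
  }
  summ <- do.call(rbind, lapply(split(res, res$depth), function(dd) {
    data.frame(depth = dd$depth[1], mean_auc = mean(dd$auc),
               sd_auc = stats::sd(dd$auc), min_auc = min(dd$auc),
               mean_accuracy = mean(dd$accuracy),
               min_accuracy = min(dd$accuracy))
  }))
  rownames(summ) <- NULL
  structure(list(results = res, summary = summ, signal = signal,
                 n_reps = n_reps, seed = seed),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat("<titration_curve>", x$signal, "signal,", x$n_reps, "reps/depth\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
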