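#' Bray-Curtis dissimilarity between samples
#'
#' `d(a, b) = sum|a_i - b_i| / sum(a_i + b_i)` over rows of a non-negative
#' matrix (samples x sites). Computed with [vegan::vegdist()]. Note the
#' classical "similarity index" naming in the ecology literature: the
#' quantity used here is the standard dissimilarity form, 0 for identical
#' profiles and 1 for disjoint supports.
#'
#' @param x non-negative matrix, samples as rows (or a
#'   [coverage_matrix()], transposed internally).
#' @return a `dist` of pairwise dissimilarities in `[0, 1]`.
#' @export
bray_curtis <- function(x) {
  if (inherits(x, "coverage_matrix")) x <- t(x$counts)
  x <- as.matrix(x)
  if (any(x < 0)) stop("Bray-Curtis requires non-negative data", call. = FALSE)
  if (sum(rowSums(x) == 0) >= 2L) {
    stop("dissimilarity undefined between all-zero samples", call. = FALSE)
  }
  vegan::vegdist(x, method = "bray")
}

#' Non-metric multidimensional scaling of a dissimilarity
#'
#' Kruskal's iterative procedure (monotone regression of configuration
#' distances on dissimilarity ranks, stress-1 badness-of-fit), run through
#' [vegan::metaMDS()] with random restarts from which the lowest-stress
#' converged solution is kept. The embedding is centered at the origin.
#'
#' @param d a `dist` (e.g. from [bray_curtis()]).
#' @param k embedding dimension (default 2).
#' @param restarts random restarts (default 20).
#' @param maxit iteration cap per start.
#' @param seed RNG seed for the restarts.
#' @return object of class `nmds_result`: list with `points` (n x k
#'   matrix), `stress` (Kruskal stress-1, on vegan's [0, 1] scale),
#'   `converged`, `n_restarts`.
#' @export
nmds <- function(d, k = 2L, restarts = 20L, maxit = 200L, seed = 1L) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  if (any(!is.finite(d))) stop("non-finite dissimilarities", call. = FALSE)
  if (restarts < 1L) stop("`restarts` must be >= 1", call. = FALSE)
  fit <- with_seed(seed, {
    vegan::metaMDS(d, k = k, trymax = restarts, maxit = maxit,
                   autotransform = FALSE, wascores = FALSE, trace = 0)
  })
  pts <- scale(fit$points, center = TRUE, scale = FALSE)
  colnames(pts) <- paste0("nMDS", seq_len(k))
  structure(
    list(points = pts, stress = fit$stress, converged = isTRUE(fit$converged),
         n_restarts = restarts),
    class = "nmds_result"
  )
}

#' Flag ordination outliers by the per-group 2-SD rule
#'
#' A sample is flagged when, on either ordination axis, it lies more than
#' `k` standard deviations from the mean of its own sample group. Flagged
#' samples are reported, never silently dropped. Groups with fewer than 3
#' members cannot support the rule and are skipped with a warning.
#'
#' @param embedding n x 2 coordinate matrix, or an `nmds_result`.
#' @param groups group label per sample.
#' @param k SD multiplier (default 2).
#' @return data.frame `sample_id`, `group`, `z1`, `z2` (per-axis deviations
#'   in group-SD units), `outlier`.
#' @export
flag_outliers <- function(embedding, groups, k = 2) {
  if (inherits(embedding, "nmds_result")) embedding <- embedding$points
  embedding <- as.matrix(embedding)
  if (ncol(embedding) < 2L) stop("need at least 2 embedding axes", call. = FALSE)
  if (nrow(embedding) != length(groups)) {
    stop("`groups` must have one label per sample", call. = FALSE)
  }
  ids <- rownames(embedding) %||% as.character(seq_len(nrow(embedding)))
  out <- data.frame(sample_id = ids, group = as.character(groups),
                    z1 = NA_real_, z2 = NA_real_, outlier = FALSE,
                    stringsAsFactors = FALSE)
  for (g in unique(out$group)) {
    sel <- out$group == g
    if (sum(sel) < 3L) {
      warning("group '", g, "' has fewer than 3 samples; outlier rule skipped")
      next
    }
    for (ax in 1:2) {
      v <- embedding[sel, ax]
      s <- stats::sd(v)
      z <- if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
      out[[paste0("z", ax)]][sel] <- z
    }
    out$outlier[sel] <- abs(out$z1[sel]) > k | abs(out$z2[sel]) > k
  }
  out
}

#' One-way ANOVA across sample groups
#'
#' Fixed-effects one-way ANOVA of a per-sample summary statistic (total
#' coverage or CG-fraction) across groups, optionally after log2
#' transformation as used for total sequencing coverage.
#'
#' @param values numeric per-sample values.
#' @param groups group label per sample (>= 2 groups).
#' @param log2_transform apply `log2(values)` first.
#' @return list with `F`, `p`, `df` (between, within).
#' @export
group_anova <- function(values, groups, log2_transform = FALSE) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (length(values) - nlevels(groups) < 1L) {
    stop("not enough residual degrees of freedom", call. = FALSE)
  }
  if (log2_transform) values <- log2(values)
  if (max(values) - min(values) <= 1e-12 * max(abs(values), 1)) {
    # constant response: no variance anywhere
    return(list(F = 0, p = 1, df = c(nlevels(groups) - 1L,
                                     length(values) - nlevels(groups))))
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  Fv <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  msb <- tab[["Mean Sq"]][1]
  msw <- tab[["Mean Sq"]][2]
  if (is.nan(Fv) || msw <= 1e-10 * msb) {
    # degenerate separation: zero within-group variance
    Fv <- Inf
    p <- 0
  }
  list(F = Fv, p = p, df = tab[["Df"]])
}
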