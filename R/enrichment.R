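#' Top-signal windows per sample group
#'
#' Divides the genome into fixed-width windows (1 kb in the standard
#' analysis), averages per-window total coverage within each sample group,
#' and returns the windows at or above the `1 - quantile` coverage
#' quantile (top 10% by default). Boundary ties are all included, which
#' keeps the selection deterministic; a fully uniform profile therefore
#' degenerates to "all windows" and is flagged.
#'
#' @param cm a [coverage_matrix()].
#' @param groups group label per sample.
#' @param width window width in bp (default 1000).
#' @param quantile upper tail mass to select (default 0.10).
#' @return named list (one entry per group): list with `windows`
#'   (data.frame `chrom`, `start`, `end`), `threshold`, `degenerate`.
#' @export
top_signal_windows <- function(cm, groups, width = 1000L, quantile = 0.10) {
  stopifnot(inherits(cm, "coverage_matrix"))
  stopifnot_scalar_prob(quantile, "quantile")
  if (length(groups) != ncol(cm$counts)) {
    stop("`groups` must label every sample", call. = FALSE)
  }
  ws <- window_stats(cm, width = width)
  out <- list()
  for (g in unique(as.character(groups))) {
    sel <- groups == g
    if (!any(sel)) stop("empty group ", g, call. = FALSE)
    mean_cov <- rowMeans(ws$coverage[, sel, drop = FALSE])
    thr <- stats::quantile(mean_cov, probs = 1 - quantile, names = FALSE)
    hit <- mean_cov >= thr
    out[[g]] <- list(
      windows = ws$windows[hit, c("chrom", "start", "end"), drop = FALSE],
      threshold = thr,
      degenerate = all(hit)
    )
    if (all(hit)) {
      warning("group '", g, "': uniform coverage, all windows tied at the threshold")
    }
  }
  out
}

#' CG-site enrichment of annotations in top-signal windows
#'
#' Contingency analysis at CG-site resolution: every CG of the catalog is
#' classified by (inside a top-signal window) x (overlapping the
#' annotation); Fisher's exact test gives the odds ratio and p-value. A CG
#' overlaps an annotation when its C position lies in the half-open
#' interval.
#'
#' @param top_windows data.frame `chrom`, `start`, `end` (e.g. one group's
#'   `windows` from [top_signal_windows()]).
#' @param annotation data.frame `chrom`, `start`, `end` intervals.
#' @param cg_catalog data.frame `chrom`, `pos` — the CG universe.
#' @return one-row data.frame: `n11`, `n10`, `n01`, `n00`, `odds_ratio`,
#'   `haldane`, `p`, `overlap_fraction` (fraction of top-window CGs
#'   overlapping the annotation).
#' @export
site_enrichment <- function(top_windows, annotation, cg_catalog) {
  in_top <- in_annot(cg_catalog, top_windows)
  if (is.null(annotation) || nrow(annotation) == 0L ||
      !any(annotation$chrom %in% cg_catalog$chrom)) {
    warning("annotation does not overlap the catalog chromosomes")
    return(data.frame(n11 = 0L, n10 = sum(in_top), n01 = 0L,
                      n00 = sum(!in_top), odds_ratio = NA_real_,
                      haldane = NA, p = NA_real_, overlap_fraction = 0))
  }
  in_ann <- in_annot(cg_catalog, annotation)
  fisher_2x2(in_top, in_ann)
}

fisher_2x2 <- function(flag_a, flag_b) {
  n11 <- sum(flag_a & flag_b)
  n10 <- sum(flag_a & !flag_b)
  n01 <- sum(!flag_a & flag_b)
  n00 <- sum(!flag_a & !flag_b)
  haldane <- any(c(n11, n10, n01, n00) == 0L)
  or <- if (haldane) {
    ((n11 + 0.5) * (n00 + 0.5)) / ((n10 + 0.5) * (n01 + 0.5))
  } else (n11 * n00) / (n10 * n01)
  p <- stats::fisher.test(matrix(c(n11, n01, n10, n00), 2L))$p.value
  data.frame(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
             odds_ratio = or, haldane = haldane, p = p,
             overlap_fraction = if (n11 + n10 > 0) n11 / (n11 + n10) else 0)
}

#' mQTL-probe overlap with DMRs
#'
#' Tests whether array probes flagged as methylation QTLs fall inside DMR
#' windows more often than expected: Fisher's exact test on
#' (probe is mQTL) x (probe inside a DMR) over all probes, plus the
#' fraction of DMRs containing at least one mQTL probe. A non-significant
#' result supports the DMRs not being driven by genotype.
#'
#' @param probes data.frame `chrom`, `pos`, `mqtl` (logical), e.g.
#'   `genome$mqtl_probes`.
#' @param dmr_windows data.frame `chrom`, `start`, `end`.
#' @return one-row data.frame as in [site_enrichment()], with
#'   `dmr_overlap_fraction` = fraction of DMRs hit by an mQTL probe.
#' @export
probe_dmr_enrichment <- function(probes, dmr_windows) {
  if (nrow(dmr_windows) == 0L) stop("no DMR windows supplied", call. = FALSE)
  rel <- probes[probes$chrom %in% unique(dmr_windows$chrom), , drop = FALSE]
  if (nrow(rel) == 0L) {
    stop("no probes on the DMR chromosomes", call. = FALSE)
  }
  in_dmr <- in_annot(rel[, c("chrom", "pos")], dmr_windows)
  res <- fisher_2x2(rel$mqtl, in_dmr)
  mq <- rel[rel$mqtl, , drop = FALSE]
  hit <- vapply(seq_len(nrow(dmr_windows)), function(i) {
    any(mq$chrom == dmr_windows$chrom[i] &
          mq$pos >= dmr_windows$start[i] & mq$pos < dmr_windows$end[i])
  }, logical(1))
  res$dmr_overlap_fraction <- mean(hit)
  res
}
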