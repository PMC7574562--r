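#' Per-CG read count matrix
#'
#' The central container of the pipeline: a sites x samples matrix of
#' non-negative integer read counts plus the CG-site index (chromosome and
#' 0-based position of the C), stored features-by-samples in the usual
#' genomics orientation.
#'
#' @param counts integer matrix, sites x samples.
#' @param site_chrom,site_pos site index vectors, sorted by (chrom, pos)
#'   with no duplicates; positions 0-based.
#' @param sample_ids column names; defaults to `counts` colnames or
#'   `sample_1 ...`.
#' @param chrom_lengths optional named lengths (bp); required by windowing
#'   so tilings cover whole chromosomes, inferred as `max(pos) + 1` per
#'   chromosome when absent.
#' @return object of class `coverage_matrix`.
#' @export
coverage_matrix <- function(counts, site_chrom, site_pos, sample_ids = NULL,
                            chrom_lengths = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != length(site_chrom) || nrow(counts) != length(site_pos)) {
    stop("site index length does not match counts rows", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  site_chrom <- as.character(site_chrom)
  chroms <- unique(site_chrom)
  o <- order(match(site_chrom, chroms), site_pos)
  if (is.unsorted(o)) {
    counts <- counts[o, , drop = FALSE]
    site_chrom <- site_chrom[o]
    site_pos <- site_pos[o]
  }
  if (anyDuplicated(paste0(site_chrom, ":", site_pos))) {
    stop("duplicate CG sites in index", call. = FALSE)
  }
  sample_ids <- sample_ids %||% colnames(counts) %||%
    paste0("sample_", seq_len(ncol(counts)))
  colnames(counts) <- sample_ids
  storage.mode(counts) <- "integer"
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(site_pos, site_chrom, max) + 1
    chrom_lengths <- chrom_lengths[chroms]
  }
  structure(
    list(counts = counts, site_chrom = site_chrom,
         site_pos = as.integer(site_pos),
         sample_ids = sample_ids,
         chrom_lengths = chrom_lengths),
    class = "coverage_matrix"
  )
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("<coverage_matrix> %d CG sites x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$site_chrom), collapse = ", ")))
  invisible(x)
}

#' Assign mapped read starts to CG sites
#'
#' A read is assigned to the nearest CG whose C position lies within 3 bp
#' of the read's 5' start (`|start - pos| <= max_dist`, both strands
#' counted, strand ignored for the distance); ties between two equidistant
#' CGs go to the lower coordinate. Reads with no CG within range are
#' dropped and tallied per sample, as are reads on chromosomes absent from
#' the catalog (with a warning).
#'
#' @param read_starts data.frame with `chrom`, `start` (0-based 5' start)
#'   and optionally `name` (sample id; single sample assumed when absent).
#' @param cg_catalog data.frame with `chrom`, `pos` (sorted C positions),
#'   e.g. `genome$sites`.
#' @param max_dist assignment radius in bp (default 3).
#' @param chrom_lengths optional named chromosome lengths passed through to
#'   the result.
#' @return list with `matrix` (a [coverage_matrix()] over the full catalog),
#'   and `qc`: per-sample data.frame of `assigned` / `dropped` read counts.
#' @examples
#' cat <- data.frame(chrom = "chr1", pos = c(100L, 200L))
#' rs <- data.frame(chrom = "chr1", start = c(97L, 100L, 103L, 104L))
#' count_cg_coverage(rs, cat)$matrix$counts  # site 100 gets 3 reads
#' @export
count_cg_coverage <- function(read_starts, cg_catalog, max_dist = 3L,
                              chrom_lengths = NULL) {
  stopifnot(all(c("chrom", "start") %in% names(read_starts)),
            all(c("chrom", "pos") %in% names(cg_catalog)))
  sample_of <- if ("name" %in% names(read_starts)) {
    as.character(read_starts$name)
  } else rep("sample", nrow(read_starts))
  samples <- unique(sample_of)
  cat_chroms <- unique(as.character(cg_catalog$chrom))

  unknown <- !(read_starts$chrom %in% cat_chroms)
  if (any(unknown)) {
    warning(sum(unknown), " reads on chromosomes absent from the catalog were dropped")
  }

  n_sites <- nrow(cg_catalog)
  # global site ordering must match coverage_matrix()'s
  o <- order(match(as.character(cg_catalog$chrom), cat_chroms), cg_catalog$pos)
  cat_chrom <- as.character(cg_catalog$chrom)[o]
  cat_pos <- as.integer(cg_catalog$pos)[o]
  offset <- c(0L, cumsum(table(factor(cat_chrom, levels = cat_chroms))))
  names(offset) <- c(cat_chroms, "end")

  site_idx <- rep(NA_integer_, nrow(read_starts))
  for (ch in cat_chroms) {
    rsel <- which(read_starts$chrom == ch)
    if (!length(rsel)) next
    pos <- cat_pos[cat_chrom == ch]
    st <- as.integer(read_starts$start[rsel])
    lo <- findInterval(st, pos)
    hi <- pmin(lo + 1L, length(pos))
    lo_ok <- lo >= 1L
    d_lo <- ifelse(lo_ok, st - pos[pmax(lo, 1L)], .Machine$integer.max)
    d_hi <- abs(pos[hi] - st)
    pick_lo <- lo_ok & d_lo <= d_hi            # tie -> lower coordinate
    idx <- ifelse(pick_lo, lo, hi)
    dist <- ifelse(pick_lo, d_lo, d_hi)
    idx[dist > max_dist] <- NA_integer_
    site_idx[rsel] <- idx + offset[[ch]]
  }

  counts <- matrix(0L, nrow = n_sites, ncol = length(samples),
                   dimnames = list(NULL, samples))
  qc <- data.frame(sample_id = samples, assigned = 0L, dropped = 0L,
                   stringsAsFactors = FALSE)
  for (j in seq_along(samples)) {
    sel <- sample_of == samples[j]
    idx <- site_idx[sel]
    ok <- !is.na(idx)
    counts[, j] <- tabulate(idx[ok], nbins = n_sites)
    qc$assigned[j] <- sum(ok)
    qc$dropped[j] <- sum(!ok)
  }
  cm <- coverage_matrix(counts, cat_chrom, cat_pos, sample_ids = samples,
                        chrom_lengths = chrom_lengths)
  list(matrix = cm, qc = qc)
}

#' Chromosome-level CG-coverage and CG-fraction
#'
#' CG-coverage of a chromosome is the total read count over its CG sites;
#' CG-fraction is the fraction of its CG sites covered by at least one
#' read. These are the two signals entering the karyotype Z-score.
#'
#' @param cm a [coverage_matrix()].
#' @return data.frame with one row per (sample, chromosome):
#'   `sample_id`, `chrom`, `total_coverage`, `covered_sites`, `n_sites`,
#'   `cg_fraction`.
#' @export
chrom_stats <- function(cm) {
  stopifnot(inherits(cm, "coverage_matrix"))
  if (nrow(cm$counts) == 0L) stop("empty coverage matrix", call. = FALSE)
  chroms <- unique(cm$site_chrom)
  g <- factor(cm$site_chrom, levels = chroms)
  tot <- rowsum(cm$counts, g, reorder = FALSE)
  cov <- rowsum((cm$counts > 0L) + 0L, g, reorder = FALSE)
  n_sites <- as.integer(table(g))
  out <- data.frame(
    sample_id = rep(cm$sample_ids, each = length(chroms)),
    chrom = rep(chroms, times = length(cm$sample_ids)),
    total_coverage = as.vector(tot),
    covered_sites = as.integer(cov),
    n_sites = rep(n_sites, times = length(cm$sample_ids)),
    stringsAsFactors = FALSE
  )
  out$cg_fraction <- out$covered_sites / out$n_sites
  out
}

#' Window-level coverage statistics
#'
#' Tiles each requested chromosome with fixed-width, non-overlapping,
#' 0-based half-open windows and reports per-window CG-coverage (sum of
#' member-site counts) and CG-fraction (covered members / members). Only
#' windows containing at least one CG are returned; the number of empty
#' (excluded) tiling windows is recorded.
#'
#' @param cm a [coverage_matrix()].
#' @param width window width in bp (> 0). The DMR analysis uses 100 bp,
#'   the signal-enrichment analysis 1,000 bp.
#' @param chroms chromosomes to tile (default: all in `cm`).
#' @return object of class `window_stats`: list with `windows` (data.frame
#'   `chrom`, `start`, `end`, `n_cg`), `coverage` and `covered` matrices
#'   (windows x samples), `fraction`, `sample_ids`, `width`,
#'   `n_empty_excluded`.
#' @export
window_stats <- function(cm, width = 100L, chroms = NULL) {
  stopifnot(inherits(cm, "coverage_matrix"))
  if (width <= 0) stop("`width` must be positive", call. = FALSE)
  chroms <- chroms %||% unique(cm$site_chrom)
  keep <- cm$site_chrom %in% chroms
  if (!any(keep)) stop("no sites on requested chromosomes", call. = FALSE)
  sc <- cm$site_chrom[keep]
  sp <- cm$site_pos[keep]
  win <- sp %/% as.integer(width)
  key <- paste0(sc, ":", win)
  # preserve genomic order
  uk <- unique(key)
  g <- factor(key, levels = uk)
  cov <- rowsum(cm$counts[keep, , drop = FALSE], g, reorder = FALSE)
  cvd <- rowsum((cm$counts[keep, , drop = FALSE] > 0L) + 0L, g, reorder = FALSE)
  n_cg <- as.integer(table(g))
  first <- !duplicated(key)
  wchrom <- sc[first]
  wstart <- (win[first]) * as.integer(width)
  n_total <- sum(ceiling(unlist(cm$chrom_lengths[chroms]) / width))
  structure(
    list(
      windows = data.frame(chrom = wchrom, start = as.integer(wstart),
                           end = as.integer(wstart + width), n_cg = n_cg,
                           stringsAsFactors = FALSE),
      coverage = cov,
      covered = cvd,
      fraction = cvd / n_cg,
      sample_ids = cm$sample_ids,
      width = as.integer(width),
      n_empty_excluded = as.integer(n_total - length(uk))
    ),
    class = "window_stats"
  )
}

#' Subsample reads without replacement
#'
#' Draws `n` of a sample's assigned reads uniformly without replacement
#' (a multivariate hypergeometric draw over sites), emulating in silico
#' library downsampling. Column sums of the result equal `n` exactly.
#'
#' @param cm a [coverage_matrix()].
#' @param n target read count, a scalar or one value per sample; must not
#'   exceed any sample's total.
#' @param seed RNG seed.
#' @return a new [coverage_matrix()] over the same site index.
#' @export
subsample_counts <- function(cm, n, seed = 1L) {
  stopifnot(inherits(cm, "coverage_matrix"))
  ns <- ncol(cm$counts)
  n <- rep_len(as.integer(n), ns)
  totals <- colSums(cm$counts)
  if (any(n > totals)) {
    bad <- cm$sample_ids[which(n > totals)[1]]
    stop("requested depth exceeds available reads for sample ", bad, call. = FALSE)
  }
  with_seed(seed, {
    out <- matrix(0L, nrow = nrow(cm$counts), ncol = ns,
                  dimnames = list(NULL, cm$sample_ids))
    for (j in seq_len(ns)) {
      if (n[j] == 0L) next
      cj <- cm$counts[, j]
      if (n[j] == totals[j]) {
        out[, j] <- cj
        next
      }
      nz <- which(cj > 0L)
      reads <- rep.int(nz, cj[nz])
      keep <- sample.int(length(reads), n[j])
      out[, j] <- tabulate(reads[keep], nbins = nrow(cm$counts))
    }
    coverage_matrix(out, cm$site_chrom, cm$site_pos, cm$sample_ids,
                    cm$chrom_lengths)
  })
}

#' Hellinger transformation of a count matrix
#'
#' Each entry becomes the square root of its within-sample relative
#' abundance, `sqrt(x_ij / rowsum_i)`, so every sample (row) has unit sum
#' of squares. Standard variance-stabilizing pre-treatment for ordination
#' of count compositions.
#'
#' @param x numeric matrix with samples as rows, or a [coverage_matrix()]
#'   (transposed internally so rows are samples).
#' @return transformed numeric matrix, samples x sites.
#' @export
hellinger <- function(x) {
  if (inherits(x, "coverage_matrix")) x <- t(x$counts)
  x <- as.matrix(x)
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  rs <- rowSums(x)
  if (any(rs == 0)) {
    bad <- rownames(x)[which(rs == 0)[1]] %||% as.character(which(rs == 0)[1])
    stop("sample ", bad, " has zero total count", call. = FALSE)
  }
  sqrt(sweep(x, 1L, rs, "/"))
}
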