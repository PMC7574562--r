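# Small fixtures built in code. The `tiny_*` family keeps unit tests fast;
# study-scale objects live only in the acceptance tests.

tiny_genome <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(chrom_lengths = c(chr21 = 3e5, chr16 = 3e5, chr20 = 3e5),
         dmr_n = 10L, mqtl_n = 100L),
    list(...)
  )
  build_genome(do.call(genome_config, args), seed = seed)
}

tiny_cohort <- function(genome, seed = 1, assay = "uCG", depth = 8000, ...) {
  simulate_cohort(genome, cohort_config(assay, depth = depth, ...), seed = seed)
}

# coverage_matrix from explicit per-site counts (sites x samples)
manual_cm <- function(counts, pos, chrom = "chr21", chrom_len = NULL) {
  counts <- as.matrix(counts)
  coverage_matrix(counts, rep(chrom, length(pos)), pos,
                  chrom_lengths = stats::setNames(
                    list(chrom_len %||% (max(pos) + 1)), chrom))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# chrom_stats-shaped data.frame from explicit ratios (ref signal fixed at 1)
manual_ratio_stats <- function(ratios, ids = names(ratios)) {
  ids <- ids %||% paste0("s", seq_along(ratios))
  rbind(
    data.frame(sample_id = ids, chrom = "chr21", total_coverage = ratios,
               covered_sites = 1L, n_sites = 1L, cg_fraction = ratios),
    data.frame(sample_id = ids, chrom = "chr16", total_coverage = 1,
               covered_sites = 1L, n_sites = 1L, cg_fraction = 1)
  )
}

# window_features built directly from feature matrices (windows x samples)
manual_features <- function(norm_cov, norm_frac, sample_ids = NULL) {
  W <- nrow(norm_cov)
  sample_ids <- sample_ids %||% paste0("s", seq_len(ncol(norm_cov)))
  colnames(norm_cov) <- sample_ids
  colnames(norm_frac) <- sample_ids
  structure(
    list(
      windows = data.frame(chrom = "chr21", start = (seq_len(W) - 1L) * 100L,
                           end = seq_len(W) * 100L, n_cg = 1L),
      norm_cov = norm_cov, norm_frac = norm_frac,
      raw_cov = 2^norm_cov, raw_frac = norm_frac,
      sample_ids = sample_ids, ref_chrom = "chr16"
    ),
    class = "window_features"
  )
}
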