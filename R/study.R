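#' Study-scale genome configurations
#'
#' Per-assay genome geometries used by the package's karyotyping benchmark
#' simulations. Scaling rationale (see the methods vignette for the full
#' argument):
#'
#' * Depths are mapped to the synthetic genome by per-CG coverage density
#'   ([scaled_depth()]), so the sampling noise of a chromosome-ratio
#'   statistic at a given paper-scale depth is governed by the synthetic
#'   CG-site count.
#' * The uCG genome carries ~600k CG sites and the 5hmCG genome ~2M sites
#'   so that, at the shallowest depths titrated (3M and 1M paper-scale
#'   reads respectively), the target chromosome still receives tens of
#'   thousands of reads — the regime in which the corresponding real
#'   analyses operate — and Z-score separation is governed by the
#'   biological effect rather than starved counting noise.
#' * The target (chr21 analog) and the assay's reference chromosome take
#'   45% of the genome each, the third chromosome 10%: concentrating CG
#'   mass on the two chromosomes entering the ratio minimizes its
#'   multinomial sampling variance at a fixed genome size.
#'
#' @param assay `"uCG"` or `"5hmCG"`.
#' @return a [genome_config()].
#' @export
study_genome_config <- function(assay = c("uCG", "5hmCG")) {
  assay <- match.arg(assay)
  # no planted marker windows: karyotype statistics should be driven purely
  # by the domain-level biology, and marker mass on the target chromosome
  # would couple the chromosome ratio to fetal-fraction variability
  if (assay == "uCG") {
    genome_config(chrom_lengths = c(chr21 = 54e6, chr16 = 54e6, chr20 = 12e6),
                  dmr_n = 0L)
  } else {
    genome_config(chrom_lengths = c(chr21 = 90e6, chr20 = 90e6, chr16 = 20e6),
                  dmr_n = 0L)
  }
}

#' Simulate a study-like cohort
#'
#' Builds the per-assay study-scale genome and simulates the default
#' cohort (uCG: 7 NPC / 8 healthy / 5 T21 / 7 CVS; 5hmCG: 7 / 7 / 4 / 3)
#' at full depth (the [scaled_depth()] equivalent of 8M processed reads
#' for uCG, 4M for 5hmCG), with fetal fractions uniform on 6-10% and T21
#' dosage 1.5.
#'
#' @param assay `"uCG"` or `"5hmCG"`.
#' @param seed RNG seed; the genome and the cohort use seeds derived from
#'   it.
#' @param cohort optional [cohort_config()] override.
#' @return list as [simulate_cohort()], plus `genome` and convenience
#'   fields `karyo_ids` (healthy + T21 sample ids), `karyotype`,
#'   `healthy_ids`, `ref_chrom`.
#' @export
study_cohort <- function(assay = c("uCG", "5hmCG"), seed = 1L, cohort = NULL) {
  assay <- match.arg(assay)
  genome <- build_genome(study_genome_config(assay), seed = derive_seed(seed, 1))
  cohort <- cohort %||% cohort_config(assay = assay)
  sim <- simulate_cohort(genome, cohort, seed = derive_seed(seed, 2))
  labeled <- !is.na(sim$meta$karyotype)
  sim$genome <- genome
  sim$karyo_ids <- sim$meta$sample_id[labeled]
  sim$karyotype <- sim$meta$karyotype[labeled]
  sim$healthy_ids <- sim$meta$sample_id[labeled & sim$meta$karyotype == "euploid"]
  sim$ref_chrom <- default_reference(assay, quiet = TRUE)
  sim
}

#' Restrict a coverage matrix to selected samples
#'
#' @param cm a [coverage_matrix()].
#' @param sample_ids columns to keep, in the given order.
#' @return a [coverage_matrix()].
#' @export
select_samples <- function(cm, sample_ids) {
  stopifnot(inherits(cm, "coverage_matrix"))
  idx <- match(sample_ids, cm$sample_ids)
  if (anyNA(idx)) stop("unknown sample id(s)", call. = FALSE)
  coverage_matrix(cm$counts[, idx, drop = FALSE], cm$site_chrom, cm$site_pos,
                  sample_ids = sample_ids, chrom_lengths = cm$chrom_lengths)
}
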