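#' Configuration for a simulated cfDNA cohort
#'
#' Default group sizes follow the cohort design the simulator emulates:
#' for uCG, 7 non-pregnant controls (NPC), 8 healthy pregnancies, 5 T21
#' pregnancies and 7 chorionic-villus samples (CVS); for 5hmCG, 7 NPC,
#' 7 healthy, 4 T21 and 3 CVS. Fetal fractions of pregnant samples are
#' drawn uniformly from `ff_range` (default 6-10%, the typical first/second
#' trimester range); NPC samples have ff = 0 and CVS ff = 1 by definition.
#' T21 samples carry a dosage factor of 1.5 on the fetal contribution of
#' the target chromosome (three fetal copies instead of two).
#'
#' @param assay `"uCG"` or `"5hmCG"`.
#' @param n_npc,n_healthy,n_t21,n_cvs group sizes; `NULL` uses the
#'   per-assay defaults above.
#' @param depth processed reads per sample; `NULL` defers to
#'   [simulate_cohort()], which uses [scaled_depth()] of 8M (uCG) or
#'   4M (5hmCG) paper-scale reads.
#' @param ff_range fetal-fraction range for pregnant samples.
#' @param t21_dosage fetal target-chromosome dosage for T21 (1.5 = trisomy).
#' @param target_chrom chromosome receiving the dosage; defaults to the
#'   genome's first chromosome (the chr21 analog).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(assay = c("uCG", "5hmCG"),
                          n_npc = NULL, n_healthy = NULL, n_t21 = NULL,
                          n_cvs = NULL, depth = NULL,
                          ff_range = c(0.06, 0.10),
                          t21_dosage = 1.5,
                          target_chrom = NULL) {
  assay <- match.arg(assay)
  def <- if (assay == "uCG") c(7L, 8L, 5L, 7L) else c(7L, 7L, 4L, 3L)
  cfg <- list(
    assay = assay,
    n_npc = as.integer(n_npc %||% def[1]),
    n_healthy = as.integer(n_healthy %||% def[2]),
    n_t21 = as.integer(n_t21 %||% def[3]),
    n_cvs = as.integer(n_cvs %||% def[4]),
    depth = depth,
    ff_range = ff_range,
    t21_dosage = t21_dosage,
    target_chrom = target_chrom
  )
  if (any(ff_range < 0) || any(ff_range > 1) || ff_range[1] > ff_range[2]) {
    stop("`ff_range` must be an increasing range inside [0, 1]", call. = FALSE)
  }
  if (t21_dosage <= 0) stop("`t21_dosage` must be positive", call. = FALSE)
  class(cfg) <- "cohort_config"
  cfg
}

#' Paper-scale read depth scaled to a synthetic genome
#'
#' Sequencing depths for these assays are quoted as processed reads
#' against the ~28 million
#' CG sites of the human genome. To keep per-CG coverage density comparable
#' on a smaller synthetic catalog, depths are multiplied by
#' `n_sites / 28e6`.
#'
#' @param genome a `genome_model` (or an integer CG-site count).
#' @param paper_reads read count on the human-genome scale.
#' @return scaled integer read count.
#' @export
scaled_depth <- function(genome, paper_reads) {
  n <- if (inherits(genome, "genome_model")) nrow(genome$sites) else as.numeric(genome)
  as.integer(round(paper_reads * n / 28e6))
}

#' Simulate a cfDNA/CVS cohort of per-CG read counts
#'
#' Each sample's expected per-site read rate is the fetal-fraction mixture
#' `(1 - ff) * maternal + ff * fetal` of the genome's tissue propensities
#' for the cohort's assay, where the fetal (placental) component of the
#' target chromosome is multiplied by the T21 dosage for affected
#' pregnancies. `depth` reads are then allocated over sites by a single
#' multinomial draw per sample, so sampling noise is pure multinomial
#' (no extra overdispersion unless built into the genome propensities).
#'
#' @param genome a [build_genome()] model.
#' @param cohort a [cohort_config()].
#' @param seed integer RNG seed.
#' @return list with
#'   * `counts`: a [coverage_matrix()] (sites x samples),
#'   * `meta`: data.frame `sample_id`, `group`, `assay`, `fetal_sex`,
#'     `ff`, `depth`, `karyotype`,
#'   * `truth`: list with per-sample `ff` and `karyotype`, plus the
#'     genome's planted marker windows.
#' @export
simulate_cohort <- function(genome, cohort = cohort_config(), seed = 1L) {
  stopifnot(inherits(genome, "genome_model"), inherits(cohort, "cohort_config"))
  prop <- genome$propensity[[cohort$assay]]
  m <- prop$maternal_blood
  f <- prop$placenta
  if (sum(m) <= 0 || sum(f) <= 0) {
    stop("degenerate genome: zero total propensity for assay ", cohort$assay,
         call. = FALSE)
  }
  target <- cohort$target_chrom %||% names(genome$chrom_lengths)[1]
  if (!target %in% names(genome$chrom_lengths)) {
    stop("target chromosome not in genome", call. = FALSE)
  }
  depth <- cohort$depth %||%
    scaled_depth(genome, if (cohort$assay == "uCG") 8e6 else 4e6)

  groups <- rep(c("NPC", "pregnant_healthy", "pregnant_T21", "CVS"),
                c(cohort$n_npc, cohort$n_healthy, cohort$n_t21, cohort$n_cvs))
  n <- length(groups)
  prefix <- if (cohort$assay == "uCG") "ucg" else "hmcg"
  sample_ids <- sprintf("%s_%s_%02d", prefix,
                        c(NPC = "npc", pregnant_healthy = "preg",
                          pregnant_T21 = "t21", CVS = "cvs")[groups],
                        stats::ave(seq_len(n), groups, FUN = seq_along))

  with_seed(seed, {
    ff <- numeric(n)
    preg <- groups %in% c("pregnant_healthy", "pregnant_T21")
    ff[preg] <- stats::runif(sum(preg), cohort$ff_range[1], cohort$ff_range[2])
    ff[groups == "CVS"] <- 1
    if (any(ff < 0 | ff > 1)) stop("fetal fraction outside [0, 1]", call. = FALSE)

    fetal_sex <- rep(NA_character_, n)
    fetal_sex[preg | groups == "CVS"] <-
      rep_len(c("XX", "XY"), sum(preg | groups == "CVS"))

    on_target <- genome$sites$chrom == target
    counts <- matrix(0L, nrow = nrow(genome$sites), ncol = n)
    for (i in seq_len(n)) {
      fet <- f
      if (groups[i] == "pregnant_T21") {
        fet[on_target] <- fet[on_target] * cohort$t21_dosage
      }
      rate <- (1 - ff[i]) * m + ff[i] * fet
      counts[, i] <- as.integer(stats::rmultinom(1L, depth, rate))
    }

    cm <- coverage_matrix(counts, genome$sites$chrom, genome$sites$pos,
                          sample_ids = sample_ids,
                          chrom_lengths = genome$chrom_lengths)
    karyotype <- ifelse(groups == "pregnant_T21", "T21",
                        ifelse(groups == "pregnant_healthy", "euploid", NA))
    meta <- data.frame(
      sample_id = sample_ids, group = groups, assay = cohort$assay,
      fetal_sex = fetal_sex, ff = ff, depth = depth, karyotype = karyotype,
      stringsAsFactors = FALSE
    )
    truth <- list(
      sample = data.frame(sample_id = sample_ids, ff = ff,
                          karyotype = karyotype, stringsAsFactors = FALSE),
      planted_dmr_windows = genome$planted_dmr,
      target_chrom = target,
      t21_dosage = cohort$t21_dosage
    )
    list(counts = cm, meta = meta, truth = truth)
  })
}

#' Emit per-read start records from site counts
#'
#' Expands a per-CG count vector into one BED-like record per read, with
#' the 5' start jittered uniformly within `jitter` bp of the source CG's C
#' position and a uniform random strand. With `jitter <= 3` every emitted
#' read remains assignable to its source site under the 3-bp assignment
#' rule of [count_cg_coverage()] (exactly recoverable when neighboring CGs
#' are at least 8 bp apart).
#'
#' @param counts integer vector of per-site read counts, aligned with
#'   `genome$sites` (or a single-sample [coverage_matrix()]).
#' @param genome the `genome_model` the counts refer to.
#' @param jitter maximum absolute start offset in bp (>= 0).
#' @param seed RNG seed.
#' @param sample_id name stored in the `name` column.
#' @return data.frame with BED6-style columns `chrom`, `start`, `end`,
#'   `name`, `score` (0), `strand`, sorted by (chrom, start).
#' @export
emit_read_starts <- function(counts, genome, jitter = 3L, seed = 1L,
                             sample_id = "sample") {
  if (inherits(counts, "coverage_matrix")) {
    if (ncol(counts$counts) != 1L) {
      stop("pass a single-sample count vector", call. = FALSE)
    }
    counts <- counts$counts[, 1L]
  }
  if (jitter < 0) stop("`jitter` must be >= 0", call. = FALSE)
  if (length(counts) != nrow(genome$sites)) {
    stop("counts not aligned with genome sites", call. = FALSE)
  }
  with_seed(seed, {
    idx <- rep.int(seq_along(counts), counts)
    n <- length(idx)
    off <- if (jitter == 0) 0L else
      as.integer(floor(stats::runif(n, -jitter, jitter + 1)))
    chrom <- genome$sites$chrom[idx]
    start <- genome$sites$pos[idx] + off
    lim <- genome$chrom_lengths[chrom]
    start <- pmax(0L, pmin(start, as.integer(lim) - 1L))
    out <- data.frame(
      chrom = chrom, start = as.integer(start), end = as.integer(start) + 1L,
      name = sample_id, score = 0L,
      strand = c("+", "-")[1L + (stats::runif(n) < 0.5)],
      stringsAsFactors = FALSE
    )
    out[order(match(out$chrom, names(genome$chrom_lengths)), out$start), ,
        drop = FALSE]
  })
}
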