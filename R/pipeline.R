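#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with the standard
#' defaults: 100-bp DMR windows, 1-kb enrichment windows, q < 0.05
#' significance (nominal p < 0.05 as the configurable fallback for sparse
#' assays), 30 titration repetitions, 2-SD ordination outlier rule, and a
#' single seed from which every stochastic stage derives its own.
#'
#' @param assay `"uCG"` or `"5hmCG"`.
#' @param seed master seed.
#' @param genome optional [genome_config()] (default: the 3 x 2 Mb demo
#'   genome).
#' @param cohort optional [cohort_config()].
#' @param target_chrom,ref_chrom analysis chromosomes (defaults: the
#'   genome's first chromosome and [default_reference()]).
#' @param dmr_width,enrich_width window widths in bp.
#' @param q_threshold,nominal_p significance thresholds in (0, 1).
#' @param titration_depths depths for [depth_titration()]; `NULL` skips
#'   titration.
#' @param n_reps titration repetitions.
#' @param outlier_k SD multiplier of the outlier rule.
#' @param ff_bin_width fetal-fraction bin width in bp.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(assay = c("uCG", "5hmCG"), seed = 1L,
                            genome = NULL, cohort = NULL,
                            target_chrom = NULL, ref_chrom = NULL,
                            dmr_width = 100L, enrich_width = 1000L,
                            q_threshold = 0.05, nominal_p = 0.05,
                            titration_depths = NULL, n_reps = 30L,
                            outlier_k = 2, ff_bin_width = 50000L) {
  assay <- match.arg(assay)
  stopifnot_scalar_prob(q_threshold, "q_threshold")
  stopifnot_scalar_prob(nominal_p, "nominal_p")
  if (dmr_width <= 0 || enrich_width <= 0 || ff_bin_width <= 0) {
    stop("window widths must be positive", call. = FALSE)
  }
  genome <- genome %||% genome_config()
  if (!is.null(ref_chrom) && !ref_chrom %in% names(genome$chrom_lengths)) {
    stop("reference chromosome not in genome", call. = FALSE)
  }
  if (!is.null(target_chrom) && !target_chrom %in% names(genome$chrom_lengths)) {
    stop("target chromosome not in genome", call. = FALSE)
  }
  structure(
    list(assay = assay, seed = as.integer(seed), genome = genome,
         cohort = cohort %||% cohort_config(assay = assay),
         target_chrom = target_chrom %||% names(genome$chrom_lengths)[1],
         ref_chrom = ref_chrom %||% default_reference(assay, quiet = TRUE),
         dmr_width = as.integer(dmr_width),
         enrich_width = as.integer(enrich_width),
         q_threshold = q_threshold, nominal_p = nominal_p,
         titration_depths = titration_depths, n_reps = as.integer(n_reps),
         outlier_k = outlier_k, ff_bin_width = as.integer(ff_bin_width)),
    class = "pipeline_config"
  )
}

#' Run the end-to-end analysis pipeline
#'
#' simulate -> ordination QC -> karyotype Z-scores + LOOCV ->
#' depth titration (optional) -> DMR discovery -> annotation enrichment ->
#' fetal-fraction model, writing every result table as TSV plus a JSON
#' manifest recording parameters and derived seeds. Deterministic for a
#' fixed config: re-running with the same seed reproduces every output
#' byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  manifest <- list(
    assay = config$assay, seed = config$seed,
    target_chrom = config$target_chrom, ref_chrom = config$ref_chrom,
    q_threshold = config$q_threshold, outlier_k = config$outlier_k,
    dmr_width = config$dmr_width, enrich_width = config$enrich_width,
    outputs = character(0)
  )
  add <- function(f) manifest$outputs <<- c(manifest$outputs, f)

  # --- simulate --------------------------------------------------------
  genome <- build_genome(config$genome, seed = derive_seed(config$seed, 1))
  sim <- simulate_cohort(genome, config$cohort, seed = derive_seed(config$seed, 2))
  write_tsv(sim$meta, path("metadata.tsv")); add("metadata.tsv")
  write_counts(sim$counts, path("counts.tsv")); add("counts.tsv")

  # --- ordination QC ---------------------------------------------------
  qc_group <- ifelse(sim$meta$group %in% c("pregnant_healthy", "pregnant_T21"),
                     "pregnant", sim$meta$group)
  h <- hellinger(sim$counts)
  emb <- nmds(bray_curtis(h), seed = derive_seed(config$seed, 3))
  rownames(emb$points) <- sim$meta$sample_id
  flags <- flag_outliers(emb, qc_group, k = config$outlier_k)
  write_tsv(cbind(flags, emb$points), path("qc_outliers.tsv")); add("qc_outliers.tsv")

  # --- karyotype -------------------------------------------------------
  cs <- chrom_stats(sim$counts)
  labeled <- !is.na(sim$meta$karyotype)
  karyo_ids <- sim$meta$sample_id[labeled]
  healthy_ids <- sim$meta$sample_id[labeled & sim$meta$karyotype == "euploid"]
  z_tabs <- lapply(c("coverage", "fraction"), function(sg) {
    z <- chrom_ratio_zscores(cs, config$target_chrom, config$ref_chrom,
                             healthy_ids, signal = sg)
    x <- stats::setNames(z$X, z$sample_id)[karyo_ids]
    cv <- loocv_classify(x, sim$meta$karyotype[labeled],
                         healthy_ids = healthy_ids)
    z$loocv_prob <- cv$prob[match(z$sample_id, names(cv$prob))]
    attr(z, "auc") <- cv$auc
    attr(z, "accuracy") <- cv$accuracy
    z
  })
  zs <- do.call(rbind, z_tabs)
  write_tsv(zs, path("zscores.tsv")); add("zscores.tsv")
  manifest$karyotype_auc <- vapply(z_tabs, attr, numeric(1), "auc")

  # --- titration -------------------------------------------------------
  titr <- NULL
  if (!is.null(config$titration_depths)) {
    titr <- depth_titration(
      select_samples(sim$counts, karyo_ids), sim$meta$karyotype[labeled],
      config$target_chrom, config$ref_chrom, config$titration_depths,
      n_reps = config$n_reps, healthy_ids = healthy_ids,
      seed = derive_seed(config$seed, 4)
    )
    write_tsv(titr$summary, path("titration.tsv")); add("titration.tsv")
  }

  # --- DMR -------------------------------------------------------------
  grp <- sim$meta$group
  contrast <- grp %in% c("NPC", "pregnant_healthy")
  sub <- select_samples(sim$counts, sim$meta$sample_id[contrast])
  ws <- window_stats(sub, width = config$dmr_width, chroms = config$target_chrom)
  feat <- normalize_window_features(ws, chrom_stats(sub), config$ref_chrom)
  dmr <- dmr_lrt(feat, grp[contrast] == "pregnant_healthy")
  dmr$q <- bh_fdr(dmr$p)
  dmr$significant <- !is.na(dmr$q) & dmr$q < config$q_threshold
  write_tsv(dmr, path("dmr.tsv")); add("dmr.tsv")

  # --- enrichment ------------------------------------------------------
  tops <- top_signal_windows(sim$counts, qc_group, width = config$enrich_width)
  enr <- do.call(rbind, lapply(names(genome$annotations), function(a) {
    res <- site_enrichment(tops[["pregnant"]]$windows, genome$annotations[[a]],
                           genome$sites)
    cbind(annotation = a, res)
  }))
  write_tsv(enr, path("enrichment.tsv")); add("enrichment.tsv")

  # --- fetal fraction --------------------------------------------------
  ff_known <- !is.na(sim$meta$ff) & sim$meta$group != "CVS"
  ffb <- bin_counts(sim$counts, width = config$ff_bin_width)
  ff_res <- NULL
  if (sum(ff_known) >= 10L && stats::sd(sim$meta$ff[ff_known]) > 0) {
    train_bins <- list(bins = ffb$bins,
                       counts = ffb$counts[, ff_known, drop = FALSE])
    model <- fit_ff(train_bins, sim$meta$ff[ff_known])
    pred <- predict_ff(model, ffb)
    ff_res <- data.frame(sample_id = sim$meta$sample_id,
                         ff_true = sim$meta$ff, ff_pred = unname(pred))
    write_tsv(ff_res, path("fetal_fraction.tsv")); add("fetal_fraction.tsv")
  }

  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(genome = genome, sim = sim, qc = flags, zscores = zs,
                 titration = titr, dmr = dmr, enrichment = enr,
                 fetal_fraction = ff_res, manifest = manifest))
}
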