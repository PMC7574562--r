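#' Configuration for a synthetic genome model
#'
#' The synthetic genome is a scaled-down stand-in for the human genome as
#' seen by targeted CG sequencing: a catalog of CG dinucleotide positions
#' (the human genome carries roughly 28 million), CG-island (CGI) clusters
#' of locally elevated CG density, megabase-scale placentally hypomethylated
#' domains rendered at a 100-kb analog length, simple gene-model
#' annotations, and per-tissue, per-assay site sampling propensities that
#' drive the read-count simulator.
#'
#' Tissue propensities encode the two biological signals the assays exploit:
#'
#' * **uCG (unmethylated CG, uTOP-seq analog).** Blood-derived DNA has a
#'   baseline per-site probability of being unmethylated (beta-distributed,
#'   mean `ucg_blood_mean`); CGI sites are boosted in both tissues
#'   (`cgi_ucg_boost`, CpG islands being broadly unmethylated). Placental
#'   DNA multiplies the blood propensity by `hypo_strength` inside the
#'   planted hypomethylated domains, which cover `hypo_domain_frac` of every
#'   chromosome. The resulting genome-wide placenta:blood uCG mass ratio is
#'   `1 + hypo_domain_frac * (hypo_strength - 1)` (2.6 at the defaults),
#'   the per-molecule capture advantage of fetal (placental) fragments.
#'   The default `hypo_strength = 5` reflects partially methylated domains
#'   that are heavily methylated in blood (~85%, uCG propensity ~0.15) but
#'   only moderately methylated in placenta (~45%, uCG propensity ~0.55).
#' * **5hmCG (hmTOP-seq analog).** 5hmC marks are sparse
#'   (`hm_density` of sites per tissue) and strongly tissue-specific, so
#'   blood and placenta receive independently drawn site sets, with an
#'   `hm_annot_boost` multiplier over exons and 3'UTRs. The placental
#'   vector is then rescaled so the genome-wide placenta:blood propensity
#'   mass ratio equals `hm_ratio` exactly; the default 0.021/0.012 = 1.75
#'   reproduces the global 5hmC content ratio of chorionic villus versus
#'   blood DNA measured by HPLC-MS/MS.
#'
#' A set of `dmr_n` marker windows ("planted DMRs") is reserved on the
#' target chromosome: dense clusters of `dmr_cluster_sites` CG sites where
#' the placental propensity is multiplied by `dmr_strength` and the blood
#' propensity by `dmr_blood_damp`, emulating placenta-specific
#' differentially modified loci. Their positions are recorded in the model
#' as ground truth for recovery benchmarks. Their propensity mass is a
#' fraction of a percent of the chromosome total, so they do not perturb
#' chromosome-scale karyotype statistics.
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bp
#'   (>= 3 chromosomes: one target analog and two candidate references).
#' @param cg_rate expected background CG sites per bp (default 1/100 bp,
#'   the human genome-wide average).
#' @param cgi_rate expected CGI clusters per bp.
#' @param cgi_sites CG sites added per CGI cluster.
#' @param cgi_density_mult local density multiplier inside a CGI; fixes the
#'   CGI span at `cgi_sites / (cgi_density_mult * cg_rate)` bp.
#' @param hypo_domain_frac fraction of each chromosome covered by
#'   placentally hypomethylated domains.
#' @param hypo_domain_len domain length in bp (100-kb analog of the
#'   megabase-scale domains seen in placenta).
#' @param hypo_strength placenta uCG propensity multiplier inside domains.
#'   Set to 0 for a null genome in which placenta and blood uCG
#'   propensities are identical (used by calibration tests).
#' @param ucg_blood_mean mean of the beta-distributed blood uCG propensity.
#' @param cgi_ucg_boost uCG propensity multiplier for CGI sites (both
#'   tissues).
#' @param hm_ratio genome-wide placenta:blood 5hmCG propensity mass ratio;
#'   set to 1 for a null genome.
#' @param hm_density fraction of sites carrying 5hmC per tissue.
#' @param hm_annot_boost 5hmCG multiplier over exons/3'UTRs.
#' @param dmr_n,dmr_cluster_sites,dmr_strength,dmr_blood_damp planted
#'   marker-window count, CG sites per marker, placental multiplier and
#'   blood damping factor. `dmr_n = 0` plants nothing.
#' @param dmr_window_width width in bp of the window grid on which markers
#'   are planted (matches the 100-bp DMR analysis grid).
#' @param gene_every approximate spacing of generated gene models in bp.
#' @param mqtl_n number of array-probe positions to scatter per chromosome;
#'   `mqtl_frac` of them are flagged as methylation QTLs, independently of
#'   everything else (the null expectation for mQTL enrichment).
#' @param mqtl_frac see `mqtl_n`.
#' @return a `genome_config` list.
#' @export
genome_config <- function(chrom_lengths = c(chr21 = 2e6, chr16 = 2e6, chr20 = 2e6),
                          cg_rate = 0.01,
                          cgi_rate = 2e-5,
                          cgi_sites = 30L,
                          cgi_density_mult = 10,
                          hypo_domain_frac = 0.4,
                          hypo_domain_len = 1e5,
                          hypo_strength = 5,
                          ucg_blood_mean = 0.25,
                          cgi_ucg_boost = 4,
                          hm_ratio = 0.021 / 0.012,
                          hm_density = 0.08,
                          hm_annot_boost = 2,
                          dmr_n = 60L,
                          dmr_cluster_sites = 8L,
                          dmr_strength = 25,
                          dmr_blood_damp = 0.2,
                          dmr_window_width = 100L,
                          gene_every = 5e4,
                          mqtl_n = 300L,
                          mqtl_frac = 0.3) {
  if (is.null(names(chrom_lengths)) || anyNA(names(chrom_lengths)) ||
      any(names(chrom_lengths) == "")) {
    stop("`chrom_lengths` must be a named vector", call. = FALSE)
  }
  if (length(chrom_lengths) < 3L) {
    stop("need at least 3 chromosomes (target + two candidate references)",
         call. = FALSE)
  }
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive", call. = FALSE)
  if (cg_rate <= 0) stop("`cg_rate` must be positive", call. = FALSE)
  if (hypo_strength < 0 || hm_ratio < 0) {
    stop("effect parameters must be non-negative", call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "genome_config"
  cfg
}

#' Build a synthetic genome model
#'
#' Deterministic for a fixed `(config, seed)` pair. See [genome_config()]
#' for what the model contains and how its parameters map to the biology
#' being emulated.
#'
#' @param config a [genome_config()].
#' @param seed integer RNG seed.
#' @return object of class `genome_model`: list with `chrom_lengths`,
#'   `sites` (data.frame `chrom`, `pos`, 0-based C positions, sorted),
#'   `propensity[[assay]][[tissue]]` numeric vectors aligned with `sites`,
#'   `annotations` (named list of interval data.frames), `mqtl_probes`,
#'   `planted_dmr` (data.frame `chrom`, `start`, `end`, `direction`),
#'   `config`, `seed`.
#' @examples
#' gm <- build_genome(genome_config(), seed = 1)
#' nrow(gm$sites)   # ~ 60,000 + CGI sites for the 3 x 2 Mb default
#' @export
build_genome <- function(config = genome_config(), seed = 1L) {
  stopifnot(inherits(config, "genome_config"))
  with_seed(seed, {
    chroms <- names(config$chrom_lengths)
    site_chrom <- character(0)
    site_pos <- integer(0)
    cgi_list <- list()
    domain_list <- list()
    cgi_span <- ceiling(config$cgi_sites / (config$cgi_density_mult * config$cg_rate))

    for (ch in chroms) {
      len <- config$chrom_lengths[[ch]]
      n_bg <- stats::rpois(1L, len * config$cg_rate)
      pos <- floor(stats::runif(n_bg, 0, len))
      n_cgi <- stats::rpois(1L, len * config$cgi_rate)
      if (n_cgi > 0L) {
        centers <- floor(stats::runif(n_cgi, 0, max(1, len - cgi_span)))
        cgi_pos <- rep(centers, each = config$cgi_sites) +
          floor(stats::runif(n_cgi * config$cgi_sites, 0, cgi_span))
        pos <- c(pos, cgi_pos)
        cgi_list[[ch]] <- data.frame(chrom = ch, start = centers,
                                     end = centers + cgi_span)
      }
      pos <- sort(unique(pmin(pos, len - 1L)))
      site_chrom <- c(site_chrom, rep(ch, length(pos)))
      site_pos <- c(site_pos, as.integer(pos))

      # hypomethylated placental domains: sample a fixed fraction of the
      # domain-length grid, per chromosome, so every chromosome carries the
      # same domain load and chromosome-ratio statistics stay ff-invariant
      n_blocks <- max(1L, floor(len / config$hypo_domain_len))
      k <- round(config$hypo_domain_frac * n_blocks)
      if (k > 0L) {
        blocks <- sort(sample.int(n_blocks, k))
        domain_list[[ch]] <- data.frame(
          chrom = ch,
          start = (blocks - 1L) * config$hypo_domain_len,
          end = pmin(blocks * config$hypo_domain_len, len)
        )
      }
    }

    sites <- data.frame(chrom = site_chrom, pos = site_pos,
                        stringsAsFactors = FALSE)
    n_sites <- nrow(sites)
    target <- abs(n_sites - sum(config$chrom_lengths) * config$cg_rate) /
      (sum(config$chrom_lengths) * config$cg_rate)
    if (target > 0.15) {
      warning("realized CG count deviates from the configured density target")
    }

    annotations <- build_annotations(config, cgi_list)
    cgi_df <- annotations$CGI

    in_cgi <- in_annot(sites, cgi_df)
    in_domain <- in_annot(sites, do.call(rbind, domain_list))

    # ---- planted marker windows on the target chromosome ----------------
    planted <- NULL
    plant_idx <- integer(0)
    if (config$dmr_n > 0L) {
      w <- config$dmr_window_width
      tgt <- chroms[1L]
      len <- config$chrom_lengths[[tgt]]
      n_win <- floor(len / w)
      win_start <- (sample.int(n_win, config$dmr_n) - 1L) * w
      planted <- data.frame(chrom = tgt, start = as.integer(win_start),
                            end = as.integer(win_start + w), direction = 1L)
      # dense CG clusters inside each planted window
      cl_pos <- rep(win_start, each = config$dmr_cluster_sites) +
        floor(stats::runif(config$dmr_n * config$dmr_cluster_sites, 0, w))
      new_sites <- data.frame(chrom = tgt, pos = as.integer(cl_pos))
      sites <- rbind(sites, new_sites)
      o <- order(match(sites$chrom, chroms), sites$pos)
      sites <- sites[o, , drop = FALSE]
      dup <- duplicated(paste(sites$chrom, sites$pos))
      sites <- sites[!dup, , drop = FALSE]
      rownames(sites) <- NULL
      in_cgi <- in_annot(sites, cgi_df)
      in_domain <- in_annot(sites, do.call(rbind, domain_list))
      plant_idx <- which(in_annot(sites, planted))
      n_sites <- nrow(sites)
    }

    # ---- uCG propensities ----------------------------------------------
    mean_u <- config$ucg_blood_mean
    a <- 2
    b <- a * (1 - mean_u) / mean_u
    base_u <- stats::rbeta(n_sites, a, b)
    blood_u <- base_u
    blood_u[in_cgi] <- blood_u[in_cgi] * config$cgi_ucg_boost
    plac_u <- blood_u
    if (config$hypo_strength > 0) {
      plac_u[in_domain] <- plac_u[in_domain] * config$hypo_strength
    }
    if (length(plant_idx) && config$hypo_strength > 0) {
      plac_u[plant_idx] <- blood_u[plant_idx] * config$dmr_strength
      blood_u[plant_idx] <- blood_u[plant_idx] * config$dmr_blood_damp
    }

    # ---- 5hmCG propensities --------------------------------------------
    in_genic <- in_annot(sites, rbind(annotations$exon, annotations$`3'UTR`))
    hm_one <- function() {
      v <- numeric(n_sites)
      on_idx <- which(stats::runif(n_sites) < config$hm_density)
      v[on_idx] <- stats::rbeta(length(on_idx), 2, 4)
      v[in_genic] <- v[in_genic] * config$hm_annot_boost
      v
    }
    blood_h <- hm_one()
    if (config$hm_ratio == 1) {
      plac_h <- blood_h  # null genome: identical 5hmC landscape
    } else {
      plac_h <- hm_one()
      if (length(plant_idx)) {
        plac_h[plant_idx] <- pmax(plac_h[plant_idx], 0.3) * config$dmr_strength
        blood_h[plant_idx] <- blood_h[plant_idx] * config$dmr_blood_damp
      }
      plac_h <- plac_h * (config$hm_ratio * sum(blood_h) / sum(plac_h))
    }

    # ---- mQTL probes ----------------------------------------------------
    mqtl <- do.call(rbind, lapply(chroms, function(ch) {
      p <- sort(floor(stats::runif(config$mqtl_n, 0, config$chrom_lengths[[ch]])))
      data.frame(chrom = ch, pos = as.integer(p),
                 mqtl = stats::runif(config$mqtl_n) < config$mqtl_frac)
    }))

    structure(
      list(
        chrom_lengths = config$chrom_lengths,
        sites = sites,
        propensity = list(
          uCG = list(maternal_blood = blood_u, placenta = plac_u),
          `5hmCG` = list(maternal_blood = blood_h, placenta = plac_h)
        ),
        annotations = annotations,
        hypo_domains = do.call(rbind, domain_list),
        mqtl_probes = mqtl,
        planted_dmr = planted,
        config = config,
        seed = seed
      ),
      class = "genome_model"
    )
  })
}

# point-in-intervals on a sites data.frame against an interval data.frame,
# chromosome by chromosome
in_annot <- function(sites, intervals) {
  out <- rep(FALSE, nrow(sites))
  if (is.null(intervals) || nrow(intervals) == 0L) return(out)
  for (ch in unique(intervals$chrom)) {
    sel <- sites$chrom == ch
    if (!any(sel)) next
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    out[sel] <- points_in_intervals(sites$pos[sel], iv$start, iv$end)
  }
  out
}

# Simple gene models: promoter / 5'UTR / exons / introns / 3'UTR laid out
# left to right every `gene_every` bp, plus enhancers and lincRNA promoters
# scattered between genes. Coordinates 0-based half-open.
build_annotations <- function(config, cgi_list) {
  ann <- list(CGI = NULL, promoter = NULL, `5'UTR` = NULL, exon = NULL,
              intron = NULL, `3'UTR` = NULL, enhancer = NULL,
              `lincRNA-promoter` = NULL)
  ann$CGI <- if (length(cgi_list)) do.call(rbind, cgi_list) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  rows <- function(ch, s, e) data.frame(chrom = ch, start = as.integer(s),
                                        end = as.integer(e))
  for (ch in names(config$chrom_lengths)) {
    len <- config$chrom_lengths[[ch]]
    if (len < 8100) next
    starts <- seq(1000, len - 7000, by = config$gene_every)
    if (!length(starts)) next
    # gene body: 5'UTR 200 | exon 200 | intron 1500 | exon 200 |
    #            intron 1500 | exon 200 | 3'UTR 300
    ann$promoter <- rbind(ann$promoter, rows(ch, starts - 1000, starts))
    ann$`5'UTR` <- rbind(ann$`5'UTR`, rows(ch, starts, starts + 200))
    ex <- c(0, 1700, 3400) + 200
    for (off in ex) {
      ann$exon <- rbind(ann$exon, rows(ch, starts + off, starts + off + 200))
    }
    for (off in c(400, 2100)) {
      ann$intron <- rbind(ann$intron, rows(ch, starts + off, starts + off + 1500))
    }
    ann$`3'UTR` <- rbind(ann$`3'UTR`, rows(ch, starts + 3800, starts + 4100))
    mid <- starts + round(config$gene_every / 2)
    mid <- mid[mid + 500 < len]
    ann$enhancer <- rbind(ann$enhancer, rows(ch, mid, mid + 500))
    lp <- starts + round(config$gene_every * 0.75)
    lp <- lp[lp + 1000 < len]
    ann$`lincRNA-promoter` <- rbind(ann$`lincRNA-promoter`, rows(ch, lp, lp + 1000))
  }
  ann
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model>\n")
  cat("  chromosomes:", paste(sprintf("%s (%.1f Mb)", names(x$chrom_lengths),
                                      x$chrom_lengths / 1e6), collapse = ", "), "\n")
  cat("  CG sites:", nrow(x$sites), "\n")
  cat("  planted marker windows:",
      if (is.null(x$planted_dmr)) 0L else nrow(x$planted_dmr), "\n")
  ratio <- vapply(x$propensity, function(p) sum(p$placenta) / sum(p$maternal_blood),
                  numeric(1))
  cat(sprintf("  placenta:blood propensity mass ratio: uCG %.3f, 5hmCG %.3f\n",
              ratio[["uCG"]], ratio[["5hmCG"]]))
  invisible(x)
}
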