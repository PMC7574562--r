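test_that("window features are normalized against the reference chromosome", {
  cm <- coverage_matrix(
    cbind(s1 = c(3L, 0L, 500L, 500L)),
    c("chr21", "chr21", "chr16", "chr16"), c(10L, 60L, 5L, 20L),
    chrom_lengths = list(chr21 = 200, chr16 = 100)
  )
  ws <- window_stats(cm, width = 100, chroms = "chr21")
  cs <- chrom_stats(cm)
  feat <- normalize_window_features(ws, cs, "chr16")
  # log2(3 + 1) - log2(1000)
  expect_equal(feat$norm_cov[1, 1], log2(4) - log2(1000))
  expect_equal(round(feat$norm_cov[1, 1], 4), -7.9658)
  # window holds 2 CGs of which 1 is covered; reference fraction is 1,
  # so norm_frac equals the raw window fraction
  expect_equal(feat$norm_frac[1, 1], 0.5)

  cm0 <- coverage_matrix(cbind(s1 = c(1L, 0L)), c("chr21", "chr16"),
                         c(10L, 10L), chrom_lengths = list(chr21 = 100, chr16 = 100))
  ws0 <- window_stats(cm0, width = 100, chroms = "chr21")
  expect_error(normalize_window_features(ws0, chrom_stats(cm0), "chr16"),
               "s1")
})

test_that("norm_frac ratio is 2 when window fraction doubles the reference", {
  f <- manual_features(matrix(0, 1, 4), matrix(0.5 / 0.25, 1, 4))
  expect_equal(unname(f$norm_frac[1, 1]), 2)
})

test_that("the LRT returns p = 1 for uninformative windows and detects planted shifts", {
  set.seed(41)
  y <- rep(c(0, 1), c(8, 5))
  # constant features
  f <- manual_features(matrix(1, 3, 13), matrix(1, 3, 13))
  r <- dmr_lrt(f, y)
  expect_equal(r$p, rep(1, 3))
  expect_equal(r$lrt_stat, rep(0, 3))
  expect_equal(r$logFC_cov, rep(0, 3))

  # 2000 windows, the first 100 carry a 2x coverage shift
  W <- 2000
  nc <- matrix(rnorm(W * 13, 0, 0.3), W, 13)
  nf <- matrix(rnorm(W * 13, 1, 0.15), W, 13)
  nc[1:100, y == 1] <- nc[1:100, y == 1] + 1      # log2(2)
  nf[1:100, y == 1] <- nf[1:100, y == 1] + 0.3
  r <- dmr_lrt(manual_features(nc, nf), y)
  q <- bh_fdr(r$p)
  sens <- mean(q[1:100] < 0.05)
  expect_gte(sens, 0.8)
  expect_gt(median(r$logFC_cov[1:100]), 0.5)
  expect_true(all(r$logFC_cov[1:100] > 0.2))

  expect_error(dmr_lrt(manual_features(nc[, 1:4], nf[, 1:4]), c(0, 0, 1, 1)),
               "fewer than 3")
})

test_that("LRT p-values are uniform under an effect-free cohort", {
  g <- build_genome(genome_config(hypo_strength = 0, hm_ratio = 1, dmr_n = 0L),
                    seed = 42)
  sim <- simulate_cohort(g, cohort_config(
    "uCG", n_npc = 60, n_healthy = 0, n_t21 = 0, n_cvs = 0, depth = 120000
  ), seed = 43)
  labels <- rep(c(FALSE, TRUE), 30)  # arbitrary split of exchangeable samples
  ws <- window_stats(sim$counts, width = 100, chroms = "chr21")
  keep <- which(rowMeans(ws$coverage) >= 2)
  keep <- keep[seq_len(min(500, length(keep)))]
  feat <- normalize_window_features(ws, chrom_stats(sim$counts), "chr16")
  sub <- lapply(feat[c("norm_cov", "norm_frac", "raw_cov", "raw_frac")],
                function(m) m[keep, , drop = FALSE])
  feat$norm_cov <- sub$norm_cov; feat$norm_frac <- sub$norm_frac
  feat$raw_cov <- sub$raw_cov; feat$raw_frac <- sub$raw_frac
  feat$windows <- feat$windows[keep, ]
  r <- dmr_lrt(feat, labels)
  p <- r$p[!is.na(r$p)]
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("covariate-adjusted LRT keeps df = 2 and tolerates sex removal", {
  set.seed(44)
  y <- rep(c(0, 1), c(8, 7))
  covars <- data.frame(
    fetal_sex = factor(rep_len(c("XX", "XY"), 15)),
    ff = runif(15, 0.06, 0.10)
  )
  nc <- matrix(rnorm(50 * 15), 50, 15)
  nf <- matrix(rnorm(50 * 15, 1, 0.2), 50, 15)
  r <- dmr_lrt(manual_features(nc, nf), y, covariates = covars)
  expect_true(all(r$df == 2L))
  expect_true(all(is.na(r$p) | (r$p >= 0 & r$p <= 1)))
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(45)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(c(1, 3), 1)
    if (i %% 7 == 0) p[sample(length(p), 1)] <- NA
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("DMR set intersection reports the sample odds ratio and exact p", {
  uni <- as.character(1:100)
  A <- as.character(1:15)   # a = 10, b = 5
  B <- as.character(c(1:10, 16, 17))  # c = 2, d = 83
  r <- intersect_dmr_sets(A, B, uni)
  expect_equal(unname(as.vector(r$table)), c(10, 2, 5, 83))
  expect_equal(r$odds_ratio, 83)
  expect_false(r$haldane)
  expect_equal(r$p, oracle_fisher_p(10, 5, 2, 83), tolerance = 1e-12)
  expect_setequal(r$overlap, as.character(1:10))

  # degenerate identical half-universe sets
  r2 <- intersect_dmr_sets(as.character(1:50), as.character(1:50), uni)
  expect_true(r2$haldane)
  expect_true(is.finite(r2$odds_ratio))

  expect_error(intersect_dmr_sets("1", "2", character(0)), "empty")
  expect_error(intersect_dmr_sets("x", "1", uni), "subsets")

  # independent random sets: median OR near 1
  set.seed(46)
  ors <- replicate(100, {
    a <- sample(uni <- as.character(1:5000), 500)
    b <- sample(uni, 500)
    intersect_dmr_sets(a, b, uni)$odds_ratio
  })
  expect_lt(abs(log(median(ors))), log(1.5))
})

test_that("Fisher p equals hypergeometric enumeration for margins <= 200", {
  set.seed(47)
  for (i in 1:25) {
    m <- sample(2:100, 1); n <- sample(2:100, 1); k <- sample(1:(m + n - 1), 1)
    a <- max(0, k - n):min(k, m)
    a <- sample(a, 1)
    tab <- matrix(c(a, k - a, m - a, n - (k - a)), 2)
    if (any(tab < 0)) next
    expect_equal(stats::fisher.test(tab)$p.value,
                 oracle_fisher_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-9)
  }
})

test_that("effect concordance and positional KS behave as defined", {
  set.seed(48)
  d <- rnorm(20)
  expect_equal(dmr_effect_concordance(d, 2 * d), 1)
  expect_equal(dmr_effect_concordance(d, -d), -1)
  expect_error(dmr_effect_concordance(d, rep(1, 20)), "zero variance")
  expect_error(dmr_effect_concordance(1:2, 1:2), ">= 3")
  # independent normals: |r| small in 95% of reps
  rs <- replicate(100, dmr_effect_concordance(rnorm(500), rnorm(500)))
  expect_gte(mean(abs(rs) < 0.15), 0.9)

  a <- rnorm(30)
  ks <- dmr_positional_ks(a, a)
  expect_equal(ks$D, 0)
  expect_equal(ks$p, 1)
  ks2 <- dmr_positional_ks(runif(100, 0, 0.5), runif(100, 0.5, 1))
  expect_equal(ks2$D, 1)
  # oracle equivalence
  for (i in 1:10) {
    x <- rnorm(sample(5:50, 1)); y <- rnorm(sample(5:50, 1), 0.3)
    expect_equal(dmr_positional_ks(x, y)$D, oracle_ks_D(x, y),
                 tolerance = 1e-12)
  }
  expect_error(dmr_positional_ks(1:3, 1:10), ">= 5")
})

test_that("per-window cross-validated AUC flags discriminatory windows", {
  set.seed(49)
  y <- rep(c(0, 1), c(6, 5))
  nc <- rbind(
    c(rnorm(6, 0, 0.2), rnorm(5, 4, 0.2)),   # separating window
    rnorm(11)                                 # noise window
  )
  nf <- matrix(1, 2, 11)
  r <- per_dmr_cv_auc(manual_features(nc, nf), y)
  expect_equal(r$cv_auc[1], 1)
  # label-independent windows hover near 0.5 over repetitions
  nulls <- replicate(30, {
    per_dmr_cv_auc(manual_features(matrix(rnorm(11), 1), matrix(1, 1, 11)),
                   sample(y))$cv_auc
  })
  expect_lt(abs(mean(nulls) - 0.5), 0.15)
  expect_error(per_dmr_cv_auc(manual_features(nc, nf), rep(1, 11)), "class")
})
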