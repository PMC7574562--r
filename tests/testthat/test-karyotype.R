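test_that("Z-scores implement the reference-ratio standardization", {
  cs <- manual_ratio_stats(c(h1 = 0.10, h2 = 0.11, h3 = 0.12, t1 = 0.14))
  z <- chrom_ratio_zscores(cs, "chr21", "chr16", c("h1", "h2", "h3"),
                           signal = "coverage")
  expect_equal(z$mu, rep(0.11, 4))
  expect_equal(z$sigma, rep(0.01, 4))              # sample SD convention
  expect_equal(z$Z[z$sample_id == "t1"], 3)
  # population SD convention
  zp <- chrom_ratio_zscores(cs, "chr21", "chr16", c("h1", "h2", "h3"),
                            signal = "coverage", sd_type = "population")
  expect_equal(zp$sigma[1], 0.01 * sqrt(2 / 3))
  # X equal to mu scores zero
  cs2 <- manual_ratio_stats(c(h1 = 0.10, h2 = 0.11, h3 = 0.12, t1 = 0.11))
  z2 <- chrom_ratio_zscores(cs2, "chr21", "chr16", c("h1", "h2", "h3"),
                            signal = "coverage")
  expect_equal(z2$Z[4], 0)
  # in-sample standardization identity
  expect_equal(mean(z$Z[1:3]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z$Z[1:3]), 1, tolerance = 1e-12)
  # degenerate training set
  cs3 <- manual_ratio_stats(c(h1 = 0.1, h2 = 0.1, h3 = 0.1, t1 = 0.2))
  expect_error(chrom_ratio_zscores(cs3, "chr21", "chr16", c("h1", "h2", "h3")),
               "degenerate")
  expect_error(chrom_ratio_zscores(cs, "chr21", "chr21", c("h1", "h2", "h3")),
               "differ")
})

test_that("AUC equals the pair-counting Mann-Whitney oracle", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    y <- c(rep(0, 3), rep(1, 3), rbinom(n - 6, 1, 0.5))
    s <- round(rnorm(n), 1)  # rounding forces ties
    expect_equal(auc(s, y), oracle_auc(s, y))
  }
  expect_equal(auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(auc(1:3, c(0, 0, 0)), "both classes")
})

test_that("penalized logistic regression stays finite under separation", {
  y <- c(0, 0, 0, 1, 1, 1)
  x <- c(-3, -2, -1, 1, 2, 3)
  fit <- penalized_logistic(x, y, lambda = 1e-4)
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$coefficients)))
  p <- predict(fit, x)
  expect_true(all(p[y == 1] > 0.9) && all(p[y == 0] < 0.1))
  # heavier penalty shrinks the standardized slope
  fit2 <- penalized_logistic(x, y, lambda = 1)
  expect_lt(abs(fit2$std_coefficients[2]), abs(fit$std_coefficients[2]))
})

test_that("LOOCV classification separates shifted ratios and is null-calibrated", {
  x <- c(h1 = 1.00, h2 = 1.01, h3 = 0.99, h4 = 1.02, t1 = 1.30, t2 = 1.35)
  y <- c("euploid", "euploid", "euploid", "euploid", "T21", "T21")
  cv <- loocv_classify(x, y)
  expect_equal(cv$auc, 1)
  expect_equal(cv$accuracy, 1)
  # all-identical ratios cannot be standardized (sigma = 0)
  expect_error(loocv_classify(stats::setNames(rep(1, 6), names(x)), y),
               "degenerate")
  expect_error(loocv_classify(x, rep("T21", 6)), "class")

  # permuted labels give AUC centered at 0.5
  set.seed(32)
  null_auc <- replicate(200, {
    xs <- stats::setNames(rnorm(13, 1, 0.05), paste0("s", 1:13))
    ys <- sample(rep(c("euploid", "T21"), c(8, 5)))
    loocv_classify(xs, ys, healthy_ids = names(xs)[ys == "euploid"])$auc
  })
  expect_lt(abs(mean(null_auc) - 0.5), 0.05)
})

test_that("depth titration reproduces full-depth results and responds to depth", {
  g <- tiny_genome(seed = 33, dmr_n = 0L)
  sim <- simulate_cohort(g, cohort_config(
    "uCG", n_npc = 0, n_healthy = 8, n_t21 = 5, n_cvs = 0, depth = 12000
  ), seed = 34)
  lab <- sim$meta$karyotype
  # full-library "subsample" is the identity
  tc <- depth_titration(sim$counts, lab, "chr21", "chr16", 12000, n_reps = 2,
                        seed = 35)
  cs <- chrom_stats(sim$counts)
  x <- stats::setNames(
    cs$cg_fraction[cs$chrom == "chr21"] / cs$cg_fraction[cs$chrom == "chr16"],
    cs$sample_id[cs$chrom == "chr21"]
  )
  cv <- loocv_classify(x, lab)
  expect_equal(tc$results$auc, rep(cv$auc, 2))

  # mean AUC non-decreasing in depth (0.02 Monte-Carlo slack)
  tc2 <- depth_titration(sim$counts, lab, "chr21", "chr16",
                         c(500, 3000, 12000), n_reps = 10, seed = 36)
  au <- tc2$summary$mean_auc
  expect_true(all(diff(au) >= -0.02))

  expect_error(depth_titration(sim$counts, lab, "chr21", "chr16", 20000),
               "infeasible")
  expect_error(depth_titration(sim$counts, lab, "chr21", "chr16", c(10, 5)),
               "increasing")
})

test_that("natively shallow samples join the evaluation loop at their own depth", {
  g <- tiny_genome(seed = 37, dmr_n = 0L)
  sim <- simulate_cohort(g, cohort_config(
    "uCG", n_npc = 0, n_healthy = 6, n_t21 = 3, n_cvs = 0, depth = 12000
  ), seed = 38)
  shallow <- simulate_cohort(g, cohort_config(
    "uCG", n_npc = 0, n_healthy = 1, n_t21 = 1, n_cvs = 0, depth = 3000
  ), seed = 39)
  sh_cm <- shallow$counts
  sh_cm$sample_ids <- paste0("sh_", sh_cm$sample_ids)
  colnames(sh_cm$counts) <- sh_cm$sample_ids
  tc <- depth_titration(sim$counts, sim$meta$karyotype, "chr21", "chr16",
                        3000, n_reps = 3, seed = 40,
                        extra = list(cm = sh_cm,
                                     karyotype = shallow$meta$karyotype))
  expect_equal(nrow(tc$results), 3L)
  expect_true(all(is.finite(tc$results$auc)))
})
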