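test_that("reads are assigned to the nearest CG within 3 bp, ties to the lower coordinate", {
  cat3 <- data.frame(chrom = "chr1", pos = 100L)
  rs <- data.frame(chrom = "chr1", start = c(97L, 100L, 103L, 104L))
  res <- count_cg_coverage(rs, cat3)
  expect_equal(unname(res$matrix$counts[, 1]), 3L)  # 104 is 4 bp away
  expect_equal(res$qc$dropped, 1L)

  cat2 <- data.frame(chrom = "chr1", pos = c(100L, 106L))
  res <- count_cg_coverage(data.frame(chrom = "chr1", start = 103L), cat2)
  expect_equal(unname(res$matrix$counts[, 1]), c(1L, 0L))
})

test_that("assignment matches the exhaustive nearest-site oracle", {
  set.seed(11)
  pos <- sort(sample.int(5000, 120))
  pos <- pos[c(TRUE, diff(pos) > 0)]
  catal <- data.frame(chrom = rep(c("chrA", "chrB"), length.out = length(pos)),
                      pos = pos)
  catal <- catal[order(catal$chrom, catal$pos), ]
  catal <- catal[!duplicated(catal), ]
  rs <- data.frame(
    chrom = sample(c("chrA", "chrB"), 800, replace = TRUE),
    start = sample.int(5000, 800, replace = TRUE)
  )
  res <- count_cg_coverage(rs, catal)
  # oracle works on the same global site ordering as the result
  sc <- res$matrix$site_chrom
  sp <- res$matrix$site_pos
  orc <- oracle_assign(rs$chrom, rs$start, sc, sp)
  expect_equal(unname(res$matrix$counts[, 1]), orc$counts)
  expect_equal(res$qc$dropped, orc$dropped)
})

test_that("reads on unknown chromosomes are dropped with a warning", {
  catal <- data.frame(chrom = "chr1", pos = c(10L, 50L))
  rs <- data.frame(chrom = c("chr1", "chrX"), start = c(10L, 10L))
  expect_warning(res <- count_cg_coverage(rs, catal), "absent")
  expect_equal(res$qc$dropped, 1L)
  expect_equal(sum(res$matrix$counts), 1L)
})

test_that("chromosome statistics implement the coverage and fraction definitions", {
  cm <- manual_cm(cbind(a = c(0L, 2L, 1L, 0L)), pos = c(10L, 20L, 30L, 40L))
  cs <- chrom_stats(cm)
  expect_equal(cs$total_coverage, 3)
  expect_equal(cs$cg_fraction, 0.5)

  # doubling counts doubles totals, leaves fractions unchanged
  cm2 <- manual_cm(cbind(a = c(0L, 4L, 2L, 0L)), pos = c(10L, 20L, 30L, 40L))
  cs2 <- chrom_stats(cm2)
  expect_equal(cs2$total_coverage, 6)
  expect_equal(cs2$cg_fraction, cs$cg_fraction)

  # all-zero sample
  cm0 <- manual_cm(cbind(a = c(0L, 0L)), pos = c(1L, 2L))
  expect_equal(chrom_stats(cm0)$cg_fraction, 0)
})

test_that("window statistics tile, summarize and exclude empty windows", {
  cm <- manual_cm(cbind(a = c(3L, 0L, 5L)), pos = c(10L, 60L, 250L),
                  chrom_len = 400)
  ws <- window_stats(cm, width = 100)
  expect_equal(nrow(ws$windows), 2L)           # [0,100) and [200,300)
  expect_equal(ws$windows$n_cg, c(2L, 1L))
  expect_equal(unname(ws$coverage[, 1]), c(3, 5))
  expect_equal(unname(ws$fraction[, 1]), c(0.5, 1))
  expect_equal(ws$n_empty_excluded, 2L)        # [100,200) and [300,400)

  # partition conservation on a simulated sample
  g <- tiny_genome(seed = 12)
  sim <- tiny_cohort(g, seed = 13, n_npc = 2, n_healthy = 0, n_t21 = 0, n_cvs = 0)
  ws <- window_stats(sim$counts, width = 100, chroms = "chr16")
  cs <- chrom_stats(sim$counts)
  expect_equal(unname(colSums(ws$coverage)),
               cs$total_coverage[cs$chrom == "chr16"])
})

test_that("subsampling draws without replacement with conserved totals", {
  g <- tiny_genome(seed = 14)
  sim <- tiny_cohort(g, seed = 15, n_npc = 3, n_healthy = 0, n_t21 = 0,
                     n_cvs = 0, depth = 5000)
  cm <- sim$counts
  sub <- subsample_counts(cm, 1000, seed = 1)
  expect_equal(unname(colSums(sub$counts)), rep(1000, 3))
  expect_true(all(sub$counts <= cm$counts))
  # identity and zero
  expect_identical(subsample_counts(cm, 5000, seed = 1)$counts, cm$counts)
  expect_equal(sum(subsample_counts(cm, 0, seed = 1)$counts), 0)
  # infeasible
  expect_error(subsample_counts(cm, 5001), "exceeds")
  # determinism
  expect_identical(subsample_counts(cm, 777, seed = 9)$counts,
                   subsample_counts(cm, 777, seed = 9)$counts)
})

test_that("subsampling is unbiased (hypergeometric moments)", {
  # one site holds half of all reads
  set.seed(17)
  cm <- manual_cm(cbind(a = c(500L, 250L, 250L)), pos = c(10L, 20L, 30L))
  shares <- replicate(30, {
    s <- subsample_counts(cm, 200, seed = sample.int(1e6, 1))
    s$counts[1, 1] / 200
  })
  se <- sqrt(0.5 * 0.5 / 200 * (1000 - 200) / (1000 - 1)) / sqrt(30)
  expect_lt(abs(mean(shares) - 0.5), 3 * se)
})

test_that("Hellinger rows have unit sum of squares", {
  h <- hellinger(rbind(c(1, 3)))
  expect_equal(unname(h[1, ]), c(0.5, sqrt(3) / 2))
  expect_equal(unname(hellinger(rbind(c(0, 5, 0)))[1, ]), c(0, 1, 0))
  set.seed(16)
  x <- matrix(rpois(60, 4), nrow = 6)
  x[1, ] <- x[1, ] + 1  # guard against a zero row
  expect_equal(rowSums(hellinger(x)^2), rep(1, 6), tolerance = 1e-12)
  bad <- rbind(good = c(1, 2), empty = c(0, 0))
  expect_error(hellinger(bad), "empty")
})
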