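test_that("genome building is deterministic and hits the CG density target", {
  cfg <- genome_config(chrom_lengths = c(chr21 = 1e6, chr16 = 1e6, chr20 = 1e6))
  g1 <- build_genome(cfg, seed = 7)
  g2 <- build_genome(cfg, seed = 7)
  expect_identical(g1, g2)
  g3 <- build_genome(cfg, seed = 8)
  expect_false(identical(g1$sites, g3$sites))

  target <- sum(cfg$chrom_lengths) * cfg$cg_rate
  # background target, plus ~6% CGI and planted-cluster sites
  expect_lt(abs(nrow(g1$sites) - target) / target, 0.10)
  # site index invariants
  by_chrom <- split(g1$sites$pos, g1$sites$chrom)
  for (ch in names(by_chrom)) {
    expect_true(all(diff(by_chrom[[ch]]) > 0))
    expect_true(all(by_chrom[[ch]] < cfg$chrom_lengths[[ch]]))
  }
  expect_true(all(vapply(g1$propensity, function(a)
    all(a$maternal_blood >= 0 & a$placenta >= 0), logical(1))))
})

test_that("5hmCG placenta:blood mass ratio matches the HPLC calibration", {
  g <- tiny_genome(seed = 2)
  r <- sum(g$propensity$`5hmCG`$placenta) / sum(g$propensity$`5hmCG`$maternal_blood)
  expect_lt(abs(r - 0.021 / 0.012) / (0.021 / 0.012), 0.01)
})

test_that("zero effect parameters give identical tissue propensities", {
  g <- build_genome(genome_config(
    chrom_lengths = c(chr21 = 2e5, chr16 = 2e5, chr20 = 2e5),
    hypo_strength = 0, hm_ratio = 1, dmr_n = 0L
  ), seed = 3)
  expect_identical(g$propensity$uCG$maternal_blood, g$propensity$uCG$placenta)
  expect_identical(g$propensity$`5hmCG`$maternal_blood,
                   g$propensity$`5hmCG`$placenta)
})

test_that("cohort simulation conserves depth and encodes group structure", {
  g <- tiny_genome(seed = 4)
  sim <- tiny_cohort(g, seed = 5)
  expect_equal(unname(colSums(sim$counts$counts)),
               rep(8000, nrow(sim$meta)))
  expect_equal(unname(table(sim$meta$group)[c("NPC", "pregnant_healthy",
                                              "pregnant_T21", "CVS")]),
               c(7L, 8L, 5L, 7L), ignore_attr = TRUE)
  # ff invariants: 0 iff NPC, 1 iff CVS, pregnant strictly inside
  expect_true(all(sim$meta$ff[sim$meta$group == "NPC"] == 0))
  expect_true(all(sim$meta$ff[sim$meta$group == "CVS"] == 1))
  preg <- grepl("^pregnant", sim$meta$group)
  expect_true(all(sim$meta$ff[preg] >= 0.06 & sim$meta$ff[preg] <= 0.10))
  # determinism
  sim2 <- tiny_cohort(g, seed = 5)
  expect_identical(sim$counts$counts, sim2$counts$counts)
  expect_identical(sim$meta, sim2$meta)
})

test_that("T21 dosage inflates the target-chromosome share as the mixture predicts", {
  g <- tiny_genome(seed = 6, dmr_n = 0L)
  m <- g$propensity$uCG$maternal_blood
  f <- g$propensity$uCG$placenta
  on21 <- g$sites$chrom == "chr21"
  ff <- 0.10
  rate_eu <- (1 - ff) * m + ff * f
  f_t21 <- f
  f_t21[on21] <- f_t21[on21] * 1.5
  rate_t21 <- (1 - ff) * m + ff * f_t21
  expected_ratio <- (sum(rate_t21[on21]) / sum(rate_t21)) /
    (sum(rate_eu[on21]) / sum(rate_eu))

  cfg <- cohort_config("uCG", n_npc = 0, n_healthy = 1, n_t21 = 1, n_cvs = 0,
                       depth = 20000, ff_range = c(ff, ff))
  set.seed(99)
  shares <- replicate(30, {
    sim <- simulate_cohort(g, cfg, seed = sample.int(1e6, 1))
    cs <- sim$counts$counts
    c(sum(cs[on21, 1]) / sum(cs[, 1]), sum(cs[on21, 2]) / sum(cs[, 2]))
  })
  ratio_emp <- mean(shares[2, ] / shares[1, ])
  se <- stats::sd(shares[2, ] / shares[1, ]) / sqrt(30)
  expect_lt(abs(ratio_emp - expected_ratio), 3 * se)
})

test_that("ff = 0 pregnant mixture degenerates to the NPC distribution", {
  g <- tiny_genome(seed = 7, dmr_n = 0L)
  m <- g$propensity$uCG$maternal_blood
  f <- g$propensity$uCG$placenta
  rate <- (1 - 0) * m + 0 * f
  expect_identical(rate, m)
})

test_that("invalid configurations are rejected", {
  expect_error(genome_config(chrom_lengths = c(chr21 = -1, chr16 = 1e5, chr20 = 1e5)),
               "positive")
  expect_error(genome_config(chrom_lengths = c(a = 1e5, b = 1e5)), "3 chromosomes")
  expect_error(cohort_config("uCG", ff_range = c(0.5, 1.2)), "ff_range")
  g <- tiny_genome(seed = 1)
  expect_error(
    simulate_cohort(g, cohort_config("zzz")), "arg"
  )
})

test_that("read-start emission conserves reads and respects the jitter bound", {
  g <- tiny_genome(seed = 8)
  counts <- integer(nrow(g$sites))
  counts[c(1, 5, 9)] <- c(2L, 0L, 1L)
  rs <- emit_read_starts(counts, g, jitter = 0, seed = 1)
  expect_equal(nrow(rs), 3L)
  expect_equal(sort(rs$start), sort(g$sites$pos[c(1, 1, 9)]))

  set.seed(42)
  counts <- integer(nrow(g$sites))
  counts[sample.int(length(counts), 50)] <- 1L
  rs <- emit_read_starts(counts, g, jitter = 3, seed = 2)
  expect_equal(nrow(rs), 50L)
  src <- g$sites$pos[rep.int(seq_along(counts), counts)]
  expect_true(all(abs(sort(rs$start) - sort(src)) <= 3))
  expect_error(emit_read_starts(counts, g, jitter = -1), "jitter")
})

test_that("emission round-trips through read assignment when sites are >= 8 bp apart", {
  pos <- seq(0L, 990L, by = 10L)
  fake <- structure(list(
    sites = data.frame(chrom = "chr21", pos = pos),
    chrom_lengths = c(chr21 = 1000)
  ), class = "genome_model")
  set.seed(3)
  counts <- as.integer(rpois(length(pos), 2))
  rs <- emit_read_starts(counts, fake, jitter = 3, seed = 4)
  got <- count_cg_coverage(rs, fake$sites, chrom_lengths = fake$chrom_lengths)
  expect_equal(unname(got$matrix$counts[, 1]), counts)
  expect_equal(got$qc$dropped, 0L)
  # brute-force nearest-site oracle agrees
  orc <- oracle_assign(rs$chrom, rs$start, fake$sites$chrom, fake$sites$pos)
  expect_equal(unname(got$matrix$counts[, 1]), orc$counts)
})
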