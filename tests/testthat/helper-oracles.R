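# Independent brute-force oracles. Each reimplements a statistic from its
# definition, deliberately avoiding the code paths it is used to check.

# nearest-CG read assignment by exhaustive search
oracle_assign <- function(read_chrom, read_start, cat_chrom, cat_pos,
                          max_dist = 3L) {
  n_sites <- length(cat_pos)
  counts <- integer(n_sites)
  dropped <- 0L
  for (i in seq_along(read_start)) {
    cand <- which(cat_chrom == read_chrom[i])
    if (!length(cand)) { dropped <- dropped + 1L; next }
    d <- abs(cat_pos[cand] - read_start[i])
    j <- cand[order(d, cat_pos[cand])][1]
    if (min(d) <= max_dist) counts[j] <- counts[j] + 1L else dropped <- dropped + 1L
  }
  list(counts = counts, dropped = dropped)
}

# BH step-up from the definition
oracle_bh <- function(p) {
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(q)
  o <- order(pv)
  qs <- pv[o] * m / seq_len(m)
  if (m > 1L) for (i in (m - 1L):1L) qs[i] <- min(qs[i], qs[i + 1])
  qs <- pmin(qs, 1)
  q[ok][o] <- qs
  q
}

# two-sided Fisher exact p by hypergeometric enumeration
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b          # row 1 total
  n <- c_ + d         # row 2 total
  k <- a + c_         # col 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-sample KS D by scanning the pooled ECDFs
oracle_ks_D <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
  Fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
  max(abs(Fa - Fb))
}

# AUC by counting concordant pairs (ties score 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Bray-Curtis from the formula
oracle_bray <- function(x) {
  n <- nrow(x)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ])
  }
  D
}

# point-in-union-of-intervals by direct scan
oracle_points_in <- function(pos, starts, ends) {
  vapply(pos, function(p) any(p >= starts & p < ends), logical(1))
}
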