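# Brute-force and textbook-formula oracles, independent of the package's
# implementation paths: explicit loops over haplotype pairs, ANOVA via lm
# for the F_ST variance components, exhaustive enumeration for the exact
# tests. Slow on purpose; used on small instances only.

# mean pairwise difference per site within a haplotype pool
# (rows = haplotypes, cols = sites, 0/1)
oracle_pi_hap <- function(h, L) {
  n <- nrow(h)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) tot <- tot + sum(h[i, ] != h[j, ])
  }
  tot / choose(n, 2) / L
}

# mean pairwise difference per site between two pools
oracle_dxy_hap <- function(h1, h2, L) {
  tot <- 0
  for (i in seq_len(nrow(h1))) {
    for (j in seq_len(nrow(h2))) tot <- tot + sum(h1[i, ] != h2[j, ])
  }
  tot / (nrow(h1) * nrow(h2)) / L
}

oracle_theta_w <- function(S, n, L) S / sum(1 / seq_len(n - 1)) / L

# Tajima's D from a haplotype matrix: pi and S by direct counting, the
# variance normalization transcribed from the original definition
oracle_tajima_d <- function(h, L) {
  n <- nrow(h)
  d <- colSums(h)
  seg <- d > 0 & d < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pi_tot <- oracle_pi_hap(h, 1)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  v <- c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1)
  (pi_tot - S / a1) / sqrt(v)
}

# Fay & Wu's H from a haplotype matrix of derived alleles: theta_H
# accumulated site by site from squared derived counts
oracle_fay_wu_h <- function(h, L) {
  n <- nrow(h)
  d <- colSums(h)
  d <- d[d > 0 & d < n]
  if (length(d) == 0) return(NA_real_)
  pi_tot <- oracle_pi_hap(h, 1)
  th_h <- sum(2 * d^2) / (n * (n - 1))
  (pi_tot - th_h) / L
}

# Weir-Cockerham theta for one bi-allelic site, two populations, computed
# through R's own ANOVA on the 0/1 allele indicators
oracle_wc_fst <- function(ac1, an1, ac2, an2) {
  y <- c(rep(1, ac1), rep(0, an1 - ac1), rep(1, ac2), rep(0, an2 - ac2))
  g <- factor(rep(c("a", "b"), c(an1, an2)))
  ss <- suppressWarnings(anova(lm(y ~ g)))  # perfect fits are fine here
  msp <- ss$`Mean Sq`[1L]
  msg <- ss$`Mean Sq`[2L]
  ntot <- an1 + an2
  nc <- ntot - (an1^2 + an2^2) / ntot
  denom <- msp + (nc - 1) * msg
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  (msp - msg) / denom
}

# exhaustive hypergeometric enumeration of the two-sided Fisher p for the
# 2x2 table [a b; c d] with fixed margins
oracle_fisher <- function(a, b, c, d, alternative = "two.sided") {
  m <- a + c; nn <- b + d; k <- a + b
  lo <- max(0, k - nn); hi <- min(k, m)
  logp <- vapply(lo:hi, function(x)
    lchoose(m, x) + lchoose(nn, k - x) - lchoose(m + nn, k), numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[a - lo + 1]
  if (alternative == "greater") sum(p[(lo:hi) >= a])
  else sum(p[p <= obs * (1 + 1e-7)])
}

# exact Mann-Whitney two-sided p by full enumeration of group assignments
oracle_mannwhitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  u_of <- function(ix) sum(r[ix]) - nx * (nx + 1) / 2
  obs <- u_of(seq_len(nx))
  combs <- combn(nx + ny, nx)
  us <- apply(combs, 2, u_of)
  mid <- nx * ny / 2
  if (obs > mid) p <- 2 * mean(us >= obs) else p <- 2 * mean(us <= obs)
  min(1, p)
}

# one-sided exact binomial tail P(X >= k), X ~ Bin(n, p)
oracle_binom_tail <- function(k, n, p) {
  if (k == 0) return(1)
  if (p >= 1) return(1)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}
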