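## Independent brute-force oracles used to cross-check the package's
## statistical kernels.  These deliberately avoid the implementation's
## code paths: enumeration, pairwise scans and direct formula
## evaluation only.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
  library(S4Vectors)
})

## Two-sided Fisher p by full enumeration of tables with fixed margins,
## hypergeometric probabilities from choose().
oracleFisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  amin <- max(0, c1 - r2); amax <- min(r1, c1)
  prob <- function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  p_obs <- prob(a)
  xs <- amin:amax
  sum(vapply(xs, prob, 1)[vapply(xs, prob, 1) <= p_obs * (1 + 1e-7)])
}

## BH by direct definition: q_(i) = min over j >= i of m p_(j) / j.
oracleBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[ord] <- q
  out
}

## Pi as the mean pairwise Hamming distance over expanded haplotypes.
## A dosage-1 genotype contributes one 0 and one 1 chromosome; the
## estimator depends only on allele counts, so the expansion order is
## irrelevant.
oraclePi <- function(g) {
  g <- rbind(g)
  hap <- apply(g, 1, function(row) {
    unlist(lapply(row, function(d) {
      if (is.na(d)) c(NA, NA) else switch(d + 1, c(0, 0), c(0, 1), c(1, 1))
    }))
  })                        # chromosomes x sites
  hap <- rbind(hap)
  n <- nrow(hap)
  tot <- 0
  npair <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(hap[i, ]) & !is.na(hap[j, ])
    tot <- tot + sum(hap[i, ok] != hap[j, ok])
    npair <- npair + 1
  }
  tot / npair * 1   # complete data assumed in oracle fixtures
}

## Tajima's D from first principles (complete-data fixtures).
oracleTajimaD <- function(g) {
  g <- rbind(g)
  n <- 2 * ncol(g)
  ac <- rowSums(g)
  seg <- ac > 0 & ac < n
  S <- sum(seg)
  if (S == 0 || n < 3) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  pi <- oraclePi(g[seg, , drop = FALSE])
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

## Hudson FST ratio-of-sums, written per site with explicit loops.
oracleHudsonFst <- function(g1, g2) {
  g1 <- rbind(g1); g2 <- rbind(g2)
  num <- den <- 0
  any_usable <- FALSE
  for (s in seq_len(nrow(g1))) {
    x1 <- g1[s, !is.na(g1[s, ])]; x2 <- g2[s, !is.na(g2[s, ])]
    n1 <- 2 * length(x1); n2 <- 2 * length(x2)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(x1) / n1; p2 <- sum(x2) / n2
    if ((p1 == 0 && p2 == 0) || (p1 == 1 && p2 == 1)) next
    any_usable <- TRUE
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
      p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  if (!any_usable) return(NA_real_)
  num / den
}

## Pearson r by the covariance formula; p via anova on lm (an
## implementation-independent route to the regression F test).
oraclePearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  p <- stats::anova(stats::lm(y ~ x))[["Pr(>F)"]][1]
  list(r = r, p = p)
}

## XP-CLR single-window oracle: 10,000-point trapezoid over the
## post-sweep frequency for both the neutral and the sweep model.
oracleXpclr <- function(pos, p1, k, n, putative_site, omega, Ne, s_grid,
                        recomb_rate, npts = 10001) {
  integ <- function(j, cc) {
    sd <- sqrt(omega * p1[j] * (1 - p1[j]))
    m0 <- pnorm(0, p1[j], sd)
    m1 <- pnorm(1, p1[j], sd, lower.tail = FALSE)
    ys <- seq(1 - cc, 1, length.out = npts)
    f <- dnorm((ys - (1 - cc)) / cc, p1[j], sd) / cc * dbinom(k[j], n[j], ys)
    h <- ys[2] - ys[1]
    sum((f[-1] + f[-npts]) / 2) * h +
      m0 * dbinom(k[j], n[j], 1 - cc) + m1 * dbinom(k[j], n[j], 1)
  }
  ll <- function(s) {
    tot <- 0
    for (j in seq_along(pos)) {
      cc <- if (s <= 0 || log(2 * Ne * s) <= 0) 1 else {
        r <- abs(pos[j] - putative_site) * recomb_rate
        min(max(1 - exp(-r * log(2 * Ne * s) / s), 0), 1)
      }
      tot <- tot + log(integ(j, cc))
    }
    tot
  }
  ll0 <- ll(0)
  max(0, max(vapply(s_grid[s_grid > 0], function(s) 2 * (ll(s) - ll0), 1)))
}

## Random complete dosage matrix with at least one segregating site.
randomDosage <- function(n_sites, n_samples, maf = NULL) {
  repeat {
    p <- if (is.null(maf)) runif(n_sites, 0.05, 0.95) else rep(maf, n_sites)
    g <- matrix(rbinom(n_sites * n_samples, 2, rep(p, n_samples)),
                nrow = n_sites)
    ac <- rowSums(g)
    if (any(ac > 0 & ac < 2 * n_samples)) return(g)
  }
}
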