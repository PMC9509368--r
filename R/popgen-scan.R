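## Sliding-window population-genetic statistics over a GenotypeMatrix.
## Diploid genotypes are treated as 2n exchangeable lineages: every
## statistic works from per-site called-allele counts, so missing
## genotypes are simply dropped site by site.

#' Sliding scan windows over chromosomes
#'
#' Builds the overlapping window grid used by the sweep scan: full-size
#' windows every `step` bp while they fit, plus a single trailing
#' truncated window when the last full window does not reach the
#' chromosome end (a chromosome shorter than `size` yields one truncated
#' window covering it entirely).
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param size Window size in bp (default 5000).
#' @param step Step between window starts in bp (default 500);
#'   `step <= size`.
#' @return `GRanges` of windows (1-based, inclusive), with `seqlengths`
#'   set.
#' @examples
#' scanWindows(c(chr1 = 7000))   # five full 5 kb windows
#' @export
scanWindows <- function(chrom_lengths, size = 5000, step = 500) {
  if (size <= 0 || step <= 0) stop("size and step must be positive")
  if (step > size) stop("step must not exceed the window size")
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  per_chr <- lapply(names(chrom_lengths), function(chr) {
    L <- chrom_lengths[[chr]]
    if (L < size) {
      starts <- 0L
      ends <- L
    } else {
      nfull <- floor((L - size) / step) + 1
      starts <- step * (seq_len(nfull) - 1)
      ends <- starts + size
      if (max(ends) < L) {          # one trailing truncated window
        starts <- c(starts, step * nfull)
        ends <- c(ends, L)
      }
    }
    list(chr = rep(chr, length(starts)), start = starts, end = ends)
  })
  gr <- GRanges(unlist(lapply(per_chr, `[[`, "chr")),
                IRanges(start = unlist(lapply(per_chr, `[[`, "start")) + 1,
                        end = unlist(lapply(per_chr, `[[`, "end"))))
  seqlengths(gr) <- chrom_lengths[seqlevels(gr)]
  gr
}

## Per-site alternate-allele count (ac) and called-allele number (an)
## from a dosage matrix (sites x samples).
.siteAlleleCounts <- function(g) {
  called <- !is.na(g)
  list(ac = rowSums(g, na.rm = TRUE), an = 2 * rowSums(called))
}

#' Nucleotide diversity of one window
#'
#' Average number of pairwise differences, summed over sites using the
#' unbiased per-site estimator 2 k (n - k) / (n (n - 1)) from called
#' allele counts.
#'
#' @param g Dosage matrix (sites x samples, 0/1/2/NA) for the window's
#'   sites.
#' @return Pi (a count, not per-bp).
#' @export
windowPi <- function(g) {
  g <- rbind(g)
  sc <- .siteAlleleCounts(g)
  if (nrow(g) > 0 && all(sc$an < 2)) stop("need at least two called alleles")
  use <- sc$an >= 2
  sum(2 * sc$ac[use] * (sc$an[use] - sc$ac[use]) /
        (sc$an[use] * (sc$an[use] - 1)))
}

#' Tajima's D constants for haploid sample size n
#'
#' @param n Number of lineages (haploid sample size), n >= 2.
#' @return List with a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajimaConstants <- function(n) {
  if (n < 2) stop("n must be >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D of one window
#'
#' D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1)). Returns `NA` when there
#' are no segregating sites or fewer than 3 lineages (at n = 2 the
#' variance constants vanish). With per-site missingness the constants
#' use n = round(mean called alleles over segregating sites).
#'
#' @param g Dosage matrix (sites x samples) for the window's sites.
#' @return Tajima's D, or `NA_real_`.
#' @export
windowTajimaD <- function(g) {
  g <- rbind(g)
  sc <- .siteAlleleCounts(g)
  seg <- sc$an >= 2 & sc$ac > 0 & sc$ac < sc$an
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  n <- round(mean(sc$an[seg]))
  if (n < 3) return(NA_real_)
  k <- tajimaConstants(n)
  pi <- sum(2 * sc$ac[seg] * (sc$an[seg] - sc$ac[seg]) /
              (sc$an[seg] * (sc$an[seg] - 1)))
  (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

## Per-site Hudson FST components; returns num/den vectors with NA at
## unusable sites (fewer than 2 called alleles in either population, or
## monomorphic across both populations).
.hudsonComponents <- function(ac1, an1, ac2, an2) {
  usable <- an1 >= 2 & an2 >= 2
  p1 <- ifelse(usable, ac1 / an1, NA_real_)
  p2 <- ifelse(usable, ac2 / an2, NA_real_)
  mono <- usable & ((ac1 + ac2 == 0) | (ac1 + ac2 == an1 + an2))
  usable <- usable & !mono
  num <- ifelse(usable,
                (p1 - p2)^2 - p1 * (1 - p1) / (an1 - 1) -
                  p2 * (1 - p2) / (an2 - 1),
                NA_real_)
  den <- ifelse(usable, p1 * (1 - p2) + p2 * (1 - p1), NA_real_)
  list(num = num, den = den, usable = usable)
}

## Weir-Cockerham (1984) two-population variance components from diploid
## genotype data; n = individuals, p = alt frequency, h = observed het.
.wcComponents <- function(g1, g2) {
  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  usable <- n1 >= 1 & n2 >= 1
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(g1 == 1, na.rm = TRUE) / n1
  h2 <- rowSums(g2 == 1, na.rm = TRUE) / n2
  mono <- (p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1)
  usable <- usable & !mono & (n1 + n2) > 2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(num = ifelse(usable, a, NA_real_),
       den = ifelse(usable, a + b + cc, NA_real_),
       usable = usable)
}

#' FST of one window (ratio of sums)
#'
#' Per-site numerator and denominator components are accumulated over the
#' window and returned as a ratio of sums. The Hudson estimator works
#' from allele counts; the Weir-Cockerham estimator uses diploid genotype
#' counts (observed heterozygosity). Sites monomorphic across both
#' populations are skipped; a window with no usable site returns `NA`.
#'
#' @param g1,g2 Dosage matrices (sites x samples) for the two
#'   populations, rows aligned.
#' @param estimator `"hudson"` (default) or `"weir_cockerham"`.
#' @return Window FST (<= 1, may be negative), or `NA_real_`.
#' @export
windowFst <- function(g1, g2, estimator = c("hudson", "weir_cockerham")) {
  estimator <- match.arg(estimator)
  g1 <- rbind(g1); g2 <- rbind(g2)
  stopifnot(nrow(g1) == nrow(g2))
  comp <- if (estimator == "hudson") {
    c1 <- .siteAlleleCounts(g1); c2 <- .siteAlleleCounts(g2)
    .hudsonComponents(c1$ac, c1$an, c2$ac, c2$an)
  } else {
    .wcComponents(g1, g2)
  }
  if (!any(comp$usable)) return(NA_real_)
  sum(comp$num[comp$usable]) / sum(comp$den[comp$usable])
}

## ---- whole-track scans ---------------------------------------------------

.popDosage <- function(gm, pop) {
  keep <- colData(gm)$population %in% pop
  if (!any(keep)) stop("no samples in population(s): ", paste(pop, collapse = ","))
  assay(gm, "dosage")[, keep, drop = FALSE]
}

## Aggregate a per-site numeric vector into per-window sums over the
## site-in-window overlap map.
.windowSums <- function(values, hits, n_windows) {
  out <- numeric(n_windows)
  cnt <- tabulate(S4Vectors::subjectHits(hits), n_windows)
  s <- rowsum(values[S4Vectors::queryHits(hits)],
              S4Vectors::subjectHits(hits))
  out[as.integer(rownames(s))] <- s[, 1]
  list(sum = out, count = cnt)
}

.newTrack <- function(windows, score, statistic) {
  tr <- granges(windows)
  mcols(tr)$score <- score
  metadata(tr)$statistic <- statistic
  tr
}

#' Per-window nucleotide diversity track
#'
#' @param gm A [GenotypeMatrix].
#' @param windows `GRanges` window grid from [scanWindows()].
#' @param pop Population label(s) to use.
#' @param min_sites Windows with fewer usable SNPs score `NA` (default 3).
#' @return `GRanges` track with a `score` column;
#'   `metadata(track)$statistic == "pi"`.
#' @export
scanPi <- function(gm, windows, pop, min_sites = 3) {
  g <- .popDosage(gm, pop)
  sc <- .siteAlleleCounts(g)
  use <- sc$an >= 2
  persite <- ifelse(use, 2 * sc$ac * (sc$an - sc$ac) /
                      pmax(sc$an * (sc$an - 1), 1), 0)
  hits <- findOverlaps(rowRanges(gm), windows)
  ws <- .windowSums(persite, hits, length(windows))
  score <- ifelse(ws$count >= min_sites, ws$sum, NA_real_)
  .newTrack(windows, score, "pi")
}

#' Per-window Tajima's D track
#'
#' @inheritParams scanPi
#' @return `GRanges` track (`statistic == "tajimas_d"`); windows with no
#'   segregating site, fewer than `min_sites` SNPs, or n < 3 lineages
#'   score `NA`.
#' @export
scanTajimaD <- function(gm, windows, pop, min_sites = 3) {
  g <- .popDosage(gm, pop)
  hits <- findOverlaps(rowRanges(gm), windows)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  score <- rep(NA_real_, length(windows))
  idx <- split(qh, sh)
  for (w in names(idx)) {
    sites <- idx[[w]]
    if (length(sites) < min_sites) next
    score[as.integer(w)] <- windowTajimaD(g[sites, , drop = FALSE])
  }
  .newTrack(windows, score, "tajimas_d")
}

#' Per-window FST track between two populations
#'
#' @inheritParams scanPi
#' @param pop1,pop2 Population labels of the two groups.
#' @param estimator `"hudson"` (ratio-of-sums, default) or
#'   `"weir_cockerham"`.
#' @return `GRanges` track (`statistic == "fst"`).
#' @export
scanFst <- function(gm, windows, pop1, pop2,
                    estimator = c("hudson", "weir_cockerham"),
                    min_sites = 3) {
  estimator <- match.arg(estimator)
  g1 <- .popDosage(gm, pop1)
  g2 <- .popDosage(gm, pop2)
  comp <- if (estimator == "hudson") {
    c1 <- .siteAlleleCounts(g1); c2 <- .siteAlleleCounts(g2)
    .hudsonComponents(c1$ac, c1$an, c2$ac, c2$an)
  } else {
    .wcComponents(g1, g2)
  }
  num <- ifelse(comp$usable, comp$num, 0)
  den <- ifelse(comp$usable, comp$den, 0)
  hits <- findOverlaps(rowRanges(gm), windows)
  usable_hit <- comp$usable[S4Vectors::queryHits(hits)]
  hits <- hits[usable_hit]
  nsum <- .windowSums(num, hits, length(windows))
  dsum <- .windowSums(den, hits, length(windows))
  score <- ifelse(nsum$count >= min_sites & dsum$sum != 0,
                  nsum$sum / dsum$sum, NA_real_)
  .newTrack(windows, score, "fst")
}

#' Genome-wide Hudson FST (ratio of sums over all usable sites)
#'
#' @param gm A [GenotypeMatrix].
#' @param pop1,pop2 Population labels.
#' @return Single FST estimate.
#' @export
genomeFst <- function(gm, pop1, pop2) {
  windowFst(.popDosage(gm, pop1), .popDosage(gm, pop2), "hudson")
}
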