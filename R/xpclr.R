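## Cross-population composite likelihood ratio (XP-CLR style) sweep score.
##
## Model: given the reference-population frequency p1 of a SNP, the
## object-population frequency p2 is, under neutral drift, distributed as
## Normal(p1, omega * p1 * (1 - p1)) truncated to (0, 1), with the
## truncated tail mass placed as point masses at 0 and 1.  A hard sweep
## with selection coefficient s at a putative site transforms the
## pre-sweep frequency x into 1 - c + c * x, where c is the probability
## that a lineage at recombination distance r escapes the sweep:
## c = 1 - exp(-r * ln(2 N s) / s).  The composite likelihood of a window
## multiplies, over its SNPs, the binomial probability of the observed
## object-population allele counts integrated over this density, and the
## reported score is max over the s grid of 2 * (logCL(s) - logCL(0)).

#' Parameters of the sweep composite-likelihood model
#'
#' @param omega Drift variance scale (dimensionless, > 0); see
#'   [estimateOmega()].
#' @param Ne Effective population size used inside ln(2 N s).
#' @param s_grid Selection-coefficient grid; must contain 0 (the neutral
#'   model). Default: 0 plus 20 log-spaced values in \[1e-4, 0.5\].
#' @param recomb_rate Per-bp recombination rate converting physical
#'   distance from the putative sweep site into r.
#' @param n_nodes Gauss-Legendre quadrature nodes for the frequency
#'   integral.
#' @return List of class `sweep_model_params`.
#' @export
sweepModelParams <- function(omega, Ne = 10000,
                             s_grid = c(0, exp(seq(log(1e-4), log(0.5),
                                                   length.out = 20))),
                             recomb_rate = 1e-6, n_nodes = 64) {
  if (omega <= 0) stop("omega must be positive")
  if (!any(s_grid == 0)) stop("s_grid must contain 0")
  if (any(s_grid < 0)) stop("selection coefficients must be >= 0")
  structure(list(omega = omega, Ne = Ne, s_grid = sort(unique(s_grid)),
                 recomb_rate = recomb_rate, n_nodes = n_nodes),
            class = "sweep_model_params")
}

#' Method-of-moments drift variance scale
#'
#' omega = mean over putatively neutral sites of
#' (p_obj - p_ref)^2 / (p_ref (1 - p_ref)). Under the Balding-Nichols
#' model this estimates the divergence parameter F.
#'
#' @param p_ref,p_obj Reference and object population allele frequencies
#'   at matched sites; sites with `p_ref` at 0 or 1 are dropped.
#' @param min_sites Minimum usable sites (default 1000).
#' @return Estimated omega.
#' @export
estimateOmega <- function(p_ref, p_obj, min_sites = 1000) {
  use <- !is.na(p_ref) & !is.na(p_obj) & p_ref > 0 & p_ref < 1
  if (sum(use) < min_sites)
    stop("need at least ", min_sites, " polymorphic reference sites")
  mean((p_obj[use] - p_ref[use])^2 / (p_ref[use] * (1 - p_ref[use])))
}

## Escape probability per SNP for a given s; c = 1 means fully neutral
## (every lineage escapes).
.escapeProb <- function(dist_bp, s, Ne, recomb_rate) {
  if (s <= 0) return(rep(1, length(dist_bp)))
  lg <- log(2 * Ne * s)
  if (lg <= 0) return(rep(1, length(dist_bp)))
  r <- dist_bp * recomb_rate
  pmin(pmax(1 - exp(-r * lg / s), 0), 1)
}

## Composite log-likelihood of one window at escape probabilities c
## (one per SNP).  p1: reference frequencies; k of n: object-population
## alternate-allele counts; D: precomputed J x Q matrix of quadrature
## weight * truncated-normal core density; m0/m1: endpoint point masses.
.logCLAt <- function(cvec, k, n, D, m0, m1, nodes) {
  J <- length(k); Q <- length(nodes)
  Y <- 1 - cvec + cvec %o% nodes              # J x Q post-sweep frequencies
  B <- matrix(dbinom(rep(k, Q), rep(n, Q), pmin(pmax(as.vector(Y), 0), 1)),
              J, Q)
  I <- m0 * dbinom(k, n, pmin(pmax(1 - cvec, 0), 1)) +
    m1 * dbinom(k, n, 1) + rowSums(D * B)
  sum(log(pmax(I, 1e-300)))
}

#' XP-CLR score of one window
#'
#' @param pos SNP positions (bp) within the window.
#' @param p_ref Reference-population allele frequencies (must lie
#'   strictly in (0, 1); other SNPs are dropped).
#' @param k_obj,n_obj Object-population alternate-allele counts and
#'   called-allele totals per SNP.
#' @param putative_site Position (bp) of the putative sweep site
#'   (typically the window midpoint).
#' @param params A [sweepModelParams()] object.
#' @param min_sites Minimum usable SNPs; fewer returns `NA`.
#' @return Score `max over s of 2 (logCL(s) - logCL(0))` (>= 0), or
#'   `NA_real_` for an unusable window.
#' @export
xpclrWindow <- function(pos, p_ref, k_obj, n_obj, putative_site, params,
                        min_sites = 3) {
  if (!inherits(params, "sweep_model_params")) stop("params must come from sweepModelParams()")
  use <- !is.na(p_ref) & p_ref > 0 & p_ref < 1 & n_obj >= 2
  if (sum(use) < min_sites) return(NA_real_)
  pos <- pos[use]; p1 <- p_ref[use]; k <- k_obj[use]; n <- n_obj[use]
  gl <- pracma::gaussLegendre(params$n_nodes, 0, 1)
  sd <- sqrt(params$omega * p1 * (1 - p1))
  m0 <- pnorm(0, p1, sd)
  m1 <- pnorm(1, p1, sd, lower.tail = FALSE)
  D <- outer(seq_along(p1), seq_along(gl$x),
             function(j, q) gl$w[q] * dnorm(gl$x[q], p1[j], sd[j]))
  dist <- abs(pos - putative_site)
  ll0 <- .logCLAt(rep(1, length(p1)), k, n, D, m0, m1, gl$x)
  best <- 0
  for (s in params$s_grid[params$s_grid > 0]) {
    cvec <- .escapeProb(dist, s, params$Ne, params$recomb_rate)
    lls <- .logCLAt(cvec, k, n, D, m0, m1, gl$x)
    best <- max(best, 2 * (lls - ll0))
  }
  best
}

#' Per-window XP-CLR track
#'
#' Reference population supplies p_ref; the object population (the one
#' scanned for sweeps) supplies allele counts. The putative sweep site of
#' each window is its midpoint.
#'
#' @param gm A [GenotypeMatrix].
#' @param windows `GRanges` window grid.
#' @param ref_pop,obj_pop Population labels.
#' @param params A [sweepModelParams()]; if `omega` is `NA` it is first
#'   estimated genome-wide with [estimateOmega()].
#' @param min_sites Minimum usable SNPs per window (default 3).
#' @return `GRanges` track (`statistic == "xpclr"`).
#' @export
scanXpclr <- function(gm, windows, ref_pop, obj_pop, params, min_sites = 3) {
  gr <- .popDosage(gm, ref_pop)
  go <- .popDosage(gm, obj_pop)
  cr <- .siteAlleleCounts(gr)
  co <- .siteAlleleCounts(go)
  p_ref <- ifelse(cr$an >= 2, cr$ac / cr$an, NA_real_)
  pos <- start(rowRanges(gm))
  hits <- findOverlaps(rowRanges(gm), windows)
  idx <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  score <- rep(NA_real_, length(windows))
  mids <- (start(windows) + end(windows)) / 2
  for (w in names(idx)) {
    wi <- as.integer(w)
    sites <- idx[[w]]
    score[wi] <- xpclrWindow(pos[sites], p_ref[sites], co$ac[sites],
                             co$an[sites], mids[wi], params, min_sites)
  }
  .newTrack(windows, score, "xpclr")
}
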