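## Seed-deterministic synthetic cohorts with known ground truth, built on
## the Balding-Nichols allele-frequency model.  These generators emulate
## the data structure of a domestication cohort: divergent populations,
## injected hard sweeps, an occupancy matrix with prescribed class
## counts, an SV cohort with group-shifted frequencies and a rare-allele
## target, and tissue expression with SV-linked effects.

#' Hitchhiking frequency transform of a hard sweep
#'
#' A lineage at recombination distance r from the selected site escapes
#' the sweep with probability c = 1 - exp(-r ln(2 N s) / s); otherwise it
#' is dragged to the derived background, so a pre-sweep frequency p
#' becomes 1 - c + c p.
#'
#' @param p Pre-sweep derived-allele frequencies.
#' @param dist_bp Physical distance from the sweep site (bp).
#' @param s Selection coefficient (> 0).
#' @param Ne Effective population size.
#' @param recomb_rate Per-bp recombination rate.
#' @return Post-sweep frequencies.
#' @export
sweepTransform <- function(p, dist_bp, s, Ne = 10000, recomb_rate = 1e-6) {
  cvec <- .escapeProb(dist_bp, s, Ne, recomb_rate)
  1 - cvec + cvec * p
}

#' Simulate a multi-population SNP cohort (Balding-Nichols)
#'
#' Ancestral frequencies are Beta-distributed; each population's
#' frequency is drawn from Beta(p (1-F)/F, (1-p)(1-F)/F), giving
#' E\[FST\] of about F. Hard sweeps are injected into named populations
#' by applying [sweepTransform()] around the sweep site. Diploid
#' genotypes are Binomial(2, p_pop) per sample.
#'
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param pops Named integer vector: diploid samples per population,
#'   e.g. `c(wild = 50, local = 50)`.
#' @param F_st Named (or single) divergence parameter per population, in
#'   (0, 1).
#' @param n_sites Total SNP count (positions uniform per chromosome,
#'   proportional to length).
#' @param beta_shape Ancestral-frequency Beta shape parameters
#'   (default c(1, 1); frequencies clipped to \[0.01, 0.99\]).
#' @param sweeps Optional data frame with columns `chrom`, `pos`, `s`,
#'   `pop` (population swept); `Ne` and `recomb_rate` give the sweep
#'   scale.
#' @param Ne,recomb_rate Sweep-model constants (defaults 1e4 and 1e-6).
#' @param seed Random seed (integer).
#' @return List with `genotypes` (a [GenotypeMatrix] over all
#'   populations), `truth` (list: per-site ancestral and per-population
#'   frequencies, sweep table).
#' @export
simulateSNPCohort <- function(chrom_lengths, pops, F_st = 0.1,
                              n_sites = 10000, beta_shape = c(1, 1),
                              sweeps = NULL, Ne = 10000,
                              recomb_rate = 1e-6, seed = 1) {
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  if (is.null(names(pops))) stop("pops must be named")
  if (length(F_st) == 1) F_st <- setNames(rep(F_st, length(pops)), names(pops))
  if (any(F_st <= 0 | F_st >= 1)) stop("F must lie in (0, 1)")
  set.seed(seed)
  ## positions proportional to chromosome length, strictly increasing
  alloc <- round(n_sites * chrom_lengths / sum(chrom_lengths))
  alloc[length(alloc)] <- n_sites - sum(alloc[-length(alloc)])
  pos_list <- lapply(seq_along(chrom_lengths), function(i)
    sort(sample.int(chrom_lengths[i], alloc[i])))
  chrom <- rep(names(chrom_lengths), alloc)
  pos <- unlist(pos_list)
  p_anc <- pmin(pmax(rbeta(n_sites, beta_shape[1], beta_shape[2]),
                     0.01), 0.99)
  pop_freq <- list()
  for (pp in names(pops)) {
    f <- F_st[[pp]]
    pf <- rbeta(n_sites, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    pop_freq[[pp]] <- pf
  }
  if (!is.null(sweeps)) {
    for (i in seq_len(nrow(sweeps))) {
      sw <- sweeps[i, ]
      on_chr <- chrom == sw$chrom
      d <- abs(pos - sw$pos)
      pf <- pop_freq[[sw$pop]]
      pf[on_chr] <- sweepTransform(pf[on_chr], d[on_chr], sw$s, Ne,
                                   recomb_rate)
      pop_freq[[sw$pop]] <- pf
    }
  }
  gt <- do.call(cbind, lapply(names(pops), function(pp) {
    matrix(rbinom(n_sites * pops[[pp]], 2, rep(pop_freq[[pp]], pops[[pp]])),
           nrow = n_sites,
           dimnames = list(NULL, sprintf("%s_%02d", pp, seq_len(pops[[pp]]))))
  }))
  gr <- GRanges(chrom, IRanges(pos, width = 1))
  seqlengths(gr) <- chrom_lengths[seqlevels(gr)]
  gm <- GenotypeMatrix(gt, gr, rep(names(pops), pops))
  list(genotypes = gm,
       truth = list(p_anc = p_anc, pop_freq = pop_freq, sweeps = sweeps,
                    Ne = Ne, recomb_rate = recomb_rate, seed = seed))
}

#' Simulate an occupancy matrix with prescribed class counts
#'
#' Deterministic construction: core rows all-present; private rows
#' present in one genome (round-robin); softcore rows with occupancy
#' drawn uniformly from the integers in (0.9 N, N); dispensable rows
#' from \[2, 0.9 N\]. Which genomes carry a row is drawn uniformly.
#' Classifying the result recovers the requested counts exactly.
#'
#' @param n_genomes N (>= 12 so that every class is realisable).
#' @param class_counts Named integer vector with entries `core`,
#'   `softcore`, `dispensable`, `private`.
#' @param groups Optional genome group labels (default: balanced
#'   wild/local/improved split).
#' @param seed Random seed.
#' @return List with `occupancy` (an [OccupancyMatrix]) and `truth`
#'   (the intended class per row).
#' @export
simulateOccupancy <- function(n_genomes,
                              class_counts = c(core = 400, softcore = 300,
                                               dispensable = 250,
                                               private = 50),
                              groups = NULL, seed = 1) {
  N <- n_genomes
  need <- c("core", "softcore", "dispensable", "private")
  if (!all(need %in% names(class_counts))) stop("class_counts incomplete")
  soft_lo <- floor(0.9 * N) + 1
  if (class_counts[["softcore"]] > 0 && soft_lo > N - 1)
    stop("no integer occupancy satisfies softcore bounds for this N")
  set.seed(seed)
  rows <- list(); cls <- character(0)
  resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]
  addrows <- function(counts) {
    t(vapply(counts, function(k) {
      v <- logical(N); v[sample.int(N, k)] <- TRUE; v
    }, logical(N)))
  }
  if (class_counts[["core"]] > 0) {
    rows$core <- matrix(TRUE, class_counts[["core"]], N)
    cls <- c(cls, rep("core", class_counts[["core"]]))
  }
  if (class_counts[["softcore"]] > 0) {
    occ <- resample(soft_lo:(N - 1), class_counts[["softcore"]])
    rows$softcore <- addrows(occ)
    cls <- c(cls, rep("softcore", class_counts[["softcore"]]))
  }
  if (class_counts[["dispensable"]] > 0) {
    occ <- resample(2:floor(0.9 * N), class_counts[["dispensable"]])
    rows$dispensable <- addrows(occ)
    cls <- c(cls, rep("dispensable", class_counts[["dispensable"]]))
  }
  if (class_counts[["private"]] > 0) {
    m <- matrix(FALSE, class_counts[["private"]], N)
    for (i in seq_len(nrow(m))) m[i, ((i - 1) %% N) + 1] <- TRUE
    rows$private <- m
    cls <- c(cls, rep("private", class_counts[["private"]]))
  }
  p <- do.call(rbind, rows)
  if (is.null(groups))
    groups <- rep(c("wild", "local", "improved"), length.out = N)
  occ <- OccupancyMatrix(p, group = groups)
  list(occupancy = occ, truth = factor(cls, levels = need))
}

#' Simulate an SV cohort with group-shifted sites
#'
#' Null sites draw one cohort-wide allele frequency whose rare
#' (AF < 0.05) share matches `rare_target`: with probability
#' `rare_target` the AF is uniform on (0.004, 0.03), otherwise uniform
#' on (0.08, 0.9) (both laws keep clear of the 0.05 boundary so that the
#' rare fraction realised after binomial genotype sampling still matches
#' the target). Shifted sites have group-A AF `base_af` and group-B
#' AF `base_af + shift` (clipped to (0, 0.99)). Genotypes are
#' Hardy-Weinberg Binomial(2, AF) draws. SV metadata (type mix, length
#' law) mimic a PAV-dominated long-read call set.
#'
#' @param n_sites Total SV sites.
#' @param n_shifted Number of group-shifted sites among them.
#' @param pops Named diploid sample sizes, exactly two groups, e.g.
#'   `c(wild = 40, local = 40)`.
#' @param base_af Group-A frequency at shifted sites (default 0.05).
#' @param shift Frequency shift added in group B (default 0.55).
#' @param rare_target Intended rare-allele fraction of null sites
#'   (default 0.8).
#' @param chrom_lengths Named chromosome lengths for SV placement.
#' @param seed Random seed.
#' @return List with `cohort` (an [SVCohort]), `truth` (shifted site
#'   ids, per-site intended AFs).
#' @export
simulateSVCohort <- function(n_sites = 5000, n_shifted = 100,
                             pops = c(wild = 40, local = 40),
                             base_af = 0.05, shift = 0.55,
                             rare_target = 0.8,
                             chrom_lengths = c(chr1 = 2e7), seed = 1) {
  if (length(pops) != 2 || is.null(names(pops)))
    stop("pops must name exactly two groups")
  if (base_af + shift <= 0 || base_af + shift >= 1)
    stop("shift out of range")
  set.seed(seed)
  n_null <- n_sites - n_shifted
  is_rare <- runif(n_null) < rare_target
  af_null <- ifelse(is_rare, runif(n_null, 0.004, 0.03),
                    runif(n_null, 0.08, 0.9))
  af_a <- c(af_null, rep(base_af, n_shifted))
  af_b <- c(af_null, rep(pmin(pmax(base_af + shift, 0.001), 0.99), n_shifted))
  shifted <- c(rep(FALSE, n_null), rep(TRUE, n_shifted))
  ord <- sample.int(n_sites)          # interleave shifted sites
  af_a <- af_a[ord]; af_b <- af_b[ord]; shifted <- shifted[ord]
  na <- pops[[1]]; nb <- pops[[2]]
  gt <- cbind(
    matrix(rbinom(n_sites * na, 2, rep(af_a, na)), n_sites,
           dimnames = list(NULL, sprintf("%s_%02d", names(pops)[1],
                                         seq_len(na)))),
    matrix(rbinom(n_sites * nb, 2, rep(af_b, nb)), n_sites,
           dimnames = list(NULL, sprintf("%s_%02d", names(pops)[2],
                                         seq_len(nb)))))
  chrom <- sample(names(chrom_lengths), n_sites, replace = TRUE,
                  prob = chrom_lengths / sum(chrom_lengths))
  pos <- vapply(chrom, function(ch) sample.int(chrom_lengths[[ch]], 1), 1L)
  type <- sample(c("INS", "DEL", "DUP", "INV"), n_sites, replace = TRUE,
                 prob = c(0.495, 0.495, 0.005, 0.005))
  svlen <- pmax(50L, as.integer(round(rlnorm(n_sites, log(300), 1.2))))
  o <- order(chrom, pos)
  gr <- GRanges(chrom[o],
                IRanges(pos[o], ifelse(type[o] == "INS", pos[o],
                                       pmin(pos[o] + svlen[o] - 1,
                                            chrom_lengths[chrom[o]]))))
  seqlengths(gr) <- chrom_lengths[seqlevels(gr)]
  mcols(gr)$svtype <- type[o]
  mcols(gr)$svlen <- svlen[o]
  mcols(gr)$site_id <- sprintf("sv%06d", seq_len(n_sites))
  svc <- SVCohort(gt[o, , drop = FALSE], gr, group = rep(names(pops), pops))
  list(cohort = svc,
       truth = list(shifted = mcols(gr)$site_id[shifted[o]],
                    af_a = af_a[o], af_b = af_b[o], seed = seed))
}

#' Simulate tissue expression with SV-linked effects
#'
#' Per strain, tissue and replicate, log2 expression of a paired gene is
#' baseline + delta x carrier + Normal(0, sigma); FPKM is the
#' back-transform 2^x, so delta = 1 is exactly a two-fold carrier effect
#' in the noise-free case.
#'
#' @param pairs Data frame from [buildSVGenePairs()] (columns `gene_id`,
#'   `carriers`); genes not in any pair get baseline expression only.
#' @param strains Strain names.
#' @param genes Gene ids to simulate (superset of the pairs' genes).
#' @param delta Carrier effect in log2 units (default 1).
#' @param sigma Noise SD in log2 units (default 0.1).
#' @param tissues Tissue names (default 6 generic tissues).
#' @param replicates Replicates per strain x tissue (default 2).
#' @param baseline_log2 Mean baseline (default 5).
#' @param seed Random seed.
#' @return List with `expression` (a [StrainExpression], assay
#'   `"fpkm"`), `truth` (per-gene carrier strains and delta).
#' @export
simulateExpression <- function(pairs, strains, genes = unique(pairs$gene_id),
                               delta = 1, sigma = 0.1,
                               tissues = paste0("tissue", 1:6),
                               replicates = 2, baseline_log2 = 5,
                               seed = 1) {
  if (sigma < 0) stop("sigma must be non-negative")
  set.seed(seed)
  carriers <- setNames(vector("list", length(genes)), genes)
  for (i in seq_len(nrow(pairs))) {
    cs <- strsplit(pairs$carriers[i], ",")[[1]]
    carriers[[pairs$gene_id[i]]] <- union(carriers[[pairs$gene_id[i]]], cs)
  }
  cd <- expand.grid(replicate = seq_len(replicates), tissue = tissues,
                    strain = strains, stringsAsFactors = FALSE)
  base <- rnorm(length(genes), baseline_log2, 0.5)
  lg <- matrix(0, length(genes), nrow(cd),
               dimnames = list(genes, NULL))
  for (j in seq_len(nrow(cd))) {
    eff <- vapply(genes, function(g)
      delta * (cd$strain[j] %in% carriers[[g]]), numeric(1))
    lg[, j] <- base + eff + rnorm(length(genes), 0, sigma)
  }
  expr <- StrainExpression(2^lg, strain = cd$strain, tissue = cd$tissue,
                           replicate = cd$replicate, unit = "fpkm")
  list(expression = expr,
       truth = list(carriers = carriers, delta = delta, sigma = sigma,
                    seed = seed))
}
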