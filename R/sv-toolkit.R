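## Non-redundant SV construction, filtering, annotation, divergence
## scanning and summary statistics.

## Per-sample SV calls are exchanged as a data.frame with columns
## sample, chrom, pos (1-based), end, type, svlen, gt (dosage 0/1/2/NA)
## and optionally seq (inserted/deleted sequence).
.checkSvCalls <- function(calls) {
  need <- c("sample", "chrom", "pos", "end", "type", "svlen", "gt")
  if (!all(need %in% colnames(calls)))
    stop("SV calls need columns: ", paste(need, collapse = ", "))
  if (any(calls$svlen < 50)) stop("SV length must be >= 50 bp")
  if (!all(calls$type %in% c("INS", "DEL", "DUP", "INV")))
    stop("SV type must be INS, DEL, DUP or INV")
  invisible(calls)
}

.pid <- function(s1, s2) {
  al <- Biostrings::pairwiseAlignment(s1, s2, type = "global")
  Biostrings::pid(al) / 100
}

## Single-linkage clustering of one (chrom, type) stratum; returns the
## cluster id per record.  Predicate: |pos difference| <= max_dist and
## min(len)/max(len) >= size_ratio_min; when both members carry
## sequences, additionally sequence identity >= seq_id_min.
.linkCluster <- function(pos, len, seqs, max_dist, size_ratio_min,
                         seq_id_min) {
  n <- length(pos)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
  ord <- order(pos)
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    for (b in (a + 1):n) {
      j <- ord[b]
      if (pos[j] - pos[i] > max_dist) break
      if (min(len[i], len[j]) / max(len[i], len[j]) < size_ratio_min) next
      if (!is.null(seqs) && !is.na(seqs[i]) && !is.na(seqs[j]) &&
          .pid(seqs[i], seqs[j]) < seq_id_min) next
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Merge per-sample SV calls into non-redundant SV sites
#'
#' Single-linkage clustering within each (chromosome, SV type) stratum.
#' Two calls are linked when their breakpoint positions differ by at most
#' `max_dist` bp and their length ratio (smaller/larger) is at least
#' `size_ratio_min`; when both calls carry sequences, a global alignment
#' identity of at least `seq_id_min` is additionally required. The
#' representative of a site is the member closest to the cluster's
#' median position (ties broken by smallest sample id). Results are
#' independent of the input row order.
#'
#' @param calls Data frame of per-sample calls (columns `sample`,
#'   `chrom`, `pos`, `end`, `type`, `svlen`, `gt`, optional `seq`).
#' @param max_dist Maximum breakpoint distance in bp (default 500; use
#'   1000 for error-region consolidation).
#' @param size_ratio_min Minimum length ratio (default 0.7).
#' @param seq_id_min Minimum sequence identity when both sequences are
#'   available (default 0.25).
#' @param samples Optional full sample vector for the genotype matrix
#'   (defaults to the samples observed in `calls`).
#' @param groups Optional named group vector for the samples.
#' @return An [SVCohort]; `rowRanges` carry `svtype`, `svlen`,
#'   `site_id`, `support` (member count). Samples without a member call
#'   at a site are genotyped 0.
#' @export
mergeSVs <- function(calls, max_dist = 500, size_ratio_min = 0.7,
                     seq_id_min = 0.25, samples = NULL, groups = NULL) {
  .checkSvCalls(calls)
  calls <- calls[order(calls$chrom, calls$type, calls$pos, calls$sample), ]
  strata <- interaction(calls$chrom, calls$type, drop = TRUE)
  calls$cluster <- NA_integer_
  nextid <- 0L
  for (st in levels(strata)) {
    idx <- which(strata == st)
    seqs <- if ("seq" %in% colnames(calls)) calls$seq[idx] else NULL
    cl <- .linkCluster(calls$pos[idx], calls$svlen[idx], seqs,
                       max_dist, size_ratio_min, seq_id_min)
    calls$cluster[idx] <- nextid + as.integer(factor(cl))
    nextid <- max(calls$cluster[idx])
  }
  if (is.null(samples)) samples <- sort(unique(calls$sample))
  reps <- do.call(rbind, lapply(split(calls, calls$cluster), function(m) {
    med <- median(m$pos)
    cand <- m[order(abs(m$pos - med), m$sample), ]
    rep <- cand[1, ]
    rep$support <- nrow(m)
    rep
  }))
  reps <- reps[order(reps$chrom, reps$pos, reps$type), ]
  gt <- matrix(0L, nrow(reps), length(samples),
               dimnames = list(NULL, samples))
  for (r in seq_len(nrow(reps))) {
    m <- calls[calls$cluster == reps$cluster[r], ]
    carried <- tapply(m$gt, m$sample, function(v)
      if (all(is.na(v))) NA_integer_ else max(v, na.rm = TRUE))
    gt[r, names(carried)] <- as.integer(carried)
  }
  gr <- GRanges(reps$chrom,
                IRanges(reps$pos,
                        ifelse(reps$type == "INS", reps$pos, reps$end)))
  mcols(gr)$svtype <- reps$type
  mcols(gr)$svlen <- reps$svlen
  mcols(gr)$support <- reps$support
  if (is.null(groups)) groups <- rep("cohort", length(samples))
  SVCohort(gt, gr, group = groups)
}

#' Filter SVs by size, genotype and error-prone regions
#'
#' Removes SVs that are larger than `max_len` bp (strictly), that carry
#' only reference genotypes (0/0 in every sample; in a per-sample call
#' table, 0/0 in the calling sample), or whose interval intersects an
#' error-prone region expanded by `flank` bp on each side. The removal
#' tally assigns each removed SV to the first failing reason in the
#' order size, genotype, region.
#'
#' @param x An [SVCohort] (cohort context) or per-sample call data frame
#'   (per-sample context).
#' @param error_regions `GRanges` of error-prone regions (may be empty).
#' @param flank Expansion of each error region in bp (default 2500).
#' @param max_len Maximum SV length in bp (default 1e5; "larger than" is
#'   strict, an SV of exactly `max_len` is kept).
#' @return List with `kept` (same class as `x`) and `tally` (named
#'   integer vector: size, genotype, region, kept).
#' @export
filterSVs <- function(x, error_regions = GRanges(), flank = 2500,
                      max_len = 1e5) {
  if (is(x, "SVCohort")) {
    len <- mcols(rowRanges(x))$svlen
    g <- dosage(x)
    all_ref <- apply(g, 1, function(v) all(is.na(v) | v == 0))
    iv <- granges(rowRanges(x))
  } else {
    .checkSvCalls(x)
    len <- x$svlen
    all_ref <- is.na(x$gt) | x$gt == 0
    iv <- GRanges(x$chrom, IRanges(x$pos, ifelse(x$type == "INS", x$pos, x$end)))
  }
  in_region <- if (length(error_regions)) {
    expanded <- suppressWarnings(resize(error_regions,
                                        width(error_regions) + 2 * flank,
                                        fix = "center"))
    overlapsAny(iv, expanded)
  } else rep(FALSE, length(len))
  size_fail <- len > max_len
  reason <- ifelse(size_fail, "size",
                   ifelse(all_ref, "genotype",
                          ifelse(in_region, "region", "kept")))
  tally <- vapply(c("size", "genotype", "region", "kept"),
                  function(r) sum(reason == r), integer(1))
  keep <- reason == "kept"
  kept <- if (is(x, "SVCohort")) x[keep, ] else x[keep, , drop = FALSE]
  list(kept = kept, tally = tally)
}

#' SV allele frequencies per sample group
#'
#' AF = alternate allele count / (2 x called samples), per site and
#' group; sites with no called sample in a group get `NA`.
#'
#' @param svc An [SVCohort].
#' @param groups Group labels to compute (default: all distinct labels
#'   plus the full `"cohort"`).
#' @return Numeric matrix, sites x groups.
#' @export
svAlleleFrequency <- function(svc, groups = NULL) {
  g <- dosage(svc)
  lab <- sampleGroups(svc)
  if (is.null(groups)) groups <- c(unique(lab), "cohort")
  out <- sapply(groups, function(gr) {
    cols <- if (gr == "cohort") rep(TRUE, ncol(g)) else lab == gr
    sub <- g[, cols, drop = FALSE]
    called <- rowSums(!is.na(sub))
    ifelse(called > 0, rowSums(sub, na.rm = TRUE) / (2 * called), NA_real_)
  })
  rownames(out) <- mcols(rowRanges(svc))$site_id
  out
}

#' Fraction of rare alleles
#'
#' @param af Numeric vector of allele frequencies (NA dropped).
#' @param threshold Rarity threshold; rare means strictly below it
#'   (default 0.05).
#' @return Fraction of rare sites among non-missing ones.
#' @export
rareFraction <- function(af, threshold = 0.05) {
  af <- af[!is.na(af)]
  if (!length(af)) stop("no non-missing allele frequencies")
  mean(af < threshold)
}

#' Group frequency-divergence scan over SV sites
#'
#' Per site, carriers (genotype with >= 1 alternate allele) are counted
#' in each group, the 2x2 carrier table is tested with Fisher's exact
#' test, p-values are BH-adjusted across all sites, and the carrier
#' frequency fold change is computed. Significant sites have q < `fdr`
#' and fold change > `fc`.
#'
#' @param svc An [SVCohort].
#' @param group_a,group_b Group labels (ancestral first).
#' @param fdr,fc Thresholds (defaults 1e-4 and 2).
#' @return Data frame, one row per site, as in
#'   [geneFrequencyDifferentiation()], plus `site_id`.
#' @export
svDivergenceScan <- function(svc, group_a, group_b, fdr = 1e-4, fc = 2) {
  g <- dosage(svc)
  lab <- sampleGroups(svc)
  ia <- lab %in% group_a
  ib <- lab %in% group_b
  if (sum(ia) < 2 || sum(ib) < 2) stop("each group needs >= 2 samples")
  carrier <- !is.na(g) & g >= 1
  res <- .freqDifferentiation(rowSums(carrier[, ia, drop = FALSE]), sum(ia),
                              rowSums(carrier[, ib, drop = FALSE]), sum(ib),
                              fdr = fdr, fc = fc)
  cbind(site_id = mcols(rowRanges(svc))$site_id, res,
        stringsAsFactors = FALSE)
}

## Long (sv index, gene, relation) table: relation is cds, intron,
## upstream or downstream (flank relations are strand-aware).  INS are
## treated as 1-bp points (already true of their ranges).
.svGeneRelations <- function(sv_gr, models, flank = 5000) {
  rel <- list()
  add <- function(hits, relation) {
    if (!length(hits$hits)) return()
    rel[[length(rel) + 1]] <<- data.frame(
      sv = S4Vectors::queryHits(hits$hits),
      gene_id = hits$gene_id[S4Vectors::subjectHits(hits$hits)],
      relation = relation, stringsAsFactors = FALSE)
  }
  if (length(models$cds))
    add(list(hits = findOverlaps(sv_gr, models$cds),
             gene_id = mcols(models$cds)$gene_id), "cds")
  introns <- .geneIntrons(models)
  if (length(introns))
    add(list(hits = findOverlaps(sv_gr, introns),
             gene_id = mcols(introns)$gene_id), "intron")
  up <- flank(models$genes, flank, start = TRUE)
  dn <- flank(models$genes, flank, start = FALSE)
  add(list(hits = findOverlaps(sv_gr, up),
           gene_id = mcols(models$genes)$gene_id), "upstream")
  add(list(hits = findOverlaps(sv_gr, dn),
           gene_id = mcols(models$genes)$gene_id), "downstream")
  if (!length(rel))
    return(data.frame(sv = integer(), gene_id = character(),
                      relation = character(), stringsAsFactors = FALSE))
  unique(do.call(rbind, rel))
}

.geneIntrons <- function(models) {
  if (!length(models$exons)) return(GRanges(gene_id = character()))
  exn <- split(models$exons, mcols(models$exons)$gene_id)
  bodies <- models$genes[match(names(exn), mcols(models$genes)$gene_id)]
  intr <- GRanges()
  for (i in seq_along(exn)) {
    gaps <- GenomicRanges::setdiff(granges(bodies[i]),
                                   reduce(granges(exn[[i]])))
    if (length(gaps)) {
      mcols(gaps)$gene_id <- mcols(bodies)$gene_id[i]
      intr <- c(intr, gaps)
    }
  }
  intr
}

#' Annotate the genomic context of SVs
#'
#' Category per SV with precedence CDS > regulatory > intergenic: an SV
#' overlapping any CDS exon is `cds`; otherwise one overlapping an
#' intron or the +/- `flank` bp gene flanks is `regulatory`; everything
#' else is `intergenic`. Multi-gene hits list every gene.
#'
#' @param sv An [SVCohort] or `GRanges` of SV intervals.
#' @param models Gene models from [readGeneModels()] (list with
#'   `genes`, `exons`, `cds`, each a `GRanges` with `gene_id`).
#' @param flank Flank width in bp (default 5000).
#' @return Data frame per SV: `category` and `genes` (comma-separated
#'   gene ids, empty for intergenic).
#' @export
annotateSVContext <- function(sv, models, flank = 5000) {
  sv_gr <- if (is(sv, "SVCohort")) granges(rowRanges(sv)) else sv
  rel <- .svGeneRelations(sv_gr, models, flank)
  category <- rep("intergenic", length(sv_gr))
  genes <- rep("", length(sv_gr))
  if (nrow(rel)) {
    category[unique(rel$sv[rel$relation != "cds"])] <- "regulatory"
    category[unique(rel$sv[rel$relation == "cds"])] <- "cds"
    allby <- split(rel$gene_id, rel$sv)
    genes[as.integer(names(allby))] <- vapply(
      allby, function(gs) paste(sort(unique(gs)), collapse = ","),
      character(1))
  }
  data.frame(category = category, genes = genes, stringsAsFactors = FALSE)
}

#' Multi-allelic SV locus summary
#'
#' Loci are formed by single-linkage over all non-redundant SVs of any
#' type whose intervals lie within `max_dist` bp of each other (the
#' merge distance without the type and size constraints). Reports the
#' allele-count histogram, the maximum alleles at one locus, and the
#' fraction of loci with >= 2 alleles.
#'
#' @param svc An [SVCohort] (or `GRanges` of nrSV intervals).
#' @param max_dist Linkage distance in bp (default 500).
#' @return List with `histogram` (table of alleles per locus), `max`,
#'   `multi_fraction` and `n_loci`.
#' @export
multiallelicSummary <- function(svc, max_dist = 500) {
  gr <- if (is(svc, "SVCohort")) granges(rowRanges(svc)) else svc
  loci <- reduce(gr, min.gapwidth = max_dist + 1)
  n <- countOverlaps(loci, gr, maxgap = 0)
  list(histogram = table(n), max = max(n),
       multi_fraction = mean(n >= 2), n_loci = length(loci))
}

#' SV / TE count correlation in uninterrupted windows
#'
#' Tiles the genome into non-overlapping windows, counts SVs (by
#' breakpoint position) and TEs (by interval midpoint) per window, and
#' correlates the two counts.
#'
#' @param sv `GRanges` of SV intervals (or an [SVCohort]).
#' @param te `GRanges` of TE intervals.
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param window Window size in bp (default 500 kb).
#' @return List with `windows` (`GRanges`), `sv_count`, `te_count`, and
#'   `r`, `r_squared`, `p_value` from [pearsonLinear()].
#' @export
svTeWindowCorrelation <- function(sv, te, chrom_lengths, window = 5e5) {
  sv_gr <- if (is(sv, "SVCohort")) granges(rowRanges(sv)) else sv
  tiles <- scanWindows(chrom_lengths, size = window, step = window)
  if (length(tiles) < 3) stop("need at least three windows")
  sv_pos <- GRanges(seqnames(sv_gr), IRanges(start(sv_gr), width = 1))
  te_mid <- GRanges(seqnames(te),
                    IRanges(floor((start(te) + end(te)) / 2), width = 1))
  sv_count <- countOverlaps(tiles, sv_pos)
  te_count <- countOverlaps(tiles, te_mid)
  ct <- pearsonLinear(te_count, sv_count)
  list(windows = tiles, sv_count = sv_count, te_count = te_count,
       r = ct$r, r_squared = ct$r_squared, p_value = ct$p_value)
}

#' Pan- and core-SV accumulation curves
#'
#' The accumulation machinery of [accumulationCurves()] applied to SV
#' presence (genotype >= 1; missing treated as absent).
#'
#' @param svc An [SVCohort].
#' @inheritParams accumulationCurves
#' @return As [accumulationCurves()].
#' @export
panSVAccumulation <- function(svc, n_orders = 100, seed = 1, order = NULL) {
  pres <- !is.na(dosage(svc)) & dosage(svc) >= 1
  keep <- rowSums(pres) > 0
  accumulationCurves(pres[keep, , drop = FALSE], n_orders = n_orders,
                     seed = seed, order = order)
}

#' Group-specific rare SVs
#'
#' SVs carried by every target sample, absent from every contrast
#' sample, and rare in the whole cohort (allele frequency strictly below
#' `af_max`).
#'
#' @param svc An [SVCohort].
#' @param target_samples,contrast_samples Disjoint sample-name sets.
#' @param af_max Cohort allele-frequency ceiling (default 0.05).
#' @return `GRanges` of qualifying SV sites, sorted by position.
#' @export
groupSpecificSVs <- function(svc, target_samples, contrast_samples,
                             af_max = 0.05) {
  if (length(intersect(target_samples, contrast_samples)))
    stop("target and contrast samples must be disjoint")
  g <- dosage(svc)
  if (!all(c(target_samples, contrast_samples) %in% colnames(g)))
    stop("unknown sample names")
  tg <- g[, target_samples, drop = FALSE]
  cg <- g[, contrast_samples, drop = FALSE]
  in_all_targets <- rowSums(!is.na(tg) & tg >= 1) == length(target_samples)
  absent_contrasts <- rowSums(!is.na(cg) & cg == 0) == length(contrast_samples)
  af <- svAlleleFrequency(svc, "cohort")[, 1]
  keep <- in_all_targets & absent_contrasts & !is.na(af) & af < af_max
  sort(rowRanges(svc)[keep])
}
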