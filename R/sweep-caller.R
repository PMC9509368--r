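## Percentile thresholding and four-condition intersection of the three
## statistic tracks into candidate selective-sweep regions.

#' Sweep-calling configuration
#'
#' Defaults follow the scan design: top 1% FST, top 5% XP-CLR, lowest 5%
#' Tajima's D in the descendant population, and D_descendant <
#' D_ancestral at the window.
#'
#' @param q_fst Upper-tail quantile for FST (default 0.99).
#' @param q_xpclr Upper-tail quantile for XP-CLR (default 0.95).
#' @param q_tajd Lower-tail quantile for descendant Tajima's D
#'   (default 0.05).
#' @param require_d_drop Require D_descendant < D_ancestral (default
#'   TRUE).
#' @return List of class `sweep_call_config`.
#' @export
sweepCallConfig <- function(q_fst = 0.99, q_xpclr = 0.95, q_tajd = 0.05,
                            require_d_drop = TRUE) {
  qs <- c(q_fst, q_xpclr, q_tajd)
  if (any(qs <= 0 | qs >= 1)) stop("quantiles must lie in (0, 1)")
  structure(list(q_fst = q_fst, q_xpclr = q_xpclr, q_tajd = q_tajd,
                 require_d_drop = require_d_drop),
            class = "sweep_call_config")
}

#' Select windows in a track's quantile tail
#'
#' The threshold is the linear-interpolation empirical quantile of the
#' non-missing scores (genome-wide); ties with the threshold are
#' included. Upper tail selects `score >= quantile(q)`; lower tail
#' selects `score <= quantile(q)`.
#'
#' @param track `GRanges` track with a `score` column.
#' @param q Quantile in (0, 1).
#' @param tail `"upper"` or `"lower"`.
#' @return Logical vector over the track's windows (FALSE at missing
#'   scores).
#' @export
selectQuantile <- function(track, q, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  s <- mcols(track)$score
  if (all(is.na(s))) stop("track has no non-missing score")
  thr <- unname(quantile(s, q, na.rm = TRUE, type = 7))
  sel <- if (tail == "upper") s >= thr else s <= thr
  sel & !is.na(s)
}

.sameGrid <- function(a, b) {
  length(a) == length(b) &&
    all(as.character(seqnames(a)) == as.character(seqnames(b))) &&
    all(start(a) == start(b)) && all(end(a) == end(b))
}

#' Call candidate selective-sweep regions
#'
#' A window is a sweep window iff it lies in the top `q_fst` tail of FST,
#' the top `q_xpclr` tail of XP-CLR, the bottom `q_tajd` tail of the
#' descendant population's Tajima's D, and (optionally) has
#' D_descendant < D_ancestral. Overlapping or adjacent sweep windows are
#' merged into maximal regions.
#'
#' @param fst,xpclr,d_descendant,d_ancestral `GRanges` tracks sharing an
#'   identical window grid.
#' @param cfg A [sweepCallConfig()].
#' @return `GRanges` of merged regions with metadata columns `n_windows`,
#'   `max_fst`, `max_xpclr`, `min_d`.
#' @export
callSweeps <- function(fst, xpclr, d_descendant, d_ancestral,
                       cfg = sweepCallConfig()) {
  if (!.sameGrid(fst, xpclr) || !.sameGrid(fst, d_descendant) ||
      !.sameGrid(fst, d_ancestral))
    stop("tracks must share an identical window grid")
  sel <- selectQuantile(fst, cfg$q_fst, "upper") &
    selectQuantile(xpclr, cfg$q_xpclr, "upper") &
    selectQuantile(d_descendant, cfg$q_tajd, "lower")
  if (cfg$require_d_drop) {
    dd <- mcols(d_descendant)$score
    da <- mcols(d_ancestral)$score
    sel <- sel & !is.na(dd) & !is.na(da) & dd < da
  }
  win <- fst[sel]
  if (!length(win)) {
    out <- GRanges()
    mcols(out) <- DataFrame(n_windows = integer(), max_fst = numeric(),
                            max_xpclr = numeric(), min_d = numeric())
    return(out)
  }
  regions <- reduce(granges(win))
  hits <- findOverlaps(win, regions)
  sh <- S4Vectors::subjectHits(hits)
  mcols(regions)$n_windows <- as.integer(table(factor(sh, seq_along(regions))))
  agg <- function(v, f) as.numeric(tapply(v[S4Vectors::queryHits(hits)], sh, f))
  mcols(regions)$max_fst <- agg(mcols(fst)$score[sel], max)
  mcols(regions)$max_xpclr <- agg(mcols(xpclr)$score[sel], max)
  mcols(regions)$min_d <- agg(mcols(d_descendant)$score[sel], min)
  regions
}

#' Assign genes to sweep regions
#'
#' A gene is assigned to a region when its gene-body interval overlaps
#' the region by at least 1 bp.
#'
#' @param regions `GRanges` of sweep regions.
#' @param genes `GRanges` of gene bodies with a `gene_id` metadata
#'   column.
#' @return List with `per_region` (list of gene-id vectors, one per
#'   region) and `genes` (sorted union of assigned gene ids).
#' @export
regionsToGenes <- function(regions, genes) {
  if (is.null(mcols(genes)$gene_id))
    stop("genes need a 'gene_id' metadata column")
  hits <- findOverlaps(genes, regions, minoverlap = 1)
  per <- vector("list", length(regions))
  for (i in seq_along(per)) per[[i]] <- character(0)
  if (length(hits)) {
    sp <- split(mcols(genes)$gene_id[S4Vectors::queryHits(hits)],
                S4Vectors::subjectHits(hits))
    for (w in names(sp)) per[[as.integer(w)]] <- unique(sp[[w]])
  }
  list(per_region = per, genes = sort(unique(unlist(per))))
}
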