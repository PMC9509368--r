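## SV-gene pair construction and presence/absence expression testing.

#' Fragments per kilobase per million (FPKM)
#'
#' FPKM = counts / ((gene_length / 1000) * (library_fragments / 1e6)).
#' Linear in counts, inversely linear in gene length and library size.
#'
#' @param counts Fragment counts (vector or matrix).
#' @param gene_length_bp Gene (transcript) length in bp, > 0.
#' @param library_fragments Mapped fragments in the library, > 0.
#' @return FPKM on the same shape as `counts`.
#' @export
computeFPKM <- function(counts, gene_length_bp, library_fragments) {
  if (any(gene_length_bp <= 0)) stop("gene length must be positive")
  if (any(library_fragments <= 0)) stop("library size must be positive")
  counts / ((gene_length_bp / 1000) * (library_fragments / 1e6))
}

#' Build testable SV-gene pairs
#'
#' A pair exists when the SV lies in the gene's introns or +/- `flank`
#' bp flanks (CDS hits are not expression-regulatory pairs). A pair is
#' testable when, among the strains with expression data, at least
#' `min_present` carry the SV and at least `min_absent` do not.
#'
#' @param svc An annotated [SVCohort].
#' @param models Gene models from [readGeneModels()].
#' @param strains Strain names with expression data; must be a subset of
#'   `colnames(svc)`.
#' @param min_present,min_absent Carrier / non-carrier minima (default 3
#'   each).
#' @param flank Flank width in bp (default 5000).
#' @return Data frame, one row per testable pair: `site_id`, `gene_id`,
#'   `relation`, `carriers`, `non_carriers` (comma-separated strain
#'   lists), `n_present`, `n_absent`.
#' @export
buildSVGenePairs <- function(svc, models, strains = colnames(svc),
                             min_present = 3, min_absent = 3,
                             flank = 5000) {
  if (!all(strains %in% colnames(svc)))
    stop("strains must be a subset of the cohort samples")
  rel <- .svGeneRelations(granges(rowRanges(svc)), models, flank)
  rel <- rel[rel$relation != "cds", , drop = FALSE]
  if (!nrow(rel)) return(.emptyPairs())
  g <- dosage(svc)[, strains, drop = FALSE]
  out <- lapply(seq_len(nrow(rel)), function(i) {
    sv <- rel$sv[i]
    carrier <- !is.na(g[sv, ]) & g[sv, ] >= 1
    absent <- !is.na(g[sv, ]) & g[sv, ] == 0
    if (sum(carrier) < min_present || sum(absent) < min_absent) return(NULL)
    data.frame(site_id = mcols(rowRanges(svc))$site_id[sv],
               gene_id = rel$gene_id[i], relation = rel$relation[i],
               carriers = paste(strains[carrier], collapse = ","),
               non_carriers = paste(strains[absent], collapse = ","),
               n_present = sum(carrier), n_absent = sum(absent),
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(.emptyPairs())
  ## one row per SV-gene pair even if several relations apply
  res <- do.call(rbind, out)
  res[!duplicated(res[, c("site_id", "gene_id")]), , drop = FALSE]
}

.emptyPairs <- function() {
  data.frame(site_id = character(), gene_id = character(),
             relation = character(), carriers = character(),
             non_carriers = character(), n_present = integer(),
             n_absent = integer(), stringsAsFactors = FALSE)
}

#' Differential expression over SV-gene pairs
#'
#' Per pair and tissue, replicates are averaged per strain, expression is
#' log2(FPKM + 1)-transformed, and carrier vs non-carrier strains are
#' compared with a two-sample t-test. p-values are BH-adjusted jointly
#' across all pair-by-tissue tests; a pair is significant when its
#' minimum q across tissues is below `fdr`. Tissues with fewer than
#' `min_per_side` strains on either side are skipped.
#'
#' @param pairs Data frame from [buildSVGenePairs()].
#' @param expr A [StrainExpression] with an `"fpkm"` assay (derived from
#'   counts via [computeFPKM()] if absent).
#' @param fdr FDR threshold (default 0.001).
#' @param min_per_side Minimum strains per side per tissue (default 3).
#' @param welch Use Welch's t-test (default FALSE: pooled variance).
#' @return List with `tests` (pair x tissue rows: p, q, direction,
#'   means) and `pairs` (per-pair min q, significant flag, and the gene
#'   tally of significant pairs in `attr(,"n_genes")`).
#' @export
pairDifferentialExpression <- function(pairs, expr, fdr = 0.001,
                                       min_per_side = 3, welch = FALSE) {
  fp <- .fpkmAssay(expr)
  cd <- colData(expr)
  ## average replicates per strain x tissue, on log2(FPKM + 1)
  key <- paste(cd$strain, cd$tissue, sep = "\r")
  lg <- log2(fp + 1)
  sums <- rowsum(t(lg), key)            # rows sorted by key
  strain_tissue <- t(sums / as.vector(table(key)))
  colnames(strain_tissue) <- rownames(sums)
  meta <- do.call(rbind, strsplit(colnames(strain_tissue), "\r"))
  st_strain <- meta[, 1]; st_tissue <- meta[, 2]
  tissues <- unique(st_tissue)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    gene <- pairs$gene_id[i]
    if (!gene %in% rownames(strain_tissue)) next
    carr <- strsplit(pairs$carriers[i], ",")[[1]]
    nonc <- strsplit(pairs$non_carriers[i], ",")[[1]]
    for (ti in tissues) {
      va <- strain_tissue[gene, st_tissue == ti & st_strain %in% carr]
      vb <- strain_tissue[gene, st_tissue == ti & st_strain %in% nonc]
      if (length(va) < min_per_side || length(vb) < min_per_side) {
        rows[[length(rows) + 1]] <- data.frame(
          site_id = pairs$site_id[i], gene_id = gene, tissue = ti,
          p_value = NA_real_, mean_carrier = NA_real_,
          mean_non_carrier = NA_real_, skipped = "too_few_strains",
          stringsAsFactors = FALSE)
        next
      }
      tt <- twoSampleT(va, vb, welch = welch)
      rows[[length(rows) + 1]] <- data.frame(
        site_id = pairs$site_id[i], gene_id = gene, tissue = ti,
        p_value = tt$p_value, mean_carrier = mean(va),
        mean_non_carrier = mean(vb), skipped = "",
        stringsAsFactors = FALSE)
    }
  }
  tests <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_id = character(), gene_id = character(),
               tissue = character(), p_value = numeric(),
               mean_carrier = numeric(), mean_non_carrier = numeric(),
               skipped = character(), stringsAsFactors = FALSE)
  tests$q_value <- bhAdjust(tests$p_value)
  tests$direction <- ifelse(tests$mean_carrier > tests$mean_non_carrier,
                            "up_in_carriers", "down_in_carriers")
  keyp <- paste(tests$site_id, tests$gene_id, sep = "\r")
  minq <- tapply(tests$q_value, keyp, function(q)
    if (all(is.na(q))) NA_real_ else min(q, na.rm = TRUE))
  pk <- paste(pairs$site_id, pairs$gene_id, sep = "\r")
  per_pair <- data.frame(
    site_id = pairs$site_id, gene_id = pairs$gene_id,
    min_q = as.numeric(minq[pk]), stringsAsFactors = FALSE)
  per_pair$significant <- !is.na(per_pair$min_q) & per_pair$min_q < fdr
  attr(per_pair, "n_genes") <- length(unique(per_pair$gene_id[per_pair$significant]))
  attr(per_pair, "transform") <- "log2(FPKM+1), replicates averaged per strain x tissue"
  list(tests = tests, pairs = per_pair)
}

.fpkmAssay <- function(expr) {
  if ("fpkm" %in% assayNames(expr)) return(assay(expr, "fpkm"))
  if (!"counts" %in% assayNames(expr))
    stop("expression needs an 'fpkm' or 'counts' assay")
  rd <- SummarizedExperiment::rowData(expr)
  cd <- colData(expr)
  if (is.null(rd$gene_length) || is.null(cd$library_fragments))
    stop("FPKM derivation needs gene_length and library_fragments")
  cnt <- assay(expr, "counts")
  t(t(cnt / (rd$gene_length / 1000)) / (cd$library_fragments / 1e6))
}
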