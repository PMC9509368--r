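#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#'   RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges
#'   colData assayNames
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges granges findOverlaps reduce resize
#'   countOverlaps seqnames start end width strand shift flank pintersect
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqnames<-
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
NULL

.validDosage <- function(g) {
  ok <- is.na(g) | (g %in% 0:2)
  if (!all(ok)) return("dosage values must be 0, 1, 2 or NA")
  TRUE
}

#' Biallelic SNP allele-dosage matrix with populations
#'
#' A `RangedSummarizedExperiment` whose single assay, `"dosage"`, holds
#' alternate-allele dosages (sites x samples, values 0/1/2 or `NA` for
#' missing calls) for diploid samples, whose `rowRanges` give 1-based SNP
#' positions (width-1 ranges), and whose `colData$population` assigns each
#' sample to a population (e.g. wild / local / CHN-I / JPN-I).
#'
#' @export
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  if (!"dosage" %in% assayNames(object))
    return("assay 'dosage' is required")
  v <- .validDosage(assay(object, "dosage"))
  if (!isTRUE(v)) return(v)
  if (!"population" %in% colnames(colData(object)))
    return("colData column 'population' is required")
  pos <- rowRanges(object)
  if (any(width(pos) != 1L))
    return("SNP ranges must have width 1")
  bychr <- split(start(pos), as.character(seqnames(pos)))
  for (p in bychr)
    if (is.unsorted(p, strictly = TRUE))
      return("positions must be strictly increasing within a chromosome")
  TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosage Integer matrix, sites x samples, values in \{0,1,2,NA\}.
#' @param positions `GRanges` of width-1 SNP positions (1-based), one per
#'   row of `dosage`; `seqlengths` should carry chromosome lengths.
#' @param population Character vector of population labels, one per sample.
#' @return A [GenotypeMatrix].
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 1))
#' gm <- GenotypeMatrix(matrix(c(0L, 1L, 2L, 1L), 2), gr, c("wild", "local"))
#' dosage(gm)
#' @export
GenotypeMatrix <- function(dosage, positions, population) {
  dosage <- as.matrix(dosage)
  mode(dosage) <- "integer"
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("S%03d", seq_len(ncol(dosage)))
  se <- SummarizedExperiment(
    assays = list(dosage = dosage),
    rowRanges = positions,
    colData = DataFrame(population = as.character(population),
                        row.names = colnames(dosage)))
  new("GenotypeMatrix", se)
}

#' Non-redundant structural-variant cohort
#'
#' A `RangedSummarizedExperiment` of merged (non-redundant) SV sites.
#' The assay `"genotype"` holds per-sample alternate-allele dosages
#' (0/1/2/`NA`); `rowRanges` carry the representative breakpoint interval
#' (1-based; insertions are 1-bp points) with metadata columns `svtype`
#' (INS/DEL/DUP/INV), `svlen` (bp, >= 50), `site_id` and `support`
#' (number of merged member calls). `colData$group` labels samples.
#'
#' @export
setClass("SVCohort", contains = "RangedSummarizedExperiment")

setValidity("SVCohort", function(object) {
  if (!"genotype" %in% assayNames(object))
    return("assay 'genotype' is required")
  v <- .validDosage(assay(object, "genotype"))
  if (!isTRUE(v)) return(v)
  m <- mcols(rowRanges(object))
  need <- c("svtype", "svlen")
  if (!all(need %in% colnames(m)))
    return("rowRanges need metadata columns 'svtype' and 'svlen'")
  if (!all(m$svtype %in% c("INS", "DEL", "DUP", "INV")))
    return("svtype must be INS, DEL, DUP or INV")
  if (any(m$svlen < 50))
    return("SV length must be >= 50 bp")
  if (!"group" %in% colnames(colData(object)))
    return("colData column 'group' is required")
  TRUE
})

#' Construct an SVCohort
#'
#' @param genotype Integer matrix, SV sites x samples, values in
#'   \{0,1,2,NA\} (alternate-allele dosage; 0 = absent).
#' @param ranges `GRanges` of representative SV intervals with metadata
#'   columns `svtype` and `svlen` (and optionally `site_id`, `support`).
#' @param group Character vector of sample group labels.
#' @return An [SVCohort].
#' @export
SVCohort <- function(genotype, ranges, group) {
  genotype <- as.matrix(genotype)
  mode(genotype) <- "integer"
  if (is.null(colnames(genotype)))
    colnames(genotype) <- sprintf("S%03d", seq_len(ncol(genotype)))
  if (is.null(mcols(ranges)$site_id))
    mcols(ranges)$site_id <- sprintf("sv%06d", seq_along(ranges))
  se <- SummarizedExperiment(
    assays = list(genotype = genotype),
    rowRanges = ranges,
    colData = DataFrame(group = as.character(group),
                        row.names = colnames(genotype)))
  new("SVCohort", se)
}

#' Orthogroup presence/absence matrix across genomes
#'
#' A `SummarizedExperiment` whose assay `"presence"` is a logical matrix
#' (orthogroups x genomes) and whose `colData$group` labels each genome
#' (wild / local / improved / genetic stock). No all-absent rows are
#' allowed: an orthogroup observed in zero genomes is not observable.
#'
#' @export
setClass("OccupancyMatrix", contains = "SummarizedExperiment")

setValidity("OccupancyMatrix", function(object) {
  if (!"presence" %in% assayNames(object))
    return("assay 'presence' is required")
  p <- assay(object, "presence")
  if (!is.logical(p)) return("presence assay must be logical")
  if (any(is.na(p))) return("presence must not contain NA")
  if (ncol(p) < 2) return("at least two genomes are required")
  if (any(rowSums(p) == 0)) return("all-absent orthogroup rows are invalid")
  if (!"group" %in% colnames(colData(object)))
    return("colData column 'group' is required")
  TRUE
})

#' Construct an OccupancyMatrix
#'
#' @param presence Logical matrix, orthogroups x genomes; row/col names
#'   are used as orthogroup and genome identifiers.
#' @param group Character vector of genome group labels.
#' @return An [OccupancyMatrix].
#' @export
OccupancyMatrix <- function(presence, group) {
  presence <- as.matrix(presence)
  mode(presence) <- "logical"
  if (is.null(rownames(presence)))
    rownames(presence) <- sprintf("OG%06d", seq_len(nrow(presence)))
  if (is.null(colnames(presence)))
    colnames(presence) <- sprintf("G%03d", seq_len(ncol(presence)))
  se <- SummarizedExperiment(
    assays = list(presence = presence),
    colData = DataFrame(group = as.character(group),
                        row.names = colnames(presence)))
  new("OccupancyMatrix", se)
}

#' Strain x tissue expression container
#'
#' A `SummarizedExperiment` of gene expression with one column per
#' library and `colData` columns `strain`, `tissue` and `replicate`.
#' Assays may include `"counts"` and/or `"fpkm"`; `rowData$gene_length`
#' (bp) and `colData$library_fragments` are required to derive FPKM
#' from counts.
#'
#' @export
setClass("StrainExpression", contains = "SummarizedExperiment")

setValidity("StrainExpression", function(object) {
  need <- c("strain", "tissue", "replicate")
  if (!all(need %in% colnames(colData(object))))
    return("colData needs 'strain', 'tissue' and 'replicate'")
  if (!length(assayNames(object)))
    return("at least one assay is required")
  if (any(assay(object, 1) < 0, na.rm = TRUE))
    return("expression values must be non-negative")
  TRUE
})

#' Construct a StrainExpression object
#'
#' @param values Numeric matrix, genes x libraries.
#' @param strain,tissue,replicate Per-library annotation vectors.
#' @param unit Either `"counts"` or `"fpkm"`; names the assay.
#' @param gene_length Optional per-gene length in bp (needed for FPKM
#'   derivation from counts).
#' @param library_fragments Optional per-library mapped-fragment totals.
#' @return A [StrainExpression].
#' @export
StrainExpression <- function(values, strain, tissue, replicate,
                             unit = c("fpkm", "counts"),
                             gene_length = NULL, library_fragments = NULL) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("gene%05d", seq_len(nrow(values)))
  cd <- DataFrame(strain = as.character(strain),
                  tissue = as.character(tissue),
                  replicate = as.integer(replicate))
  if (!is.null(library_fragments)) cd$library_fragments <- library_fragments
  rd <- DataFrame(row.names = rownames(values))
  if (!is.null(gene_length)) rd$gene_length <- gene_length
  assays <- setNames(list(values), unit)
  se <- SummarizedExperiment(assays = assays, colData = cd, rowData = rd)
  new("StrainExpression", se)
}

## ---- accessors -----------------------------------------------------------

#' @rdname dosage
#' @export
setMethod("dosage", "GenotypeMatrix", function(x) assay(x, "dosage"))

#' @rdname dosage
#' @export
setMethod("dosage", "SVCohort", function(x) assay(x, "genotype"))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "GenotypeMatrix",
          function(x) setNames(colData(x)$population, colnames(x)))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "SVCohort",
          function(x) setNames(colData(x)$group, colnames(x)))

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "OccupancyMatrix",
          function(x) setNames(colData(x)$group, colnames(x)))

#' @rdname presence
#' @export
setMethod("presence", "OccupancyMatrix", function(x) assay(x, "presence"))

setMethod("show", "GenotypeMatrix", function(object) {
  pops <- table(colData(object)$population)
  cat("GenotypeMatrix:", nrow(object), "SNP sites x", ncol(object),
      "diploid samples\n")
  cat("  chromosomes:",
      paste(unique(as.character(seqnames(rowRanges(object)))), collapse = ", "),
      "\n")
  cat("  populations:",
      paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
})

setMethod("show", "SVCohort", function(object) {
  ty <- table(mcols(rowRanges(object))$svtype)
  cat("SVCohort:", nrow(object), "non-redundant SV sites x", ncol(object),
      "samples\n")
  cat("  types:", paste(sprintf("%s (%d)", names(ty), ty), collapse = ", "),
      "\n")
})

setMethod("show", "OccupancyMatrix", function(object) {
  cat("OccupancyMatrix:", nrow(object), "orthogroups x", ncol(object),
      "genomes\n")
  gr <- table(colData(object)$group)
  cat("  groups:", paste(sprintf("%s (%d)", names(gr), gr), collapse = ", "),
      "\n")
})

setMethod("show", "StrainExpression", function(object) {
  cat("StrainExpression:", nrow(object), "genes x", ncol(object),
      "libraries (", paste(assayNames(object), collapse = "/"), ")\n")
  cat("  strains:", length(unique(colData(object)$strain)),
      " tissues:", length(unique(colData(object)$tissue)), "\n")
})
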