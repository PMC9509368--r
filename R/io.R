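## Standard-format I/O: VCF (SNP and SV dialects) via VariantAnnotation,
## BED and GFF3 via rtracklayer, TSV tables for tracks, occupancy and
## genotype matrices.

.gtToDosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  d[gt %in% c("0/0", "0|0")] <- 0L
  d[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  d[gt %in% c("1/1", "1|1")] <- 2L
  d
}

.dosageToGt <- function(d) {
  gt <- matrix("./.", nrow(d), ncol(d), dimnames = dimnames(d))
  gt[!is.na(d) & d == 0] <- "0/0"
  gt[!is.na(d) & d == 1] <- "0/1"
  gt[!is.na(d) & d == 2] <- "1/1"
  gt
}

.vcfHeader <- function(samples, sv = FALSE) {
  hdr <- VariantAnnotation::VCFHeader(samples = samples)
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    fileformat = DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
  VariantAnnotation::geno(hdr) <- DataFrame(
    Number = "1", Type = "String", Description = "Genotype",
    row.names = "GT")
  if (sv)
    VariantAnnotation::info(hdr) <- DataFrame(
      Number = c("1", "1", "1"),
      Type = c("String", "Integer", "Integer"),
      Description = c("Type of structural variant",
                      "Length of structural variant",
                      "End position of structural variant"),
      row.names = c("SVTYPE", "SVLEN", "END"))
  hdr
}

#' Read a multi-sample SNP VCF into a GenotypeMatrix
#'
#' Honours per-sample GT fields; genotypes other than 0/0, 0/1, 1/1
#' (any phasing) become missing. Multi-allelic records are dropped.
#'
#' @param path VCF file.
#' @param population Named population vector (sample -> label), or a
#'   single label applied to all samples.
#' @return A [GenotypeMatrix].
#' @export
readSNPVcf <- function(path, population) {
  vcf <- VariantAnnotation::readVcf(path)
  alt_n <- lengths(VariantAnnotation::alt(vcf))
  vcf <- vcf[alt_n == 1, ]
  gt <- VariantAnnotation::geno(vcf)$GT
  d <- .gtToDosage(gt)
  gr <- granges(SummarizedExperiment::rowRanges(vcf))
  mcols(gr) <- NULL
  samples <- colnames(gt)
  pop <- if (length(population) == 1 && is.null(names(population)))
    rep(population, length(samples)) else unname(population[samples])
  GenotypeMatrix(d, gr, pop)
}

#' Write a GenotypeMatrix as a SNP VCF
#'
#' @param gm A [GenotypeMatrix].
#' @param path Output path (plain `.vcf`).
#' @return `path`, invisibly.
#' @export
writeSNPVcf <- function(gm, path) {
  d <- dosage(gm)
  rr <- granges(rowRanges(gm))
  names(rr) <- sprintf("snp%06d", seq_along(rr))
  vcf <- VariantAnnotation::VCF(
    rowRanges = rr,
    colData = DataFrame(Samples = seq_len(ncol(d)), row.names = colnames(d)),
    exptData = list(header = .vcfHeader(colnames(d))),
    fixed = DataFrame(REF = Biostrings::DNAStringSet(rep("A", length(rr))),
                      ALT = Biostrings::DNAStringSetList(
                        as.list(rep("T", length(rr)))),
                      QUAL = rep(NA_real_, length(rr)),
                      FILTER = rep("PASS", length(rr))),
    geno = S4Vectors::SimpleList(GT = .dosageToGt(d)))
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

#' Read an SV VCF (SVTYPE/SVLEN/END INFO dialect) into an SVCohort
#'
#' @param path VCF file.
#' @param group Named group vector (sample -> label) or single label.
#' @return An [SVCohort]; DEL/DUP/INV ranges span POS..END, INS are
#'   1-bp points.
#' @export
readSVVcf <- function(path, group = "cohort") {
  vcf <- VariantAnnotation::readVcf(path)
  inf <- VariantAnnotation::info(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  d <- .gtToDosage(gt)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ends <- ifelse(inf$SVTYPE == "INS", start(rr), inf$END)
  gr <- GRanges(seqnames(rr), IRanges(start(rr), ends))
  seqlengths(gr) <- seqlengths(rr)[seqlevels(gr)]
  mcols(gr)$svtype <- inf$SVTYPE
  mcols(gr)$svlen <- abs(inf$SVLEN)
  mcols(gr)$site_id <- rownames(inf)
  samples <- colnames(gt)
  grp <- if (length(group) == 1 && is.null(names(group)))
    rep(group, length(samples)) else unname(group[samples])
  SVCohort(d, gr, grp)
}

#' Write an SVCohort as an SV VCF
#'
#' @param svc An [SVCohort].
#' @param path Output path (plain `.vcf`).
#' @return `path`, invisibly.
#' @export
writeSVVcf <- function(svc, path) {
  d <- dosage(svc)
  rr <- rowRanges(svc)
  m <- mcols(rr)
  pts <- GRanges(seqnames(rr), IRanges(start(rr), width = 1))
  seqlengths(pts) <- seqlengths(rr)[seqlevels(pts)]
  names(pts) <- m$site_id
  vcf <- VariantAnnotation::VCF(
    rowRanges = pts,
    colData = DataFrame(Samples = seq_len(ncol(d)), row.names = colnames(d)),
    exptData = list(header = .vcfHeader(colnames(d), sv = TRUE)),
    fixed = DataFrame(REF = Biostrings::DNAStringSet(rep("N", length(pts))),
                      ALT = IRanges::CharacterList(
                        as.list(paste0("<", m$svtype, ">"))),
                      QUAL = rep(NA_real_, length(pts)),
                      FILTER = rep("PASS", length(pts))),
    info = DataFrame(SVTYPE = m$svtype, SVLEN = as.integer(m$svlen),
                     END = end(rr)),
    geno = S4Vectors::SimpleList(GT = .dosageToGt(d)))
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

#' Write a window track as BED (chrom, start, end, score)
#'
#' BED coordinates are 0-based half-open.
#'
#' @param track `GRanges` track with a `score` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTrackBed <- function(track, path) {
  sc <- mcols(track)$score
  if (is.null(sc)) sc <- rep(".", length(track))
  df <- data.frame(chrom = as.character(seqnames(track)),
                   start = start(track) - 1L, end = end(track),
                   score = sc)
  write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write / read a window track as TSV with a one-line header
#'
#' Columns: chrom, start (0-based), end, score; the statistic name is
#' stored in a `#statistic=` comment line.
#'
#' @param track `GRanges` track.
#' @param path File path.
#' @return `writeTrackTsv`: `path` invisibly; `readTrackTsv`: the track.
#' @export
writeTrackTsv <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  stat <- metadata(track)$statistic
  writeLines(paste0("#statistic=", if (is.null(stat)) "NA" else stat), con)
  df <- data.frame(chrom = as.character(seqnames(track)),
                   start = start(track) - 1L, end = end(track),
                   score = mcols(track)$score)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrackTsv
#' @export
readTrackTsv <- function(path) {
  first <- readLines(path, n = 1)
  stat <- sub("^#statistic=", "", first)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  tr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  mcols(tr)$score <- df$score
  metadata(tr)$statistic <- stat
  tr
}

#' Read gene models from GFF3
#'
#' @param path GFF3 file with `gene`, `exon` and `CDS` features; gene
#'   identity is taken from the `ID` of genes and the `Parent` (through
#'   mRNA if present) of exons/CDS.
#' @return List with `genes`, `exons`, `cds` (`GRanges`, each with a
#'   `gene_id` column).
#' @export
readGeneModels <- function(path) {
  g <- rtracklayer::import(path, format = "gff3")
  genes <- g[g$type == "gene"]
  mcols(genes) <- DataFrame(gene_id = genes$ID)
  ## map mRNA -> gene so exon/CDS Parent resolves to a gene id
  tx <- g[g$type %in% c("mRNA", "transcript")]
  tx2gene <- setNames(as.character(unlist(tx$Parent)), tx$ID)
  resolve <- function(parent) {
    p <- as.character(unlist(parent))
    ifelse(p %in% names(tx2gene), tx2gene[p], p)
  }
  pick <- function(type) {
    f <- g[g$type == type]
    if (!length(f)) {
      out <- GRanges()
      mcols(out)$gene_id <- character()
      return(out)
    }
    mcols(f) <- DataFrame(gene_id = resolve(f$Parent))
    f
  }
  list(genes = genes, exons = pick("exon"), cds = pick("CDS"))
}

#' Read / write an orthogroup occupancy matrix as TSV
#'
#' Rows are orthogroups, columns genomes, entries 0/1; the first column
#' holds orthogroup ids. Group labels travel in a separate manifest
#' (see [readSampleManifest()]).
#'
#' @param path TSV file.
#' @param group Genome group labels (named by genome, or in column
#'   order).
#' @return `readOccupancyTsv`: an [OccupancyMatrix];
#'   `writeOccupancyTsv`: `path` invisibly.
#' @export
readOccupancyTsv <- function(path, group) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  m <- as.matrix(df) > 0
  grp <- if (!is.null(names(group))) unname(group[colnames(m)]) else group
  OccupancyMatrix(m, grp)
}

#' @rdname readOccupancyTsv
#' @param occ An [OccupancyMatrix].
#' @export
writeOccupancyTsv <- function(occ, path) {
  m <- presence(occ) * 1L
  df <- data.frame(orthogroup = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample manifest (sample TAB group)
#'
#' @param path Two-column TSV with header `sample`, `group`.
#' @return Named character vector sample -> group.
#' @export
readSampleManifest <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  setNames(df$group, df$sample)
}

#' Read error-prone regions or TE intervals from BED
#'
#' @param path BED file (0-based half-open).
#' @return `GRanges` (1-based).
#' @export
readBedRegions <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' Write regions as BED
#'
#' @param gr `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBedRegions <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
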