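## Small programmatic fixtures shared across test files.

## Two-gene models on one chromosome: gene g1 [10001, 20000] with exons
## [10001,12000] and [15001,20000] (CDS equal to the exons), gene g2
## [40001, 45000] single-exon, no CDS annotated.
toyGeneModels <- function() {
  genes <- GRanges("chr1", IRanges(c(10001, 40001), c(20000, 45000)),
                   strand = c("+", "-"))
  mcols(genes)$gene_id <- c("g1", "g2")
  exons <- GRanges("chr1", IRanges(c(10001, 15001, 40001),
                                   c(12000, 20000, 45000)),
                   strand = c("+", "+", "-"))
  mcols(exons)$gene_id <- c("g1", "g1", "g2")
  cds <- GRanges("chr1", IRanges(c(10001, 15001), c(12000, 20000)),
                 strand = "+")
  mcols(cds)$gene_id <- c("g1", "g1")
  list(genes = genes, exons = exons, cds = cds)
}

## Write toy gene models as a GFF3 file (gene -> mRNA -> exon/CDS).
writeToyGff3 <- function(path) {
  lines <- c(
    "##gff-version 3",
    "chr1\ttest\tgene\t10001\t20000\t.\t+\t.\tID=g1",
    "chr1\ttest\tmRNA\t10001\t20000\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\ttest\texon\t10001\t12000\t.\t+\t.\tID=g1.e1;Parent=g1.t1",
    "chr1\ttest\texon\t15001\t20000\t.\t+\t.\tID=g1.e2;Parent=g1.t1",
    "chr1\ttest\tCDS\t10001\t12000\t.\t+\t0\tID=g1.c1;Parent=g1.t1",
    "chr1\ttest\tCDS\t15001\t20000\t.\t+\t0\tID=g1.c2;Parent=g1.t1",
    "chr1\ttest\tgene\t40001\t45000\t.\t-\t.\tID=g2",
    "chr1\ttest\tmRNA\t40001\t45000\t.\t-\t.\tID=g2.t1;Parent=g2",
    "chr1\ttest\texon\t40001\t45000\t.\t-\t.\tID=g2.e1;Parent=g2.t1")
  writeLines(lines, path)
  path
}

## A deterministic little SVCohort: n sites, m samples, given seed.
toySVCohort <- function(n_sites = 50, n_samples = 8, seed = 42,
                        groups = NULL) {
  set.seed(seed)
  gt <- matrix(rbinom(n_sites * n_samples, 2, 0.25), n_sites,
               dimnames = list(NULL, sprintf("s%02d", seq_len(n_samples))))
  pos <- sort(sample.int(1e6, n_sites))
  type <- sample(c("INS", "DEL"), n_sites, replace = TRUE)
  len <- sample(50:5000, n_sites, replace = TRUE)
  gr <- GRanges("chr1", IRanges(pos, ifelse(type == "INS", pos,
                                            pos + len - 1)))
  mcols(gr)$svtype <- type
  mcols(gr)$svlen <- len
  if (is.null(groups)) groups <- rep(c("a", "b"), length.out = n_samples)
  SVCohort(gt, gr, groups)
}

## Brute-force interval overlap (1-based closed coordinates).
overlaps1 <- function(s1, e1, s2, e2) s1 <= e2 && s2 <= e1
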