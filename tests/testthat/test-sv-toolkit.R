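test_that("SV merging clusters by distance, size ratio and type", {
  calls <- data.frame(
    sample = c("s1", "s2", "s1", "s2"),
    chrom = "chr1",
    pos = c(1000, 1200, 5000, 1000),
    end = c(1499, 1679, 5499, 1000),
    type = c("DEL", "DEL", "DEL", "INS"),
    svlen = c(500, 480, 500, 300),
    gt = c(1, 2, 1, 1))
  svc <- mergeSVs(calls)
  expect_equal(nrow(svc), 3L)
  m <- mcols(rowRanges(svc))
  expect_equal(m$support[m$svtype == "DEL" & start(rowRanges(svc)) < 2000], 2L)
  ## identical DEL in two samples -> one site, support 2
  dup <- data.frame(sample = c("x", "y"), chrom = "chr1", pos = 100,
                    end = 599, type = "DEL", svlen = 500, gt = 1)
  expect_equal(nrow(mergeSVs(dup)), 1L)
  ## size ratio below 0.7 blocks the link
  far <- data.frame(sample = c("x", "y"), chrom = "chr1", pos = c(100, 150),
                    end = c(599, 249), type = "DEL", svlen = c(500, 100),
                    gt = 1)
  expect_equal(nrow(mergeSVs(far)), 2L)
})

test_that("SV merging is idempotent and input-order invariant", {
  set.seed(19)
  ## well separated clusters (gaps > max_dist)
  centers <- seq(1e4, 2e5, by = 5e3)
  calls <- do.call(rbind, lapply(seq_along(centers), function(i) {
    k <- sample(1:4, 1)
    data.frame(sample = sprintf("s%02d", sample(10, k)),
               chrom = "chr1",
               pos = centers[i] + sample(0:400, k, replace = TRUE),
               end = centers[i] + 999, type = "DEL",
               svlen = sample(900:1000, k, replace = TRUE), gt = 1)
  }))
  svc <- mergeSVs(calls, samples = sprintf("s%02d", 1:10))
  expect_equal(nrow(svc), length(centers))
  ## shuffle input rows: same representatives
  svc2 <- mergeSVs(calls[sample(nrow(calls)), ],
                   samples = sprintf("s%02d", 1:10))
  expect_equal(start(rowRanges(svc)), start(rowRanges(svc2)))
  expect_identical(dosage(svc), dosage(svc2))
  ## idempotence: re-merging the representatives changes nothing
  m <- mcols(rowRanges(svc))
  reps <- data.frame(sample = "rep", chrom = "chr1",
                     pos = start(rowRanges(svc)), end = end(rowRanges(svc)),
                     type = m$svtype, svlen = m$svlen, gt = 1)
  expect_equal(nrow(mergeSVs(reps)), nrow(svc))
})

test_that("SV filtering removes size, genotype and error-region failures", {
  gt <- matrix(c(1L, 1L, 0L, 0L, 1L, 0L, 0L, 1L), nrow = 4, byrow = TRUE,
               dimnames = list(NULL, c("s1", "s2")))
  gr <- GRanges("chr1", IRanges(c(1000, 20000, 50000, 80000),
                                width = c(150000, 500, 300, 200)))
  mcols(gr)$svtype <- "DEL"
  mcols(gr)$svlen <- c(150000, 500, 300, 200)
  x <- SVCohort(gt, gr, group = c("a", "b"))
  err <- GRanges("chr1", IRanges(48000, 48500))  # 50000 within 2.5 kb flank
  fl <- filterSVs(x, err)
  expect_equal(unname(fl$tally), c(1L, 1L, 1L, 1L))
  expect_equal(nrow(fl$kept), 1L)
  expect_equal(sum(fl$tally), nrow(x))
  ## empty region set: only size/genotype
  fl2 <- filterSVs(x)
  expect_equal(unname(fl2$tally[c("size", "genotype", "region")]),
               c(1L, 1L, 0L))
  ## exactly max_len is kept ("larger than" is strict)
  gr3 <- GRanges("chr1", IRanges(1, width = 1e5))
  mcols(gr3)$svtype <- "DEL"; mcols(gr3)$svlen <- 1e5
  x3 <- SVCohort(matrix(1L, 1, 1), gr3, "a")
  expect_equal(nrow(filterSVs(x3)$kept), 1L)
})

test_that("allele frequencies and the rare fraction count alleles correctly", {
  gt <- matrix(0L, 2, 10)
  gt[1, 1:3] <- 1L          # 3 heterozygous carriers of 10 diploids
  gt[2, ] <- 2L
  gr <- GRanges("chr1", IRanges(c(100, 200), width = 1))
  mcols(gr)$svtype <- "INS"; mcols(gr)$svlen <- c(60, 70)
  x <- SVCohort(gt, gr, group = rep("g", 10))
  af <- svAlleleFrequency(x, "cohort")[, 1]
  expect_equal(unname(af), c(0.15, 1))
  ## rare fraction from a constructed 40% fixture
  af2 <- c(runif(40, 0.001, 0.049), runif(60, 0.05, 0.9))
  expect_equal(rareFraction(af2), 0.4)
  expect_error(rareFraction(NA_real_), "non-missing")
})

test_that("divergence scan has power on shifted sites and clean null behaviour", {
  sim <- simulateSVCohort(n_sites = 5000, n_shifted = 100, seed = 1)
  res <- svDivergenceScan(sim$cohort, "wild", "local")
  hits <- res$site_id[res$significant]
  recall <- mean(sim$truth$shifted %in% hits)
  expect_gte(recall, 0.9)
  expect_lte(sum(!(hits %in% sim$truth$shifted)), 0.05 * length(hits))
  ## identical carrier frequencies -> nothing significant
  gt <- matrix(rep(c(1L, 0L), each = 4), 1)
  gr <- GRanges("chr1", IRanges(1000, width = 1))
  mcols(gr)$svtype <- "INS"; mcols(gr)$svlen <- 60
  x <- SVCohort(rbind(rep(c(1L, 0L), 4)), gr, rep(c("a", "b"), 4))
  expect_equal(sum(svDivergenceScan(x, "a", "b")$significant), 0L)
})

test_that("null SV cohorts yield essentially no significant sites", {
  total <- 0
  for (seed in 1:10) {
    sim <- simulateSVCohort(n_sites = 1000, n_shifted = 0, seed = seed)
    res <- svDivergenceScan(sim$cohort, "wild", "local")
    total <- total + sum(res$significant)
  }
  expect_lte(total, 1)
})

test_that("SV context annotation respects CDS > regulatory > intergenic", {
  models <- toyGeneModels()
  sv <- GRanges("chr1", IRanges(c(13000, 7000, 26000, 11000), width = 1))
  an <- annotateSVContext(sv, models)
  expect_equal(an$category,
               c("regulatory", "regulatory", "intergenic", "cds"))
  ## an SV spanning CDS of g1 and flank of g2 is category cds, genes both
  sv2 <- GRanges("chr1", IRanges(19000, 42000))
  an2 <- annotateSVContext(sv2, models)
  expect_equal(an2$category, "cds")
  expect_true(grepl("g1", an2$genes) && grepl("g2", an2$genes))
  ## no annotation -> intergenic
  empty <- list(genes = GRanges(gene_id = character()),
                exons = GRanges(gene_id = character()),
                cds = GRanges(gene_id = character()))
  expect_equal(annotateSVContext(sv, empty)$category, rep("intergenic", 4))
})

test_that("randomised context fixtures agree with a brute-force interval oracle", {
  set.seed(71)
  for (rep in 1:40) {
    gs <- sort(sample(seq(1e4, 3e5, by = 1e3), 3))
    genes <- GRanges("chr1", IRanges(gs, gs + 9999), strand = "+")
    mcols(genes)$gene_id <- paste0("g", 1:3)
    ## one exon at each end, intron between
    exons <- GRanges("chr1", IRanges(c(gs, gs + 7000), c(gs + 2999, gs + 9999)),
                     strand = "+")
    mcols(exons)$gene_id <- rep(paste0("g", 1:3), 2)
    cds <- exons[1:3]
    mcols(cds)$gene_id <- paste0("g", 1:3)
    models <- list(genes = genes, exons = exons, cds = cds)
    svp <- sample.int(3.2e5, 25)
    an <- annotateSVContext(GRanges("chr1", IRanges(svp, width = 1)), models)
    for (i in seq_along(svp)) {
      p <- svp[i]
      in_cds <- any(vapply(seq_along(cds), function(j)
        overlaps1(p, p, start(cds)[j], end(cds)[j]), TRUE))
      in_intron <- any(vapply(1:3, function(j)
        p >= gs[j] + 3000 && p <= gs[j] + 6999, TRUE))
      in_flank <- any(vapply(1:3, function(j)
        (p >= gs[j] - 5000 && p < gs[j]) ||
          (p > gs[j] + 9999 && p <= gs[j] + 9999 + 5000), TRUE))
      expected <- if (in_cds) "cds" else
        if (in_intron || in_flank) "regulatory" else "intergenic"
      expect_equal(an$category[i], expected)
    }
  }
})

test_that("multi-allelic loci are single-linkage clusters of nearby nrSVs", {
  ## isolated SVs -> no multi-allelic loci
  iso <- GRanges("chr1", IRanges(seq(1e4, 5e4, by = 1e4), width = 1))
  expect_equal(multiallelicSummary(iso)$multi_fraction, 0)
  ## three co-located insertions -> one locus with three alleles
  tri <- GRanges("chr1", IRanges(c(100, 150, 180), width = 1))
  ms <- multiallelicSummary(tri)
  expect_equal(ms$n_loci, 1L)
  expect_equal(ms$max, 3L)
  ## 20-SV fixture vs brute-force single linkage
  set.seed(5)
  pos <- sort(sample.int(2e4, 20))
  gr <- GRanges("chr1", IRanges(pos, width = 1))
  got <- multiallelicSummary(gr, max_dist = 500)
  ## brute force: link consecutive positions with gap <= 500
  cl <- cumsum(c(1, diff(pos) > 501))
  expect_equal(got$n_loci, length(unique(cl)))
  sizes_got <- rep(as.integer(names(got$histogram)),
                   as.integer(got$histogram))
  expect_equal(sort(sizes_got), sort(as.integer(table(cl))))
})

test_that("SV and TE counts correlate per uninterrupted window", {
  set.seed(9)
  ## TE-rich regions attract SVs: construct proportional counts
  win_te <- rpois(20, 30)
  te <- GRanges("chr1", IRanges(unlist(lapply(1:20, function(i)
    sample((i - 1) * 5e5 + seq(1, 5e5 - 200), win_te[i]))), width = 100))
  sv <- GRanges("chr1", IRanges(unlist(lapply(1:20, function(i)
    sample((i - 1) * 5e5 + seq(1, 5e5), win_te[i] * 2))), width = 1))
  res <- svTeWindowCorrelation(sv, te, c(chr1 = 1e7))
  expect_equal(res$te_count, win_te)
  expect_equal(res$sv_count, win_te * 2)
  expect_equal(res$r, 1, tolerance = 1e-12)
  ## hand-computed correlation on fixed vectors
  res2 <- pearsonLinear(c(1, 2, 3, 5), c(2, 2, 4, 7))
  expect_equal(res2$r, oraclePearson(c(1, 2, 3, 5), c(2, 2, 4, 7))$r,
               tolerance = 1e-12)
  ## empty TE set: constant zeros are undefined
  expect_error(svTeWindowCorrelation(sv, GRanges(), c(chr1 = 1e7)),
               "constant")
})

test_that("pan-SV accumulation mirrors the occupancy machinery", {
  svc <- toySVCohort(n_sites = 60, n_samples = 6, seed = 2)
  pres <- !is.na(dosage(svc)) & dosage(svc) >= 1
  pres <- pres[rowSums(pres) > 0, ]
  cv <- panSVAccumulation(svc, n_orders = 20, seed = 3)
  expect_equal(cv$pan[6], nrow(pres))
  expect_equal(cv$core[6], sum(rowSums(pres) == 6))
  cv1 <- panSVAccumulation(svc, order = 1:6)
  expect_equal(cv1$pan[1], sum(pres[, 1]))
})

test_that("group-specific SVs obey strict presence, absence and rarity", {
  gt <- rbind(c(1L, 1L, 0L, 0L, rep(0L, 36)),
              c(1L, 1L, 1L, 0L, rep(0L, 36)),
              c(1L, 1L, 0L, 0L, rep(1L, 36)))
  colnames(gt) <- sprintf("s%02d", 1:40)
  gr <- GRanges("chr1", IRanges(c(100, 200, 300), width = 1))
  mcols(gr)$svtype <- "INS"; mcols(gr)$svlen <- 60
  x <- SVCohort(gt, gr, rep("g", 40))
  got <- groupSpecificSVs(x, c("s01", "s02"), c("s03", "s04"))
  ## site 1: carried by both targets, absent in contrasts, AF = 2/80 < 0.05
  expect_equal(start(got), 100L)
  ## site 2 excluded (carried by a contrast), site 3 excluded (AF = 38/80)
  expect_error(groupSpecificSVs(x, c("s01",  "s02"), c("s02", "s03")),
               "disjoint")
})
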