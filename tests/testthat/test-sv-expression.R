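test_that("FPKM is the standard per-kilobase per-million normalisation", {
  expect_equal(computeFPKM(100, 1000, 1e6), 100)
  expect_equal(computeFPKM(0, 1000, 1e6), 0)
  expect_equal(computeFPKM(250, 2000, 5e6), 25)
  ## linear in counts, inversely linear in length and library size
  expect_equal(computeFPKM(200, 1000, 1e6), 2 * computeFPKM(100, 1000, 1e6))
  expect_equal(computeFPKM(100, 2000, 1e6), computeFPKM(100, 1000, 1e6) / 2)
  expect_equal(computeFPKM(100, 1000, 2e6), computeFPKM(100, 1000, 1e6) / 2)
  expect_error(computeFPKM(10, 0, 1e6), "positive")
})

## A deterministic SV cohort + gene models with one SV per gene intron.
pairFixture <- function(n_pairs = 10, n_strains = 14, carriers_per = 7,
                        seed = 1) {
  set.seed(seed)
  strains <- sprintf("st%02d", seq_len(n_strains))
  gs <- seq(1e5, by = 5e4, length.out = n_pairs)
  genes <- GRanges("chr1", IRanges(gs, gs + 19999), strand = "+")
  mcols(genes)$gene_id <- paste0("g", seq_len(n_pairs))
  exons <- GRanges("chr1", IRanges(c(gs, gs + 15000), c(gs + 4999, gs + 19999)),
                   strand = "+")
  mcols(exons)$gene_id <- rep(paste0("g", seq_len(n_pairs)), 2)
  models <- list(genes = genes, exons = exons, cds = GRanges())
  gt <- matrix(0L, n_pairs, n_strains, dimnames = list(NULL, strains))
  for (i in seq_len(n_pairs))
    gt[i, sample(n_strains, carriers_per)] <- 1L
  gr <- GRanges("chr1", IRanges(gs + 10000, width = 1))   # intron midpoint
  mcols(gr)$svtype <- "INS"; mcols(gr)$svlen <- 300
  svc <- SVCohort(gt, gr, rep("strain", n_strains))
  list(svc = svc, models = models, strains = strains)
}

test_that("pair construction enforces the distance and 3-vs-3 rules", {
  fx <- pairFixture()
  pairs <- buildSVGenePairs(fx$svc, fx$models, fx$strains)
  expect_equal(nrow(pairs), 10L)
  expect_true(all(pairs$relation == "intron"))
  expect_true(all(pairs$n_present >= 3 & pairs$n_absent >= 3))
  ## SV carried by every strain: dropped
  fx2 <- pairFixture(n_pairs = 2, carriers_per = 14)
  expect_equal(nrow(buildSVGenePairs(fx2$svc, fx2$models, fx2$strains)), 0L)
  ## SV 6 kb away from the gene and outside introns: no pair
  models <- toyGeneModels()
  gr <- GRanges("chr1", IRanges(26000, width = 1))   # 6 kb past g1 end
  mcols(gr)$svtype <- "INS"; mcols(gr)$svlen <- 100
  svc <- SVCohort(matrix(c(rep(1L, 7), rep(0L, 7)), 1), gr,
                  rep("s", 14))
  colnames(svc) <- sprintf("st%02d", 1:14)
  expect_equal(nrow(buildSVGenePairs(svc, models, colnames(svc))), 0L)
})

test_that("carrier effects are detected and null panels stay clean", {
  fx <- pairFixture(n_pairs = 10, seed = 3)
  pairs <- buildSVGenePairs(fx$svc, fx$models, fx$strains)
  sim <- simulateExpression(pairs, strains = fx$strains, delta = 1,
                            sigma = 0.1, seed = 11)
  res <- pairDifferentialExpression(pairs, sim$expression)
  expect_true(all(res$pairs$significant))
  expect_equal(attr(res$pairs, "n_genes"), 10L)
  carr1 <- strsplit(pairs$carriers[1], ",")[[1]]
  t1 <- res$tests[res$tests$gene_id == pairs$gene_id[1], ]
  expect_true(all(t1$direction == "up_in_carriers"))
  ## null panel
  sim0 <- simulateExpression(pairs, strains = fx$strains, delta = 0,
                             sigma = 0.1, seed = 12)
  res0 <- pairDifferentialExpression(pairs, sim0$expression)
  expect_equal(sum(res0$pairs$significant), 0L)
  ## significance is invariant to strain labelling order
  perm <- sample(ncol(sim$expression))
  expr_perm <- sim$expression[, perm]
  res_perm <- pairDifferentialExpression(pairs, expr_perm)
  expect_equal(res_perm$pairs$significant[order(res_perm$pairs$site_id)],
               res$pairs$significant[order(res$pairs$site_id)])
})

test_that("effect detection succeeds across repeated seeds", {
  ok <- 0
  for (seed in 1:10) {
    fx <- pairFixture(n_pairs = 4, seed = seed)
    pairs <- buildSVGenePairs(fx$svc, fx$models, fx$strains)
    sim <- simulateExpression(pairs, strains = fx$strains, delta = 1,
                              sigma = 0.1, seed = 100 + seed)
    res <- pairDifferentialExpression(pairs, sim$expression)
    if (all(res$pairs$significant)) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("noise-free unit effect doubles carrier FPKM exactly", {
  fx <- pairFixture(n_pairs = 3, seed = 8)
  pairs <- buildSVGenePairs(fx$svc, fx$models, fx$strains)
  sim <- simulateExpression(pairs, strains = fx$strains, delta = 1,
                            sigma = 0, seed = 1)
  fp <- SummarizedExperiment::assay(sim$expression, "fpkm")
  cd <- SummarizedExperiment::colData(sim$expression)
  g <- pairs$gene_id[1]
  carr <- strsplit(pairs$carriers[1], ",")[[1]]
  v_carr <- fp[g, cd$strain %in% carr]
  v_non <- fp[g, !cd$strain %in% carr]
  expect_equal(unique(round(v_carr / unique(v_non), 10)), 2)
})
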