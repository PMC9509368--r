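test_that("sliding windows follow the size/step/truncation policy", {
  w <- scanWindows(c(chr1 = 5000))
  expect_length(w, 1)
  expect_equal(c(start(w), end(w)), c(1, 5000))
  ## 5 full windows exactly cover L = 7000
  w <- scanWindows(c(chr1 = 7000))
  expect_length(w, 5)
  expect_equal(start(w), seq(1, 2001, 500))
  expect_true(all(width(w) == 5000))
  ## chromosome shorter than a window: one truncated window
  w <- scanWindows(c(chr1 = 400))
  expect_length(w, 1)
  expect_equal(width(w), 400)
  ## a single trailing truncated window when needed
  w <- scanWindows(c(chr1 = 7200))
  expect_length(w, 6)
  expect_equal(end(w)[6], 7200)
  expect_equal(sum(width(w) != 5000), 1)
  expect_error(scanWindows(c(chr1 = 1000), size = 0), "positive")
  expect_error(scanWindows(c(chr1 = 1000), size = 100, step = 200), "step")
})

test_that("pi equals the pairwise-difference oracle", {
  ## monomorphic window
  expect_equal(windowPi(matrix(0L, 5, 4)), 0)
  ## two haplotypes (one diploid... use two haploid-like samples):
  ## 2 diploids sharing fixed opposite homozygotes at k sites -> check
  ## against the expansion oracle instead of a closed form
  set.seed(33)
  for (i in 1:200) {
    g <- randomDosage(sample(1:20, 1), sample(2:5, 1))
    expect_equal(windowPi(g), oraclePi(g), tolerance = 1e-10)
  }
})

test_that("Tajima's D matches the independent formula oracle", {
  expect_true(is.na(windowTajimaD(matrix(0L, 4, 5))))     # S = 0
  expect_true(is.na(windowTajimaD(matrix(1L, 1, 1))))       # n = 2
  k <- tajimaConstants(2)
  expect_equal(k$e1, 0, tolerance = 1e-12)
  expect_equal(k$e2, 0, tolerance = 1e-12)
  set.seed(44)
  for (i in 1:200) {
    g <- randomDosage(sample(2:20, 1), sample(2:5, 1))
    expect_equal(windowTajimaD(g), oracleTajimaD(g), tolerance = 1e-10)
  }
})

test_that("Hudson window FST matches the per-site oracle and is at most 1", {
  ## fixed difference
  expect_equal(windowFst(matrix(2L, 3, 40), matrix(0L, 3, 40)), 1)
  ## both monomorphic -> missing
  expect_true(is.na(windowFst(matrix(2L, 2, 5), matrix(2L, 2, 5))))
  ## hand-built two-site toy (n1 = n2 = 10 alleles)
  g1 <- rbind(c(2L, 2L, 2L, 1L, 1L), c(1L, 1L, 1L, 0L, 0L)) # p1 = 0.8, 0.3
  g2 <- rbind(c(1L, 1L, 0L, 0L, 0L), c(2L, 1L, 0L, 0L, 0L)) # p2 = 0.2, 0.3
  expect_equal(windowFst(g1, g2), oracleHudsonFst(g1, g2), tolerance = 1e-12)
  set.seed(55)
  for (i in 1:200) {
    ns <- sample(1:15, 1)
    g1 <- randomDosage(ns, sample(3:8, 1))
    g2 <- randomDosage(ns, sample(3:8, 1))
    f <- windowFst(g1, g2)
    o <- oracleHudsonFst(g1, g2)
    if (is.na(o)) expect_true(is.na(f)) else {
      expect_equal(f, o, tolerance = 1e-10)
      expect_lte(f, 1)
    }
  }
})

test_that("Hudson and Weir-Cockerham agree on balanced simulated data", {
  sim <- simulateSNPCohort(c(chr1 = 1e5), c(p1 = 40, p2 = 40), F_st = 0.1,
                           n_sites = 5000, seed = 5)
  g1 <- dosage(sim$genotypes)[, 1:40]
  g2 <- dosage(sim$genotypes)[, 41:80]
  fh <- windowFst(g1, g2, "hudson")
  fw <- windowFst(g1, g2, "weir_cockerham")
  expect_lt(abs(fh - fw), 0.02)
})

test_that("track scans aggregate per-site statistics over the window grid", {
  sim <- simulateSNPCohort(c(chr1 = 3e4), c(wild = 10, local = 10),
                           n_sites = 400, seed = 8)
  gm <- sim$genotypes
  w <- scanWindows(c(chr1 = 3e4))
  tr <- scanPi(gm, w, "wild")
  expect_length(tr, length(w))
  expect_identical(S4Vectors::metadata(tr)$statistic, "pi")
  ## spot-check three windows against the single-window kernels
  pos <- start(rowRanges(gm))
  g <- dosage(gm)[, 1:10]
  for (i in c(1, 10, length(w))) {
    sites <- which(pos >= start(w)[i] & pos <= end(w)[i])
    expected <- if (length(sites) >= 3)
      windowPi(g[sites, , drop = FALSE]) else NA_real_
    expect_equal(mcols(tr)$score[i], expected, tolerance = 1e-12)
  }
  trd <- scanTajimaD(gm, w, "wild")
  for (i in c(2, 20)) {
    sites <- which(pos >= start(w)[i] & pos <= end(w)[i])
    expected <- if (length(sites) >= 3)
      windowTajimaD(g[sites, , drop = FALSE]) else NA_real_
    expect_equal(mcols(trd)$score[i], expected, tolerance = 1e-12)
  }
  trf <- scanFst(gm, w, "wild", "local")
  g2 <- dosage(gm)[, 11:20]
  for (i in c(5, 15)) {
    sites <- which(pos >= start(w)[i] & pos <= end(w)[i])
    if (length(sites) < 3) next
    expect_equal(mcols(trf)$score[i],
                 windowFst(g[sites, , drop = FALSE], g2[sites, , drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("windows carrying an injected sweep show depressed Tajima's D", {
  lower <- 0
  for (seed in 1:10) {
    sim <- simulateSNPCohort(
      c(chr1 = 1e5, chr2 = 1e5), c(wild = 20, local = 20), F_st = 0.1,
      n_sites = 1600,
      sweeps = data.frame(chrom = "chr1", pos = 5e4, s = 0.1, pop = "local"),
      seed = seed)
    w <- scanWindows(c(chr1 = 1e5, chr2 = 1e5))
    d <- scanTajimaD(sim$genotypes, w, "local")
    near <- as.character(seqnames(w)) == "chr1" &
      abs((start(w) + end(w)) / 2 - 5e4) < 10000
    far <- as.character(seqnames(w)) == "chr2"
    m_near <- mean(mcols(d)$score[near], na.rm = TRUE)
    m_far <- mean(mcols(d)$score[far], na.rm = TRUE)
    if (m_near < m_far) lower <- lower + 1
  }
  expect_gte(lower, 9)
})
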