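mkTrack <- function(scores, stat = "fst", chrlen = NULL) {
  n <- length(scores)
  if (is.null(chrlen)) chrlen <- 500 * (n - 1) + 5000
  w <- scanWindows(c(chr1 = chrlen))[seq_len(n)]
  mcols(w)$score <- scores
  S4Vectors::metadata(w)$statistic <- stat
  w
}

test_that("quantile selection uses linear interpolation and includes ties", {
  tr <- mkTrack(as.numeric(1:100))
  sel <- selectQuantile(tr, 0.99, "upper")
  ## threshold = quantile(1:100, 0.99) = 99.01 -> only window 100
  expect_equal(which(sel), 100L)
  sel5 <- selectQuantile(tr, 0.5, "upper")
  expect_equal(which(sel5), which(1:100 >= quantile(1:100, 0.5)))
  ## constant track: everything ties the threshold
  trc <- mkTrack(rep(3.3, 20))
  expect_true(all(selectQuantile(trc, 0.99, "upper")))
  expect_true(all(selectQuantile(trc, 0.05, "lower")))
  ## lower tail on a strictly increasing track
  sel_lo <- selectQuantile(tr, 0.05, "lower")
  expect_equal(which(sel_lo), which(1:100 <= quantile(1:100, 0.05)))
  ## missing scores never selected
  trm <- mkTrack(c(NA, 1:9))
  expect_false(selectQuantile(trm, 0.5, "upper")[1])
  expect_error(selectQuantile(mkTrack(c(NA_real_, NA_real_)), 0.5),
               "non-missing")
})

test_that("sweep calling is the brute-force four-condition intersection", {
  set.seed(17)
  n <- 200
  fst <- mkTrack(runif(n), "fst")
  xp <- mkTrack(runif(n), "xpclr")
  dd <- mkTrack(rnorm(n), "tajimas_d")
  da <- mkTrack(rnorm(n), "tajimas_d")
  cfg <- sweepCallConfig(q_fst = 0.8, q_xpclr = 0.7, q_tajd = 0.3)
  got <- callSweeps(fst, xp, dd, da, cfg)
  ## brute force mask
  s_f <- mcols(fst)$score; s_x <- mcols(xp)$score
  s_d <- mcols(dd)$score; s_a <- mcols(da)$score
  mask <- s_f >= quantile(s_f, 0.8) & s_x >= quantile(s_x, 0.7) &
    s_d <= quantile(s_d, 0.3) & s_d < s_a
  expected <- reduce(granges(fst)[mask])
  expect_equal(granges(got), expected)
  ## windows in regions all passed; region summaries match members
  if (length(got)) {
    hit <- findOverlaps(fst[mask], got)
    expect_equal(sum(mcols(got)$n_windows), sum(mask))
    expect_equal(max(mcols(got)$max_fst), max(s_f[mask]))
  }
  ## fourth condition excludes D_desc >= D_anc windows
  dd2 <- da
  got2 <- callSweeps(fst, xp, dd2, da, cfg)
  expect_length(got2, 0)
  ## disjoint top sets -> empty
  a <- mkTrack(c(rep(1, 100), rep(0, 100)))
  b <- mkTrack(c(rep(0, 100), rep(1, 100)))
  expect_length(callSweeps(a, b, dd, da, cfg), 0)
  ## mismatched grids error
  expect_error(callSweeps(fst[1:100], xp, dd, da, cfg), "grid")
})

test_that("loosening quantiles never removes regions, tightening never adds", {
  set.seed(23)
  n <- 300
  fst <- mkTrack(runif(n)); xp <- mkTrack(runif(n))
  dd <- mkTrack(rnorm(n)); da <- mkTrack(rnorm(n) + 0.5)
  base <- callSweeps(fst, xp, dd, da,
                     sweepCallConfig(0.9, 0.8, 0.2))
  loose <- callSweeps(fst, xp, dd, da,
                      sweepCallConfig(0.8, 0.7, 0.3))
  tight <- callSweeps(fst, xp, dd, da,
                      sweepCallConfig(0.95, 0.9, 0.1))
  expect_true(all(overlapsAny(base, loose)))
  expect_true(all(overlapsAny(tight, base)))
})

test_that("genes are assigned by >= 1 bp overlap with half-open windows respected", {
  regions <- GRanges("chr1", IRanges(c(1000, 9000), c(2000, 9500)))
  genes <- GRanges("chr1", IRanges(c(1200, 2001, 500, 9400, 20000),
                                   c(1300, 2100, 999, 9600, 21000)))
  mcols(genes)$gene_id <- paste0("g", 1:5)
  got <- regionsToGenes(regions, genes)
  expect_setequal(got$per_region[[1]], c("g1"))
  expect_setequal(got$per_region[[2]], c("g4"))
  expect_setequal(got$genes, c("g1", "g4"))
  ## brute force on random fixtures
  set.seed(31)
  for (i in 1:50) {
    rs <- sort(sample.int(1e5, 4))
    regions <- GRanges("chr1", IRanges(rs[c(1, 3)], rs[c(2, 4)]))
    gs <- sort(sample.int(1e5, 10))
    genes <- GRanges("chr1", IRanges(gs, gs + sample.int(5000, 10)))
    mcols(genes)$gene_id <- paste0("g", 1:10)
    got <- regionsToGenes(regions, genes)
    for (r in 1:2) {
      exp_ids <- sprintf("g%d", which(vapply(seq_len(10), function(j)
        overlaps1(start(regions)[r], end(regions)[r],
                  start(genes)[j], end(genes)[j]), TRUE)))
      expect_setequal(got$per_region[[r]], exp_ids)
    }
  }
})
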