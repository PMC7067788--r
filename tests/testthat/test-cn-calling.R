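cfg <- CallingConfig()

test_that("gain/loss thresholds are strict and sub-threshold segments drop", {
  seg <- mkSegments(list("1", 1, 10000000, 0.30),
                    list("2", 1, 10000000, 0.10),
                    list("3", 1, 10000000, -0.30),
                    list("4", 1, 10000000, 0.15),
                    list("5", 1, 10000000, -0.15))
  calls <- callCnas(seg, cfg)
  expect_equal(as.character(seqnames(calls)), c("1", "3"))
  expect_equal(mcols(calls)$direction, c("gain", "loss"))
})

test_that("the 1 Mb noise filter removes short calls (non-strict keep at 1 Mb)", {
  seg <- mkSegments(list("1", 1, 800000, 0.8),        # 0.8 Mb: filtered
                    list("2", 1, 1000000, 0.8),       # exactly 1 Mb: kept
                    list("3", 1, 10000000, 0.8))
  calls <- callCnas(seg, cfg)
  expect_equal(as.character(seqnames(calls)), c("2", "3"))
})

test_that("adjacent same-direction calls merge across small gaps with weighted log2", {
  seg <- mkSegments(list("1", 1, 10000000, 0.4),
                    list("1", 10000001, 10050000, 0.0),   # 1-bin neutral gap
                    list("1", 10050001, 20000000, 0.2))
  calls <- callCnas(seg, cfg)
  expect_length(calls, 1)
  expect_equal(start(calls), 1)
  expect_equal(end(calls), 20000000)
  w1 <- 10000000; w2 <- 20000000 - 10050000
  expect_equal(mcols(calls)$mean_log2, (0.4 * w1 + 0.2 * w2) / (w1 + w2))

  # a gap wider than mergeGap keeps the calls apart
  seg2 <- mkSegments(list("1", 1, 10000000, 0.4),
                     list("1", 10000001, 10150000, 0.0),
                     list("1", 10150001, 20000000, 0.2))
  expect_length(callCnas(seg2, cfg), 2)

  # opposite directions never merge
  seg3 <- mkSegments(list("1", 1, 10000000, 0.4),
                     list("1", 10000001, 20000000, -0.4))
  expect_length(callCnas(seg3, cfg), 2)
})

test_that("calling is idempotent on its own output", {
  seg <- mkSegments(list("1", 1, 10000000, 0.4),
                    list("1", 10050001, 20000000, 0.2),
                    list("7", 1, 30000000, -0.5))
  once <- callCnas(seg, cfg)
  twice <- callCnas(once, cfg)
  expect_equal(as.data.frame(once), as.data.frame(twice))
})

test_that("calls are contained in same-direction input segments (no-merge config)", {
  cfg0 <- CallingConfig(mergeGap = 0)
  set.seed(42)
  for (rep in 1:20) {
    segs <- randomCallSet(5)
    if (!length(segs)) next
    mcols(segs)$log2 <- mcols(segs)$mean_log2
    calls <- callCnas(segs, cfg0)
    for (d in c("gain", "loss")) {
      src <- segs[mcols(segs)$direction == d]
      out <- calls[mcols(calls)$direction == d]
      if (!length(out)) next
      cov <- reduce(src)
      expect_true(all(overlapsAny(out, cov, type = "within")))
    }
  }
})

test_that("lowering the gain threshold never loses gain calls", {
  set.seed(7)
  for (rep in 1:15) {
    n <- sample(1:6, 1)
    rows <- lapply(seq_len(n), function(i) {
      s <- sample(seq(1e6, 5e7, by = 1e6), 1)   # one segment per chromosome
      list(as.character(i), s, s + sample(seq(2e6, 1e7, by = 1e6), 1),
           runif(1, -0.1, 0.6))
    })
    segs <- do.call(mkSegments, rows)
    nGain <- function(th) {
      calls <- callCnas(segs, CallingConfig(gainThreshold = th))
      sum(mcols(calls)$direction == "gain")
    }
    counts <- vapply(c(0.40, 0.25, 0.15, 0.05), nGain, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("only calls strictly longer than 5 Mb are reportable", {
  calls <- mkCalls(list("1", 1, 2000000, "gain"),
                   list("2", 1, 8000000, "gain"),
                   list("3", 1, 5000000, "loss"))   # exactly 5 Mb: excluded
  rep <- reportableCnas(calls, cfg)
  expect_equal(as.character(seqnames(rep)), "2")
  expect_length(reportableCnas(mkCalls(), cfg), 0)
})

test_that("event counts fall into the expected bins", {
  mk <- function(n) {
    if (n == 0) return(mkCalls())
    do.call(mkCalls, lapply(seq_len(n), function(i)
      list(as.character(i), 1, 10000000, "gain")))
  }
  expect_equal(countCnEvents(mk(0))$bin, "0")
  expect_equal(countCnEvents(mk(1))$bin, "1")
  expect_equal(countCnEvents(mk(2))$bin, "2")
  expect_equal(countCnEvents(mk(3))$bin, "3-4")
  expect_equal(countCnEvents(mk(4))$bin, "3-4")
  expect_equal(countCnEvents(mk(7)), list(count = 7L, bin = ">4"))
})

test_that("arm attribution distinguishes full, partial and whole-chromosome calls", {
  cen16 <- centromeres(hg)[["16"]]
  len16 <- chromLengths(hg)[["16"]]
  full16q <- armOverlap(mkCalls(list("16", cen16 + 1, len16, "loss")), hg)
  expect_equal(full16q$arm, "16q")
  expect_equal(full16q$status, "full")
  expect_false(attr(full16q, "wholeChromosome"))

  wcx <- armOverlap(mkCalls(list("X", 1, chromLengths(hg)[["X"]], "loss")), hg)
  expect_true(attr(wcx, "wholeChromosome"))
  expect_equal(sort(wcx$arm), c("Xp", "Xq"))

  part12q <- armOverlap(mkCalls(list("12", 76000000, 82000000, "gain")), hg)
  expect_equal(part12q$arm, "12q")
  expect_equal(part12q$status, "partial")

  gr <- GRanges("99", IRanges(1, 100), direction = "gain", mean_log2 = 1)
  expect_error(armOverlap(gr, hg), "unknown chromosome")
})

test_that("a flat bin profile yields one near-zero segment per chromosome", {
  bins <- GRanges(rep(c("1", "2"), each = 100),
                  IRanges(rep(seq(1, by = 50000, length.out = 100), 2),
                          width = 50000),
                  log2 = rnorm(200, 0, 1e-12))
  seg <- segmentBins(bins)
  expect_length(seg, 2)
  expect_equal(mcols(seg)$log2, c(0, 0), tolerance = 1e-9)
})

test_that("a noiseless step is segmented exactly at the step boundary", {
  bins <- GRanges("1", IRanges(seq(1, by = 50000, length.out = 200), width = 50000),
                  log2 = rep(c(0, 0.6), each = 100))
  seg <- segmentBins(bins)
  expect_length(seg, 2)
  expect_equal(end(seg)[1], 100 * 50000)
  expect_equal(mcols(seg)$log2, c(0, 0.6))
})

test_that("noisy change-points are located within 2 bins in >= 95% of replicates", {
  set.seed(123)
  hits <- vapply(1:100, function(i) {
    x <- rep(c(0, 0.6), each = 100) + rnorm(200, 0, 0.1)
    bins <- GRanges("1", IRanges(seq(1, by = 50000, length.out = 200),
                                 width = 50000), log2 = x)
    seg <- segmentBins(bins)
    bp <- end(seg)[-length(seg)] / 50000
    length(bp) >= 1 && any(abs(bp - 100) <= 2)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("segmenting an empty profile is an error", {
  expect_error(segmentBins(GRanges()), "empty")
})
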