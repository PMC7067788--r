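ccfg <- ClonalityConfig()
cen1 <- centromeres(hg)[["1"]]
len1 <- chromLengths(hg)[["1"]]

test_that("an identical whole-arm 1q gain shares one informative proximal breakpoint", {
  a <- mkCalls(list("1", cen1 + 1, len1, "gain"))
  b <- mkCalls(list("1", cen1 + 1, len1, "gain"))
  bp <- matchBreakpoints(a, b, hg, ccfg)
  expect_equal(nrow(bp), 2)
  expect_equal(sum(bp$informative), 1)
  prox <- bp[bp$informative, ]
  expect_equal(prox$side, "start")
  expect_equal(prox$offset, 0)
  term <- bp[!bp$informative, ]
  expect_equal(term$pos_a, len1)  # q-terminus boundary is non-informative
})

test_that("a shared 1q gain with proximal boundaries 400 kb apart is not clonal", {
  a <- LesionProfile("S13_P", mkSegments(list("1", cen1 + 1, len1, 0.32)))
  b <- LesionProfile("S13_D", mkSegments(list("1", cen1 + 400001, len1, 0.35)))
  res <- cnClonality(a, b, hg, config = ccfg)
  expect_equal(res$cnVerdict, "non_clonal")
  expect_equal(res$sharedCnaCount, 1)  # same CNA, but no shared breakpoint

  # identical proximal boundary: clonal
  b2 <- LesionProfile("S13_D2", mkSegments(list("1", cen1 + 1, len1, 0.35)))
  expect_equal(cnClonality(a, b2, hg, config = ccfg)$cnVerdict, "clonal")
})

test_that("breakpoints must match direction and side", {
  a <- mkCalls(list("5", 20000000, 60000000, "gain"))
  b <- mkCalls(list("5", 20000000, 60000000, "loss"))
  expect_equal(nrow(matchBreakpoints(a, b, hg, ccfg)), 0)
  # a's end near b's start: same position, different sides, no match
  a2 <- mkCalls(list("5", 10000000, 20000000, "gain"))
  b2 <- mkCalls(list("5", 20000010, 40000000, "gain"))
  expect_equal(nrow(matchBreakpoints(a2, b2, hg, ccfg)), 0)
})

test_that("matching is symmetric in the two components", {
  set.seed(11)
  for (rep in 1:25) {
    a <- randomCallSet(5)
    b <- randomCallSet(5)
    ab <- matchBreakpoints(a, b, hg, ccfg)
    ba <- matchBreakpoints(b, a, hg, ccfg)
    expect_equal(nrow(ab), nrow(ba))
    if (nrow(ab)) {
      expect_equal(ab$offset, ba$offset)
      expect_equal(ab$pos_a, ba$pos_b)
      expect_equal(ab$informative, ba$informative)
    }
  }
})

test_that("greedy matching equals the exhaustive all-pairs oracle", {
  set.seed(21)
  for (rep in 1:200) {
    a <- randomCallSet(5)
    b <- if (runif(1) < 0.5) {
      # jittered copy of a: forces near-matches at varied offsets
      if (length(a)) {
        sh <- a
        ranges(sh) <- IRanges(start(a) + sample(c(0, 2e4, 6e4, 3e5),
                                                length(a), replace = TRUE),
                              width = width(a))
        sh
      } else randomCallSet(5)
    } else randomCallSet(5)
    got <- matchBreakpoints(a, b, hg, ccfg)
    want <- bruteMatchBreakpoints(a, b, hg, ccfg)
    expect_equal(nrow(got), NROW(want))
    if (nrow(got)) {
      cols <- c("chrom", "side", "direction", "pos_a", "pos_b", "offset",
                "informative")
      expect_equal(got[, cols], want[, cols])
    }
  }
})

test_that("raising the tolerance never turns a clonal pair non-clonal", {
  set.seed(31)
  for (rep in 1:30) {
    a <- randomCallSet(4)
    b <- randomCallSet(4)
    if (!length(a) || !length(b)) next
    verd <- function(tol) {
      bp <- matchBreakpoints(a, b, hg, ClonalityConfig(tolerance = tol))
      nrow(bp) > 0 && any(bp$informative)
    }
    tols <- c(5e4, 2e5, 1e6)
    v <- vapply(tols, verd, logical(1))
    expect_true(all(diff(v) >= 0))
  }
})

test_that("a profile with calls is clonal with itself", {
  p <- LesionProfile("X1", mkSegments(list("3", 10000000, 60000000, 0.4),
                                      list("8", 20000000, 90000000, -0.5)))
  expect_equal(cnClonality(p, p, hg, config = ccfg)$cnVerdict, "clonal")
})

test_that("a call-free component makes the CN channel uninformative", {
  empty <- LesionProfile("NP", mkSegments())
  busy <- LesionProfile("NC", mkSegments(list("1", cen1 + 1, len1, 0.4),
                                         list("16", 40000000, 90354753, -0.5)))
  res <- cnClonality(empty, busy, hg, config = ccfg)
  expect_equal(res$cnVerdict, "uninformative")
  expect_equal(res$sharedCnaCount, 0)
})

bgTest <- BackgroundFrequencyTable(data.frame(
  gene = c("PIK3CA", "TP53", "GATA3", "AKT1"),
  protein_change = c("*", "*", "*", "*"),
  frequency = c(0.2, 0.1, 0.05, 0.01)), cohortSize = 977)

test_that("clonality index follows its closed form", {
  none <- sharedMutations(mkMut("AKT1", "E17K"), mkMut("TP53", "R175H"))
  expect_equal(clonalityIndex(none, bgTest, ccfg), 0)

  one <- sharedMutations(mkMut("PIK3CA", "H1047R"), mkMut("PIK3CA", "H1047R"))
  expect_equal(clonalityIndex(one, bgTest, ccfg), 0.8)  # 1 - 0.2

  two <- sharedMutations(mkMut(c("TP53", "GATA3"), c("R175H", "M1V")),
                         mkMut(c("TP53", "GATA3"), c("R175H", "M1V")))
  expect_equal(clonalityIndex(two, bgTest, ccfg), 0.995)  # 1 - 0.1*0.05
})

test_that("CI grows with shared mutations and shrinks with frequency", {
  genes <- c("TP53", "GATA3", "AKT1")
  changes <- c("R175H", "M1V", "E17K")
  cis <- vapply(1:3, function(k) {
    sh <- sharedMutations(mkMut(genes[1:k], changes[1:k]),
                          mkMut(genes[1:k], changes[1:k]))
    clonalityIndex(sh, bgTest, ccfg)
  }, numeric(1))
  expect_true(all(diff(cis) > 0))

  # ubiquitous shared mutations carry no information
  bgOne <- BackgroundFrequencyTable(data.frame(
    gene = "TP53", protein_change = "*", frequency = 1), cohortSize = 977)
  sh <- sharedMutations(mkMut("TP53", "R175H"), mkMut("TP53", "R175H"))
  expect_equal(clonalityIndex(sh, bgOne, ccfg), 0)
})

test_that("the frequency floor keeps CI strictly below 1", {
  genes <- sprintf("NOVEL%d", 1:3)
  changes <- sprintf("A%dV", 1:3)
  sh <- sharedMutations(mkMut(genes, changes), mkMut(genes, changes))
  ci <- clonalityIndex(sh, bgTest, ccfg)
  expect_lt(ci, 1)
  expect_equal(ci, 1 - (1 / 977)^3)
})

test_that("CI2 is the negative log10 of the frequency product", {
  bg <- BackgroundFrequencyTable(data.frame(
    gene = c("G1", "G2"), protein_change = c("*", "*"),
    frequency = c(0.01, 0.01)), cohortSize = 977)
  expect_equal(clonalityIndex2(sharedMutations(mkMut("A", "x"), mkMut("B", "y")),
                               bg, ccfg), 0)
  one <- sharedMutations(mkMut("G1", "p1"), mkMut("G1", "p1"))
  expect_equal(clonalityIndex2(one, bg, ccfg), 2)          # below 2.84
  two <- sharedMutations(mkMut(c("G1", "G2"), c("p1", "p2")),
                         mkMut(c("G1", "G2"), c("p1", "p2")))
  expect_equal(clonalityIndex2(two, bg, ccfg), 4)          # above 2.84
  expect_gt(4, ccfg@ci2Threshold)
})

test_that("shared-mutation matching uses gene + protein change, never VAF", {
  a <- mkMut(c("PIK3CA", "TP53"), c("H1047R", "R175H"), vaf = c(0.4, 0.3))
  b <- mkMut(c("PIK3CA", "TP53"), c("E545K", "R175H"), vaf = c(0.1, 0.05))
  sh <- sharedMutations(a, b)
  expect_equal(sh$gene, "TP53")
  expect_equal(sh$vaf_a, 0.3)
  expect_equal(sh$vaf_b, 0.05)
})

test_that("the combined verdict integrates the two evidence channels", {
  segShared <- list(list("16", 36600001, 80000000, -0.5))
  papC <- LesionProfile("c_P", do.call(mkSegments, segShared),
                        mutations = mkMut("TP53", "R175H", 0.3))
  carC <- LesionProfile("c_C", do.call(mkSegments, segShared),
                        mutations = mkMut("TP53", "R175H", 0.35))
  v <- assessClonality(papC, carC, bgTest, hg, caseId = "c")
  expect_equal(combinedVerdict(v), "clonal")
  expect_equal(cnVerdict(v), "clonal")
  expect_equal(clonalityCI(v), 0.9)
  expect_false(v@discordant)

  # private mutations only, no CN calls in the papilloma: non-clonal
  papN <- LesionProfile("n_P", mkSegments(), mutations = mkMut("HRAS", "Q61R", 0.2))
  carN <- LesionProfile("n_C", do.call(mkSegments, segShared),
                        mutations = mkMut("TP53", "R175H", 0.3))
  v2 <- assessClonality(papN, carN, bgTest, hg, caseId = "n")
  expect_equal(combinedVerdict(v2), "non_clonal")
  expect_equal(cnVerdict(v2), "uninformative")
  expect_equal(clonalityCI(v2), 0)

  # CN uninformative but CI above threshold: clonal on one channel, not discordant
  papM <- LesionProfile("m_P", mkSegments(),
                        mutations = mkMut(c("TP53", "GATA3"), c("R175H", "M1V")))
  carM <- LesionProfile("m_C", mkSegments(),
                        mutations = mkMut(c("TP53", "GATA3"), c("R175H", "M1V")))
  v3 <- assessClonality(papM, carM, bgTest, hg, caseId = "m")
  expect_equal(combinedVerdict(v3), "clonal")
  expect_false(v3@discordant)

  # CN clonal but mutation channel silent (CI below threshold): discordant
  papD <- LesionProfile("d_P", do.call(mkSegments, segShared),
                        mutations = mkMut("HRAS", "Q61R"))
  carD <- LesionProfile("d_C", do.call(mkSegments, segShared),
                        mutations = mkMut("ERBB3", "V104M"))
  v4 <- assessClonality(papD, carD, bgTest, hg, caseId = "d")
  expect_equal(combinedVerdict(v4), "clonal")
  expect_true(v4@discordant)

  # no evidence at all is an error
  e1 <- LesionProfile("e_P", mkSegments())
  e2 <- LesionProfile("e_C", mkSegments())
  expect_error(assessClonality(e1, e2, bgTest, hg, caseId = "e"), "evidence")
})

test_that("the colonization check compares linear-scale magnitudes", {
  a <- mkCalls(list("16", 36600001, 80000000, "loss", -0.4))
  b <- mkCalls(list("16", 36600001, 80000000, "loss", -0.4))
  sm <- data.frame(gene = "TP53", protein_change = "R175H",
                   vaf_a = 0.3, vaf_b = 0.3)
  expect_equal(colonizationCheck(a, b, sm)$status, "consistent_with_clonality")

  smDiluted <- data.frame(gene = c("TP53", "GATA3"),
                          protein_change = c("R175H", "M1V"),
                          vaf_a = c(0.05, 0.04), vaf_b = c(0.40, 0.35))
  res <- colonizationCheck(mkCalls(), mkCalls(), smDiluted)
  expect_equal(res$status, "suggests_colonization")
  expect_lt(res$medianRatio, 0.30)

  a2 <- mkCalls(list("16", 36600001, 80000000, "loss", -0.38))
  b2 <- mkCalls(list("16", 36600001, 80000000, "loss", -0.40))
  res2 <- colonizationCheck(a2, b2, NULL)
  expect_equal(res2$status, "consistent_with_clonality")
  expect_equal(res2$medianRatio, abs(2 * 2^-0.38 - 2) / abs(2 * 2^-0.40 - 2))
  expect_equal(round(res2$medianRatio, 2), 0.96)

  expect_equal(colonizationCheck(mkCalls(), mkCalls(), NULL)$status,
               "uninformative")
})
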