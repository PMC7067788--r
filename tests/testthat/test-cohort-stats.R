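test_that("FGA follows the per-chromosome averaged definition", {
  expect_equal(fga(mkCalls(), hg), 0)

  len2 <- chromLengths(hg)[["2"]]
  whole2 <- mkCalls(list("2", 1, len2, "gain"))
  expect_equal(fga(whole2, hg), 100 / 23)

  len1 <- chromLengths(hg)[["1"]]
  halves <- mkCalls(list("1", 1, len1 / 2, "gain"),
                    list("2", 1, len2 / 2, "loss"))
  expect_equal(fga(halves, hg), (50 + 50) / 23)
})

test_that("FGA is invariant under splitting a call into adjacent pieces", {
  one <- mkCalls(list("7", 10000001, 50000000, "loss"))
  split <- mkCalls(list("7", 10000001, 30000000, "loss"),
                   list("7", 30000001, 50000000, "loss"))
  expect_equal(fga(one, hg), fga(split, hg))
})

test_that("FGA rejects calls outside the build", {
  gr <- GRanges("1", IRanges(1, 999999999), direction = "gain", mean_log2 = 1)
  expect_error(fga(gr, hg), "outside")
})

test_that("Fisher exact matches enumeration and handles degenerate tables", {
  expect_equal(fisherExact(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisherExact(matrix(c(0, 0, 3, 4), 2)), 1)  # zero margin
  set.seed(5)
  for (rep in 1:50) {
    m <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisherExact(m), fisherOracle(m), tolerance = 1e-10)
    expect_equal(fisherExact(m), fisherExact(t(m)), tolerance = 1e-12)
  }
  expect_error(fisherExact(matrix(c(1, -1, 2, 3), 2)), "non-negative")
})

test_that("Woolf odds-ratio intervals behave under row swaps and contain the estimate", {
  set.seed(9)
  for (rep in 1:25) {
    m <- matrix(sample(1:20, 4, replace = TRUE), 2)
    res <- oddsRatioWoolf(m)
    expect_gt(res$or, res$lower)
    expect_lt(res$or, res$upper)
    swapped <- oddsRatioWoolf(m[2:1, ])
    expect_equal(swapped$or, 1 / res$or)
    expect_equal(swapped$lower, 1 / res$upper)
    expect_equal(swapped$upper, 1 / res$lower)
  }
})

test_that("zero cells require the Haldane correction", {
  m <- matrix(c(5, 0, 2, 9), 2)
  expect_error(oddsRatioWoolf(m), "Haldane")
  res <- oddsRatioWoolf(m, correct = TRUE)
  expect_true(res$corrected)
  expect_equal(res$or, (5.5 * 9.5) / (0.5 * 2.5))
})

test_that("chi-square equals the direct O/E summation", {
  m0 <- matrix(c(10, 10, 10, 10), 2)
  res0 <- chiSquare(m0)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)

  set.seed(13)
  for (rep in 1:20) {
    m <- matrix(sample(1:25, 4, replace = TRUE), 2)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    res <- chiSquare(m)
    expect_equal(res$statistic, sum((m - e)^2 / e), tolerance = 1e-12)
    expect_equal(res$df, 1)
  }
  m3 <- matrix(sample(1:9, 12, replace = TRUE), 3)
  expect_equal(chiSquare(m3)$df, 6)
  expect_error(chiSquare(matrix(c(0, 0, 3, 4), 2)), "collapse")
})

test_that("Mann-Whitney uses exact enumeration for small untied samples", {
  res <- mannWhitney(1:5, 6:10)
  expect_equal(res$p.value, 2 / choose(10, 5))
  expect_equal(res$p.value, mannWhitney(6:10, 1:5)$p.value)
  expect_equal(mannWhitney(c(1, 1, 2, 2), c(1, 2, 1, 2))$p.value, 1)
  expect_equal(mannWhitney(rep(3, 4), rep(3, 5))$p.value, 1)
  expect_error(mannWhitney(numeric(), 1:3), "non-empty")
})

test_that("biomarker flags encode the 1q gain / 16q loss / 11q loss trio", {
  loss16q <- mkCalls(list("16", 40000001, 60000000, "loss"))
  f1 <- biomarkerFlags(loss16q, mkMut(character(), character()), hg)
  expect_true(f1[["hasAnyCna"]])
  expect_true(f1[["hasBiomarkerCna"]])
  expect_false(f1[["pik3caMutant"]])

  f2 <- biomarkerFlags(mkCalls(), mkMut("PIK3CA", "H1047R"), hg)
  expect_false(f2[["hasAnyCna"]])
  expect_false(f2[["hasBiomarkerCna"]])
  expect_true(f2[["pik3caMutant"]])

  loss7q <- mkCalls(list("7", 70000001, 100000000, "loss"))
  f3 <- biomarkerFlags(loss7q, mkMut(character(), character()), hg)
  expect_true(f3[["hasAnyCna"]])
  expect_false(f3[["hasBiomarkerCna"]])

  # a 16q GAIN is not the biomarker loss
  gain16q <- mkCalls(list("16", 40000001, 60000000, "gain"))
  expect_false(biomarkerFlags(gain16q, mkMut(character(), character()),
                              hg)[["hasBiomarkerCna"]])
})

test_that("case summaries apply the reporting filter to events but not FGA", {
  seg <- mkSegments(list("3", 10000001, 13000000, 0.4),   # 3 Mb: FGA yes, event no
                    list("16", 40000001, 60000000, -0.5))
  prof <- LesionProfile("S", seg, mkMut("PIK3CA", "E545K", 0.2))
  s <- summarizeCase("S", "pure", "benign", prof, hg)
  expect_equal(s$cn_event_count, 1)
  expect_true(s$has_biomarker_cna)
  expect_true(s$pik3ca_mutant)
  expect_gt(s$fga, 0)
  lens <- chromLengths(hg)
  expect_equal(s$fga, (3e6 / lens[["3"]] + 2e7 / lens[["16"]]) * 100 / 23)
})

test_that("cohort reports roll up counts and pairwise tests", {
  mkSummary <- function(id, group, pik, cna) {
    data.frame(case_id = id, group = group, histology = "benign",
               fga = runif(1, 0, 10) * cna, cn_event_count = cna,
               has_any_cna = cna > 0, has_biomarker_cna = FALSE,
               pik3ca_mutant = pik, mutations_assayed = TRUE)
  }
  set.seed(3)
  summ <- rbind(
    do.call(rbind, lapply(1:13, function(i)
      mkSummary(paste0("P", i), "pure", i <= 9, as.integer(i > 9)))),
    do.call(rbind, lapply(1:7, function(i)
      mkSummary(paste0("C", i), "clonal", FALSE, 1L))))
  rep <- cohortReport(summ)
  expect_equal(sort(rep$groups$group), c("clonal", "pure"))
  expect_equal(rep$groups$pik3ca_pos[rep$groups$group == "pure"], 9)
  expect_equal(rep$groups$pik3ca_pos[rep$groups$group == "clonal"], 0)
  row <- rep$tests[rep$tests$comparison == "pik3ca_mutant", ]
  expect_equal(row$p.value, fisherExact(matrix(c(0, 7, 9, 4), 2, byrow = TRUE)))
  expect_true("mann_whitney" %in% rep$tests$test)

  single <- cohortReport(summ[summ$group == "pure", ])
  expect_null(single$tests)
})

test_that("odds ratios print at the conventional precision", {
  expect_equal(formatOddsRatio(5.625), 5.63)
  expect_equal(formatOddsRatio(35.0), 35)
  expect_equal(formatOddsRatio(465.373), 470)
  expect_equal(formatOddsRatio(1.857), 1.86)
})
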