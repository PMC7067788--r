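#' Fraction of genome altered (FGA)
#'
#' For each of the 23 modeled chromosomes (1-22, X) the altered base pairs
#' are summed and divided by the chromosome length; FGA is the unweighted
#' mean of these per-chromosome percentages, chromosomes without calls
#' contributing zero.
#'
#' @param calls \code{GRanges} of non-overlapping calls for one case.
#' @param build a \code{\link{GenomeBuild}}.
#' @return FGA as a percentage in [0, 100].
#' @export
fga <- function(calls, build = grch37Build()) {
  lens <- chromLengths(build)
  if (length(calls)) {
    chrom <- as.character(seqnames(calls))
    if (!all(chrom %in% names(lens)))
      stop("call on chromosome outside the build")
    if (any(end(calls) > lens[chrom]) || any(start(calls) < 1))
      stop("call coordinates outside the build")
    altered <- tapply(as.numeric(width(calls)), chrom, sum)
  } else {
    altered <- numeric()
  }
  perChrom <- stats::setNames(numeric(length(lens)), names(lens))
  perChrom[names(altered)] <- altered
  mean(perChrom / lens * 100)
}

#' Progression-biomarker flags for one case
#'
#' \code{hasAnyCna} is true when any reportable (>5 Mb) call exists;
#' \code{hasBiomarkerCna} when a reportable gain touches 1q or a
#' reportable loss touches 16q or 11q (the alteration trio enriched in
#' papillomas clonal with carcinoma); \code{pik3caMutant} when any PIK3CA
#' mutation record is present.
#'
#' @param calls \code{GRanges} of calls at reporting-filter level.
#' @param mutations mutation \code{data.frame}.
#' @param build a \code{\link{GenomeBuild}}.
#' @return named logical vector with elements \code{hasAnyCna},
#'   \code{hasBiomarkerCna}, \code{pik3caMutant}.
#' @export
biomarkerFlags <- function(calls, mutations, build = grch37Build()) {
  hasAny <- length(calls) > 0
  hasBio <- hasAny && (anyCallOnArm(calls, "1q", build, "gain") ||
                       anyCallOnArm(calls, "16q", build, "loss") ||
                       anyCallOnArm(calls, "11q", build, "loss"))
  pik <- nrow(mutations) > 0 && any(mutations$gene == "PIK3CA")
  c(hasAnyCna = hasAny, hasBiomarkerCna = hasBio, pik3caMutant = pik)
}

#' Summarise one case for cohort statistics
#'
#' @param caseId case label.
#' @param group one of \code{pure}, \code{clonal}, \code{non_clonal}.
#' @param histology \code{benign} or \code{atypical} (papilloma histology).
#' @param profile papilloma \code{\link{LesionProfile}}.
#' @param build a \code{\link{GenomeBuild}}.
#' @param callingConfig a \code{\link{CallingConfig}}.
#' @return one-row \code{data.frame} (a CaseSummary): fga, cnEventCount and
#'   the biomarker flags, computed at noise level for FGA and reporting
#'   level for events/flags.
#' @export
summarizeCase <- function(caseId, group, histology, profile,
                          build = grch37Build(),
                          callingConfig = CallingConfig()) {
  calls <- callCnas(cnSegments(profile), callingConfig)
  rep <- reportableCnas(calls, callingConfig)
  flags <- biomarkerFlags(rep, mutationTable(profile), build)
  data.frame(case_id = caseId, group = group, histology = histology,
             fga = fga(calls, build), cn_event_count = length(rep),
             has_any_cna = unname(flags["hasAnyCna"]),
             has_biomarker_cna = unname(flags["hasBiomarkerCna"]),
             pik3ca_mutant = unname(flags["pik3caMutant"]),
             mutations_assayed = mutationsAssayed(profile),
             stringsAsFactors = FALSE)
}

.asTable <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m)))
    stop("contingency table must hold non-negative integers")
  m
}

#' Two-tailed Fisher exact test
#'
#' Exact two-tailed p by the minimum-likelihood rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table.  A table
#' with a zero margin is uninformative and returns p = 1 by convention.
#'
#' @param table 2x2 matrix of counts.
#' @return p-value in [0, 1].
#' @export
fisherExact <- function(table) {
  m <- .asTable(table)
  if (!all(dim(m) == c(2L, 2L))) stop("fisherExact expects a 2x2 table")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m)$p.value
}

#' Odds ratio with Woolf (logit) confidence interval
#'
#' OR = (a d)/(b c) with CI exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)).
#' With a zero cell the OR or its variance is degenerate; the Haldane
#' +0.5 correction is applied to every cell when \code{correct = TRUE},
#' otherwise a zero cell is an error.
#'
#' @param table 2x2 matrix of counts, rows = exposure, columns = outcome.
#' @param conf.level confidence level (default 0.95).
#' @param correct apply the Haldane correction when a cell is zero.
#' @return list with \code{or}, \code{lower}, \code{upper},
#'   \code{conf.level} and \code{corrected}.
#' @export
oddsRatioWoolf <- function(table, conf.level = 0.95, correct = FALSE) {
  m <- .asTable(table)
  if (!all(dim(m) == c(2L, 2L))) stop("oddsRatioWoolf expects a 2x2 table")
  corrected <- FALSE
  if (any(m == 0)) {
    if (!correct)
      stop("zero cell; re-run with correct = TRUE for the Haldane correction")
    m <- m + 0.5
    corrected <- TRUE
  }
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  se <- sqrt(sum(1 / m))
  list(or = or, lower = exp(log(or) - z * se), upper = exp(log(or) + z * se),
       conf.level = conf.level, corrected = corrected)
}

#' Pearson chi-square test on an r x c table
#'
#' Without continuity correction; df = (r-1)(c-1).  A zero expected cell
#' makes the statistic undefined and raises an error suggesting bins be
#' collapsed.
#'
#' @param table r x c matrix of counts (r, c >= 2).
#' @return list with \code{statistic}, \code{df}, \code{p.value}.
#' @export
chiSquare <- function(table) {
  m <- .asTable(table)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("chiSquare needs an r x c table with r, c >= 2")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0))
    stop("zero expected count; collapse sparse rows/columns before testing")
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value)
}

#' Mann-Whitney U test (two-tailed)
#'
#' Exact enumeration when the combined sample size is at most 12 and no
#' ties are present, otherwise the tie-corrected normal approximation
#' (without continuity correction).  Identical samples give p = 1.
#'
#' @param x,y numeric vectors.
#' @return list with \code{U} and \code{p.value}.
#' @export
mannWhitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exact <- (length(x) + length(y) <= 12L) && !anyDuplicated(c(x, y))
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                             correct = FALSE))
  p <- res$p.value
  if (is.nan(p)) p <- 1  # zero variance: all observations tied
  list(U = unname(res$statistic), p.value = min(p, 1))
}

#' Cohort report: grouped counts and pairwise comparisons
#'
#' Rolls a set of case summaries (rows from \code{\link{summarizeCase}})
#' into per-group counts of alteration presence, biomarker-trio presence
#' and PIK3CA status plus FGA summaries, and runs every pairwise
#' two-group comparison: Fisher exact tests on the three binary flags
#' (restricted, for PIK3CA, to cases with mutation data) and Mann-Whitney
#' tests on FGA.  With a single group only counts are produced.
#'
#' @param summaries \code{data.frame} of case summaries.
#' @return list with \code{groups} (per-group counts) and \code{tests}
#'   (one row per comparison: groups, counts, estimate, p, test name).
#' @export
cohortReport <- function(summaries) {
  stopifnot(nrow(summaries) > 0)
  grp <- split(summaries, summaries$group)
  groups <- do.call(rbind, lapply(names(grp), function(g) {
    s <- grp[[g]]
    mutN <- sum(s$mutations_assayed)
    data.frame(group = g, n = nrow(s),
               cna_pos = sum(s$has_any_cna),
               biomarker_pos = sum(s$has_biomarker_cna),
               pik3ca_pos = sum(s$pik3ca_mutant & s$mutations_assayed),
               pik3ca_assayed = mutN,
               fga_mean = mean(s$fga), fga_median = stats::median(s$fga),
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  if (length(grp) < 2L) return(list(groups = groups, tests = NULL))
  tests <- list()
  combos <- utils::combn(names(grp), 2L)
  addTest <- function(g1, g2, what, tab, test, p, estimate = NA_real_) {
    tests[[length(tests) + 1L]] <<- data.frame(
      group1 = g1, group2 = g2, comparison = what,
      a = tab[1], b = tab[2], c = tab[3], d = tab[4],
      estimate = estimate, p.value = p, test = test,
      stringsAsFactors = FALSE)
  }
  for (j in seq_len(ncol(combos))) {
    g1 <- combos[1, j]; g2 <- combos[2, j]
    s1 <- grp[[g1]]; s2 <- grp[[g2]]
    for (what in c("has_any_cna", "has_biomarker_cna", "pik3ca_mutant")) {
      a1 <- s1; a2 <- s2
      if (what == "pik3ca_mutant") {
        a1 <- s1[s1$mutations_assayed, , drop = FALSE]
        a2 <- s2[s2$mutations_assayed, , drop = FALSE]
      }
      if (!nrow(a1) || !nrow(a2)) next
      tab <- matrix(c(sum(a1[[what]]), nrow(a1) - sum(a1[[what]]),
                      sum(a2[[what]]), nrow(a2) - sum(a2[[what]])),
                    nrow = 2, byrow = TRUE)
      or <- tryCatch(oddsRatioWoolf(tab, correct = TRUE)$or, error = function(e) NA_real_)
      addTest(g1, g2, what, as.vector(t(tab)), "fisher_exact",
              fisherExact(tab), or)
    }
    mw <- mannWhitney(s1$fga, s2$fga)
    addTest(g1, g2, "fga", c(nrow(s1), NA, nrow(s2), NA), "mann_whitney",
            mw$p.value, unname(mw$U))
  }
  list(groups = groups, tests = do.call(rbind, tests))
}

#' Round an odds ratio for display
#'
#' Two significant figures at or above 10, two decimals below, matching
#' the usual print style of clinical reports; full precision should be
#' kept for computation.
#'
#' @param or numeric odds ratio(s).
#' @return rounded numeric.
#' @export
formatOddsRatio <- function(or) {
  halfUp <- function(x, d) floor(x * 10^d + 0.5) / 10^d
  ifelse(or >= 10, signif(or, 2), halfUp(or, 2))
}
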