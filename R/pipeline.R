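#' Call copy-number alterations directly from per-chromosome bin vectors
#'
#' Fast path used by the pipeline: segments each chromosome's bin log2
#' vector (\code{\link{segmentBins}} semantics) and classifies the
#' segments (\code{\link{callCnas}}).
#'
#' @param binValues named list of per-chromosome numeric log2 vectors (as
#'   stored by \code{\link{generateCohort}}).
#' @param build a \code{\link{GenomeBuild}}.
#' @param binSize bin width, bp.
#' @param callingConfig a \code{\link{CallingConfig}}.
#' @param minBins,zThreshold segmentation parameters.
#' @return list with \code{segments} and \code{calls} (both \code{GRanges}).
#' @export
callBinProfile <- function(binValues, build, binSize = 5e4,
                           callingConfig = CallingConfig(),
                           minBins = 5L, zThreshold = 2.5) {
  lens <- chromLengths(build)
  si <- buildSeqinfo(build)
  chroms <- intersect(names(lens), names(binValues))
  segs <- lapply(chroms, function(ch) {
    x <- binValues[[ch]]
    seg <- .segmentVector(x, minBins, zThreshold)
    data.frame(chrom = ch, start = (seg$startBin - 1) * binSize + 1,
               end = pmin(seg$endBin * binSize, lens[[ch]]),
               log2 = seg$log2, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, segs)
  segments <- GRanges(df$chrom, IRanges(df$start, df$end), log2 = df$log2,
                      seqinfo = si)
  segments <- GenomicRanges::sort(segments)
  cdf <- .callCnasCore(df$chrom, df$start, df$end, df$log2, callingConfig)
  calls <- GenomicRanges::sort(
    GRanges(cdf$chrom, IRanges(cdf$start, cdf$end), direction = cdf$direction,
            mean_log2 = cdf$mean_log2, seqinfo = si))
  list(segments = segments, calls = calls)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulate a cohort, segment and call every component's bin profile,
#' assess clonality of every paired case (copy-number breakpoint channel
#' plus mutation clonality indices, with the colonization check),
#' summarise cases, roll up cohort contingency statistics, and cluster
#' the paired components' copy-number states (Pearson dissimilarity,
#' average linkage).  Deterministic given the spec's seed.
#'
#' @param spec a \code{\link{CohortSpec}}.
#' @param build a \code{\link{GenomeBuild}}.
#' @param callingConfig a \code{\link{CallingConfig}}.
#' @param clonalityConfig a \code{\link{ClonalityConfig}}.
#' @param outdir optional output directory; when given, the cohort files,
#'   calls, verdicts, summaries, report, copy-number matrix and Newick
#'   tree are written there.
#' @return list with elements \code{cohort}, \code{calls} (per sample),
#'   \code{verdicts} (per paired case), \code{colonization},
#'   \code{summaries}, \code{report}, \code{clustering} (hclust),
#'   \code{pairing} (mutual-nearest-leaf fraction of truth-clonal pairs)
#'   and \code{accuracy} (verdicts vs ground truth).
#' @export
runPipeline <- function(spec = CohortSpec(), build = grch37Build(),
                        callingConfig = CallingConfig(),
                        clonalityConfig = ClonalityConfig(),
                        outdir = NULL) {
  cohort <- generateCohort(spec, build, render = TRUE)
  bg <- cohortBackground(cohort)
  profiles <- list()
  calls <- list()
  for (case in cohort@truth) {
    for (comp in case$components) {
      res <- callBinProfile(cohort@bins[[comp$sample_id]], build,
                            spec@binSize, callingConfig)
      profiles[[comp$sample_id]] <-
        LesionProfile(comp$sample_id, res$segments, comp$mutations,
                      component = comp$component)
      calls[[comp$sample_id]] <- res$calls
    }
  }
  verdicts <- list()
  colonization <- list()
  paired <- Filter(function(case) length(case$components) == 2L, cohort@truth)
  for (case in paired) {
    pid <- case$components$P$sample_id
    cid <- case$components$C$sample_id
    v <- assessClonality(profiles[[pid]], profiles[[cid]], bg, build,
                         callingConfig, clonalityConfig,
                         caseId = case$case_id)
    verdicts[[case$case_id]] <- v
    sm <- sharedMutations(mutationTable(profiles[[pid]]),
                          mutationTable(profiles[[cid]]))
    colonization[[case$case_id]] <-
      colonizationCheck(calls[[pid]], calls[[cid]], sm)
  }
  summaries <- do.call(rbind, lapply(cohort@truth, function(case) {
    group <- if (is.na(case$clonal)) "pure"
             else combinedVerdict(verdicts[[case$case_id]])
    if (group == "clonal" || group == "non_clonal") group <- group
    summarizeCase(case$case_id, group, case$histology,
                  profiles[[case$components$P$sample_id]], build,
                  callingConfig)
  }))
  rownames(summaries) <- NULL
  report <- cohortReport(summaries)
  pairedIds <- unlist(lapply(paired, function(case)
    c(case$components$P$sample_id, case$components$C$sample_id)))
  clustering <- NULL
  pairing <- NULL
  if (length(pairedIds) >= 2L) {
    cnm <- segmentsToMatrix(calls[pairedIds], build, binSize = 1e6,
                            mode = "state")
    clustering <- averageLinkage(pearsonDissimilarity(cnm))
    clonalPairs <- do.call(rbind, lapply(paired, function(case)
      if (isTRUE(case$clonal))
        c(case$components$P$sample_id, case$components$C$sample_id)))
    if (!is.null(clonalPairs))
      pairing <- copheneticPairing(clustering, clonalPairs)
  }
  truthFlags <- vapply(paired, `[[`, logical(1), "clonal")
  verdictFlags <- vapply(paired, function(case)
    combinedVerdict(verdicts[[case$case_id]]) == "clonal", logical(1))
  accuracy <- if (length(paired)) mean(truthFlags == verdictFlags) else NA_real_
  out <- list(cohort = cohort, profiles = profiles, calls = calls,
              verdicts = verdicts, colonization = colonization,
              summaries = summaries, report = report,
              clustering = clustering, pairing = pairing,
              accuracy = accuracy)
  if (!is.null(outdir)) out$files <- .writePipelineOutputs(out, outdir)
  out
}

.writePipelineOutputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  spec <- res$cohort@spec
  hdr <- .provenanceHeader(spec)
  files <- writeCohort(res$cohort, outdir)
  callRows <- do.call(rbind, lapply(names(res$calls), function(s) {
    g <- res$calls[[s]]
    if (!length(g)) return(NULL)
    data.frame(sample = s, chrom = as.character(seqnames(g)),
               start = start(g), end = end(g),
               direction = mcols(g)$direction,
               mean_log2 = round(mcols(g)$mean_log2, 4),
               stringsAsFactors = FALSE)
  }))
  .writeTsv <- function(df, path) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste0("# ", hdr), con)
    if (is.null(df)) df <- data.frame()
    suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
    path
  }
  files["calls"] <- .writeTsv(callRows, file.path(outdir, "calls.tsv"))
  files["summaries"] <- .writeTsv(res$summaries, file.path(outdir, "summaries.tsv"))
  files["report"] <- .writeTsv(res$report$tests, file.path(outdir, "report.tsv"))
  vjson <- lapply(res$verdicts, function(v) list(
    case_id = v@caseId, cn_verdict = v@cnVerdict,
    shared_breakpoints = v@sharedBreakpoints,
    shared_cna_count = v@sharedCnaCount,
    ci = v@ci, ci2 = v@ci2, combined_verdict = v@combinedVerdict,
    discordant = v@discordant,
    colonization = res$colonization[[v@caseId]]$status))
  files["verdicts"] <- file.path(outdir, "verdicts.json")
  jsonlite::write_json(list(provenance = hdr, verdicts = vjson),
                       files["verdicts"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(res$clustering)) {
    files["tree"] <- file.path(outdir, "tree.nwk")
    writeNewick(res$clustering, files["tree"])
  }
  files
}
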