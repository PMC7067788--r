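## Event spectra: weights follow the relative frequencies of recurrent
## arm-level alterations in pure papilloma, papilloma clonal with
## carcinoma, and the carcinoma components (trio = 1q gain / 16q loss /
## 11q loss, the progression-biomarker alterations).

.SPECTRA <- list(
  pure = data.frame(
    chrom = c("X", "16", "7", "17", "10", "12", "16", "1", "6", "15", "17", "19", "19"),
    arm   = c("WC", "q", "q", "p", "q", "q", "p", "p", "p", "q", "q", "p", "q"),
    direction = c("loss", "loss", "loss", "loss", "loss", "gain", "gain",
                  "gain", "gain", "gain", "gain", "gain", "gain"),
    weight = c(3, 2, 2, 1, 1, 1, 1, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    stringsAsFactors = FALSE),
  trio = data.frame(
    chrom = c("1", "16", "11"), arm = c("q", "q", "q"),
    direction = c("gain", "loss", "loss"), weight = c(1, 1, 1),
    stringsAsFactors = FALSE),
  sharedExtra = data.frame(
    chrom = c("16", "17", "8", "22", "X", "10", "20", "12", "13"),
    arm   = c("p", "q", "q", "q", "WC", "q", "q", "q", "q"),
    direction = c("gain", "gain", "gain", "loss", "loss", "loss", "gain",
                  "gain", "loss"),
    weight = c(1, 1, 1, 1, 0.5, 0.5, 0.5, 0.5, 0.5),
    stringsAsFactors = FALSE),
  carcinomaExtra = data.frame(
    chrom = c("5", "5", "17", "8", "13", "16", "14", "18"),
    arm   = c("WC", "p", "q", "q", "q", "p", "q", "q"),
    direction = c("gain", "gain", "gain", "gain", "loss", "gain", "loss", "loss"),
    weight = c(1, 1, 1, 1, 1, 0.5, 0.5, 0.5),
    stringsAsFactors = FALSE),
  nonclonalCarcinoma = data.frame(
    chrom = c("1", "16", "11", "17", "8", "17", "5", "13"),
    arm   = c("q", "q", "q", "p", "q", "q", "WC", "q"),
    direction = c("gain", "loss", "loss", "loss", "gain", "gain", "gain", "loss"),
    weight = c(1.5, 1.5, 1, 1, 1, 1, 0.5, 0.5),
    stringsAsFactors = FALSE))

.PIK3CA_HOTSPOTS <- c("E545K", "H1047R", "E542K")
.PASSENGER_GENES <- c("SPEN", "ERBB3", "HRAS", "TP53", "PIK3R3", "GATA3",
                      "MAP2K4", "NF1", "KMT2C", "CDH1", "RUNX1", "SF3B1")
.SHARED_GENES <- c("AKT1", "PIK3R1", "GATA3", "ARID1A", "SPEN", "MAP3K1",
                   "CBFB", "RUNX1")

.randomProteinChange <- function(n) {
  aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  paste0(sample(aa, n, replace = TRUE),
         sample(50:1200, n, replace = TRUE),
         sample(aa, n, replace = TRUE))
}

# Snap an interval to the bin grid (start to a bin start, end to a bin end,
# capped at the chromosome length).
.snapInterval <- function(start, end, binSize, chromLen) {
  s <- floor((start - 1) / binSize) * binSize + 1
  e <- min(ceiling(end / binSize) * binSize, chromLen)
  c(s, e)
}

# Draw one event on the given arm row; whole-arm with probability
# wholeArmP, else a partial interval kept >= 1 Mb clear of the arm ends so
# neutral flanks remain segmentable.  Returns c(chrom, start, end).
.drawEvent <- function(row, build, binSize, wholeArmP = 0.5) {
  lens <- chromLengths(build)
  cens <- centromeres(build)
  len <- lens[[row$chrom]]
  cenEnd <- floor(cens[[row$chrom]] / binSize) * binSize
  bounds <- switch(row$arm,
    WC = c(1, len),
    p = c(1, cenEnd),
    q = c(cenEnd + 1, len))
  armLen <- bounds[2] - bounds[1] + 1
  if (row$arm == "WC" || armLen < 12.5e6 || stats::runif(1) < wholeArmP) {
    iv <- bounds
  } else {
    lo <- bounds[1] + 1e6
    hi <- bounds[2] - 1e6
    L <- stats::runif(1, 1e7, min(0.8 * armLen, hi - lo))
    s <- stats::runif(1, lo, hi - L)
    iv <- .snapInterval(s, s + L - 1, binSize, len)
    iv[2] <- min(iv[2], hi)
  }
  list(chrom = row$chrom, start = iv[1], end = iv[2])
}

# Sample event rows from a spectrum without arm collisions (a WC event
# occupies both arms); occupied = character vector of taken arm keys.
.sampleSpectrum <- function(spectrum, n, occupied = character()) {
  keysOf <- function(rows) {
    unlist(lapply(seq_len(nrow(rows)), function(i) {
      if (rows$arm[i] == "WC") paste0(rows$chrom[i], c("p", "q"))
      else paste0(rows$chrom[i], rows$arm[i])
    }))
  }
  chosen <- spectrum[0, ]
  avail <- spectrum
  while (nrow(chosen) < n && nrow(avail)) {
    i <- sample.int(nrow(avail), 1L, prob = avail$weight)
    row <- avail[i, ]
    rk <- keysOf(row)
    if (!any(rk %in% occupied)) {
      chosen <- rbind(chosen, row)
      occupied <- c(occupied, rk)
    }
    avail <- avail[-i, ]
  }
  list(rows = chosen, occupied = occupied)
}

.eventsToGRanges <- function(events, build, spec) {
  si <- buildSeqinfo(build)
  if (!length(events))
    return(GRanges(seqinfo = si))
  df <- do.call(rbind, lapply(events, function(e)
    data.frame(chrom = e$chrom, start = e$start, end = e$end,
               direction = e$direction, log2 = e$log2)))
  GenomicRanges::sort(GRanges(df$chrom, IRanges(df$start, df$end),
                              direction = df$direction, log2 = df$log2,
                              seqinfo = si))
}

.drawEvents <- function(spectrum, n, build, spec, occupied = character()) {
  pick <- .sampleSpectrum(spectrum, n, occupied)
  events <- lapply(seq_len(nrow(pick$rows)), function(i) {
    row <- pick$rows[i, ]
    ev <- .drawEvent(row, build, spec@binSize)
    ev$direction <- row$direction
    base <- if (row$direction == "gain") spec@gainLog2 else spec@lossLog2
    ev$log2 <- base + stats::runif(1, -0.02, 0.02)
    ev
  })
  list(events = events, occupied = pick$occupied)
}

.drawMutations <- function(genes, vafRange = c(0.05, 0.5)) {
  if (!length(genes)) return(.emptyMutations())
  data.frame(gene = genes, protein_change = .randomProteinChange(length(genes)),
             vaf = round(stats::runif(length(genes), vafRange[1], vafRange[2]), 3),
             classification = "missense", stringsAsFactors = FALSE)
}

#' Synthetic paired-lesion cohort
#'
#' Produced by \code{\link{generateCohort}}; holds the per-case ground
#' truth, the rendered bin-level log2 profiles, the background mutation
#' frequency table and the generating spec.
#'
#' @slot truth list of per-case truth records.
#' @slot bins named list (sample id -> list of per-chromosome bin log2
#'   vectors); empty when rendering was skipped.
#' @slot background a \code{BackgroundFrequencyTable}.
#' @slot spec the generating \code{CohortSpec}.
#' @slot build the \code{GenomeBuild} used.
#' @export
setClass("SyntheticCohort",
  representation(truth = "list", bins = "list",
                 background = "BackgroundFrequencyTable",
                 spec = "CohortSpec", build = "GenomeBuild"))

setMethod("show", "SyntheticCohort", function(object) {
  groups <- vapply(object@truth, `[[`, character(1), "group")
  cat(sprintf("SyntheticCohort: %d cases (%d pure, %d clonal, %d non-clonal), %d rendered profiles\n",
              length(object@truth), sum(groups == "pure"),
              sum(groups == "clonal"), sum(groups == "non_clonal"),
              length(object@bins)))
})

#' @describeIn SyntheticCohort-class per-case ground-truth records.
#' @param x a \code{SyntheticCohort}.
#' @export
cohortTruth <- function(x) x@truth

#' @describeIn SyntheticCohort-class the background frequency table.
#' @export
cohortBackground <- function(x) x@background

#' Rendered bin profile of one sample as GRanges
#' @param cohort a \code{SyntheticCohort} generated with
#'   \code{render = TRUE}.
#' @param sampleId sample identifier.
#' @return \code{GRanges} of bins with \code{log2} metadata.
#' @export
binProfileGRanges <- function(cohort, sampleId) {
  v <- cohort@bins[[sampleId]]
  if (is.null(v)) stop("no rendered bins for sample ", sampleId)
  grid <- binGrid(cohort@build, cohort@spec@binSize)
  mcols(grid)$log2 <- unlist(v[as.character(unique(seqnames(grid)))],
                             use.names = FALSE)
  grid
}

#' Generate a seeded synthetic cohort of paired lesion profiles
#'
#' Emulates the cohort architecture the clonality analysis assumes.  Pure
#' papillomas carry alterations with probability \code{pureCnaRate}
#' (mostly single events from the pure spectrum, dominated by X loss, 16q
#' loss and 7q loss), a PIK3CA hotspot with probability
#' \code{purePik3caRate} and 0-4 passenger mutations (median 1).  Clonal
#' pairs share at least \code{sharedCnaMin} alterations with identical
#' breakpoints, always including a trio event (1q gain / 16q loss / 11q
#' loss) in the papilloma; the carcinoma acquires private extra
#' alterations (5p gain, 17q gain, ...) with probability
#' \code{clonalExtraCnaRate}; the pair shares at least one mutation and
#' never carries PIK3CA.  Non-clonal papillomas are alteration-free in
#' 8/9 of cases, with private mutations only; a coincidental same-arm
#' alteration, when present, has its breakpoints jittered by
#' \code{breakpointJitterNonclonal} so it never shares a breakpoint.
#' Rendered bin log2 values are truth + Gaussian noise + a sinusoidal
#' wave (FFPE artefact).
#'
#' All randomness derives from \code{spec@seed}; a fixed spec yields
#' byte-identical output.
#'
#' @param spec a \code{\link{CohortSpec}}.
#' @param build a \code{\link{GenomeBuild}}.
#' @param render render bin-level profiles (skip for truth-only use).
#' @return a \code{\link{SyntheticCohort}}.
#' @export
generateCohort <- function(spec, build = grch37Build(), render = TRUE) {
  validObject(spec)
  set.seed(as.integer(spec@seed))
  bg <- generateBackgroundFreqs()
  truth <- list()
  for (i in seq_len(spec@nPure))
    truth[[length(truth) + 1L]] <- .genPureCase(sprintf("P%02d", i), spec, build)
  for (i in seq_len(spec@nClonal))
    truth[[length(truth) + 1L]] <-
      .genPairedCase(sprintf("SC%02d", i), TRUE, spec, build)
  for (i in seq_len(spec@nNonclonal))
    truth[[length(truth) + 1L]] <-
      .genPairedCase(sprintf("SN%02d", i), FALSE, spec, build)
  names(truth) <- vapply(truth, `[[`, character(1), "case_id")
  bins <- list()
  if (render) {
    for (case in truth) {
      for (comp in case$components) {
        bins[[comp$sample_id]] <- .renderBins(comp$truthCalls, spec, build)
      }
    }
  }
  new("SyntheticCohort", truth = truth, bins = bins, background = bg,
      spec = spec, build = build)
}

.genPureCase <- function(caseId, spec, build) {
  histology <- if (stats::runif(1) < 4 / 24) "atypical" else "benign"
  events <- list()
  if (stats::runif(1) < spec@pureCnaRate) {
    nEv <- sample(c(1L, 2L, 7L), 1L, prob = c(6, 2, 1))
    events <- .drawEvents(.SPECTRA$pure, nEv, build, spec)$events
  }
  muts <- .emptyMutations()
  if (stats::runif(1) < spec@purePik3caRate) {
    muts <- rbind(muts, data.frame(gene = "PIK3CA",
      protein_change = sample(.PIK3CA_HOTSPOTS, 1L),
      vaf = round(stats::runif(1, 0.1, 0.4), 3),
      classification = "missense", stringsAsFactors = FALSE))
  }
  nPass <- sample(0:4, 1L, prob = c(0.25, 0.40, 0.18, 0.10, 0.07))
  muts <- rbind(muts, .drawMutations(sample(.PASSENGER_GENES, nPass)))
  calls <- .eventsToGRanges(events, build, spec)
  list(case_id = caseId, group = "pure", histology = histology, clonal = NA,
       components = list(P = list(sample_id = caseId, component = "papilloma",
                                  truthCalls = calls, mutations = muts)),
       shared_cnas = .eventsToGRanges(list(), build, spec),
       shared_mutations = .emptyMutations())
}

.genPairedCase <- function(caseId, clonal, spec, build) {
  grade <- sample(c("LG", "IG", "HG"), 1L, prob = c(6, 3, 2))
  carcComponent <- sample(c("DCIS", "IDC"), 1L, prob = c(2, 1))
  if (clonal) {
    histology <- if (stats::runif(1) < 10 / 11) "atypical" else "benign"
    nShared <- spec@sharedCnaMin + stats::rpois(1, 0.8)
    nTrio <- min(sample(1:2, 1L), nShared)
    trio <- .drawEvents(.SPECTRA$trio, nTrio, build, spec)
    rest <- .drawEvents(.SPECTRA$sharedExtra, nShared - nTrio, build, spec,
                        trio$occupied)
    shared <- c(trio$events, rest$events)
    occupied <- rest$occupied
    papEvents <- shared
    carcEvents <- shared
    if (stats::runif(1) < spec@clonalExtraCnaRate) {
      extra <- .drawEvents(.SPECTRA$carcinomaExtra, sample(1:3, 1L), build,
                           spec, occupied)
      carcEvents <- c(carcEvents, extra$events)
      occupied <- extra$occupied
    }
    if (stats::runif(1) < 4 / 11) {
      own <- .drawEvents(.SPECTRA$carcinomaExtra, 1L, build, spec, occupied)
      papEvents <- c(papEvents, own$events)
    }
    nSharedMut <- sample(1:2, 1L, prob = c(2, 1))
    sharedMut <- .drawMutations(sample(.SHARED_GENES, nSharedMut),
                                vafRange = c(0.2, 0.45))
    papMut <- sharedMut
    papMut$vaf <- round(pmin(pmax(sharedMut$vaf * stats::runif(nSharedMut, 0.8, 1.2),
                                  0.05), 0.6), 3)
    papPriv <- .drawMutations(sample(setdiff(.PASSENGER_GENES, "TP53"),
                                     sample(0:1, 1L)))
    carcPriv <- .drawMutations(sample(.PASSENGER_GENES, sample(0:2, 1L)))
    papMutAll <- rbind(papMut, papPriv)
    carcMutAll <- rbind(sharedMut, carcPriv)
  } else {
    histology <- if (stats::runif(1) < 2 / 9) "atypical" else "benign"
    carc <- .drawEvents(.SPECTRA$nonclonalCarcinoma, sample(2:6, 1L), build, spec)
    carcEvents <- carc$events
    papEvents <- list()
    if (stats::runif(1) >= 8 / 9 && length(carcEvents)) {
      # coincidental same-arm event, breakpoints jittered far beyond tolerance
      src <- carcEvents[[1]]
      jit <- spec@breakpointJitterNonclonal
      lens <- chromLengths(build)
      s <- .snapInterval(src$start + jit, min(src$end - jit, src$start + jit + 2e7),
                         spec@binSize, lens[[src$chrom]])
      if (s[2] - s[1] > 6e6) {
        ev <- list(chrom = src$chrom, start = s[1], end = s[2],
                   direction = src$direction,
                   log2 = src$log2 + stats::runif(1, -0.02, 0.02))
        papEvents <- list(ev)
      }
    }
    shared <- list()
    papMutAll <- .drawMutations(sample(.PASSENGER_GENES, sample(1:2, 1L)))
    if (stats::runif(1) < 2 / 6)
      papMutAll <- rbind(papMutAll, data.frame(gene = "PIK3CA",
        protein_change = sample(.PIK3CA_HOTSPOTS, 1L),
        vaf = round(stats::runif(1, 0.1, 0.4), 3),
        classification = "missense", stringsAsFactors = FALSE))
    carcMutAll <- .drawMutations(sample(setdiff(.PASSENGER_GENES,
                                                papMutAll$gene),
                                        sample(1:3, 1L)))
    sharedMut <- .emptyMutations()
  }
  papId <- paste0(caseId, "_P")
  carcId <- paste0(caseId, "_C")
  list(case_id = caseId, group = if (clonal) "clonal" else "non_clonal",
       histology = histology, clonal = clonal,
       grade = grade,
       components = list(
         P = list(sample_id = papId, component = "papilloma",
                  truthCalls = .eventsToGRanges(papEvents, build, spec),
                  mutations = papMutAll),
         C = list(sample_id = carcId, component = carcComponent,
                  truthCalls = .eventsToGRanges(carcEvents, build, spec),
                  mutations = carcMutAll)),
       shared_cnas = .eventsToGRanges(shared, build, spec),
       shared_mutations = sharedMut)
}

# Render one profile's bin-level log2 vectors: truth + sinusoidal wave
# (random phase per profile, 10 Mb period) + Gaussian noise.
.renderBins <- function(truthCalls, spec, build) {
  lens <- chromLengths(build)
  phase <- stats::runif(1, 0, 2 * pi)
  wavePeriod <- 1e7
  evChrom <- as.character(seqnames(truthCalls))
  evStart <- start(truthCalls)
  evEnd <- end(truthCalls)
  evLog2 <- mcols(truthCalls)$log2
  out <- lapply(names(lens), function(ch) {
    starts <- seq(1, lens[[ch]], by = spec@binSize)
    ends <- pmin(starts + spec@binSize - 1, lens[[ch]])
    x <- numeric(length(starts))
    for (i in which(evChrom == ch))
      x[starts >= evStart[i] & ends <= evEnd[i]] <- evLog2[i]
    centers <- (starts + ends) / 2
    if (spec@waveAmplitude > 0)
      x <- x + spec@waveAmplitude * sin(2 * pi * centers / wavePeriod + phase)
    if (spec@noiseSd > 0)
      x <- x + stats::rnorm(length(x), 0, spec@noiseSd)
    x
  })
  stats::setNames(out, names(lens))
}

#' Generate a synthetic background mutation-frequency table
#'
#' Emulates the frequency architecture of a large breast-carcinoma
#' reference cohort (n = 977): a handful of frequently mutated genes
#' (PIK3CA near 0.33 with named hotspot variants, TP53 near 0.30), a
#' moderate tier, and a long tail floored at 1/977.
#'
#' @param seed integer seed (the table is deterministic given the seed).
#' @param nGenes number of long-tail genes to add.
#' @param cohortSize reference cohort size.
#' @return a \code{\link{BackgroundFrequencyTable}}.
#' @export
generateBackgroundFreqs <- function(seed = NULL, nGenes = 150, cohortSize = 977) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (nGenes < 1) stop("nGenes must be >= 1")
  fixed <- data.frame(
    gene = c("PIK3CA", "PIK3CA", "PIK3CA", "PIK3CA", "TP53", "GATA3",
             "CDH1", "MAP3K1", "KMT2C", "AKT1", "ARID1A", "SPEN", "PIK3R1",
             "RUNX1", "CBFB", "ERBB3", "HRAS", "SF3B1", "MAP2K4", "NF1",
             "PIK3R3"),
    protein_change = c("E545K", "H1047R", "E542K", "*", "*", "*", "*", "*",
                       "*", "*", "*", "*", "*", "*", "*", "*", "*", "*",
                       "*", "*", "*"),
    frequency = c(0.07, 0.13, 0.04, 0.33, 0.30, 0.11, 0.12, 0.08, 0.07,
                  0.025, 0.04, 0.03, 0.03, 0.035, 0.02, 0.02, 0.01, 0.018,
                  0.04, 0.03, 0.012),
    stringsAsFactors = FALSE)
  tailGenes <- sprintf("GENE%03d", seq_len(nGenes))
  floorF <- 1 / cohortSize
  tailF <- pmin(pmax(stats::rlnorm(nGenes, log(3 / cohortSize), 1), floorF), 0.05)
  tail <- data.frame(gene = tailGenes, protein_change = "*",
                     frequency = round(tailF, 6), stringsAsFactors = FALSE)
  BackgroundFrequencyTable(rbind(fixed, tail), cohortSize = cohortSize)
}

#' Write a synthetic cohort to disk
#'
#' Emits \code{cohort.seg} (segment-level export: the truth partition of
#' each chromosome with, when bins were rendered, the realised mean log2
#' of each interval), \code{mutations.tsv}, \code{freq.tsv} and
#' \code{truth.json}.
#'
#' @param cohort a \code{\link{SyntheticCohort}}.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- cohort@spec
  build <- cohort@build
  profiles <- list()
  mutations <- list()
  for (case in cohort@truth) {
    for (comp in case$components) {
      seg <- .truthPartition(comp$truthCalls, build)
      v <- cohort@bins[[comp$sample_id]]
      if (!is.null(v)) {
        lens <- chromLengths(build)
        ml <- vapply(seq_along(seg), function(i) {
          ch <- as.character(seqnames(seg)[i])
          j1 <- ceiling(start(seg)[i] / spec@binSize)
          j2 <- ceiling(end(seg)[i] / spec@binSize)
          mean(v[[ch]][j1:j2])
        }, numeric(1))
        mcols(seg)$log2 <- ml
      }
      profiles[[comp$sample_id]] <- LesionProfile(comp$sample_id, seg,
                                                  comp$mutations,
                                                  component = comp$component)
      mutations[[comp$sample_id]] <- comp$mutations
    }
  }
  paths <- c(seg = file.path(dir, "cohort.seg"),
             mutations = file.path(dir, "mutations.tsv"),
             freq = file.path(dir, "freq.tsv"),
             truth = file.path(dir, "truth.json"))
  hdr <- .provenanceHeader(spec)
  writeSeg(profiles, paths["seg"], header = hdr)
  writeMutations(mutations, paths["mutations"], header = hdr)
  writeFrequencyTable(cohort@background, paths["freq"])
  jsonlite::write_json(.truthAsJson(cohort@truth), paths["truth"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths
}

# Truth partition of the genome: event intervals plus neutral gaps, tiling
# every chromosome.
.truthPartition <- function(truthCalls, build) {
  lens <- chromLengths(build)
  si <- buildSeqinfo(build)
  out <- lapply(names(lens), function(ch) {
    ev <- truthCalls[as.character(seqnames(truthCalls)) == ch]
    ev <- GenomicRanges::sort(ev)
    bounds <- c(1, as.vector(rbind(start(ev), end(ev) + 1)), lens[[ch]] + 1)
    s <- bounds[-length(bounds)]
    e <- bounds[-1] - 1
    keep <- e >= s
    lg <- numeric(sum(keep))
    gr <- GRanges(ch, IRanges(s[keep], e[keep]), seqinfo = si)
    lg <- rep(0, length(gr))
    if (length(ev)) {
      hit <- findOverlaps(gr, ev, type = "equal")
      lg[queryHits(hit)] <- mcols(ev)$log2[subjectHits(hit)]
    }
    mcols(gr)$log2 <- lg
    gr
  })
  GenomicRanges::sort(do.call(c, out))
}

.grToJson <- function(gr) {
  if (!length(gr)) return(list())
  lapply(seq_along(gr), function(i) list(
    chrom = as.character(seqnames(gr)[i]), start = start(gr)[i],
    end = end(gr)[i], direction = mcols(gr)$direction[i],
    log2 = mcols(gr)$log2[i]))
}

.truthAsJson <- function(truth) {
  lapply(truth, function(case) list(
    case_id = case$case_id, group = case$group, histology = case$histology,
    clonal = case$clonal,
    components = lapply(case$components, function(comp) list(
      sample_id = comp$sample_id, component = comp$component,
      cnas = .grToJson(comp$truthCalls),
      mutations = comp$mutations)),
    shared_mutations = case$shared_mutations))
}

.provenanceHeader <- function(spec) {
  cfg <- paste0("nPure=", spec@nPure, ",nClonal=", spec@nClonal,
                ",nNonclonal=", spec@nNonclonal, ",seed=", spec@seed,
                ",noiseSd=", spec@noiseSd, ",wave=", spec@waveAmplitude,
                ",binSize=", spec@binSize)
  paste0("papclone ", as.character(utils::packageVersion("papclone")),
         "; ", cfg)
}
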