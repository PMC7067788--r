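#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom GenomeInfoDb Seqinfo seqinfo seqlengths seqlevels
NULL

.COMPONENTS <- c("papilloma", "DCIS", "IDC", "papillary_DCIS", "mucinous", "unknown")
.HISTOLOGIES <- c("benign", "atypical", "LG", "IG", "HG", "unknown")

#' Genome model for copy-number analysis
#'
#' A \code{GenomeBuild} carries the ordered chromosomes (1--22 and X; the Y
#' chromosome is excluded, as the method targets breast lesions), their
#' lengths and centromere positions.  Arm attribution of copy-number calls
#' and the fraction-of-genome-altered denominator both derive from it.
#'
#' @slot name text label for the build (e.g. \code{"GRCh37"}).
#' @slot chromosomes \code{data.frame} with columns \code{chrom},
#'   \code{length} and \code{centromere} (bp).
#' @export
setClass("GenomeBuild",
  representation(name = "character", chromosomes = "data.frame"))

setValidity("GenomeBuild", function(object) {
  ch <- object@chromosomes
  msg <- character()
  need <- c("chrom", "length", "centromere")
  if (!all(need %in% names(ch)))
    return(paste("chromosomes must have columns", paste(need, collapse = ", ")))
  if (nrow(ch) != 23L)
    msg <- c(msg, "exactly 23 chromosomes (1-22, X) are required")
  if (anyDuplicated(ch$chrom))
    msg <- c(msg, "duplicated chromosome names")
  if (any(grepl("^chr", ch$chrom)))
    msg <- c(msg, "chromosome names must not carry a 'chr' prefix")
  if (any(ch$length <= 0))
    msg <- c(msg, "all chromosome lengths must be positive")
  if (any(ch$centromere <= 0 | ch$centromere >= ch$length))
    msg <- c(msg, "centromere positions must lie strictly inside (0, length)")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeBuild
#'
#' @param name build label.
#' @param chromosomes data.frame with columns \code{chrom}, \code{length},
#'   \code{centromere}; \code{chr} prefixes are stripped.
#' @return a \code{GenomeBuild}.
#' @export
GenomeBuild <- function(name, chromosomes) {
  chromosomes$chrom <- normalizeChrom(chromosomes$chrom)
  new("GenomeBuild", name = name,
      chromosomes = as.data.frame(chromosomes)[, c("chrom", "length", "centromere")])
}

#' Bundled GRCh37 genome build (chr1-22, X)
#'
#' @return a \code{GenomeBuild} with hg19/GRCh37 chromosome lengths and
#'   centromere midpoints.
#' @examples
#' b <- grch37Build()
#' chromLengths(b)[["16"]]
#' @export
grch37Build <- function() {
  path <- system.file("extdata", "grch37_chromosomes.tsv", package = "papclone")
  GenomeBuild("GRCh37", utils::read.delim(path, colClasses = c("character", "numeric", "numeric")))
}

#' Strip 'chr' prefixes from chromosome names
#' @param x character vector of chromosome names.
#' @return normalized names.
#' @export
normalizeChrom <- function(x) sub("^chr", "", as.character(x))

#' @describeIn GenomeBuild-class chromosome names in build order.
#' @param build a \code{GenomeBuild}.
#' @export
chromNames <- function(build) build@chromosomes$chrom

#' Named chromosome lengths of a build
#' @param build a \code{GenomeBuild}.
#' @return named numeric vector of lengths in bp.
#' @export
chromLengths <- function(build) {
  stats::setNames(build@chromosomes$length, build@chromosomes$chrom)
}

#' Named centromere positions of a build
#' @param build a \code{GenomeBuild}.
#' @return named numeric vector of centromere positions in bp.
#' @export
centromeres <- function(build) {
  stats::setNames(build@chromosomes$centromere, build@chromosomes$chrom)
}

#' Seqinfo view of a build (for GRanges construction)
#' @param build a \code{GenomeBuild}.
#' @return a \code{Seqinfo}.
#' @export
buildSeqinfo <- function(build) {
  Seqinfo(seqnames = chromNames(build),
          seqlengths = unname(chromLengths(build)),
          genome = build@name)
}

setMethod("show", "GenomeBuild", function(object) {
  cat("GenomeBuild", object@name, "with", nrow(object@chromosomes),
      "chromosomes;", sprintf("%.2f Gb total\n", sum(object@chromosomes$length) / 1e9))
})

#' One micro-dissected lesion component
#'
#' A \code{LesionProfile} holds the copy-number evidence (segmented mean
#' log2-ratio intervals as a \code{GRanges} with a \code{log2} metadata
#' column and an optional \code{allelic_state} column) and the somatic
#' mutation records of one dissected component (papilloma, DCIS, IDC, ...).
#'
#' Mutation tables have columns \code{gene}, \code{protein_change} and
#' optionally \code{vaf} (variant allele fraction in [0, 1]).  A component
#' that was never sequenced for mutations carries
#' \code{mutationsAssayed = FALSE}; this is distinct from an assayed
#' component in which no mutation was found.
#'
#' @slot sampleId sample identifier.
#' @slot component one of papilloma, DCIS, IDC, papillary_DCIS, mucinous, unknown.
#' @slot histology one of benign, atypical, LG, IG, HG, unknown.
#' @slot segments \code{GRanges} of non-overlapping, sorted segments with a
#'   numeric \code{log2} column.
#' @slot mutations \code{data.frame} of mutation records.
#' @slot mutationsAssayed logical; \code{FALSE} when no mutation data exist.
#' @export
setClass("LesionProfile",
  representation(sampleId = "character", component = "character",
                 histology = "character", segments = "GRanges",
                 mutations = "data.frame", mutationsAssayed = "logical"))

setValidity("LesionProfile", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L) msg <- c(msg, "sampleId must be a single string")
  if (!object@component %in% .COMPONENTS)
    msg <- c(msg, paste("component must be one of", paste(.COMPONENTS, collapse = ", ")))
  if (!object@histology %in% .HISTOLOGIES)
    msg <- c(msg, paste("histology must be one of", paste(.HISTOLOGIES, collapse = ", ")))
  seg <- object@segments
  if (length(seg)) {
    if (!"log2" %in% names(mcols(seg)) || !is.numeric(mcols(seg)$log2))
      msg <- c(msg, "segments need a numeric 'log2' metadata column")
    if (.hasOverlapWithin(seg))
      msg <- c(msg, "segments of one profile must not overlap")
  }
  mut <- object@mutations
  if (nrow(mut)) {
    if (!all(c("gene", "protein_change") %in% names(mut)))
      msg <- c(msg, "mutations need 'gene' and 'protein_change' columns")
    if ("vaf" %in% names(mut)) {
      v <- mut$vaf[!is.na(mut$vaf)]
      if (length(v) && (any(v < 0) || any(v > 1)))
        msg <- c(msg, "vaf values must lie in [0, 1]")
    }
  }
  if (length(msg)) msg else TRUE
})

.hasOverlapWithin <- function(gr) {
  if (length(gr) < 2L) return(FALSE)
  hits <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  length(hits) > 0L
}

.emptyMutations <- function() {
  data.frame(gene = character(), protein_change = character(),
             vaf = numeric(), classification = character(),
             stringsAsFactors = FALSE)
}

#' Construct a LesionProfile
#'
#' @param sampleId sample identifier.
#' @param segments \code{GRanges} with a numeric \code{log2} column; sorted
#'   on construction.
#' @param mutations mutation \code{data.frame} (columns \code{gene},
#'   \code{protein_change}, optional \code{vaf}), or \code{NULL} when the
#'   component was not assayed for mutations.
#' @param component,histology lesion annotations.
#' @return a \code{LesionProfile}.
#' @export
LesionProfile <- function(sampleId, segments = GRanges(), mutations = NULL,
                          component = "unknown", histology = "unknown") {
  segments <- GenomicRanges::sort(segments)
  assayed <- !is.null(mutations)
  if (is.null(mutations)) mutations <- .emptyMutations()
  mutations <- as.data.frame(mutations)
  new("LesionProfile", sampleId = sampleId, component = component,
      histology = histology, segments = segments,
      mutations = mutations, mutationsAssayed = assayed)
}

#' @describeIn LesionProfile-class sample identifier.
#' @param x a \code{LesionProfile}.
#' @export
sampleId <- function(x) x@sampleId

#' Segment ranges of a lesion profile
#' @param x a \code{LesionProfile}.
#' @return \code{GRanges} of segments with \code{log2} metadata.
#' @export
cnSegments <- function(x) x@segments

#' Mutation records of a lesion profile
#' @param x a \code{LesionProfile}.
#' @return mutation \code{data.frame}.
#' @export
mutationTable <- function(x) x@mutations

#' Whether a profile carries mutation data
#' @param x a \code{LesionProfile}.
#' @export
mutationsAssayed <- function(x) x@mutationsAssayed

#' @describeIn LesionProfile-class component label.
#' @export
component <- function(x) x@component

#' @describeIn LesionProfile-class histology label.
#' @export
histology <- function(x) x@histology

setMethod("show", "LesionProfile", function(object) {
  cat("LesionProfile", object@sampleId,
      sprintf("(%s, %s): %d segments, %d mutations%s\n",
              object@component, object@histology, length(object@segments),
              nrow(object@mutations),
              if (object@mutationsAssayed) "" else " (not assayed)"))
})

#' Copy-number calling parameters
#'
#' Holds the thresholds and size filters for turning segmented log2-ratio
#' profiles into gain/loss calls: segments with mean log2 ratio above
#' \code{gainThreshold} (+0.15) become gains and below \code{lossThreshold}
#' (-0.15) losses, both strict; calls shorter than \code{noiseFilter} (1 Mb)
#' are discarded as noise, and only calls longer than
#' \code{reportingFilter} (5 Mb, strict) enter cohort event counts.
#' Adjacent same-direction calls separated by at most \code{mergeGap}
#' (one 50 kb bin) are merged, since segmentation can fragment a single
#' arm-level event.
#'
#' @export
setClass("CallingConfig",
  representation(gainThreshold = "numeric", lossThreshold = "numeric",
                 noiseFilter = "numeric", reportingFilter = "numeric",
                 mergeGap = "numeric"))

setValidity("CallingConfig", function(object) {
  msg <- character()
  if (!(object@lossThreshold < 0 && 0 < object@gainThreshold))
    msg <- c(msg, "need lossThreshold < 0 < gainThreshold")
  if (object@noiseFilter > object@reportingFilter)
    msg <- c(msg, "noiseFilter must not exceed reportingFilter")
  if (object@mergeGap < 0) msg <- c(msg, "mergeGap must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct calling parameters
#' @param gainThreshold log2 ratio above which a segment is a gain (strict).
#' @param lossThreshold log2 ratio below which a segment is a loss (strict).
#' @param noiseFilter minimum call length kept, bp.
#' @param reportingFilter length a call must exceed (strictly) to be
#'   reportable, bp.
#' @param mergeGap maximum gap bridged when merging adjacent same-direction
#'   calls, bp.
#' @return a \code{CallingConfig}.
#' @export
CallingConfig <- function(gainThreshold = 0.15, lossThreshold = -0.15,
                          noiseFilter = 1e6, reportingFilter = 5e6,
                          mergeGap = 5e4) {
  new("CallingConfig", gainThreshold = gainThreshold,
      lossThreshold = lossThreshold, noiseFilter = noiseFilter,
      reportingFilter = reportingFilter, mergeGap = mergeGap)
}

setMethod("show", "CallingConfig", function(object) {
  cat(sprintf("CallingConfig: gain > %g, loss < %g, noise filter %g bp, reporting filter %g bp, merge gap %g bp\n",
              object@gainThreshold, object@lossThreshold, object@noiseFilter,
              object@reportingFilter, object@mergeGap))
})

#' Clonality-assessment parameters
#'
#' \code{tolerance} is the maximum distance (bp) between two components'
#' copy-number breakpoints for them to count as shared (default 50 kb, the
#' bin resolution of the copy-number data).  \code{ciThreshold} is the
#' clonality-index cutoff (pairs with CI > 0.8 are clonal);
#' \code{ci2Threshold} the alternative index cutoff (2.84).
#' \code{frequencyFloor} (1/977) is applied to background mutation
#' frequencies of variants unobserved in the reference cohort.
#' \code{centromereInformative} controls whether a shared breakpoint lying
#' at a centromere (the proximal boundary of a whole-arm event) counts as
#' informative; breakpoints at chromosome termini never do.
#'
#' @export
setClass("ClonalityConfig",
  representation(tolerance = "numeric", ciThreshold = "numeric",
                 ci2Threshold = "numeric", frequencyFloor = "numeric",
                 centromereInformative = "logical"))

setValidity("ClonalityConfig", function(object) {
  msg <- character()
  if (object@tolerance < 0) msg <- c(msg, "tolerance must be >= 0")
  if (!(object@ciThreshold > 0 && object@ciThreshold < 1))
    msg <- c(msg, "ciThreshold must lie in (0, 1)")
  if (object@frequencyFloor <= 0 || object@frequencyFloor > 1)
    msg <- c(msg, "frequencyFloor must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct clonality parameters
#' @param tolerance breakpoint matching tolerance, bp.
#' @param ciThreshold clonality-index cutoff.
#' @param ci2Threshold alternative (log-scale) index cutoff.
#' @param frequencyFloor floor for background mutation frequencies.
#' @param centromereInformative treat centromere-side breakpoints as
#'   informative.
#' @return a \code{ClonalityConfig}.
#' @export
ClonalityConfig <- function(tolerance = 5e4, ciThreshold = 0.8,
                            ci2Threshold = 2.84, frequencyFloor = 1 / 977,
                            centromereInformative = TRUE) {
  new("ClonalityConfig", tolerance = tolerance, ciThreshold = ciThreshold,
      ci2Threshold = ci2Threshold, frequencyFloor = frequencyFloor,
      centromereInformative = centromereInformative)
}

setMethod("show", "ClonalityConfig", function(object) {
  cat(sprintf("ClonalityConfig: tolerance %g bp, CI > %g, CI2 > %g, frequency floor %.3g\n",
              object@tolerance, object@ciThreshold, object@ci2Threshold,
              object@frequencyFloor))
})

#' Background mutation-frequency table
#'
#' Maps mutations to the fraction of a reference breast-carcinoma cohort
#' carrying them, at variant level (gene + protein change) with a
#' gene-level fallback (rows with \code{protein_change == "*"}).  Variants
#' absent from the table are floored at \code{1/cohortSize}, so a single
#' shared mutation can never push the clonality index to exactly 1.
#'
#' @slot entries \code{data.frame} with columns \code{gene},
#'   \code{protein_change} (\code{"*"} for gene-level rows) and
#'   \code{frequency} in (0, 1].
#' @slot cohortSize reference cohort size (default 977).
#' @export
setClass("BackgroundFrequencyTable",
  representation(entries = "data.frame", cohortSize = "numeric"))

setValidity("BackgroundFrequencyTable", function(object) {
  msg <- character()
  need <- c("gene", "protein_change", "frequency")
  if (!all(need %in% names(object@entries)))
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  f <- object@entries$frequency
  if (length(f) && (any(f <= 0) || any(f > 1)))
    msg <- c(msg, "frequencies must lie in (0, 1]")
  if (object@cohortSize < 1) msg <- c(msg, "cohortSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a background frequency table
#' @param entries data.frame with gene, protein_change ("*" = gene level),
#'   frequency.
#' @param cohortSize reference cohort size; the frequency floor is
#'   \code{1/cohortSize}.
#' @return a \code{BackgroundFrequencyTable}.
#' @export
BackgroundFrequencyTable <- function(entries, cohortSize = 977) {
  new("BackgroundFrequencyTable", entries = as.data.frame(entries),
      cohortSize = cohortSize)
}

#' Look up background frequencies for mutations
#'
#' Variant-level match first, then gene-level (\code{"*"}) fallback, then
#' the floor \code{1/cohortSize}; results are additionally floored so no
#' frequency falls below the floor.
#'
#' @param bg a \code{BackgroundFrequencyTable}.
#' @param gene,protein_change character vectors (recycled to equal length).
#' @return numeric vector of frequencies in (0, 1].
#' @export
lookupFrequency <- function(bg, gene, protein_change) {
  n <- max(length(gene), length(protein_change))
  gene <- rep_len(as.character(gene), n)
  protein_change <- rep_len(as.character(protein_change), n)
  floorF <- 1 / bg@cohortSize
  ent <- bg@entries
  variantKey <- paste(ent$gene, ent$protein_change, sep = "\r")
  out <- numeric(n)
  for (i in seq_len(n)) {
    hit <- match(paste(gene[i], protein_change[i], sep = "\r"), variantKey)
    if (is.na(hit))
      hit <- match(paste(gene[i], "*", sep = "\r"), variantKey)
    out[i] <- if (is.na(hit)) floorF else ent$frequency[hit]
  }
  pmax(out, floorF)
}

setMethod("show", "BackgroundFrequencyTable", function(object) {
  cat("BackgroundFrequencyTable:", nrow(object@entries), "entries, cohort size",
      object@cohortSize, sprintf("(floor %.3g)\n", 1 / object@cohortSize))
})

#' Paired-lesion clonality decision
#'
#' Produced by \code{\link{assessClonality}}.  The copy-number verdict is
#' \code{clonal} when the two components share at least one informative
#' breakpoint of the same alteration direction, \code{uninformative} when
#' either component has no calls, otherwise \code{non_clonal}.  The
#' mutation channel contributes the clonality indices CI and CI2 computed
#' from shared mutations.  The combined verdict is clonal when either the
#' copy-number rule fires or CI exceeds its threshold; \code{discordant}
#' flags pairs where the two informative channels disagree.
#'
#' @export
setClass("ClonalityVerdict",
  representation(caseId = "character", cnVerdict = "character",
                 sharedBreakpoints = "data.frame", sharedCnaCount = "numeric",
                 ci = "numeric", ci2 = "numeric",
                 combinedVerdict = "character", discordant = "logical"))

setValidity("ClonalityVerdict", function(object) {
  msg <- character()
  if (!object@cnVerdict %in% c("clonal", "non_clonal", "uninformative"))
    msg <- c(msg, "cnVerdict must be clonal/non_clonal/uninformative")
  if (!object@combinedVerdict %in% c("clonal", "non_clonal"))
    msg <- c(msg, "combinedVerdict must be clonal/non_clonal")
  if (object@cnVerdict == "clonal") {
    bp <- object@sharedBreakpoints
    if (!nrow(bp) || !any(bp$informative))
      msg <- c(msg, "a clonal CN verdict requires >= 1 informative shared breakpoint")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ClonalityVerdict-class combined clonal/non-clonal decision.
#' @param x a \code{ClonalityVerdict}.
#' @export
combinedVerdict <- function(x) x@combinedVerdict

#' @describeIn ClonalityVerdict-class copy-number channel verdict.
#' @export
cnVerdict <- function(x) x@cnVerdict

#' Shared breakpoints behind a verdict
#' @param x a \code{ClonalityVerdict}.
#' @return \code{data.frame} of matched breakpoints.
#' @export
sharedBreakpoints <- function(x) x@sharedBreakpoints

#' @describeIn ClonalityVerdict-class clonality index (NA when no mutation
#'   data).
#' @export
clonalityCI <- function(x) x@ci

#' @describeIn ClonalityVerdict-class alternative clonality index.
#' @export
clonalityCI2 <- function(x) x@ci2

setMethod("show", "ClonalityVerdict", function(object) {
  nInf <- sum(object@sharedBreakpoints$informative)
  cat(sprintf("ClonalityVerdict %s: %s (CN: %s, %d informative shared breakpoint%s, %d shared CNA%s; CI = %s, CI2 = %s)%s\n",
              object@caseId, object@combinedVerdict, object@cnVerdict,
              nInf, if (nInf == 1) "" else "s",
              object@sharedCnaCount, if (object@sharedCnaCount == 1) "" else "s",
              if (is.na(object@ci)) "NA" else sprintf("%.3f", object@ci),
              if (is.na(object@ci2)) "NA" else sprintf("%.2f", object@ci2),
              if (isTRUE(object@discordant)) " [discordant]" else ""))
})

#' Synthetic-cohort generation parameters
#'
#' Defaults encode the cohort architecture the analysis assumes: pure
#' papillomas carry a copy-number alteration with probability 0.37 and an
#' activating PIK3CA hotspot mutation with probability 0.69; clonal
#' papilloma--carcinoma pairs share at least three alterations (always
#' including one of 1q gain / 16q loss / 11q loss) with identical
#' breakpoints and never carry PIK3CA, the carcinoma gaining extra
#' alterations with probability 0.73; non-clonal papillomas are mostly
#' alteration-free (8/9), and any coincidental same-arm alteration has its
#' breakpoints jittered well beyond the matching tolerance.  Bin-level
#' noise is Gaussian (sd 0.1 log2 units) plus a low-amplitude sinusoidal
#' wave emulating FFPE artefacts.
#'
#' @export
setClass("CohortSpec",
  representation(nPure = "numeric", nClonal = "numeric", nNonclonal = "numeric",
                 seed = "numeric", noiseSd = "numeric", waveAmplitude = "numeric",
                 binSize = "numeric", purePik3caRate = "numeric",
                 pureCnaRate = "numeric", clonalExtraCnaRate = "numeric",
                 sharedCnaMin = "numeric", breakpointJitterNonclonal = "numeric",
                 gainLog2 = "numeric", lossLog2 = "numeric"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  rates <- c(object@purePik3caRate, object@pureCnaRate, object@clonalExtraCnaRate)
  if (any(rates < 0 | rates > 1)) msg <- c(msg, "rates must lie in [0, 1]")
  if (object@binSize <= 0) msg <- c(msg, "binSize must be positive")
  if (object@nPure + object@nClonal + object@nNonclonal < 1)
    msg <- c(msg, "at least one case must be requested")
  if (object@noiseSd < 0 || object@waveAmplitude < 0)
    msg <- c(msg, "noiseSd and waveAmplitude must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic-cohort specification
#'
#' @param nPure,nClonal,nNonclonal case counts per group (defaults 27/13/10,
#'   a 50-case cohort preserving the 24/11/9 group architecture).
#' @param seed integer seed governing all randomness.
#' @param noiseSd bin-level Gaussian noise sd, log2 units.
#' @param waveAmplitude amplitude of the sinusoidal FFPE wave, log2 units.
#' @param binSize bin width, bp.
#' @param purePik3caRate PIK3CA hotspot probability in pure cases.
#' @param pureCnaRate probability a pure case carries any alteration.
#' @param clonalExtraCnaRate probability the carcinoma of a clonal pair has
#'   extra private alterations.
#' @param sharedCnaMin minimum shared alterations per clonal pair.
#' @param breakpointJitterNonclonal jitter (bp) applied to coincidental
#'   same-arm alterations of non-clonal pairs (>= 5x the matching
#'   tolerance).
#' @param gainLog2,lossLog2 event log2 ratios (single-copy gain/loss at
#'   roughly 70 percent tumour purity).
#' @return a \code{CohortSpec}.
#' @export
CohortSpec <- function(nPure = 27, nClonal = 13, nNonclonal = 10, seed = 1,
                       noiseSd = 0.1, waveAmplitude = 0.05, binSize = 5e4,
                       purePik3caRate = 0.69, pureCnaRate = 0.37,
                       clonalExtraCnaRate = 0.73, sharedCnaMin = 3,
                       breakpointJitterNonclonal = 2.5e5,
                       gainLog2 = 0.32, lossLog2 = -0.55) {
  new("CohortSpec", nPure = nPure, nClonal = nClonal, nNonclonal = nNonclonal,
      seed = seed, noiseSd = noiseSd, waveAmplitude = waveAmplitude,
      binSize = binSize, purePik3caRate = purePik3caRate,
      pureCnaRate = pureCnaRate, clonalExtraCnaRate = clonalExtraCnaRate,
      sharedCnaMin = sharedCnaMin,
      breakpointJitterNonclonal = breakpointJitterNonclonal,
      gainLog2 = gainLog2, lossLog2 = lossLog2)
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d pure + %d clonal + %d non-clonal cases (seed %d, noise sd %.2g, wave %.2g)\n",
              object@nPure, object@nClonal, object@nNonclonal,
              as.integer(object@seed), object@noiseSd, object@waveAmplitude))
})
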