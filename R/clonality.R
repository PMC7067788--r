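#' Match copy-number breakpoints between two components
#'
#' Every call contributes two breakpoints (its start and end boundary).
#' Boundaries of the two components are candidates for matching when they
#' lie on the same chromosome, on the same side (start vs start, end vs
#' end), belong to calls of the same direction, and are at most
#' \code{tolerance} bp apart.  Candidates are paired greedily
#' nearest-first (ties broken by leftmost position), each boundary used at
#' most once.  A matched breakpoint is informative unless it lies within
#' tolerance of a chromosome terminus (or, when
#' \code{centromereInformative} is off, of the centromere), since
#' whole-arm events shared by chance would otherwise auto-trigger
#' clonality.
#'
#' @param a,b \code{GRanges} of calls (with \code{direction} metadata) for
#'   the two components of one case.
#' @param build a \code{\link{GenomeBuild}}.
#' @param config a \code{\link{ClonalityConfig}}.
#' @return \code{data.frame} with columns \code{chrom}, \code{side},
#'   \code{direction}, \code{pos_a}, \code{pos_b}, \code{position}
#'   (midpoint), \code{offset} and \code{informative}, ordered by
#'   (chrom, position).
#' @export
matchBreakpoints <- function(a, b, build, config = ClonalityConfig()) {
  .chk <- function(g, nm) {
    if (length(g) && !all(as.character(seqnames(g)) %in% chromNames(build)))
      stop("calls of '", nm, "' lie outside the genome build")
  }
  .chk(a, "a"); .chk(b, "b")
  ba <- .boundaries(a)
  bb <- .boundaries(b)
  empty <- data.frame(chrom = character(), side = character(),
                      direction = character(), pos_a = numeric(),
                      pos_b = numeric(), position = numeric(),
                      offset = numeric(), informative = logical())
  if (!nrow(ba) || !nrow(bb)) return(empty)
  cand <- merge(ba, bb, by = c("chrom", "side", "direction"),
                suffixes = c("_a", "_b"))
  if (!nrow(cand)) return(empty)
  cand$offset <- abs(cand$pos_a - cand$pos_b)
  cand <- cand[cand$offset <= config@tolerance, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand <- cand[order(cand$offset, pmin(cand$pos_a, cand$pos_b),
                     cand$chrom, cand$side), , drop = FALSE]
  usedA <- character(); usedB <- character()
  keep <- logical(nrow(cand))
  keyA <- paste(cand$chrom, cand$side, cand$direction, cand$id_a)
  keyB <- paste(cand$chrom, cand$side, cand$direction, cand$id_b)
  for (i in seq_len(nrow(cand))) {
    if (!(keyA[i] %in% usedA) && !(keyB[i] %in% usedB)) {
      keep[i] <- TRUE
      usedA <- c(usedA, keyA[i])
      usedB <- c(usedB, keyB[i])
    }
  }
  out <- cand[keep, c("chrom", "side", "direction", "pos_a", "pos_b", "offset"),
              drop = FALSE]
  out$position <- floor((out$pos_a + out$pos_b) / 2)
  lens <- chromLengths(build)
  cens <- centromeres(build)
  tol <- config@tolerance
  terminal <- function(pos, chrom) {
    (pos - 1) <= tol | (lens[chrom] - pos) <= tol
  }
  inf <- !(terminal(out$pos_a, out$chrom) | terminal(out$pos_b, out$chrom))
  if (!config@centromereInformative) {
    nearCen <- abs(out$pos_a - cens[out$chrom]) <= tol |
      abs(out$pos_b - cens[out$chrom]) <= tol
    inf <- inf & !nearCen
  }
  out$informative <- unname(inf)
  out <- out[order(out$chrom, out$position), c("chrom", "side", "direction",
                                               "pos_a", "pos_b", "position",
                                               "offset", "informative")]
  rownames(out) <- NULL
  out
}

# One row per call boundary: start boundaries sit at the call start, end
# boundaries at the call end (1-based inclusive).
.boundaries <- function(calls) {
  if (!length(calls))
    return(data.frame(chrom = character(), side = character(),
                      direction = character(), pos = numeric(), id = integer()))
  chrom <- as.character(seqnames(calls))
  dir <- mcols(calls)$direction
  data.frame(chrom = rep(chrom, 2L),
             side = rep(c("start", "end"), each = length(calls)),
             direction = rep(dir, 2L),
             pos = c(start(calls), end(calls)),
             id = rep(seq_along(calls), 2L),
             stringsAsFactors = FALSE)
}

#' Copy-number clonality verdict for a component pair
#'
#' The pair is \code{clonal} when at least one informative shared
#' breakpoint of matching direction exists; \code{uninformative} when
#' either component has no calls at the noise-filter level (no
#' copy-number evidence either way); otherwise \code{non_clonal} -- even
#' when the components carry the same alteration, sharing the event
#' without sharing a breakpoint is not evidence of common origin.
#'
#' @param a,b \code{\link{LesionProfile}}s of the two components.
#' @param build a \code{\link{GenomeBuild}}.
#' @param callingConfig a \code{\link{CallingConfig}} used to derive calls
#'   from each profile's segments.
#' @param config a \code{\link{ClonalityConfig}}.
#' @return list with \code{cnVerdict}, \code{sharedBreakpoints}
#'   (data.frame), \code{sharedCnaCount} (direction-matched overlapping
#'   call pairs) and the two call sets.
#' @export
cnClonality <- function(a, b, build, callingConfig = CallingConfig(),
                        config = ClonalityConfig()) {
  callsA <- callCnas(cnSegments(a), callingConfig)
  callsB <- callCnas(cnSegments(b), callingConfig)
  if (!length(callsA) || !length(callsB)) {
    return(list(cnVerdict = "uninformative",
                sharedBreakpoints = matchBreakpoints(callsA, callsB, build, config),
                sharedCnaCount = 0L, callsA = callsA, callsB = callsB))
  }
  bp <- matchBreakpoints(callsA, callsB, build, config)
  hits <- findOverlaps(callsA, callsB)
  sameDir <- mcols(callsA)$direction[queryHits(hits)] ==
    mcols(callsB)$direction[subjectHits(hits)]
  verdict <- if (nrow(bp) && any(bp$informative)) "clonal" else "non_clonal"
  list(cnVerdict = verdict, sharedBreakpoints = bp,
       sharedCnaCount = sum(sameDir), callsA = callsA, callsB = callsB)
}

#' Mutations shared by two components
#'
#' Matching is on gene + protein change equality; allele fractions play no
#' role in matching (they only enter the colonization check).
#'
#' @param a,b mutation \code{data.frame}s (columns \code{gene},
#'   \code{protein_change}, optional \code{vaf}).
#' @return \code{data.frame} of shared records with columns \code{gene},
#'   \code{protein_change}, \code{vaf_a}, \code{vaf_b}.
#' @export
sharedMutations <- function(a, b) {
  keyA <- paste(a$gene, a$protein_change, sep = "\r")
  keyB <- paste(b$gene, b$protein_change, sep = "\r")
  ia <- which(keyA %in% keyB)
  ia <- ia[!duplicated(keyA[ia])]
  ib <- match(keyA[ia], keyB)
  data.frame(gene = a$gene[ia], protein_change = a$protein_change[ia],
             vaf_a = if ("vaf" %in% names(a)) a$vaf[ia] else NA_real_,
             vaf_b = if ("vaf" %in% names(b)) b$vaf[ib] else NA_real_,
             stringsAsFactors = FALSE)
}

#' Clonality index from shared mutations
#'
#' CI = 1 - prod(f_k) over the background frequencies f_k of the n shared
#' mutations, and 0 when n = 0.  Rare shared mutations (small f_k) push CI
#' towards 1; ubiquitous ones (f_k = 1) carry no information.  Frequencies
#' are looked up variant-level with gene-level fallback and floored at
#' \code{frequencyFloor}, bounding CI strictly below 1.
#'
#' @param shared shared-mutation \code{data.frame} (from
#'   \code{\link{sharedMutations}}).
#' @param bg a \code{\link{BackgroundFrequencyTable}}.
#' @param config a \code{\link{ClonalityConfig}}.
#' @return CI in [0, 1).
#' @export
clonalityIndex <- function(shared, bg, config = ClonalityConfig()) {
  if (!nrow(shared)) return(0)
  f <- pmax(lookupFrequency(bg, shared$gene, shared$protein_change),
            config@frequencyFloor)
  1 - prod(f)
}

#' Alternative clonality index (log scale)
#'
#' CI2 = -log10(prod(f_k)) with the same frequency lookup and floor; 0
#' when no mutation is shared.  Pairs with CI2 above the 2.84 cutoff are
#' clonal by this channel.
#'
#' @inheritParams clonalityIndex
#' @return CI2 >= 0.
#' @export
clonalityIndex2 <- function(shared, bg, config = ClonalityConfig()) {
  if (!nrow(shared)) return(0)
  f <- pmax(lookupFrequency(bg, shared$gene, shared$protein_change),
            config@frequencyFloor)
  -log10(prod(f))
}

#' Combined clonality verdict for a paired lesion
#'
#' Runs the copy-number channel (\code{\link{cnClonality}}) and, when both
#' components carry mutation data, the mutation channel
#' (\code{\link{clonalityIndex}} / \code{\link{clonalityIndex2}}).  The
#' combined verdict is clonal iff the copy-number rule fires or CI exceeds
#' its threshold; CI2 is reported but never overrides.  The
#' \code{discordant} flag is set when both channels are informative and
#' disagree.
#'
#' @param a,b \code{\link{LesionProfile}}s (papilloma first, carcinoma
#'   second, by convention).
#' @param bg a \code{\link{BackgroundFrequencyTable}} (may be \code{NULL}
#'   when neither component has mutation data).
#' @param build a \code{\link{GenomeBuild}}.
#' @param callingConfig a \code{\link{CallingConfig}}.
#' @param config a \code{\link{ClonalityConfig}}.
#' @param caseId case label for the verdict.
#' @return a \code{\link{ClonalityVerdict}}.
#' @export
assessClonality <- function(a, b, bg = NULL, build = grch37Build(),
                            callingConfig = CallingConfig(),
                            config = ClonalityConfig(),
                            caseId = sub("_[^_]*$", "", sampleId(a))) {
  cn <- cnClonality(a, b, build, callingConfig, config)
  haveMut <- mutationsAssayed(a) && mutationsAssayed(b)
  ci <- ci2 <- NA_real_
  if (haveMut) {
    if (is.null(bg)) stop("mutation data present but no background frequency table supplied")
    shared <- sharedMutations(mutationTable(a), mutationTable(b))
    ci <- clonalityIndex(shared, bg, config)
    ci2 <- clonalityIndex2(shared, bg, config)
  }
  cnInformative <- cn$cnVerdict != "uninformative"
  if (!cnInformative && !haveMut)
    stop("no clonality evidence: both components lack calls and mutation data")
  mutClonal <- haveMut && !is.na(ci) && ci > config@ciThreshold
  combined <- if (cn$cnVerdict == "clonal" || mutClonal) "clonal" else "non_clonal"
  discordant <- cnInformative && haveMut &&
    ((cn$cnVerdict == "clonal") != mutClonal)
  new("ClonalityVerdict", caseId = caseId, cnVerdict = cn$cnVerdict,
      sharedBreakpoints = cn$sharedBreakpoints,
      sharedCnaCount = cn$sharedCnaCount, ci = ci, ci2 = ci2,
      combinedVerdict = combined, discordant = discordant)
}

#' Check shared events for carcinoma colonization (dilution)
#'
#' If the papilloma's shared genetic events were in fact contributed by
#' carcinoma cells colonizing its ducts, the atypical population would be
#' at most ~30 percent of the dissected papilloma, so the papilloma-side
#' signal of every shared event -- copy-number magnitude on the linear
#' scale (|2 * 2^log2 - 2|) and variant allele fraction -- would be
#' diluted to at most that proportion of the carcinoma-side signal.  The
#' check computes the papilloma/carcinoma magnitude ratio per shared event
#' and flags colonization when the median ratio falls below
#' \code{dilution}.
#'
#' @param aCalls,bCalls \code{GRanges} of calls for papilloma (a) and
#'   carcinoma (b) with \code{direction} and \code{mean_log2} metadata;
#'   shared events are direction-matched overlapping pairs.
#' @param sharedMuts shared-mutation \code{data.frame} with \code{vaf_a},
#'   \code{vaf_b} (from \code{\link{sharedMutations}}); may be empty.
#' @param dilution dilution fraction threshold (default 0.30).
#' @return list with \code{status}
#'   (\code{"consistent_with_clonality"}, \code{"suggests_colonization"}
#'   or \code{"uninformative"}), \code{medianRatio} and the per-event
#'   \code{ratios}.
#' @export
colonizationCheck <- function(aCalls, bCalls, sharedMuts = NULL,
                              dilution = 0.30) {
  ratios <- numeric()
  if (length(aCalls) && length(bCalls)) {
    hits <- findOverlaps(aCalls, bCalls)
    qi <- queryHits(hits); si <- subjectHits(hits)
    same <- mcols(aCalls)$direction[qi] == mcols(bCalls)$direction[si]
    qi <- qi[same]; si <- si[same]
    magA <- abs(2 * 2^mcols(aCalls)$mean_log2[qi] - 2)
    magB <- abs(2 * 2^mcols(bCalls)$mean_log2[si] - 2)
    ok <- magB > 0
    ratios <- c(ratios, magA[ok] / magB[ok])
  }
  if (!is.null(sharedMuts) && nrow(sharedMuts)) {
    ok <- !is.na(sharedMuts$vaf_a) & !is.na(sharedMuts$vaf_b) &
      sharedMuts$vaf_b > 0
    ratios <- c(ratios, sharedMuts$vaf_a[ok] / sharedMuts$vaf_b[ok])
  }
  if (!length(ratios))
    return(list(status = "uninformative", medianRatio = NA_real_,
                ratios = ratios))
  med <- stats::median(ratios)
  list(status = if (med < dilution) "suggests_colonization"
                else "consistent_with_clonality",
       medianRatio = med, ratios = ratios)
}
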