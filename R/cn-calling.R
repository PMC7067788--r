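#' Fixed-width bin grid over a genome build
#'
#' @param build a \code{\link{GenomeBuild}}.
#' @param binSize bin width, bp (last bin of each chromosome is truncated).
#' @return \code{GRanges} of bins tiling every chromosome.
#' @export
binGrid <- function(build, binSize = 5e4) {
  lens <- chromLengths(build)
  si <- buildSeqinfo(build)
  grl <- lapply(names(lens), function(ch) {
    s <- seq(1, lens[[ch]], by = binSize)
    GRanges(ch, IRanges(s, pmin(s + binSize - 1, lens[[ch]])), seqinfo = si)
  })
  do.call(c, grl)
}

# Recursive CUSUM binary splitting on one chromosome's bin values.
# Returns sorted split indices k (segment boundary after bin k).
.splitPoints <- function(x, minBins, zThreshold, sdHat) {
  n <- length(x)
  if (n < 2L * minBins) return(integer())
  cs <- cumsum(x)
  k <- seq_len(n - 1L)
  meanL <- cs[k] / k
  meanR <- (cs[n] - cs[k]) / (n - k)
  diff <- abs(meanL - meanR)
  stat <- sqrt(k * (n - k) / n) * diff
  ok <- k >= minBins & k <= n - minBins
  stat[!ok] <- -Inf
  kbest <- which.max(stat)          # ties: smallest index
  # numeric floor so cumsum rounding never splits an exactly constant run
  floorEps <- 1e-10 * max(1, abs(x))
  if (!is.finite(stat[kbest]) || diff[kbest] <= max(zThreshold * sdHat, floorEps))
    return(integer())
  c(.splitPoints(x[seq_len(kbest)], minBins, zThreshold, sdHat),
    kbest,
    kbest + .splitPoints(x[(kbest + 1L):n], minBins, zThreshold, sdHat))
}

# Segment one numeric vector of bin log2 values; returns data.frame
# (startBin, endBin, log2).
.segmentVector <- function(x, minBins, zThreshold) {
  n <- length(x)
  sdHat <- if (n > 1L) stats::mad(diff(x)) / sqrt(2) else 0
  splits <- .splitPoints(x, minBins, zThreshold, sdHat)
  bounds <- c(0L, splits, n)
  s <- bounds[-length(bounds)] + 1L
  e <- bounds[-1]
  means <- vapply(seq_along(s), function(i) mean(x[s[i]:e[i]]), numeric(1))
  data.frame(startBin = s, endBin = e, log2 = means)
}

#' Segment a binned log2 profile into mean-shift segments
#'
#' A greedy binary change-point segmenter: within each chromosome the bin
#' series is recursively split at the maximiser of the standardised CUSUM
#' statistic, and a split is accepted when the absolute difference of the
#' flanking segment means exceeds \code{zThreshold} times the bin-level
#' noise standard deviation (estimated robustly from first differences, so
#' a noiseless piecewise-constant profile is recovered exactly).  Each side
#' of an accepted split must contain at least \code{minBins} bins.
#' Segments tile each chromosome and take the mean log2 of their member
#' bins.
#'
#' @param bins \code{GRanges} of equal-width bins (sorted, tiling each
#'   chromosome) with a numeric \code{log2} metadata column.
#' @param minBins minimum bins on each side of a split.
#' @param zThreshold acceptance threshold in noise-sd units.
#' @return \code{GRanges} of segments with \code{log2} metadata.
#' @export
segmentBins <- function(bins, minBins = 5L, zThreshold = 2.5) {
  if (!length(bins)) stop("empty bin profile")
  if (!"log2" %in% names(mcols(bins))) stop("bins need a 'log2' metadata column")
  bins <- GenomicRanges::sort(bins)
  chroms <- unique(as.character(seqnames(bins)))
  out <- lapply(chroms, function(ch) {
    b <- bins[seqnames(bins) == ch]
    seg <- .segmentVector(mcols(b)$log2, minBins, zThreshold)
    GRanges(ch, IRanges(start(b)[seg$startBin], end(b)[seg$endBin]),
            log2 = seg$log2, seqinfo = seqinfo(bins))
  })
  GenomicRanges::sort(do.call(c, out))
}

#' Call copy-number alterations from segments
#'
#' Segments with mean log2 ratio strictly above the gain threshold (+0.15)
#' become gains, strictly below the loss threshold (-0.15) losses; all
#' others are dropped.  Adjacent same-direction calls separated by at most
#' \code{mergeGap} bp are merged (length-weighted mean log2), then calls
#' shorter than the 1 Mb noise filter are removed.
#'
#' @param segments \code{GRanges} with a numeric \code{log2} column (e.g.
#'   from \code{\link{segmentBins}} or \code{\link{cnSegments}}).
#' @param config a \code{\link{CallingConfig}}.
#' @return sorted \code{GRanges} of calls with \code{direction} and
#'   \code{mean_log2} metadata.
#' @export
callCnas <- function(segments, config = CallingConfig()) {
  if (!length(segments))
    return(GRanges(direction = character(), mean_log2 = numeric(),
                   seqinfo = seqinfo(segments)))
  log2v <- mcols(segments)$log2
  if (is.null(log2v)) log2v <- mcols(segments)$mean_log2
  if (is.null(log2v)) stop("segments need a 'log2' (or 'mean_log2') metadata column")
  ord <- order(as.character(seqnames(segments)), start(segments))
  df <- .callCnasCore(as.character(seqnames(segments))[ord],
                      start(segments)[ord], end(segments)[ord], log2v[ord],
                      config)
  gr <- GRanges(df$chrom, IRanges(df$start, df$end), direction = df$direction,
                mean_log2 = df$mean_log2, seqinfo = seqinfo(segments))
  GenomicRanges::sort(gr)
}

# Vector-level classify + merge + noise filter (chrom/start sorted input).
.callCnasCore <- function(chrom, start, end, log2v, config) {
  dir <- ifelse(log2v > config@gainThreshold, "gain",
                ifelse(log2v < config@lossThreshold, "loss", NA_character_))
  keep <- !is.na(dir)
  chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
  dir <- dir[keep]; log2v <- log2v[keep]
  n <- length(chrom)
  if (n >= 2L) {
    gap <- start[-1] - end[-n] - 1
    joins <- chrom[-1] == chrom[-n] & dir[-1] == dir[-n] &
      gap >= 0 & gap <= config@mergeGap
    grpId <- cumsum(c(TRUE, !joins))
    if (any(joins)) {
      w <- end - start + 1
      start <- as.numeric(tapply(start, grpId, min))
      newEnd <- as.numeric(tapply(end, grpId, max))
      log2v <- as.numeric(tapply(log2v * w, grpId, sum) /
                            tapply(w, grpId, sum))
      first <- !duplicated(grpId)
      chrom <- chrom[first]; dir <- dir[first]; end <- newEnd
    }
  }
  keep <- (end - start + 1) >= config@noiseFilter
  data.frame(chrom = chrom[keep], start = start[keep], end = end[keep],
             direction = dir[keep], mean_log2 = log2v[keep],
             stringsAsFactors = FALSE)
}

#' Restrict calls to the reportable (>5 Mb) level
#'
#' Cohort summaries (event counts, biomarker flags) only count alterations
#' strictly longer than the reporting filter.
#'
#' @param calls \code{GRanges} of calls.
#' @param config a \code{\link{CallingConfig}}.
#' @return the subset of calls with width > \code{reportingFilter}.
#' @export
reportableCnas <- function(calls, config = CallingConfig()) {
  calls[width(calls) > config@reportingFilter]
}

#' Count copy-number events and bin the count
#'
#' @param calls \code{GRanges} of reportable calls for one case.
#' @return list with \code{count} and \code{bin} (one of
#'   \code{"0" "1" "2" "3-4" ">4"}).
#' @export
countCnEvents <- function(calls) {
  n <- length(calls)
  bin <- if (n == 0) "0" else if (n == 1) "1" else if (n == 2) "2"
         else if (n <= 4) "3-4" else ">4"
  list(count = n, bin = bin)
}

#' Chromosome-arm ranges of a build
#' @param build a \code{\link{GenomeBuild}}.
#' @return \code{GRanges} named \code{"1p","1q",...} with p arms ending at
#'   the centromere position.
#' @export
.armRangesCache <- new.env(parent = emptyenv())

armRanges <- function(build) {
  key <- paste0(build@name, ":", nrow(build@chromosomes), ":",
                sum(build@chromosomes$length))
  cached <- get0(key, envir = .armRangesCache)
  if (!is.null(cached)) return(cached)
  ch <- build@chromosomes
  si <- buildSeqinfo(build)
  p <- GRanges(ch$chrom, IRanges(1, ch$centromere), seqinfo = si)
  q <- GRanges(ch$chrom, IRanges(ch$centromere + 1, ch$length), seqinfo = si)
  arms <- c(p, q)
  names(arms) <- c(paste0(ch$chrom, "p"), paste0(ch$chrom, "q"))
  arms <- GenomicRanges::sort(arms)
  assign(key, arms, envir = .armRangesCache)
  arms
}

#' Attribute a call to chromosome arms
#'
#' p/q attribution uses the centromere position: for each overlapped arm
#' the covered fraction is reported, with status \code{"full"} at >= 90
#' percent coverage and \code{"partial"} otherwise.  A call covering at
#' least 90 percent of both arms is flagged whole-chromosome.
#'
#' @param call a single-range \code{GRanges}.
#' @param build a \code{\link{GenomeBuild}}.
#' @return \code{data.frame} with columns \code{arm}, \code{overlap} (bp),
#'   \code{fraction} (of the arm) and \code{status}; attribute
#'   \code{wholeChromosome} is \code{TRUE} for whole-chromosome calls.
#' @export
armOverlap <- function(call, build) {
  if (length(call) != 1L) stop("armOverlap expects a single call")
  ch <- as.character(seqnames(call))
  if (!ch %in% chromNames(build)) stop("unknown chromosome: ", ch)
  arms <- armRanges(build)
  arms <- arms[as.character(seqnames(arms)) == ch]
  ov <- pmax(0, pmin(end(call), end(arms)) - pmax(start(call), start(arms)) + 1)
  frac <- ov / width(arms)
  hit <- ov > 0
  out <- data.frame(arm = names(arms)[hit], overlap = ov[hit],
                    fraction = frac[hit],
                    status = ifelse(frac[hit] >= 0.9, "full", "partial"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "wholeChromosome") <- all(frac >= 0.9)
  out
}

#' Arms overlapped by each call
#'
#' Vectorised helper: which calls touch a given arm (any overlap), with
#' optional direction filtering.
#'
#' @param calls \code{GRanges} of calls with \code{direction} metadata.
#' @param arm arm label such as \code{"16q"}.
#' @param build a \code{\link{GenomeBuild}}.
#' @param direction optional \code{"gain"} or \code{"loss"} filter.
#' @return logical: does any (matching) call overlap the arm?
#' @export
anyCallOnArm <- function(calls, arm, build, direction = NULL) {
  if (!length(calls)) return(FALSE)
  arms <- armRanges(build)
  if (!arm %in% names(arms)) stop("unknown arm: ", arm)
  if (!is.null(direction)) calls <- calls[mcols(calls)$direction == direction]
  if (!length(calls)) return(FALSE)
  any(overlapsAny(calls, arms[arm]))
}
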