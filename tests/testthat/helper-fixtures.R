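suppressPackageStartupMessages({
  library(GenomicRanges)
})

hg <- grch37Build()

# GRanges of calls from a compact spec: list of c(chrom, start, end, dir, log2)
mkCalls <- function(..., build = hg) {
  rows <- list(...)
  if (!length(rows)) return(GRanges(seqinfo = buildSeqinfo(build)))
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = as.character(r[[1]]), start = as.numeric(r[[2]]),
               end = as.numeric(r[[3]]), direction = as.character(r[[4]]),
               log2 = if (length(r) >= 5) as.numeric(r[[5]])
                      else if (r[[4]] == "gain") 0.32 else -0.55)))
  sort(GRanges(df$chrom, IRanges(df$start, df$end), direction = df$direction,
               mean_log2 = df$log2, seqinfo = buildSeqinfo(build)))
}

# GRanges of segments (log2 column) from compact rows c(chrom, start, end, log2)
mkSegments <- function(..., build = hg) {
  rows <- list(...)
  if (!length(rows)) return(GRanges(seqinfo = buildSeqinfo(build)))
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = as.character(r[[1]]), start = as.numeric(r[[2]]),
               end = as.numeric(r[[3]]), log2 = as.numeric(r[[4]]))))
  sort(GRanges(df$chrom, IRanges(df$start, df$end), log2 = df$log2,
               seqinfo = buildSeqinfo(build)))
}

mkMut <- function(genes, changes, vaf = NA_real_) {
  data.frame(gene = genes, protein_change = changes,
             vaf = rep_len(vaf, length(genes)),
             classification = rep_len("missense", length(genes)),
             stringsAsFactors = FALSE)
}

# Random interior call set (boundaries well away from chromosome termini so
# terminal non-informativeness does not interact with tolerance properties).
randomCallSet <- function(maxCalls = 5, build = hg) {
  n <- sample.int(maxCalls + 1, 1) - 1L
  if (n == 0) return(mkCalls(build = build))
  lens <- chromLengths(build)
  rows <- list()
  taken <- list()
  while (length(rows) < n) {
    ch <- sample(names(lens), 1)
    lo <- 6e6; hi <- lens[[ch]] - 6e6
    s <- round(runif(1, lo, hi - 8e6))
    e <- s + round(runif(1, 2e6, 6e7))
    e <- min(e, hi)
    ok <- TRUE
    for (t in taken)
      if (t$ch == ch && s <= t$e && e >= t$s) ok <- FALSE
    if (!ok) next
    taken[[length(taken) + 1L]] <- list(ch = ch, s = s, e = e)
    rows[[length(rows) + 1L]] <- list(ch, s, e, sample(c("gain", "loss"), 1))
  }
  do.call(mkCalls, c(rows, list(build = build)))
}

# Exhaustive all-pairs breakpoint matching oracle (independent of the
# package implementation): enumerate every boundary pair with nested loops,
# then select greedily nearest-first with leftmost tie-break.
bruteMatchBreakpoints <- function(a, b, build, config) {
  boundsOf <- function(calls) {
    out <- list()
    for (i in seq_along(calls)) {
      ch <- as.character(seqnames(calls)[i])
      d <- mcols(calls)$direction[i]
      out[[length(out) + 1L]] <- list(chrom = ch, side = "start",
                                      dir = d, pos = start(calls)[i], id = i)
      out[[length(out) + 1L]] <- list(chrom = ch, side = "end",
                                      dir = d, pos = end(calls)[i], id = i)
    }
    out
  }
  ba <- boundsOf(a); bb <- boundsOf(b)
  cand <- list()
  for (x in ba) for (y in bb) {
    if (x$chrom == y$chrom && x$side == y$side && x$dir == y$dir &&
        abs(x$pos - y$pos) <= config@tolerance)
      cand[[length(cand) + 1L]] <- list(x = x, y = y,
                                        offset = abs(x$pos - y$pos),
                                        minpos = min(x$pos, y$pos))
  }
  if (!length(cand)) return(data.frame())
  ord <- order(vapply(cand, `[[`, numeric(1), "offset"),
               vapply(cand, `[[`, numeric(1), "minpos"),
               vapply(cand, function(z) z$x$chrom, character(1)),
               vapply(cand, function(z) z$x$side, character(1)))
  usedA <- usedB <- character()
  rows <- list()
  lens <- chromLengths(build)
  for (k in ord) {
    z <- cand[[k]]
    ka <- paste(z$x$chrom, z$x$side, z$x$dir, z$x$id)
    kb <- paste(z$y$chrom, z$y$side, z$y$dir, z$y$id)
    if (ka %in% usedA || kb %in% usedB) next
    usedA <- c(usedA, ka); usedB <- c(usedB, kb)
    terminal <- function(p) (p - 1) <= config@tolerance ||
      (lens[[z$x$chrom]] - p) <= config@tolerance
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = z$x$chrom, side = z$x$side, direction = z$x$dir,
      pos_a = z$x$pos, pos_b = z$y$pos, offset = z$offset,
      informative = !(terminal(z$x$pos) || terminal(z$y$pos)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$position <- floor((out$pos_a + out$pos_b) / 2)
  out <- out[order(out$chrom, out$position), ]
  rownames(out) <- NULL
  out
}

# Exact two-tailed Fisher p by direct hypergeometric enumeration.
fisherOracle <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); N <- sum(m)
  if (r1 == 0 || r1 == N || c1 == 0 || c1 == N) return(1)
  amin <- max(0, r1 + c1 - N); amax <- min(r1, c1)
  av <- amin:amax
  pr <- stats::dhyper(av, c1, N - c1, r1)
  pobs <- pr[av == m[1, 1]]
  sum(pr[pr <= pobs * (1 + 1e-7)])
}
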