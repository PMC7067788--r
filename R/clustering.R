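#' Build a component x bin copy-number matrix
#'
#' Each lesion component becomes a row over a fixed genome-wide bin grid
#' (default 1 Mb).  In \code{state} mode a bin takes +1/-1 when a gain or
#' loss call covers the majority (>50 percent) of the bin, 0 otherwise; in
#' \code{log2} mode it takes the log2 value of the majority-covering
#' range.  All rows share the identical column grid, so the matrix feeds
#' directly into \code{\link{pearsonDissimilarity}}.
#'
#' @param callSets named list of \code{GRanges}: calls (with
#'   \code{direction}) for \code{state} mode, or segments/calls with
#'   \code{log2}/\code{mean_log2} for \code{log2} mode.
#' @param build a \code{\link{GenomeBuild}}.
#' @param binSize grid bin width, bp.
#' @param mode \code{"state"} or \code{"log2"}.
#' @return numeric matrix, rows = components, columns = bins named
#'   \code{chrom:start}.
#' @export
segmentsToMatrix <- function(callSets, build = grch37Build(), binSize = 1e6,
                             mode = c("state", "log2")) {
  mode <- match.arg(mode)
  grid <- binGrid(build, binSize)
  colnames <- paste0(as.character(seqnames(grid)), ":", start(grid))
  m <- matrix(0, nrow = length(callSets), ncol = length(grid),
              dimnames = list(names(callSets), colnames))
  halfBin <- width(grid) / 2
  for (i in seq_along(callSets)) {
    gr <- callSets[[i]]
    if (!length(gr)) next
    hits <- findOverlaps(grid, gr)
    if (!length(hits)) next
    qi <- queryHits(hits); si <- subjectHits(hits)
    ov <- width(pintersect(grid[qi], gr[si]))
    # majority rule per bin: the overlapping range with the largest cover
    best <- tapply(seq_along(qi), qi, function(ix) ix[which.max(ov[ix])])
    best <- unlist(best)
    qi2 <- qi[best]; si2 <- si[best]; ov2 <- ov[best]
    covered <- ov2 > halfBin[qi2]
    if (!any(covered)) next
    if (mode == "state") {
      val <- ifelse(mcols(gr)$direction[si2] == "gain", 1, -1)
    } else {
      lv <- mcols(gr)$log2
      if (is.null(lv)) lv <- mcols(gr)$mean_log2
      val <- lv[si2]
    }
    m[i, qi2[covered]] <- val[covered]
  }
  m
}

#' Pearson dissimilarity between profile rows
#'
#' d(i, j) = 1 - r(i, j) with r the Pearson correlation of rows; values
#' lie in [0, 2] with zero diagonal.  Correlation is undefined for
#' constant rows: a constant row is at distance 0 from an identical
#' constant row and 1 from anything else.
#'
#' @param m numeric matrix with at least two rows.
#' @return symmetric dissimilarity matrix.
#' @export
pearsonDissimilarity <- function(m) {
  if (nrow(m) < 2L) stop("need at least two rows")
  const <- apply(m, 1, function(r) max(r) == min(r))
  d <- matrix(1, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  if (any(!const)) {
    r <- suppressWarnings(stats::cor(t(m[!const, , drop = FALSE])))
    d[!const, !const] <- 1 - r
  }
  if (any(const)) {
    ci <- which(const)
    for (i in ci) for (j in ci)
      d[i, j] <- if (identical(m[i, ], m[j, ])) 0 else 1
  }
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) agglomeration
#'
#' Repeatedly merges the closest pair of clusters, with inter-cluster
#' distance the unweighted mean of member pairwise distances; merge
#' heights are monotone non-decreasing on metric-like input, and ties are
#' resolved deterministically.
#'
#' @param d symmetric dissimilarity matrix (or \code{dist}).
#' @return an \code{hclust} object (merge order + heights).
#' @export
averageLinkage <- function(d) {
  if (is.matrix(d)) d <- stats::as.dist(d)
  stats::hclust(d, method = "average")
}

#' Fraction of component pairs that are mutual nearest leaves
#'
#' A case's two components "cluster together" when they merge with each
#' other before either merges with any other leaf, i.e. a dendrogram
#' merge step joins exactly those two singletons.
#'
#' @param hc an \code{hclust} over the components.
#' @param pairs two-column matrix or data.frame of leaf-label pairs.
#' @return list with \code{fraction}, and logical \code{paired} per pair.
#' @export
copheneticPairing <- function(hc, pairs) {
  pairs <- as.matrix(pairs)
  labels <- hc$labels
  paired <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ia <- match(pairs[i, 1], labels)
    ib <- match(pairs[i, 2], labels)
    if (is.na(ia) || is.na(ib))
      stop("unknown leaf: ", pairs[i, which(c(is.na(ia), is.na(ib)))[1]])
    paired[i] <- any(hc$merge[, 1] == -ia & hc$merge[, 2] == -ib) ||
      any(hc$merge[, 1] == -ib & hc$merge[, 2] == -ia)
  }
  list(fraction = mean(paired), paired = stats::setNames(paired,
       paste(pairs[, 1], pairs[, 2], sep = "|")))
}

#' Serialise a dendrogram as Newick
#'
#' Branch lengths derive from the merge heights.
#'
#' @param hc an \code{hclust}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeNewick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
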