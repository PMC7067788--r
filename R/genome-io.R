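#' Read a SEG-style segmented copy-number file
#'
#' Reads a tab-delimited segment file (columns: sample, chromosome, start,
#' end, optional marker count, segment mean log2 ratio; 1-based inclusive
#' coordinates, the SEG convention) into one \code{\link{LesionProfile}}
#' per sample.  Chromosome names are normalized by stripping any
#' \code{chr} prefix; lines starting with \code{#} are ignored.  Internally
#' segments are \code{GRanges}, which use the same 1-based inclusive
#' convention, so no coordinate shift occurs on read.
#'
#' @param path file path.
#' @param build a \code{\link{GenomeBuild}}; coordinates are checked
#'   against its chromosome lengths.
#' @return named list of \code{LesionProfile}, one per sample, in order of
#'   first appearance.
#' @export
readSeg <- function(path, build = grch37Build()) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  colmap <- c(sample = "^(sample|id|sample_id)$",
              chrom = "^(chrom|chromosome|chr)$",
              start = "^(start|loc\\.start)$",
              end = "^(end|loc\\.end)$",
              log2 = "^(log2|seg\\.mean|seg_mean|mean)$")
  idx <- vapply(colmap, function(p) {
    i <- grep(p, names(df))
    if (length(i)) i[1] else NA_integer_
  }, integer(1))
  if (anyNA(idx))
    stop("SEG file ", path, " lacks required column(s): ",
         paste(names(idx)[is.na(idx)], collapse = ", "))
  df <- df[, idx]
  names(df) <- names(colmap)
  lineNo <- seq_len(nrow(df)) + 1L  # header is line 1
  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  log2 <- suppressWarnings(as.numeric(df$log2))
  bad <- which(is.na(start) | is.na(end) | is.na(log2))
  if (length(bad))
    stop("malformed SEG row at line ", lineNo[bad[1]], " of ", path)
  df$chrom <- normalizeChrom(df$chrom)
  lens <- chromLengths(build)
  unknown <- which(!df$chrom %in% names(lens))
  if (length(unknown))
    stop("unknown chromosome '", df$chrom[unknown[1]], "' at line ",
         lineNo[unknown[1]], " of ", path)
  oob <- which(start < 1 | end > lens[df$chrom] | start > end)
  if (length(oob))
    stop("coordinates outside build bounds at line ", lineNo[oob[1]], " of ", path)
  si <- buildSeqinfo(build)
  samples <- unique(df$sample)
  out <- lapply(samples, function(s) {
    rows <- df$sample == s
    gr <- GRanges(df$chrom[rows], IRanges(start[rows], end[rows]),
                  log2 = log2[rows], seqinfo = si)
    gr <- GenomicRanges::sort(gr)
    if (.hasOverlapWithin(gr))
      stop("overlapping segments in sample '", s, "' of ", path)
    LesionProfile(sampleId = s, segments = gr)
  })
  stats::setNames(out, samples)
}

#' Write lesion profiles as a SEG file
#'
#' Inverse of \code{\link{readSeg}}: 1-based inclusive coordinates, one row
#' per segment.
#'
#' @param profiles list of \code{LesionProfile} (or a single one).
#' @param path output path.
#' @param header optional comment lines written before the table (each
#'   prefixed with \code{#}).
#' @return invisibly, the path.
#' @export
writeSeg <- function(profiles, path, header = NULL) {
  if (is(profiles, "LesionProfile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    gr <- cnSegments(p)
    if (!length(gr)) return(NULL)
    data.frame(sample = sampleId(p), chrom = as.character(seqnames(gr)),
               start = start(gr), end = end(gr), log2 = mcols(gr)$log2,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(sample = character(), chrom = character(),
                     start = numeric(), end = numeric(), log2 = numeric())
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("sample", "chrom", "start", "end", "log2"), collapse = "\t"), con)
  if (nrow(df))
    writeLines(paste(df$sample, df$chrom,
                     format(df$start, scientific = FALSE, trim = TRUE),
                     format(df$end, scientific = FALSE, trim = TRUE),
                     format(df$log2, digits = 15, trim = TRUE), sep = "\t"), con)
  invisible(path)
}

#' Read a somatic mutation table
#'
#' Tab-delimited with columns sample, gene, protein_change and optionally
#' vaf and classification; returns one \code{data.frame} per sample.
#'
#' @param path file path.
#' @return named list of mutation \code{data.frame}s keyed by sample.
#' @export
readMutations <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("sample", "gene", "protein_change")
  if (!all(need %in% names(df)))
    stop("mutation file ", path, " lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if ("vaf" %in% names(df)) {
    df$vaf <- suppressWarnings(as.numeric(df$vaf))
    v <- df$vaf[!is.na(df$vaf)]
    if (length(v) && (any(v < 0) || any(v > 1)))
      stop("vaf outside [0, 1] in ", path)
  } else {
    df$vaf <- NA_real_
  }
  if (!"classification" %in% names(df)) df$classification <- "other"
  samples <- unique(df$sample)
  out <- lapply(samples, function(s) {
    m <- df[df$sample == s, c("gene", "protein_change", "vaf", "classification")]
    rownames(m) <- NULL
    m
  })
  stats::setNames(out, samples)
}

#' Write per-sample mutation tables
#' @param mutations named list of mutation data.frames (as from
#'   \code{\link{readMutations}}).
#' @param path output path.
#' @param header optional comment lines.
#' @return invisibly, the path.
#' @export
writeMutations <- function(mutations, path, header = NULL) {
  rows <- lapply(names(mutations), function(s) {
    m <- mutations[[s]]
    if (!nrow(m)) return(NULL)
    cbind(sample = s, m[, intersect(c("gene", "protein_change", "vaf", "classification"),
                                    names(m)), drop = FALSE])
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  cols <- c("sample", "gene", "protein_change", "vaf", "classification")
  writeLines(paste(cols, collapse = "\t"), con)
  if (!is.null(df) && nrow(df)) {
    for (cn in setdiff(cols, names(df))) df[[cn]] <- NA
    utils::write.table(df[, cols], con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, na = "")
  }
  invisible(path)
}

#' Write copy-number calls as BED
#'
#' BED is 0-based half-open, so starts are shifted down by one relative to
#' the internal 1-based inclusive ranges.  The name field carries the call
#' direction.
#'
#' @param calls \code{GRanges} of calls with a \code{direction} metadata
#'   column (\code{gain}/\code{loss}).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCallsBed <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(calls)) {
    writeLines(paste(as.character(seqnames(calls)),
                     format(start(calls) - 1L, scientific = FALSE, trim = TRUE),
                     format(end(calls), scientific = FALSE, trim = TRUE),
                     mcols(calls)$direction, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a background mutation-frequency table
#'
#' Tab-delimited with columns gene, protein_change (\code{"*"} marks
#' gene-level rows) and frequency; an optional header comment
#' \code{# cohort_size=N} sets the cohort size.
#'
#' @param path file path.
#' @param cohortSize reference cohort size; overridden by a
#'   \code{cohort_size} header comment if present.
#' @return a \code{\link{BackgroundFrequencyTable}}.
#' @export
readFrequencyTable <- function(path, cohortSize = 977) {
  head <- readLines(path, n = 5L)
  m <- regmatches(head, regexpr("cohort_size=[0-9]+", head))
  if (length(m)) cohortSize <- as.numeric(sub("cohort_size=", "", m[1]))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  BackgroundFrequencyTable(df[, c("gene", "protein_change", "frequency")],
                           cohortSize = cohortSize)
}

#' Write a background mutation-frequency table
#' @param bg a \code{BackgroundFrequencyTable}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeFrequencyTable <- function(bg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# cohort_size=", format(bg@cohortSize, scientific = FALSE)), con)
  writeLines("gene\tprotein_change\tfrequency", con)
  ent <- bg@entries
  if (nrow(ent))
    writeLines(paste(ent$gene, ent$protein_change,
                     format(ent$frequency, digits = 15, trim = TRUE), sep = "\t"), con)
  invisible(path)
}
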