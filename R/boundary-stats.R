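## The broken boundary index (BBI): per-boundary window counts, the
## ratio-of-ratios statistic, ranking and top-N heatmap matrices.

#' Per-boundary window counts
#'
#' Counts filtered-read anchors (both strands pooled) falling in the outside
#' (MDS) and inside (IES) window of each boundary. The 13th-nt anchor is the
#' convention for boundary statistics.
#'
#' @param lib an [ScnLibrary-class].
#' @param bw boundary window rows from [boundaries()]; all must be eligible.
#' @param anchorMode see [anchorPositions()].
#' @return `bw` with `mds_count` (outside) and `ies_count` (inside) columns
#'   appended.
#' @export
boundaryCounts <- function(lib, bw, anchorMode = "nt13") {
  if (!all(bw$eligible)) {
    i <- which(!bw$eligible)[1L]
    stop(sprintf("ineligible boundary %s/%s: callers must pre-filter on the eligible flag",
                 bw$ies_id[i], bw$side[i]))
  }
  reads <- filteredReads(lib)
  countIn <- function(s, e) {
    if (length(reads) == 0L || nrow(bw) == 0L) return(integer(nrow(bw)))
    a0 <- anchorPositions(reads, anchorMode)
    anch <- GRanges(as.character(seqnames(reads)), IRanges(a0 + 1L, a0 + 1L))
    winGr <- GRanges(bw$chrom, IRanges(s + 1L, e))
    GenomicRanges::countOverlaps(winGr, anch)
  }
  bw$mds_count <- countIn(bw$outside_start, bw$outside_end)
  bw$ies_count <- countIn(bw$inside_start, bw$inside_end)
  bw
}

#' Broken boundary index
#'
#' `BBI = (MDS_sample / IES_sample) / (MDS_control / IES_control)`: the
#' outside/inside read ratio of a boundary in the sample library, normalized
#' by the same ratio in the control (wild-type) library. A value of 1 means
#' no disturbance; values above 1 mean the sample produces relatively more
#' small RNAs outside the boundary than the control. A pseudocount is added
#' to all four counts to stabilize the ratio at low coverage.
#'
#' @param mdsSample,iesSample outside/inside counts in the sample library.
#' @param mdsControl,iesControl the same counts in the control library.
#' @param pseudocount added to every count (default 1; with 0, all four
#'   counts must be positive).
#' @return The BBI value(s); vectorized over the four count arguments.
#' @export
computeBbi <- function(mdsSample, iesSample, mdsControl, iesControl,
                       pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 &&
      any(c(mdsSample, iesSample, mdsControl, iesControl) == 0))
    stop("zero count with pseudocount 0: the BBI is undefined")
  p <- pseudocount
  ((mdsSample + p) / (iesSample + p)) / ((mdsControl + p) / (iesControl + p))
}

#' BBI table over all eligible boundaries
#'
#' Computes the broken boundary index at every eligible boundary of the
#' genome, using one library as sample and another as control. Boundaries
#' whose control inside-window count falls below `minControlReads` are
#' flagged `eligible = FALSE` (unstable denominator) and excluded from
#' ranking and summaries. Ranks (1 = highest BBI) are assigned over the
#' eligible boundaries, ties broken by (chrom, position, side).
#'
#' @param sampleLib,controlLib [ScnLibrary-class] objects.
#' @param genome a [SegmentedGenome-class].
#' @param window boundary window width in bases (default 500).
#' @param pseudocount see [computeBbi()].
#' @param minControlReads minimum raw control inside-window count (default
#'   10).
#' @param anchorMode see [anchorPositions()].
#' @param excludeForeign drop boundaries whose outside window overlaps a
#'   neighboring IES.
#' @return data.frame with one row per window-eligible boundary: identity
#'   columns, the four counts (`mds_sample`, `ies_sample`, `mds_control`,
#'   `ies_control`), `bbi`, `eligible` and `rank` (`NA` when ineligible).
#' @export
bbiTable <- function(sampleLib, controlLib, genome, window = 500,
                     pseudocount = 1, minControlReads = 10,
                     anchorMode = "nt13", excludeForeign = FALSE) {
  bw <- boundaries(genome, window)
  bw <- bw[bw$eligible, , drop = FALSE]
  if (excludeForeign) bw <- bw[!bw$overlaps_foreign_ies, , drop = FALSE]
  if (nrow(bw) == 0L) stop("no eligible boundaries in the genome")
  s <- boundaryCounts(sampleLib, bw, anchorMode)
  c_ <- boundaryCounts(controlLib, bw, anchorMode)
  out <- data.frame(ies_id = bw$ies_id, side = bw$side,
                    ies_type = bw$ies_type, chrom = bw$chrom,
                    boundary_pos = bw$boundary_pos,
                    inside_start = bw$inside_start,
                    mds_sample = s$mds_count, ies_sample = s$ies_count,
                    mds_control = c_$mds_count, ies_control = c_$ies_count,
                    stringsAsFactors = FALSE)
  out$bbi <- computeBbi(out$mds_sample, out$ies_sample,
                        out$mds_control, out$ies_control, pseudocount)
  out$eligible <- out$ies_control >= minControlReads
  out$rank <- NA_integer_
  el <- which(out$eligible)
  if (length(el)) {
    o <- el[order(-out$bbi[el], out$chrom[el], out$inside_start[el],
                  out$side[el])]
    out$rank[o] <- seq_along(o)
  }
  out
}

#' @describeIn bbiTable distribution summary (n, median, quartiles) of the
#'   eligible BBIs, the numbers behind the boxplot display.
#' @param tbl a BBI table.
#' @export
bbiSummary <- function(tbl) {
  v <- tbl$bbi[tbl$eligible]
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  list(n = length(v), q1 = q[1L], median = q[2L], q3 = q[3L])
}

#' Top-N boundary heatmap matrices
#'
#' Selects the `n` highest-BBI boundaries from one reference strain's BBI
#' table and profiles the SAME rows in every supplied strain library
#' (cross-strain comparability): each row is the boundary's RPM in
#' `binSize`-bp bins over the mirrored `-window..+window` axis, strands
#' pooled, 13th-nt anchor.
#'
#' @param bbi the reference strain's table from [bbiTable()].
#' @param libs named list of [ScnLibrary-class] objects (one per strain).
#' @param genome the [SegmentedGenome-class] the table was computed on.
#' @param n number of rows (default 50).
#' @param binSize heatmap bin width (default 50).
#' @param window boundary window width used for the table (default 500).
#' @param anchorMode see [anchorPositions()].
#' @param perIes rank IESs by their max-BBI boundary and take the top `n`
#'   IESs (one row each) instead of the top `n` boundaries.
#' @return Named list of `n x (2 * window / binSize)` matrices, rows in rank
#'   order (`ies_id:side` row names), columns labeled by bin left-edge
#'   offset.
#' @export
topNHeatmap <- function(bbi, libs, genome, n = 50, binSize = 50,
                        window = 500, anchorMode = "nt13", perIes = FALSE) {
  el <- bbi[bbi$eligible, , drop = FALSE]
  if (perIes) {
    el <- el[order(el$rank), , drop = FALSE]
    el <- el[!duplicated(el$ies_id), , drop = FALSE]
  }
  if (n > nrow(el))
    stop(sprintf("n = %d exceeds the %d eligible %s", n, nrow(el),
                 if (perIes) "IESs" else "boundaries"))
  top <- el[order(el$rank), , drop = FALSE][seq_len(n), , drop = FALSE]
  bw <- boundaries(genome, window)
  key <- paste(bw$ies_id, bw$side)
  rows <- match(paste(top$ies_id, top$side), key)
  bwSel <- bw[rows, , drop = FALSE]
  nb <- as.integer(ceiling(2 * window / binSize))
  offs <- seq(-window, window - 1, by = binSize)[seq_len(nb)]
  lapply(libs, function(lib) {
    h <- .metaHits(lib, bwSel, window, binSize, anchorMode)
    m <- matrix(0, nrow = n, ncol = nb,
                dimnames = list(paste0(top$ies_id, ":", top$side), offs))
    if (length(h$win)) {
      tab <- table(factor(h$win, levels = seq_len(n)),
                   factor(h$bin, levels = seq_len(nb)))
      m[] <- as.numeric(tab)
    }
    rpm(m, lib)
  })
}

#' Write a heatmap matrix as TSV and (optionally) a figure
#'
#' @param mat one matrix from [topNHeatmap()].
#' @param path output TSV path (row names in the first column).
#' @param pdfPath optional path for a PDF rendering (rank order top to
#'   bottom).
#' @param strain label used in the figure title.
#' @export
writeHeatmap <- function(mat, path, pdfPath = NULL, strain = "") {
  df <- data.frame(boundary = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pdfPath)) {
    grDevices::pdf(pdfPath, width = 5, height = 7)
    on.exit(grDevices::dev.off())
    graphics::image(t(mat[rev(seq_len(nrow(mat))), , drop = FALSE]),
                    axes = FALSE, xlab = "boundary offset",
                    ylab = "rank (top = 1)",
                    main = sprintf("%s: top-%d boundary RPM", strain,
                                   nrow(mat)))
  }
  invisible(path)
}
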