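## Binned locus profiles and compiled boundary meta-profiles.
##
## Meta-axis convention: offsets run from -W (far outside, in the flanking
## MDS) to +W (far inside the IES). Right boundaries are mirrored
## (offset = boundary - 1 - anchor) so positive offsets always point into
## the IES, and the strand of mirrored reads is flipped so sense/antisense
## stay boundary-relative.

## Anchor hits of a library in a set of boundary windows, on the mirrored
## meta axis. Returns per-hit window row, bin index (1-based) and
## boundary-relative sense flag.
.metaHits <- function(lib, bw, window, binSize, anchorMode) {
  reads <- filteredReads(lib)
  res <- list(win = integer(0), bin = integer(0), sense = logical(0))
  if (length(reads) == 0L || nrow(bw) == 0L) return(res)
  a0 <- anchorPositions(reads, anchorMode)
  st <- as.character(strand(reads))
  anch <- GRanges(as.character(seqnames(reads)), IRanges(a0 + 1L, a0 + 1L))
  b <- bw$boundary_pos
  win <- GRanges(bw$chrom, IRanges(b - window + 1L, b + window))
  hits <- GenomicRanges::findOverlaps(anch, win)
  qa <- a0[queryHits(hits)]
  sj <- subjectHits(hits)
  left <- bw$side[sj] == "left"
  off <- ifelse(left, qa - b[sj], b[sj] - 1L - qa)
  bin <- (off + window) %/% binSize + 1L
  plus <- st[queryHits(hits)] == "+"
  list(win = sj, bin = as.integer(bin), sense = ifelse(left, plus, !plus))
}

.selectBoundaries <- function(genome, iesType, window, excludeForeign) {
  bw <- boundaries(genome, window)
  bw <- bw[bw$ies_type == iesType & bw$eligible, , drop = FALSE]
  if (excludeForeign)
    bw <- bw[!bw$overlaps_foreign_ies, , drop = FALSE]
  if (nrow(bw) == 0L)
    stop("no eligible type-", iesType, " boundaries")
  bw
}

#' Boundary-anchored meta-profile
#'
#' Compiles anchor counts of a small-RNA library over the 500-bp windows
#' inside and outside every eligible boundary of the requested IES type onto
#' a common offset axis (negative offsets outside in the MDS, positive
#' offsets inside the IES; right boundaries are mirrored and their read
#' strands flipped so sense/antisense remain boundary-relative). Raw counts
#' are summed across boundaries, then RPM-normalized. For a [ChipPair-class]
#' the call is forwarded to [chipRatio()].
#'
#' @param x an [ScnLibrary-class] or [ChipPair-class].
#' @param genome a [SegmentedGenome-class].
#' @param iesType `"A"` or `"B"`.
#' @param binSize bin width in bases (default 10).
#' @param window half-width of the meta axis in bases (default 500).
#' @param anchorMode anchor for counting; the 13th-nt anchor is the default
#'   for scnRNA meta-profiles.
#' @param excludeForeign drop boundaries whose outside window overlaps a
#'   neighboring IES (kept but flagged by default).
#' @return A meta-mode [BinnedProfile-class] (`value_kind = "RPM"`).
#' @export
metaProfile <- function(x, genome, iesType = c("A", "B"), binSize = 10,
                        window = 500, anchorMode = "nt13",
                        excludeForeign = FALSE) {
  iesType <- match.arg(iesType)
  if (is(x, "ChipPair"))
    return(chipRatio(x, genome = genome, iesType = iesType,
                     binSize = binSize, window = window,
                     excludeForeign = excludeForeign))
  stopifnot(is(x, "ScnLibrary"), binSize > 0, window > 0)
  bw <- .selectBoundaries(genome, iesType, window, excludeForeign)
  nb <- as.integer(ceiling(2 * window / binSize))
  h <- .metaHits(x, bw, window, binSize, anchorMode)
  rawS <- tabulate(h$bin[h$sense], nb)
  rawA <- tabulate(h$bin[!h$sense], nb)
  new("BinnedProfile", mode = "meta", chrom = "", start = -window,
      end = window, binSize = binSize,
      offsets = seq(-window, window - 1, by = binSize)[seq_len(nb)],
      sense = rpm(rawS, x), antisense = rpm(rawA, x),
      rawSense = as.numeric(rawS), rawAntisense = as.numeric(rawA),
      valueKind = "RPM", nBoundaries = nrow(bw),
      params = list(ies_type = iesType, window = window, bin_size = binSize,
                    anchor = anchorMode, library = x@name,
                    total_filtered = x@totalFiltered,
                    exclude_foreign = excludeForeign))
}

#' Binned locus profile
#'
#' Per-strand RPM in fixed-width bins over one genomic region; anchors are
#' assigned to bin `floor((anchor - start) / binSize)` (half-open bins).
#' The 5'-end anchor with 100-bp bins is the convention for individual-locus
#' small-RNA views.
#'
#' @param lib an [ScnLibrary-class].
#' @param chrom chromosome name.
#' @param start,end region, 0-based half-open.
#' @param binSize bin width in bases (default 100).
#' @param anchorMode see [anchorPositions()].
#' @param genome optional [SegmentedGenome-class]; when given the region is
#'   checked to lie within the chromosome.
#' @return A locus-mode [BinnedProfile-class].
#' @export
locusProfile <- function(lib, chrom, start, end, binSize = 100,
                         anchorMode = "five_prime", genome = NULL) {
  stopifnot(binSize > 0, end > start)
  if (!is.null(genome)) {
    cl <- chromLengths(genome)
    if (!chrom %in% names(cl) || start < 0 || end > cl[[chrom]])
      stop(sprintf("region %s:[%d,%d) lies outside the genome",
                   chrom, start, end))
  }
  reads <- filteredReads(lib)
  sel <- as.character(seqnames(reads)) == chrom
  a0 <- if (any(sel)) anchorPositions(reads[sel], anchorMode) else integer(0)
  st <- as.character(strand(reads[sel]))
  keep <- a0 >= start & a0 < end
  a0 <- a0[keep]; st <- st[keep]
  nb <- as.integer(ceiling((end - start) / binSize))
  bin <- (a0 - start) %/% binSize + 1L
  rawS <- tabulate(bin[st == "+"], nb)
  rawA <- tabulate(bin[st == "-"], nb)
  new("BinnedProfile", mode = "locus", chrom = chrom, start = start,
      end = end, binSize = binSize,
      offsets = seq(start, end - 1, by = binSize)[seq_len(nb)],
      sense = rpm(rawS, lib), antisense = rpm(rawA, lib),
      rawSense = as.numeric(rawS), rawAntisense = as.numeric(rawA),
      valueKind = "RPM", nBoundaries = 0L,
      params = list(anchor = anchorMode, bin_size = binSize,
                    library = lib@name, total_filtered = lib@totalFiltered))
}

#' ChIP / input enrichment profile
#'
#' Bins ChIP and input fragments (fragment-midpoint anchor, strands pooled),
#' RPM-normalizes each library, and reports the per-bin ratio
#' `chip RPM / input RPM`. Bins with zero input RPM are masked (`NA`, never
#' 0 or `Inf`). With `genome`/`iesType` the profile is a boundary
#' meta-profile; with `chrom`/`start`/`end` a locus profile.
#'
#' @param pair a [ChipPair-class] (both libraries unfiltered by length).
#' @inheritParams metaProfile
#' @inheritParams locusProfile
#' @param anchorMode anchor for fragment counting (default `"midpoint"`).
#' @return A [BinnedProfile-class] with `value_kind = "chip_over_input"`;
#'   the ratio is in `sense`, `antisense` is empty, raw ChIP counts in
#'   `rawSense` and raw input counts in `params$input_raw`.
#' @export
chipRatio <- function(pair, genome = NULL, iesType = c("A", "B"),
                      chrom = NULL, start = NULL, end = NULL,
                      binSize = NULL, window = 500,
                      anchorMode = "midpoint", excludeForeign = FALSE) {
  stopifnot(is(pair, "ChipPair"))
  meta <- !is.null(genome)
  if (meta) iesType <- match.arg(iesType)
  if (is.null(binSize)) binSize <- if (meta) 10 else 100
  one <- function(lib) {
    if (meta) {
      bw <- .selectBoundaries(genome, iesType, window, excludeForeign)
      nb <- as.integer(ceiling(2 * window / binSize))
      h <- .metaHits(lib, bw, window, binSize, anchorMode)
      list(raw = tabulate(h$bin, nb), nb = nb, nbound = nrow(bw),
           offsets = seq(-window, window - 1, by = binSize)[seq_len(nb)])
    } else {
      p <- locusProfile(lib, chrom, start, end, binSize, anchorMode)
      list(raw = p@rawSense + p@rawAntisense, nb = length(p@offsets),
           nbound = 0L, offsets = p@offsets)
    }
  }
  ch <- one(pair@chip)
  inp <- one(pair@input)
  chipRpm <- rpm(ch$raw, pair@chip)
  inputRpm <- rpm(inp$raw, pair@input)
  ratio <- ifelse(inputRpm == 0, NA_real_, chipRpm / inputRpm)
  new("BinnedProfile", mode = if (meta) "meta" else "locus",
      chrom = if (meta) "" else chrom,
      start = if (meta) -window else start,
      end = if (meta) window else end,
      binSize = binSize, offsets = ch$offsets,
      sense = ratio, antisense = numeric(0),
      rawSense = as.numeric(ch$raw), rawAntisense = numeric(0),
      valueKind = "chip_over_input", nBoundaries = ch$nbound,
      params = list(anchor = anchorMode, bin_size = binSize,
                    window = if (meta) window else NA,
                    ies_type = if (meta) iesType else NA,
                    chip = pair@chip@name, input = pair@input@name,
                    input_raw = as.numeric(inp$raw),
                    masked_bins = sum(is.na(ratio))))
}

#' @describeIn metaProfile bin left edges (genomic position or signed
#'   boundary offset).
#' @param profile a `BinnedProfile`.
#' @export
binOffsets <- function(profile) profile@offsets

#' @describeIn metaProfile normalized sense-strand (or unstranded ratio)
#'   values.
#' @export
senseValues <- function(profile) profile@sense

#' @describeIn metaProfile normalized antisense-strand values (empty for
#'   ChIP ratios).
#' @export
antisenseValues <- function(profile) profile@antisense

#' @describeIn metaProfile raw per-bin anchor counts,
#'   `list(sense, antisense)`.
#' @export
rawCounts <- function(profile)
  list(sense = profile@rawSense, antisense = profile@rawAntisense)

#' Profile as a data.frame
#'
#' Columns `offset_bin` (bin left edge), `sense`, `antisense` (when
#' stranded) or `ratio`/`masked` (ChIP), and `n_boundaries` in meta mode.
#'
#' @param x a `BinnedProfile`.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "BinnedProfile", function(x, ...) {
  if (x@valueKind == "chip_over_input") {
    df <- data.frame(offset_bin = x@offsets, ratio = x@sense,
                     masked = is.na(x@sense))
  } else {
    df <- data.frame(offset_bin = x@offsets, sense = x@sense,
                     antisense = x@antisense)
  }
  if (x@mode == "meta") df$n_boundaries <- x@nBoundaries
  df
})

#' @export
setMethod("show", "BinnedProfile", function(object) {
  cat(sprintf("BinnedProfile (%s, %s): %d bins of %g bp",
              object@mode, object@valueKind, length(object@offsets),
              object@binSize))
  if (object@mode == "meta")
    cat(sprintf(", %d boundaries compiled", object@nBoundaries))
  cat("\n")
})

#' Plot a meta-profile
#'
#' Line plot of the meta-axis values (sense up, antisense down for stranded
#' profiles; single ratio trace for ChIP), written to the active device.
#' Figures are conveniences: the numbers always come from the same
#' `BinnedProfile` that [as.data.frame()] exports.
#'
#' @param profile a meta-mode `BinnedProfile`.
#' @param main plot title.
#' @export
plotMetaProfile <- function(profile, main = "") {
  x <- profile@offsets + profile@binSize / 2
  if (profile@valueKind == "chip_over_input") {
    graphics::plot(x, profile@sense, type = "l", xlab = "offset (bp)",
                   ylab = "ChIP / input", main = main)
    graphics::abline(h = 1, lty = 3)
  } else {
    ylim <- range(c(profile@sense, -profile@antisense, 0))
    graphics::plot(x, profile@sense, type = "l", ylim = ylim, col = "blue",
                   xlab = "offset (bp)", ylab = "RPM (antisense down)",
                   main = main)
    graphics::lines(x, -profile@antisense, col = "red")
    graphics::abline(h = 0, lty = 3)
  }
  graphics::abline(v = 0, lty = 2)
  invisible(NULL)
}
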