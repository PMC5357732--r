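## Segmented genome construction, BED round-trip and boundary windows.
## Public coordinates are 0-based half-open (BED); GRanges internals 1-based.

.gr0 <- function(chrom, start0, end0, strand = "*", chromLengths = NULL) {
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
  if (!is.null(chromLengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(chromLengths)
    seqlengths(gr) <- unname(chromLengths)
  }
  gr
}

.start0 <- function(gr) start(gr) - 1L
.end0 <- function(gr) end(gr)

.asChromLengths <- function(chromLengths) {
  if (is.character(chromLengths) && length(chromLengths) == 1L &&
      file.exists(chromLengths)) {
    tab <- utils::read.table(chromLengths, sep = "\t", header = FALSE,
                             col.names = c("chrom", "length"),
                             colClasses = c("character", "numeric"))
    chromLengths <- stats::setNames(tab$length, tab$chrom)
  }
  if (is.null(names(chromLengths)) || any(names(chromLengths) == ""))
    stop("chromLengths must be a named vector or a two-column TSV")
  chromLengths
}

#' Build a segmented genome from IES annotations
#'
#' Constructs a [SegmentedGenome-class] from a table of IES intervals; gaps
#' between IESs (and chromosome ends) are filled with MDS segments so that
#' every chromosome is tiled completely. Abutting IESs are accepted and no
#' zero-width MDS is inserted between them.
#'
#' @param segments data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `label` (`IES_A`/`IES_B`; `MDS` rows are ignored and
#'   re-derived), and optionally `ies_id`.
#' @param chromLengths named numeric vector of chromosome lengths, or path
#'   to a two-column `chrom<TAB>length` TSV.
#' @return A `SegmentedGenome`.
#' @examples
#' g <- segmentedGenome(
#'   data.frame(chrom = "chr1", start = 1000, end = 3000, label = "IES_A"),
#'   c(chr1 = 10000))
#' iesCount(g)
#' @export
segmentedGenome <- function(segments, chromLengths) {
  chromLengths <- .asChromLengths(chromLengths)
  ies <- segments[segments$label != "MDS", , drop = FALSE]
  if (nrow(ies)) {
    if (!all(ies$label %in% c("IES_A", "IES_B")))
      stop("IES labels must be IES_A or IES_B")
    if (!all(ies$chrom %in% names(chromLengths)))
      stop("IES on unknown chromosome: ",
           paste(setdiff(ies$chrom, names(chromLengths)), collapse = ", "))
    bad <- ies$end > chromLengths[ies$chrom] | ies$start < 0
    if (any(bad))
      stop(sprintf("IES [%d,%d) on %s extends past the chromosome bounds",
                   ies$start[which(bad)[1L]], ies$end[which(bad)[1L]],
                   ies$chrom[which(bad)[1L]]))
    if (any(ies$start >= ies$end))
      stop("IES intervals must satisfy start < end")
    ies <- ies[order(ies$chrom, ies$start), , drop = FALSE]
    ov <- ies$chrom[-1L] == ies$chrom[-nrow(ies)] &
      ies$start[-1L] < ies$end[-nrow(ies)]
    if (any(ov)) {
      i <- which(ov)[1L]
      stop(sprintf("overlapping IES records on %s: [%d,%d) and [%d,%d)",
                   ies$chrom[i], ies$start[i], ies$end[i],
                   ies$start[i + 1L], ies$end[i + 1L]))
    }
    if (is.null(ies$ies_id) || any(is.na(ies$ies_id)) || any(ies$ies_id == ""))
      ies$ies_id <- sprintf("ies%05d", seq_len(nrow(ies)))
  } else {
    ies$ies_id <- character(0)
  }

  rows <- vector("list", length(chromLengths))
  for (k in seq_along(chromLengths)) {
    chr <- names(chromLengths)[k]
    len <- chromLengths[[k]]
    ci <- ies[ies$chrom == chr, , drop = FALSE]
    pos <- 0
    out <- list()
    for (i in seq_len(nrow(ci))) {
      if (ci$start[i] > pos)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chr, start = pos, end = ci$start[i],
          label = "MDS", ies_id = "")
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = ci$start[i], end = ci$end[i],
        label = ci$label[i], ies_id = ci$ies_id[i])
      pos <- ci$end[i]
    }
    if (pos < len)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = pos, end = len, label = "MDS", ies_id = "")
    rows[[k]] <- do.call(rbind, out)
  }
  seg <- do.call(rbind, rows)
  gr <- .gr0(seg$chrom, seg$start, seg$end, chromLengths = chromLengths)
  mcols(gr)$label <- seg$label
  mcols(gr)$ies_id <- seg$ies_id
  new("SegmentedGenome", segments = gr)
}

#' Load a genome segmentation from BED
#'
#' Reads IES annotations from a BED file (0-based half-open). The BED name
#' field encodes the label, either bare (`IES_A`, `IES_B`, `MDS`) or with an
#' identifier suffix (`IES_A:ies00001`). MDS records are ignored: every gap
#' between IESs is (re)filled as MDS, so a file of IES records alone is a
#' complete segmentation.
#'
#' @inheritParams segmentedGenome
#' @param bedPath path to a BED file.
#' @return A `SegmentedGenome`.
#' @export
loadSegmentation <- function(bedPath, chromLengths) {
  chromLengths <- .asChromLengths(chromLengths)
  gr <- rtracklayer::import(bedPath, format = "BED")
  if (length(gr) == 0L)
    return(segmentedGenome(
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 label = character(0)), chromLengths))
  nm <- mcols(gr)$name
  if (is.null(nm)) stop("BED name field must carry the segment label")
  lab <- sub(":.*$", "", nm)
  id <- ifelse(grepl(":", nm), sub("^[^:]*:", "", nm), "")
  if (!all(lab %in% SEGMENT_LABELS))
    stop("unrecognized segment labels in BED name field: ",
         paste(unique(setdiff(lab, SEGMENT_LABELS)), collapse = ", "))
  keep <- lab != "MDS"
  seg <- data.frame(chrom = as.character(seqnames(gr)), start = .start0(gr),
                    end = .end0(gr), label = lab, ies_id = id,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (nrow(seg) && any(seg$ies_id == ""))
    seg$ies_id <- NULL
  segmentedGenome(seg, chromLengths)
}

#' Write a genome segmentation as BED
#'
#' Writes all segments (MDS and IES) as BED records with the label (and IES
#' identifier) in the name field, 0-based half-open coordinates. A
#' [loadSegmentation()] of the written file reproduces the segment list
#' exactly.
#'
#' @param genome a `SegmentedGenome`.
#' @param bedPath output BED path.
#' @param chromLengthsPath optional path for a `chrom<TAB>length` TSV.
#' @return `bedPath`, invisibly.
#' @export
writeSegmentation <- function(genome, bedPath, chromLengthsPath = NULL) {
  gr <- genome@segments
  nm <- ifelse(mcols(gr)$label == "MDS", mcols(gr)$label,
               paste0(mcols(gr)$label, ":", mcols(gr)$ies_id))
  out <- gr
  mcols(out) <- NULL
  mcols(out)$name <- nm
  rtracklayer::export(out, bedPath, format = "BED")
  if (!is.null(chromLengthsPath)) {
    sl <- seqlengths(gr)
    utils::write.table(data.frame(chrom = names(sl), length = unname(sl)),
                       chromLengthsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(bedPath)
}

#' @describeIn segmentedGenome all segments as a 0-based data.frame.
#' @param genome a `SegmentedGenome`.
#' @export
genomeSegments <- function(genome) {
  gr <- genome@segments
  data.frame(chrom = as.character(seqnames(gr)), start = .start0(gr),
             end = .end0(gr), label = mcols(gr)$label,
             ies_id = mcols(gr)$ies_id, stringsAsFactors = FALSE)
}

#' @describeIn segmentedGenome named chromosome length vector.
#' @export
chromLengths <- function(genome) seqlengths(genome@segments)

#' @describeIn segmentedGenome number of IESs, optionally of one type.
#' @param type `"A"`, `"B"` or `NULL` for all IESs.
#' @export
iesCount <- function(genome, type = NULL) {
  lab <- mcols(genome@segments)$label
  if (is.null(type)) sum(lab != "MDS")
  else sum(lab == paste0("IES_", match.arg(type, c("A", "B"))))
}

.iesRanges <- function(genome, type = NULL) {
  gr <- genome@segments
  lab <- mcols(gr)$label
  keep <- if (is.null(type)) lab != "MDS" else lab == paste0("IES_", type)
  gr[keep]
}

#' Oriented boundary windows for every IES
#'
#' Derives the two boundary windows (left and right edge) of every IES: a
#' window of width `windowWidth` immediately inside the IES and one
#' immediately outside in the flanking sequence, both abutting the edge.
#' Windows are the unit of boundary meta-profiling and of the broken
#' boundary index. A window is `eligible` only when both its inside and
#' outside intervals have the full width (IESs shorter than `windowWidth`,
#' or edges within `windowWidth` of a chromosome end, are flagged out, not
#' truncated). Outside windows that overlap a neighboring IES are kept but
#' flagged `overlaps_foreign_ies`; the two inside windows of one IES overlap
#' each other iff the IES is shorter than `2 * windowWidth`, flagged
#' `sides_overlap`.
#'
#' @param genome a [SegmentedGenome-class].
#' @param windowWidth window width in bases (default 500).
#' @return data.frame with one row per boundary: `ies_id`, `side`
#'   (`left`/`right`), `ies_type` (`A`/`B`), `chrom`, `boundary_pos` (0-based
#'   position of the IES edge), `inside_start`, `inside_end`,
#'   `outside_start`, `outside_end` (0-based half-open), `orientation_sign`
#'   (+1 left, -1 right), `eligible`, `overlaps_foreign_ies`,
#'   `sides_overlap`.
#' @export
boundaries <- function(genome, windowWidth = 500) {
  stopifnot(windowWidth > 0)
  W <- as.integer(windowWidth)
  ies <- .iesRanges(genome)
  if (length(ies) == 0L)
    return(data.frame(ies_id = character(0), side = character(0),
                      ies_type = character(0), chrom = character(0),
                      boundary_pos = integer(0), inside_start = integer(0),
                      inside_end = integer(0), outside_start = integer(0),
                      outside_end = integer(0), orientation_sign = integer(0),
                      eligible = logical(0),
                      overlaps_foreign_ies = logical(0),
                      sides_overlap = logical(0)))
  chr <- as.character(seqnames(ies))
  s <- .start0(ies); e <- .end0(ies)
  len <- e - s
  clen <- seqlengths(ies)[chr]
  id <- mcols(ies)$ies_id
  typ <- sub("IES_", "", mcols(ies)$label)

  mk <- function(side) {
    if (side == "left") {
      inS <- s; inE <- pmin(s + W, e)
      outS <- pmax(s - W, 0L); outE <- s
      b <- s; sign <- 1L
    } else {
      inS <- pmax(e - W, s); inE <- e
      outS <- e; outE <- pmin(e + W, clen)
      b <- e; sign <- -1L
    }
    data.frame(ies_id = id, side = side, ies_type = typ, chrom = chr,
               boundary_pos = b, inside_start = inS, inside_end = inE,
               outside_start = outS, outside_end = outE,
               orientation_sign = sign,
               eligible = (inE - inS == W) & (outE - outS == W),
               overlaps_foreign_ies = FALSE,
               sides_overlap = len < 2L * W,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  bw <- rbind(mk("left"), mk("right"))
  bw <- bw[order(bw$chrom, bw$inside_start, bw$side), , drop = FALSE]
  rownames(bw) <- NULL

  nonEmpty <- bw$outside_end > bw$outside_start
  if (any(nonEmpty)) {
    outGr <- .gr0(bw$chrom[nonEmpty], bw$outside_start[nonEmpty],
                  bw$outside_end[nonEmpty])
    hits <- GenomicRanges::findOverlaps(outGr, ies)
    foreign <- id[subjectHits(hits)] != bw$ies_id[nonEmpty][queryHits(hits)]
    flag <- logical(sum(nonEmpty))
    flag[unique(queryHits(hits)[foreign])] <- TRUE
    bw$overlaps_foreign_ies[nonEmpty] <- flag
  }
  bw
}

#' Reflect a genome (and reads) end-for-end
#'
#' Maps every coordinate `x` to `L - x` on its chromosome, turning left IES
#' boundaries into right boundaries and vice versa, and flipping read
#' strands. Boundary meta-profiles built with the 5'-end or 13th-nt anchor
#' are invariant under this reflection, which is used as a correctness check
#' of the right-boundary mirroring.
#'
#' @param genome a `SegmentedGenome`.
#' @return The reflected `SegmentedGenome`.
#' @export
reflectGenome <- function(genome) {
  seg <- genomeSegments(genome)
  cl <- chromLengths(genome)
  L <- cl[seg$chrom]
  new <- data.frame(chrom = seg$chrom, start = L - seg$end,
                    end = L - seg$start, label = seg$label,
                    ies_id = seg$ies_id, stringsAsFactors = FALSE)
  new <- new[new$label != "MDS", , drop = FALSE]
  segmentedGenome(new, cl)
}

#' @describeIn reflectGenome reflect a stranded read `GRanges` in the same
#'   coordinate flip (interval reversed, strand inverted).
#' @param reads a `GRanges` of reads.
#' @param chromLens named chromosome length vector.
#' @export
reflectReads <- function(reads, chromLens) {
  chr <- as.character(seqnames(reads))
  L <- chromLens[chr]
  s0 <- .start0(reads); e0 <- .end0(reads)
  st <- as.character(strand(reads))
  .gr0(chr, L - e0, L - s0,
       strand = ifelse(st == "+", "-", ifelse(st == "-", "+", "*")),
       chromLengths = chromLens)
}

#' @export
setMethod("show", "SegmentedGenome", function(object) {
  sl <- seqlengths(object@segments)
  cat(sprintf("SegmentedGenome: %d chromosome(s), %.0f bp total\n",
              length(sl), sum(as.numeric(sl))))
  cat(sprintf("  IESs: %d type-A, %d type-B; %d MDS segments\n",
              iesCount(object, "A"), iesCount(object, "B"),
              sum(mcols(object@segments)$label == "MDS")))
})
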