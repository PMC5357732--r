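suppressPackageStartupMessages({
  library(GenomicRanges)
})

## Reads from 0-based half-open coordinates.
mkReads <- function(chrom, start0, end0, strand = "+", chromLens = NULL) {
  gr <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = strand)
  if (!is.null(chromLens)) {
    GenomeInfoDb::seqlevels(gr) <- names(chromLens)
    GenomeInfoDb::seqlengths(gr) <- unname(chromLens)
  }
  gr
}

## One type-A IES [1000,3000) on a 10 kb chromosome.
toyGenome <- function() {
  segmentedGenome(
    data.frame(chrom = "chr1", start = 1000, end = 3000, label = "IES_A",
               ies_id = "iesA1"),
    c(chr1 = 10000))
}

## Count reads whose anchors land in [s0, e0) on `chrom` — brute force.
naiveWindowCount <- function(reads, anchorMode, chrom, s0, e0) {
  a0 <- anchorPositions(reads, anchorMode)
  sum(as.character(seqnames(reads)) == chrom & a0 >= s0 & a0 < e0)
}

## Independent meta-profile oracle: loop over boundaries and reads, apply
## the mirroring arithmetic directly, sum raw counts per bin and strand.
naiveMetaProfile <- function(lib, genome, iesType, binSize, window,
                             anchorMode = "nt13") {
  bw <- boundaries(genome, window)
  bw <- bw[bw$ies_type == iesType & bw$eligible, , drop = FALSE]
  reads <- filteredReads(lib)
  a0 <- anchorPositions(reads, anchorMode)
  st <- as.character(strand(reads))
  chr <- as.character(seqnames(reads))
  nb <- ceiling(2 * window / binSize)
  sense <- numeric(nb); anti <- numeric(nb)
  for (i in seq_len(nrow(bw))) {
    b <- bw$boundary_pos[i]
    for (j in seq_along(a0)) {
      if (chr[j] != bw$chrom[i]) next
      if (a0[j] < b - window || a0[j] >= b + window) next
      off <- if (bw$side[i] == "left") a0[j] - b else b - 1L - a0[j]
      k <- (off + window) %/% binSize + 1L
      isSense <- if (bw$side[i] == "left") st[j] == "+" else st[j] == "-"
      if (isSense) sense[k] <- sense[k] + 1 else anti[k] <- anti[k] + 1
    }
  }
  list(sense = sense, antisense = anti, n = nrow(bw))
}

## Anchors (0-based) falling inside any IES of the genome.
mdsAnchored <- function(lib, genome, anchorMode = "five_prime") {
  fr <- filteredReads(lib)
  if (length(fr) == 0L) return(0L)
  a0 <- anchorPositions(fr, anchorMode)
  seg <- genomeSegments(genome)
  ies <- seg[seg$label != "MDS", , drop = FALSE]
  anch <- GRanges(as.character(seqnames(fr)), IRanges(a0 + 1L, a0 + 1L))
  iesGr <- GRanges(ies$chrom, IRanges(ies$start + 1L, ies$end))
  sum(GenomicRanges::countOverlaps(anch, iesGr) == 0L)
}
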