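#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<- seqnames
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom BiocGenerics strand start end width
NULL

SEGMENT_LABELS <- c("MDS", "IES_A", "IES_B")

#' Segmented germline genome
#'
#' An ordered, gap-free tiling of each chromosome into labeled segments:
#' MAC-destined sequence (`MDS`), type-A IES (`IES_A`) or type-B IES
#' (`IES_B`). The segmentation is the coordinate frame for boundary windows,
#' meta-profiles and the broken boundary index. Internally segments are held
#' as a [GenomicRanges::GRanges] (1-based closed, Bioconductor convention);
#' all exported tables and files use 0-based half-open (BED) coordinates.
#'
#' @slot segments A `GRanges` with metadata columns `label` (one of `MDS`,
#'   `IES_A`, `IES_B`) and `ies_id` (non-empty for IES segments, `""` for
#'   MDS). Seqinfo carries the chromosome lengths.
#'
#' @seealso [segmentedGenome()], [loadSegmentation()], [boundaries()]
#' @export
setClass("SegmentedGenome", representation(segments = "GRanges"))

setValidity("SegmentedGenome", function(object) {
  gr <- object@segments
  msg <- character(0)
  need <- c("label", "ies_id")
  if (!all(need %in% names(mcols(gr))))
    return("segments must carry 'label' and 'ies_id' metadata columns")
  lab <- mcols(gr)$label
  if (!all(lab %in% SEGMENT_LABELS))
    msg <- c(msg, "segment labels must be MDS, IES_A or IES_B")
  ids <- mcols(gr)$ies_id
  if (any(lab != "MDS" & (is.na(ids) | ids == "")))
    msg <- c(msg, "every IES segment needs a non-empty ies_id")
  if (any(lab == "MDS" & ids != ""))
    msg <- c(msg, "MDS segments must have empty ies_id")
  iesIds <- ids[lab != "MDS"]
  if (anyDuplicated(iesIds))
    msg <- c(msg, "ies_id values must be unique")
  sl <- seqlengths(gr)
  if (any(is.na(sl)))
    msg <- c(msg, "all chromosome lengths must be known")
  for (chr in seqlevels(gr)) {
    g <- gr[as.character(seqnames(gr)) == chr]
    if (length(g) == 0L) {
      msg <- c(msg, sprintf("chromosome %s has no segments", chr))
      next
    }
    o <- order(start(g))
    g <- g[o]
    if (start(g)[1L] != 1L)
      msg <- c(msg, sprintf("%s: first segment does not start at position 0", chr))
    if (end(g)[length(g)] != sl[[chr]])
      msg <- c(msg, sprintf("%s: last segment does not reach the chromosome end", chr))
    if (length(g) > 1L) {
      if (any(start(g)[-1L] != end(g)[-length(g)] + 1L))
        msg <- c(msg, sprintf("%s: segments do not tile the chromosome", chr))
      adjMds <- mcols(g)$label[-1L] == "MDS" & mcols(g)$label[-length(g)] == "MDS"
      if (any(adjMds))
        msg <- c(msg, sprintf("%s: adjacent MDS segments must be merged", chr))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Small-RNA (or ChIP) read library
#'
#' Holds mapped reads as a stranded `GRanges` together with the scnRNA
#' length-filter bounds and the RPM normalization factor. For scnRNA
#' libraries the default filter keeps 26-32 nt reads (inclusive); ChIP and
#' input libraries are built with `minLen = NULL` (no length filter). The
#' RPM denominator is the number of reads passing the filter, recorded in
#' `totalFiltered`, with `rpmFactor = 1e6 / totalFiltered`.
#'
#' @slot reads `GRanges` of all mapped reads (strand `+`/`-`).
#' @slot minLen,maxLen numeric filter bounds; `NA` when no filter applies.
#' @slot totalFiltered number of reads passing the filter.
#' @slot rpmFactor `1e6 / totalFiltered` (`NA` for an empty library).
#' @slot name library label used in messages and metadata.
#'
#' @seealso [scnLibrary()], [filterScnrna()], [rpm()]
#' @export
setClass("ScnLibrary", representation(
  reads = "GRanges",
  minLen = "numeric",
  maxLen = "numeric",
  totalFiltered = "numeric",
  rpmFactor = "numeric",
  name = "character"
))

setValidity("ScnLibrary", function(object) {
  msg <- character(0)
  if (object@totalFiltered < 0)
    msg <- c(msg, "totalFiltered must be >= 0")
  if (object@totalFiltered > 0 &&
      abs(object@rpmFactor * object@totalFiltered - 1e6) > 1e-6)
    msg <- c(msg, "rpmFactor * totalFiltered must equal 1e6")
  if (!is.na(object@minLen) && !is.na(object@maxLen) &&
      object@minLen > object@maxLen)
    msg <- c(msg, "minLen must not exceed maxLen")
  if (length(msg)) msg else TRUE
})

#' ChIP / input library pair
#'
#' Couples a ChIP library with its matched input (chromatin) library.
#' Enrichment profiles are reported as the per-bin ratio of RPM-normalized
#' ChIP counts over input counts.
#'
#' @slot chip,input [ScnLibrary-class] objects built without a length filter.
#' @seealso [chipPair()], [chipRatio()]
#' @export
setClass("ChipPair", representation(chip = "ScnLibrary", input = "ScnLibrary"))

setValidity("ChipPair", function(object) {
  msg <- character(0)
  if (length(object@chip@reads) == 0L)
    msg <- c(msg, "chip library is empty")
  if (length(object@input@reads) == 0L)
    msg <- c(msg, "input library is empty")
  if (length(msg)) msg else TRUE
})

#' Binned coverage / enrichment profile
#'
#' A per-bin profile either over a genomic locus (`mode = "locus"`) or over
#' the compiled boundary meta-axis (`mode = "meta"`, offsets from `-W`
#' outside the IES to `+W` inside; the bin whose left edge is offset 0 is
#' the first bin inside the IES). `sense`/`antisense` hold normalized
#' values (`RPM` or `chip_over_input`); `rawSense`/`rawAntisense` hold the
#' underlying raw anchor counts. For unstranded values (ChIP ratios) the
#' `antisense` vector is empty. Masked ratio bins (input RPM = 0) are `NA`.
#'
#' @slot mode `"locus"` or `"meta"`.
#' @slot chrom locus chromosome (`""` in meta mode).
#' @slot start,end 0-based half-open locus span, or `-W`/`+W` in meta mode.
#' @slot binSize bin width in bases.
#' @slot offsets left edge of every bin (0-based genomic position in locus
#'   mode; signed boundary offset in meta mode).
#' @slot sense,antisense per-bin normalized values.
#' @slot rawSense,rawAntisense per-bin raw anchor counts.
#' @slot valueKind `"raw_count"`, `"RPM"` or `"chip_over_input"`.
#' @slot nBoundaries number of boundaries compiled (meta mode; 0 otherwise).
#' @slot params list of the parameters the profile was built with.
#' @export
setClass("BinnedProfile", representation(
  mode = "character",
  chrom = "character",
  start = "numeric",
  end = "numeric",
  binSize = "numeric",
  offsets = "numeric",
  sense = "numeric",
  antisense = "numeric",
  rawSense = "numeric",
  rawAntisense = "numeric",
  valueKind = "character",
  nBoundaries = "integer",
  params = "list"
))

setValidity("BinnedProfile", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("locus", "meta"))
    msg <- c(msg, "mode must be 'locus' or 'meta'")
  nb <- length(object@offsets)
  if (length(object@sense) != nb)
    msg <- c(msg, "sense values and offsets differ in length")
  if (length(object@antisense) && length(object@antisense) != nb)
    msg <- c(msg, "antisense values and offsets differ in length")
  if (nb != ceiling((object@end - object@start) / object@binSize))
    msg <- c(msg, "bin count must be ceiling(span / bin size)")
  if (length(msg)) msg else TRUE
})
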