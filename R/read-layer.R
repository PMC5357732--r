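## Read ingestion, the 26-32 nt scnRNA filter, anchor arithmetic and RPM.

#' Read mapped reads from BED6
#'
#' Ingests alignment records (chrom, start, end, name, score, strand) as a
#' stranded `GRanges`. Strand is required for small-RNA libraries.
#'
#' @param path BED6 file path.
#' @param requireStrand error on any record without `+`/`-` strand.
#' @return A `GRanges`.
#' @export
readBed6 <- function(path, requireStrand = TRUE) {
  gr <- rtracklayer::import(path, format = "BED")
  if (requireStrand && any(as.character(strand(gr)) == "*"))
    stop("BED records in ", path, " lack strand information")
  mcols(gr) <- NULL
  gr
}

#' @describeIn readBed6 write reads as BED6 (name `.`, score 0).
#' @param reads a `GRanges`.
#' @export
writeBed6 <- function(reads, path) {
  out <- reads
  mcols(out) <- NULL
  mcols(out)$name <- rep(".", length(out))
  mcols(out)$score <- rep(0L, length(out))
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' scnRNA length filter
#'
#' Keeps reads whose length is within `[minLen, maxLen]` (inclusive; the
#' scnRNA class is 26-32 nt). Order is preserved and the filter is
#' idempotent.
#'
#' @param reads `GRanges` of mapped reads.
#' @param minLen,maxLen inclusive length bounds in nt.
#' @return The filtered `GRanges`.
#' @export
filterScnrna <- function(reads, minLen = 26, maxLen = 32) {
  if (minLen > maxLen)
    stop("minLen (", minLen, ") must not exceed maxLen (", maxLen, ")")
  reads[width(reads) >= minLen & width(reads) <= maxLen]
}

#' Construct a read library
#'
#' Wraps mapped reads into a [ScnLibrary-class]. With the default bounds the
#' scnRNA filter (26-32 nt) defines `totalFiltered` and hence the RPM
#' factor; pass `minLen = NULL` for ChIP/input libraries, where every mapped
#' read counts.
#'
#' @param reads `GRanges` of mapped reads, or a BED6 path.
#' @param minLen,maxLen scnRNA filter bounds; `NULL` to disable the filter.
#' @param name library label used in messages and metadata.
#' @return An `ScnLibrary`.
#' @export
scnLibrary <- function(reads, minLen = 26, maxLen = 32, name = "library") {
  if (is.character(reads)) reads <- readBed6(reads)
  noFilter <- is.null(minLen) || is.null(maxLen)
  tf <- if (noFilter) length(reads)
        else length(filterScnrna(reads, minLen, maxLen))
  new("ScnLibrary", reads = reads,
      minLen = if (noFilter) NA_real_ else minLen,
      maxLen = if (noFilter) NA_real_ else maxLen,
      totalFiltered = as.numeric(tf),
      rpmFactor = if (tf > 0) 1e6 / tf else NA_real_,
      name = name)
}

#' @describeIn scnLibrary the reads passing the library's filter.
#' @param lib an `ScnLibrary`.
#' @export
filteredReads <- function(lib) {
  if (is.na(lib@minLen)) lib@reads
  else filterScnrna(lib@reads, lib@minLen, lib@maxLen)
}

#' @describeIn scnLibrary number of reads passing the filter (the RPM
#'   denominator).
#' @export
totalFiltered <- function(lib) lib@totalFiltered

#' @describeIn scnLibrary the factor `1e6 / totalFiltered`.
#' @export
rpmFactor <- function(lib) lib@rpmFactor

#' @describeIn scnLibrary library label.
#' @export
libraryName <- function(lib) lib@name

#' Pair a ChIP library with its input
#'
#' @param chip,input [ScnLibrary-class] objects (no length filter), or
#'   `GRanges`/BED6 paths, in which case unfiltered libraries are built.
#' @return A [ChipPair-class].
#' @export
chipPair <- function(chip, input) {
  if (!is(chip, "ScnLibrary"))
    chip <- scnLibrary(chip, minLen = NULL, maxLen = NULL, name = "chip")
  if (!is(input, "ScnLibrary"))
    input <- scnLibrary(input, minLen = NULL, maxLen = NULL, name = "input")
  new("ChipPair", chip = chip, input = input)
}

#' Anchor position of mapped reads
#'
#' The single base each read is counted at, 0-based: `five_prime` is the 5'
#' end (start for `+` reads, `end - 1` for `-` reads), used for 100-bp locus
#' profiles; `nt13` is the 13th nucleotide (`start + 12` / `end - 13`), used
#' for 10-bp meta-profile and 50-bp heatmap bins; `midpoint` is the fragment
#' midpoint (`floor((start + end) / 2)`), used for ChIP fragments.
#'
#' @param reads `GRanges` of reads.
#' @param mode `"five_prime"`, `"nt13"` or `"midpoint"`.
#' @return Integer vector of 0-based anchor positions, one per read.
#' @export
anchorPositions <- function(reads, mode = c("five_prime", "nt13", "midpoint")) {
  mode <- match.arg(mode)
  s0 <- .start0(reads); e0 <- .end0(reads)
  st <- as.character(strand(reads))
  if (mode == "nt13" && any(e0 - s0 < 13))
    stop("nt13 anchor requires read length >= 13 nt")
  switch(mode,
    five_prime = ifelse(st == "-", e0 - 1L, s0),
    nt13 = ifelse(st == "-", e0 - 13L, s0 + 12L),
    midpoint = floor((s0 + e0) / 2))
}

#' Reads-per-million normalization
#'
#' @param count raw read (anchor) count in a bin or window.
#' @param lib the [ScnLibrary-class] providing the denominator.
#' @return `count * 1e6 / totalFiltered(lib)`.
#' @export
rpm <- function(count, lib) {
  if (lib@totalFiltered <= 0)
    stop("library '", lib@name, "' has no filtered reads; cannot normalize")
  count * lib@rpmFactor
}

#' Write per-library JSON metadata
#'
#' Records read totals, the filter bounds and the RPM factor, so normalized
#' profiles remain interpretable.
#'
#' @param lib an `ScnLibrary`.
#' @param path output JSON path.
#' @export
writeLibraryMeta <- function(lib, path) {
  jsonlite::write_json(list(
    name = lib@name,
    n_reads = length(lib@reads),
    filter_min_len = lib@minLen,
    filter_max_len = lib@maxLen,
    total_filtered = lib@totalFiltered,
    rpm_factor = lib@rpmFactor,
    rpm_denominator = "reads passing the length filter (all mapped reads when no filter)"
  ), path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @export
setMethod("show", "ScnLibrary", function(object) {
  filt <- if (is.na(object@minLen)) "no length filter"
          else sprintf("%g-%g nt filter", object@minLen, object@maxLen)
  cat(sprintf("ScnLibrary '%s': %d reads (%s; %.0f pass)\n",
              object@name, length(object@reads), filt, object@totalFiltered))
})

#' @export
setMethod("show", "ChipPair", function(object) {
  cat(sprintf("ChipPair: chip '%s' (%d reads) / input '%s' (%d reads)\n",
              object@chip@name, length(object@chip@reads),
              object@input@name, length(object@input@reads)))
})
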