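## Seeded synthetic-data generator: toy segmented genomes and simulated
## scnRNA / ChIP libraries with the statistical structure the analysis
## assumes (stage-dependent scnRNA origin, scnRNA selection, per-boundary
## spreading into MDS, IES-enriched ChIP). Coordinates/lengths/strands only;
## no nucleotide sequence is generated.

#' Simulation configuration
#'
#' Collects every generator parameter; all randomness is driven by `seed`
#' (Mersenne-Twister via [withr::with_seed()]), so identical configurations
#' give bit-identical output.
#'
#' @param seed integer RNG seed.
#' @param nChrom,chromLength number and length (bp) of chromosomes.
#' @param nIesA,nIesB number of type-A / type-B IESs.
#' @param iesLengthRange,mdsLengthRange inclusive length ranges (bp) that
#'   IES and MDS segments are drawn from uniformly.
#' @param stage `"late"`, `"early_3h"` or `"post_selection_6h"`: Early
#'   scnRNAs arise from type-A IESs plus flanking MDS; after scnRNA
#'   selection the MDS-mapped fraction is purged; Late scnRNAs arise from
#'   type-A and type-B IES bodies.
#' @param nReads number of reads to simulate (before `globalScale`).
#' @param lengthDist probabilities of read lengths 26..32 nt (sums to 1).
#' @param contaminantFraction fraction of reads given out-of-range lengths
#'   (drawn uniformly from 20-25 and 33-40 nt, exercising both filter
#'   edges); placement follows the same rules as scnRNA-length reads.
#' @param spread `NULL` or data.frame(`ies_id`, `side`, `f`, `lambda`):
#'   at each listed boundary a fraction `f` of its proximal reads (within
#'   `spreadProximal` bp of the edge) is displaced outside, at a distance
#'   drawn from a one-sided exponential with mean `lambda` bp truncated at
#'   the adjacent MDS segment.
#' @param spreadProximal proximity window (bp) defining which reads a
#'   spread boundary can displace (default 500).
#' @param selectionEfficiency probability that an MDS-mapped Early scnRNA
#'   is removed at the `post_selection_6h` stage.
#' @param lateTypeBFraction share of late-stage reads drawn from type-B
#'   IESs (the rest from type-A).
#' @param earlyFlankFraction share of early-stage reads drawn from the MDS
#'   flanks of type-A IESs (the rest from type-A bodies).
#' @param earlyLambda decay length (bp) of the early-stage flank
#'   distribution, same truncated-exponential kernel as `spread`.
#' @param chipEnrichment ChIP fragment density over IES bodies relative to
#'   MDS (>= 1).
#' @param chipFragRange inclusive ChIP fragment length range (bp).
#' @param globalScale multiplier on `nReads` (global small-RNA elevation,
#'   as seen on loss of a genome-wide negative regulator).
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L, nChrom = 1L, chromLength = 1e6,
                      nIesA = 10L, nIesB = 10L,
                      iesLengthRange = c(1000, 3000),
                      mdsLengthRange = c(1000, 3000),
                      stage = c("late", "early_3h", "post_selection_6h"),
                      nReads = 1e5,
                      lengthDist = c(0.05, 0.15, 0.25, 0.25, 0.15, 0.10, 0.05),
                      contaminantFraction = 0.05,
                      spread = NULL, spreadProximal = 500,
                      selectionEfficiency = 0.9,
                      lateTypeBFraction = 0.5,
                      earlyFlankFraction = 0.3, earlyLambda = 200,
                      chipEnrichment = 5, chipFragRange = c(150, 250),
                      globalScale = 1) {
  stage <- match.arg(stage)
  stopifnot(nChrom >= 1, chromLength > 0, nIesA >= 0, nIesB >= 0,
            nIesA + nIesB > 0, nReads > 0, globalScale > 0,
            length(lengthDist) == 7, all(lengthDist >= 0),
            contaminantFraction >= 0, contaminantFraction <= 1,
            selectionEfficiency >= 0, selectionEfficiency <= 1,
            lateTypeBFraction >= 0, lateTypeBFraction <= 1,
            earlyFlankFraction >= 0, earlyFlankFraction <= 1,
            earlyLambda > 0, chipEnrichment >= 1,
            diff(iesLengthRange) >= 0, diff(mdsLengthRange) >= 0,
            iesLengthRange[1] > 0, mdsLengthRange[1] > 0)
  if (abs(sum(lengthDist) - 1) > 1e-8)
    stop("lengthDist must sum to 1")
  if (!is.null(spread)) {
    need <- c("ies_id", "side", "f", "lambda")
    if (!all(need %in% names(spread)))
      stop("spread needs columns ies_id, side, f, lambda")
    stopifnot(all(spread$f >= 0 & spread$f <= 1), all(spread$lambda > 0),
              all(spread$side %in% c("left", "right")))
  }
  structure(list(
    seed = as.integer(seed), nChrom = as.integer(nChrom),
    chromLength = chromLength, nIesA = as.integer(nIesA),
    nIesB = as.integer(nIesB), iesLengthRange = iesLengthRange,
    mdsLengthRange = mdsLengthRange, stage = stage, nReads = nReads,
    lengthDist = lengthDist, contaminantFraction = contaminantFraction,
    spread = spread, spreadProximal = spreadProximal,
    selectionEfficiency = selectionEfficiency,
    lateTypeBFraction = lateTypeBFraction,
    earlyFlankFraction = earlyFlankFraction, earlyLambda = earlyLambda,
    chipEnrichment = chipEnrichment, chipFragRange = chipFragRange,
    globalScale = globalScale), class = "SimConfig")
}

## sample() that never falls into the scalar-x gotcha.
.sampleFrom <- function(x, n, prob = NULL)
  x[sample.int(length(x), n, replace = TRUE, prob = prob)]

## Sample from Exp(lambda) truncated at `upper` (one per element).
.truncExp <- function(n, lambda, upper) {
  u <- stats::runif(n) * (1 - exp(-upper / lambda))
  -lambda * log(1 - u)
}

.iesTable <- function(genome) {
  seg <- genomeSegments(genome)
  ies <- seg[seg$label != "MDS", , drop = FALSE]
  ies$len <- ies$end - ies$start
  rownames(ies) <- NULL
  ies
}

## Adjacent-MDS length for each (ies row, side); 0 when an IES abuts.
.adjacentMds <- function(genome) {
  seg <- genomeSegments(genome)
  idx <- which(seg$label != "MDS")
  adjLen <- function(i) {
    if (i < 1L || i > nrow(seg)) return(0)
    if (seg$label[i] == "MDS") seg$end[i] - seg$start[i] else 0
  }
  sameChrom <- function(i, j)
    i >= 1L && j <= nrow(seg) && seg$chrom[i] == seg$chrom[j]
  data.frame(
    ies_id = seg$ies_id[idx],
    left = vapply(idx, function(i)
      if (sameChrom(i - 1L, i)) adjLen(i - 1L) else 0, numeric(1)),
    right = vapply(idx, function(i)
      if (sameChrom(i, i + 1L)) adjLen(i + 1L) else 0, numeric(1)))
}

#' Generate a toy segmented genome
#'
#' Lays out alternating MDS / IES segments per chromosome: IESs (types
#' shuffled under the seed, counts from the config) are distributed
#' round-robin over the chromosomes, segment lengths drawn uniformly from
#' the configured ranges, and the final MDS stretched to the chromosome
#' end. Deterministic under `cfg$seed`.
#'
#' @param cfg a [simConfig()].
#' @return A [SegmentedGenome-class].
#' @export
makeGenome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  withr::with_seed(cfg$seed, {
    nIes <- cfg$nIesA + cfg$nIesB
    types <- sample(rep(c("IES_A", "IES_B"), c(cfg$nIesA, cfg$nIesB)))
    chromOf <- rep(seq_len(cfg$nChrom), length.out = nIes)
    chromNames <- sprintf("chr%d", seq_len(cfg$nChrom))
    rows <- list()
    for (k in seq_len(cfg$nChrom)) {
      tk <- types[chromOf == k]
      m <- length(tk)
      if (m == 0L) stop("more chromosomes than IESs: reduce nChrom")
      iesLen <- .sampleFrom(seq(cfg$iesLengthRange[1], cfg$iesLengthRange[2]), m)
      mdsLen <- .sampleFrom(seq(cfg$mdsLengthRange[1], cfg$mdsLengthRange[2]),
                            m + 1L)
      if (sum(iesLen) + sum(mdsLen) > cfg$chromLength)
        stop(sprintf("infeasible packing: %d IES + %d MDS bp exceed chromLength %g",
                     sum(iesLen), sum(mdsLen), cfg$chromLength))
      s <- cumsum(mdsLen[-(m + 1L)] + c(0, iesLen[-m]))
      rows[[k]] <- data.frame(chrom = chromNames[k], start = s,
                              end = s + iesLen, label = tk,
                              stringsAsFactors = FALSE)
    }
    ies <- do.call(rbind, rows)
    ies$ies_id <- sprintf("ies%05d", seq_len(nrow(ies)))
    segmentedGenome(ies, stats::setNames(rep(cfg$chromLength, cfg$nChrom),
                                         chromNames))
  })
}

## Displace anchors across spread boundaries. a0: anchor positions;
## iesRow: row index into iesTab per anchor (NA when not in an IES).
.applySpread <- function(a0, iesRow, iesTab, adj, cfg) {
  sp <- cfg$spread
  if (is.null(sp) || nrow(sp) == 0L) return(a0)
  moved <- logical(length(a0))
  for (i in seq_len(nrow(sp))) {
    r <- match(sp$ies_id[i], iesTab$ies_id)
    if (is.na(r)) stop("spread boundary refers to unknown IES ", sp$ies_id[i])
    mdsLen <- adj[match(sp$ies_id[i], adj$ies_id),
                  if (sp$side[i] == "left") "left" else "right"]
    if (mdsLen <= 0) next
    prox <- !moved & !is.na(iesRow) & iesRow == r &
      (if (sp$side[i] == "left") a0 - iesTab$start[r] < cfg$spreadProximal
       else iesTab$end[r] - 1L - a0 < cfg$spreadProximal)
    hit <- which(prox)[stats::runif(sum(prox)) < sp$f[i]]
    if (length(hit)) {
      d <- floor(.truncExp(length(hit), sp$lambda[i], mdsLen))
      a0[hit] <- if (sp$side[i] == "left") iesTab$start[r] - 1L - d
                 else iesTab$end[r] + d
      moved[hit] <- TRUE
    }
  }
  a0
}

## Build read GRanges from 0-based 5' anchors, strands and lengths,
## clamping the rare read that would overrun a chromosome end.
.readsFromAnchors <- function(chrom, a0, plus, len, chromLens) {
  L <- chromLens[chrom]
  s0 <- ifelse(plus, a0, a0 - len + 1L)
  s0 <- pmax(0L, pmin(s0, L - len))
  .gr0(chrom, s0, s0 + len, strand = ifelse(plus, "+", "-"),
       chromLengths = chromLens)
}

#' Simulate a scnRNA library
#'
#' Draws reads according to the configured conjugation stage. Body reads
#' are transcript fragments of their source IES, placed so the whole read
#' lies within the segment; flank and displaced reads are 5'-anchored in
#' the MDS and may straddle the boundary. Stages: `early_3h` from type-A
#' IES bodies plus their MDS flanks (truncated
#' exponential decay, `earlyLambda`); `post_selection_6h` the same followed
#' by removal of MDS-anchored reads with probability
#' `selectionEfficiency` (scnRNA selection); `late` from type-A and type-B
#' IES bodies, with optional per-boundary displacement into MDS
#' (`cfg$spread`, emulating ectopic Late-scnRNA production). Read lengths
#' come from `lengthDist` plus out-of-range contaminants; strands are
#' Bernoulli(0.5). Deterministic under the seed.
#'
#' @param cfg a [simConfig()].
#' @param genome the [SegmentedGenome-class] to simulate on.
#' @param seed RNG seed (defaults to `cfg$seed`; pass different seeds for
#'   independent replicate libraries).
#' @param name library label.
#' @return An [ScnLibrary-class] with the standard 26-32 nt filter.
#' @export
simulateScnrna <- function(cfg, genome, seed = cfg$seed,
                           name = paste0("sim_", cfg$stage)) {
  stopifnot(inherits(cfg, "SimConfig"))
  withr::with_seed(as.integer(seed), {
    n <- round(cfg$nReads * cfg$globalScale)
    iesTab <- .iesTable(genome)
    adj <- .adjacentMds(genome)
    chromLens <- chromLengths(genome)

    contam <- stats::runif(n) < cfg$contaminantFraction
    len <- integer(n)
    len[!contam] <- sample(26:32, sum(!contam), replace = TRUE,
                           prob = cfg$lengthDist)
    len[contam] <- sample(c(20:25, 33:40), sum(contam), replace = TRUE)
    plus <- stats::runif(n) < 0.5

    ## Body reads are fragments of the segment's transcript: the whole read
    ## interval is placed within the segment, so no anchor (5' or nt13) of a
    ## body read ever falls outside it.
    drawBody <- function(sel, tab) {
      k <- sum(sel)
      idx <- sample.int(nrow(tab), k, replace = TRUE, prob = tab$len)
      l <- len[sel]; p <- plus[sel]
      nPos <- tab$len[idx] - l + 1
      if (any(nPos < 1))
        stop("an IES is shorter than a read; increase iesLengthRange")
      off <- floor(stats::runif(k) * nPos)
      list(row = idx,
           a0 = tab$start[idx] + ifelse(p, off, l - 1L + off))
    }

    if (cfg$stage %in% c("early_3h", "post_selection_6h")) {
      aTab <- iesTab[iesTab$label == "IES_A", , drop = FALSE]
      if (nrow(aTab) == 0L) stop("early stages need at least one type-A IES")
      flank <- stats::runif(n) < cfg$earlyFlankFraction
      a0 <- integer(n); chrom <- character(n)
      body <- drawBody(!flank, aTab)
      a0[!flank] <- body$a0
      chrom[!flank] <- aTab$chrom[body$row]
      nf <- sum(flank)
      if (nf) {
        bTab <- rbind(
          data.frame(chrom = aTab$chrom, edge = aTab$start, dir = -1L,
                     mds = adj$left[match(aTab$ies_id, adj$ies_id)]),
          data.frame(chrom = aTab$chrom, edge = aTab$end, dir = 1L,
                     mds = adj$right[match(aTab$ies_id, adj$ies_id)]))
        bTab <- bTab[bTab$mds > 0, , drop = FALSE]
        bi <- sample.int(nrow(bTab), nf, replace = TRUE)
        d <- floor(.truncExp(nf, cfg$earlyLambda, bTab$mds[bi]))
        a0[flank] <- ifelse(bTab$dir[bi] < 0, bTab$edge[bi] - 1L - d,
                            bTab$edge[bi] + d)
        chrom[flank] <- bTab$chrom[bi]
      }
      if (cfg$stage == "post_selection_6h") {
        drop <- flank & stats::runif(n) < cfg$selectionEfficiency
        a0 <- a0[!drop]; chrom <- chrom[!drop]
        len <- len[!drop]; plus <- plus[!drop]
      }
    } else {
      hasB <- any(iesTab$label == "IES_B")
      typeB <- if (hasB) stats::runif(n) < cfg$lateTypeBFraction
               else rep(FALSE, n)
      a0 <- integer(n); chrom <- character(n); row <- integer(n)
      for (tb in c(FALSE, TRUE)) {
        if (!any(typeB == tb)) next
        tab <- iesTab[iesTab$label == (if (tb) "IES_B" else "IES_A"), ,
                      drop = FALSE]
        dr <- drawBody(typeB == tb, tab)
        globalRow <- match(tab$ies_id[dr$row], iesTab$ies_id)
        a0[typeB == tb] <- dr$a0
        chrom[typeB == tb] <- tab$chrom[dr$row]
        row[typeB == tb] <- globalRow
      }
      a0 <- .applySpread(a0, row, iesTab, adj, cfg)
    }
    scnLibrary(.readsFromAnchors(chrom, a0, plus, len, chromLens),
               name = name)
  })
}

#' Simulate a ChIP / input library pair
#'
#' Input fragment midpoints are uniform over the genome; ChIP midpoints are
#' drawn with per-base density `chipEnrichment`-fold higher on IES bodies
#' than on MDS. Fragment lengths are uniform in `chipFragRange`; when
#' `cfg$spread` is set, ChIP midpoints proximal to the listed boundaries are
#' displaced into MDS with the same kernel as the scnRNA simulator
#' (heterochromatin spreading). Deterministic under the seed.
#'
#' @inheritParams simulateScnrna
#' @return A [ChipPair-class] of two unfiltered libraries.
#' @export
simulateChip <- function(cfg, genome, seed = cfg$seed) {
  stopifnot(inherits(cfg, "SimConfig"))
  withr::with_seed(as.integer(seed), {
    seg <- genomeSegments(genome)
    seg$len <- seg$end - seg$start
    iesTab <- .iesTable(genome)
    adj <- .adjacentMds(genome)
    chromLens <- chromLengths(genome)
    n <- round(cfg$nReads)

    drawLib <- function(weights, spread) {
      si <- sample.int(nrow(seg), n, replace = TRUE, prob = weights)
      mid <- seg$start[si] + floor(stats::runif(n) * seg$len[si])
      if (spread) {
        row <- match(seg$ies_id[si], iesTab$ies_id)
        mid <- .applySpread(mid, row, iesTab, adj, cfg)
      }
      fl <- .sampleFrom(seq(cfg$chipFragRange[1], cfg$chipFragRange[2]), n)
      s0 <- mid - floor(fl / 2)
      s0 <- pmax(0L, pmin(s0, chromLens[seg$chrom[si]] - fl))
      .gr0(seg$chrom[si], s0, s0 + fl, strand = "+",
           chromLengths = chromLens)
    }
    isIes <- seg$label != "MDS"
    chip <- drawLib(seg$len * ifelse(isIes, cfg$chipEnrichment, 1),
                    spread = !is.null(cfg$spread))
    input <- drawLib(seg$len, spread = FALSE)
    chipPair(scnLibrary(chip, NULL, NULL, "sim_chip"),
             scnLibrary(input, NULL, NULL, "sim_input"))
  })
}
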