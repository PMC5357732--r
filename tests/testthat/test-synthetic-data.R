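test_that("generated genomes honor the configured counts and are seeded", {
  cfg <- simConfig(seed = 31, nIesA = 2, nIesB = 1, chromLength = 5e4)
  g <- makeGenome(cfg)
  expect_equal(iesCount(g, "A"), 2)
  expect_equal(iesCount(g, "B"), 1)
  expect_identical(genomeSegments(makeGenome(cfg)), genomeSegments(g))
  tooSmall <- simConfig(seed = 1, nIesA = 10, nIesB = 10, chromLength = 2e4)
  expect_error(makeGenome(tooSmall), "infeasible")
})

test_that("random configs always produce valid tilings", {
  set.seed(99)
  for (i in 1:30) {
    cfg <- simConfig(seed = i, nIesA = sample(1:10, 1),
                     nIesB = sample(0:10, 1), nChrom = sample(1:3, 1),
                     chromLength = 2e5,
                     iesLengthRange = sort(sample(200:3000, 2)),
                     mdsLengthRange = sort(sample(500:3000, 2)))
    g <- makeGenome(cfg)       # validity method runs on construction
    seg <- genomeSegments(g)
    expect_true(all(seg$start < seg$end))
    expect_equal(iesCount(g), cfg$nIesA + cfg$nIesB)
    byChrom <- split(seg, seg$chrom)
    for (b in byChrom)
      expect_equal(b$start[-1], b$end[-nrow(b)])
  }
})

test_that("late-stage reads stay inside IESs and within chromosomes", {
  cfg <- simConfig(seed = 41, nIesA = 8, nIesB = 8, chromLength = 1e5,
                   nReads = 2e4)
  g <- makeGenome(cfg)
  lib <- simulateScnrna(cfg, g)
  expect_equal(mdsAnchored(lib, g, "five_prime"), 0L)
  cl <- chromLengths(g)
  reads <- lib@reads
  expect_true(all(start(reads) >= 1))
  expect_true(all(end(reads) <= cl[as.character(seqnames(reads))]))
  # filter pass rate tracks 1 - contaminant fraction
  frac <- totalFiltered(lib) / length(reads)
  expect_equal(frac, 1 - cfg$contaminantFraction, tolerance = 0.02)
  # determinism under the seed
  lib2 <- simulateScnrna(cfg, g)
  expect_identical(as.data.frame(lib2@reads), as.data.frame(lib@reads))
})

test_that("scnRNA selection purges MDS-mapped early reads; flanks are type-A only", {
  cfg <- simConfig(seed = 42, nIesA = 10, nIesB = 10, chromLength = 5e5,
                   mdsLengthRange = c(3000, 5000), nReads = 2e4,
                   stage = "early_3h")
  g <- makeGenome(cfg)
  early <- simulateScnrna(cfg, g)
  expect_gt(mdsAnchored(early, g, "five_prime"), 0L)
  bw <- boundaries(g, 500)
  ct <- boundaryCounts(early, bw[bw$eligible, ], anchorMode = "five_prime")
  expect_gt(sum(ct$mds_count[ct$ies_type == "A"]), 0)
  expect_equal(sum(ct$mds_count[ct$ies_type == "B"]), 0)
  post <- cfg; post$stage <- "post_selection_6h"; post$selectionEfficiency <- 1
  sel <- simulateScnrna(post, g)
  expect_equal(mdsAnchored(sel, g, "five_prime"), 0L)
  expect_lt(length(sel@reads), length(early@reads))
})

test_that("boundary spreading matches its closed-form displacement kernel", {
  n <- 5e4; f <- 0.3; lambda <- 200; W <- 500; L <- 2000; mds <- 2000
  cfg <- simConfig(seed = 43, nIesA = 1, nIesB = 0, chromLength = 10000,
                   iesLengthRange = c(L, L), mdsLengthRange = c(mds, mds),
                   nReads = n, contaminantFraction = 0,
                   spread = data.frame(ies_id = "ies00001", side = "left",
                                       f = f, lambda = lambda))
  g <- makeGenome(cfg)
  lib <- simulateScnrna(cfg, g)
  bw <- boundaries(g, W)
  ct <- boundaryCounts(lib, bw[bw$side == "left", ], anchorMode = "five_prime")
  # body reads fit inside the IES: a read of length l has L-l+1 start
  # positions; its 5' anchor is proximal to the left boundary (< W) with
  # probability W/(L-l+1) on + and (W-l+1)/(L-l+1) on -; displaced reads
  # move by Exp(lambda) truncated at the adjacent MDS length
  lens <- 26:32
  ld <- c(0.05, 0.15, 0.25, 0.25, 0.15, 0.10, 0.05)
  pProx <- sum(ld * 0.5 * (W / (L - lens + 1) + (W - lens + 1) / (L - lens + 1)))
  q <- (1 - exp(-W / lambda)) / (1 - exp(-mds / lambda))
  muOut <- n * pProx * f * q
  muIn <- n * pProx * (1 - f)
  expect_lt(abs(ct$mds_count - muOut), 3 * sqrt(muOut))
  expect_lt(abs(ct$ies_count - muIn), 3 * sqrt(muIn))
})

test_that("ChIP simulation is enrichment-faithful and deterministic", {
  cfg <- simConfig(seed = 44, nIesA = 8, nIesB = 8, chromLength = 2e5,
                   nReads = 1e5, chipEnrichment = 1)
  g <- makeGenome(cfg)
  pair <- simulateChip(cfg, g)
  cr <- chipRatio(pair, genome = g, iesType = "B")
  v <- senseValues(cr)
  expect_equal(mean(v, na.rm = TRUE), 1, tolerance = 0.1)
  f1 <- tempfile(fileext = ".bed"); f2 <- tempfile(fileext = ".bed")
  writeBed6(pair@chip@reads, f1)
  writeBed6(simulateChip(cfg, g)@chip@reads, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
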