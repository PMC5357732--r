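test_that("locus profile places anchors in half-open bins per strand", {
  lib <- scnLibrary(mkReads("chr1", c(150, 200 - 28 + 1), c(150 + 28, 201),
                            c("+", "-")), name = "toy")
  p <- locusProfile(lib, "chr1", 0, 1000, binSize = 100)
  # + read 5' anchor 150 -> bin 2; - read 5' anchor 200 -> bin 3 (edge case)
  expect_equal(rawCounts(p)$sense, c(0, 1, rep(0, 8)))
  expect_equal(rawCounts(p)$antisense, c(0, 0, 1, rep(0, 7)))
  expect_equal(senseValues(p)[2], rpm(1, lib))
  expect_error(locusProfile(lib, "chr1", 5000, 20000, genome = toyGenome()),
               "outside the genome")
})

test_that("uniform coverage fills locus bins within binomial tolerance", {
  set.seed(11)
  n <- 10000
  s0 <- sample(1000:(3000 - 28), n, replace = TRUE)
  lib <- scnLibrary(mkReads("chr1", s0, s0 + 28), name = "unif")
  p <- locusProfile(lib, "chr1", 1000, 3000, binSize = 100)
  counts <- rawCounts(p)$sense
  pbin <- 100 / (2000 - 27)       # anchors uniform over the start range
  expected <- n * pbin
  sd <- sqrt(n * pbin * (1 - pbin))
  inner <- counts[1:19]           # last bin loses starts near the IES end
  expect_true(all(abs(inner - expected) < 3 * sd + 1))
})

test_that("meta-profile mirrors right boundaries (hand-traced example)", {
  g <- toyGenome()
  lib <- scnLibrary(mkReads("chr1", 3100, 3128, "+"), name = "one")
  p <- metaProfile(lib, g, "A", binSize = 10, window = 500,
                   anchorMode = "five_prime")
  expect_equal(p@nBoundaries, 2L)
  # 5' anchor 3100; right boundary 3000: offset = 2999 - 3100 = -101,
  # bin [-110,-100); the + read is antisense after mirroring
  off <- binOffsets(p)
  expect_equal(sum(rawCounts(p)$sense), 0)
  expect_equal(sum(rawCounts(p)$antisense), 1)
  expect_equal(off[rawCounts(p)$antisense == 1], -110)
})

test_that("reads confined to IES bodies leave all outside bins empty", {
  cfg <- simConfig(seed = 2, nIesA = 5, nIesB = 5, chromLength = 1e5,
                   nReads = 5000)
  g <- makeGenome(cfg)
  lib <- simulateScnrna(cfg, g)
  p <- metaProfile(lib, g, "A", anchorMode = "five_prime")
  neg <- binOffsets(p) < 0
  expect_equal(sum(rawCounts(p)$sense[neg] + rawCounts(p)$antisense[neg]), 0)
})

test_that("meta-profile equals the per-boundary brute-force oracle", {
  cfg <- simConfig(seed = 9, nIesA = 3, nIesB = 3, chromLength = 6e4,
                   nReads = 2000,
                   spread = data.frame(ies_id = "ies00001", side = "left",
                                       f = 0.4, lambda = 150))
  g <- makeGenome(cfg)
  lib <- simulateScnrna(cfg, g)
  for (ty in c("A", "B")) {
    p <- metaProfile(lib, g, ty, binSize = 50, window = 500)
    o <- naiveMetaProfile(lib, g, ty, 50, 500)
    expect_equal(rawCounts(p)$sense, o$sense)
    expect_equal(rawCounts(p)$antisense, o$antisense)
    expect_equal(p@nBoundaries, o$n)
    # conservation: all raw counts are anchors in eligible windows
    expect_equal(sum(rawCounts(p)$sense) + sum(rawCounts(p)$antisense),
                 sum(o$sense) + sum(o$antisense))
  }
  expect_error(metaProfile(lib, toyGenome(), "B"), "type-B")
})

test_that("symmetric coverage gives a meta-profile symmetric about 0", {
  set.seed(21)
  g <- toyGenome()
  # same number of anchors at +/- each offset around both boundaries
  offs <- sample(0:499, 400, replace = TRUE)
  a0 <- c(1000 + offs, 999 - offs, 2999 - offs, 3000 + offs)
  lib <- scnLibrary(mkReads("chr1", a0 - 12, a0 - 12 + 28), name = "sym")
  p <- metaProfile(lib, g, "A", binSize = 10)
  tot <- rawCounts(p)$sense + rawCounts(p)$antisense
  expect_equal(tot, rev(tot))
})

test_that("ChIP/input ratio recovers values and masks zero-input bins", {
  g <- toyGenome()
  chip <- scnLibrary(mkReads("chr1", c(100, 110, 120, 130, 700),
                             c(100, 110, 120, 130, 700) + 200),
                     minLen = NULL, maxLen = NULL, name = "chip")
  input <- scnLibrary(mkReads("chr1", c(105, 125), c(305, 325)),
                      minLen = NULL, maxLen = NULL, name = "input")
  cr <- chipRatio(chipPair(chip, input), chrom = "chr1", start = 0,
                  end = 1000, binSize = 100)
  v <- senseValues(cr)
  # bin 3 (200-300): chip midpoints 200,210,220,230 -> 4/5 RPM;
  # input midpoints 205,225 -> 2/2 RPM; ratio = (4/5)/(2/2)
  expect_equal(v[3], (4 / 5) / (2 / 2))
  # bin 9 (800-900): chip midpoint 800, input empty -> masked
  expect_true(is.na(v[9]))
  expect_equal(cr@params$masked_bins, sum(is.na(v)))
})

test_that("ChIP meta-ratio plateau recovers the simulated enrichment", {
  cfg <- simConfig(seed = 4, nIesA = 10, nIesB = 10, chromLength = 2e5,
                   nReads = 2e5, chipEnrichment = 5)
  g <- makeGenome(cfg)
  cr <- chipRatio(simulateChip(cfg, g), genome = g, iesType = "A")
  v <- senseValues(cr); off <- binOffsets(cr)
  inside <- mean(v[off >= 100 & off < 400], na.rm = TRUE)
  outside <- mean(v[off >= -400 & off < -100], na.rm = TRUE)
  expect_equal(inside / outside, 5, tolerance = 0.15)
})
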