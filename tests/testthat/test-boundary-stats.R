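test_that("boundary window counts match brute-force interval membership", {
  set.seed(5)
  g <- toyGenome()
  s0 <- sample(0:9900, 800, replace = TRUE)
  lib <- scnLibrary(mkReads("chr1", s0, s0 + sample(26:32, 800, TRUE),
                            sample(c("+", "-"), 800, TRUE)), name = "rand")
  bw <- boundaries(g, 500)
  ct <- boundaryCounts(lib, bw)
  fr <- filteredReads(lib)
  for (i in seq_len(nrow(ct))) {
    expect_equal(ct$mds_count[i],
                 naiveWindowCount(fr, "nt13", ct$chrom[i],
                                  ct$outside_start[i], ct$outside_end[i]))
    expect_equal(ct$ies_count[i],
                 naiveWindowCount(fr, "nt13", ct$chrom[i],
                                  ct$inside_start[i], ct$inside_end[i]))
  }
  empty <- scnLibrary(GRanges(), name = "none")
  ct0 <- boundaryCounts(empty, bw)
  expect_equal(ct0$mds_count, c(0, 0))
  expect_equal(ct0$ies_count, c(0, 0))
  bad <- bw; bad$eligible <- c(TRUE, FALSE)
  expect_error(boundaryCounts(lib, bad), "ineligible")
})

test_that("the BBI formula evaluates the printed ratio-of-ratios", {
  expect_equal(computeBbi(200, 1000, 50, 1000, pseudocount = 0), 4)
  expect_equal(computeBbi(37, 512, 37, 512, pseudocount = 0), 1)
  expect_equal(computeBbi(0, 99, 0, 99, pseudocount = 1), 1)
  expect_error(computeBbi(0, 10, 5, 10, pseudocount = 0), "undefined")
  expect_error(computeBbi(1, 1, 1, 1, pseudocount = -1), ">= 0")
})

test_that("BBI is scale invariant at pseudocount 0 and asymptotically at 1", {
  base <- c(mds_s = 30, ies_s = 70, mds_c = 10, ies_c = 90)
  b0 <- computeBbi(base[1], base[2], base[3], base[4], 0)
  for (c_ in c(2, 10, 1000))
    expect_equal(computeBbi(base[1] * c_, base[2] * c_, base[3] * c_,
                            base[4] * c_, 0), b0)
  big <- base * 100   # all counts >= 1e3
  rel <- abs(computeBbi(big[1], big[2], big[3], big[4], 1) - b0) / b0
  expect_lt(rel, 0.01)
})

test_that("bbiTable ranks eligible boundaries as a permutation, ties deterministic", {
  cfg <- simConfig(seed = 6, nIesA = 6, nIesB = 6, chromLength = 1e5,
                   nReads = 3e4)
  g <- makeGenome(cfg)
  s <- simulateScnrna(cfg, g, seed = 61, name = "s")
  ctrl <- simulateScnrna(cfg, g, seed = 62, name = "c")
  tbl <- bbiTable(s, ctrl, g, minControlReads = 10)
  el <- tbl[tbl$eligible, ]
  expect_setequal(el$rank, seq_len(nrow(el)))
  expect_true(all(is.na(tbl$rank[!tbl$eligible])))
  expect_true(all(diff(el$bbi[order(el$rank)]) <= 0))
  # identical sample and control: every BBI is exactly 1
  same <- bbiTable(s, s, g)
  expect_true(all(same$bbi == 1))
  expect_equal(bbiSummary(same)$median, 1)
  # ties (all BBI = 1) are broken by genomic order
  o <- same[order(same$rank[same$eligible]), ]
  expect_false(is.unsorted(order(o$chrom, o$inside_start, o$side)))
})

test_that("top-N heatmap rows are conserved window counts in rank order", {
  cfg <- simConfig(seed = 8, nIesA = 5, nIesB = 5, chromLength = 1e5,
                   nReads = 2e4,
                   spread = data.frame(ies_id = "ies00002", side = "right",
                                       f = 0.5, lambda = 200))
  g <- makeGenome(cfg)
  s <- simulateScnrna(cfg, g, seed = 81, name = "mut")
  ctrl0 <- simConfig(seed = 8, nIesA = 5, nIesB = 5, chromLength = 1e5,
                     nReads = 2e4)
  ctrl <- simulateScnrna(ctrl0, g, seed = 82, name = "wt")
  tbl <- bbiTable(s, ctrl, g)
  hm <- topNHeatmap(tbl, list(mut = s, wt = ctrl), g, n = 4, binSize = 50)
  expect_named(hm, c("mut", "wt"))
  expect_equal(dim(hm$mut), c(4, 20))
  # row order follows the reference ranking; spread boundary ranks first
  top <- tbl[tbl$eligible, ][order(tbl$rank[tbl$eligible]), ][1:4, ]
  expect_equal(rownames(hm$mut), paste0(top$ies_id, ":", top$side))
  expect_equal(rownames(hm$wt), rownames(hm$mut))
  expect_equal(top$ies_id[1], "ies00002")
  # conservation: heatmap halves equal RPM-normalized window counts
  bw <- boundaries(g, 500)
  bw <- bw[match(paste(top$ies_id, top$side), paste(bw$ies_id, bw$side)), ]
  ct <- boundaryCounts(s, bw)
  expect_equal(unname(rowSums(hm$mut[, 1:10])), rpm(ct$mds_count, s))
  expect_equal(unname(rowSums(hm$mut[, 11:20])), rpm(ct$ies_count, s))
  expect_error(topNHeatmap(tbl, list(s = s), g, n = 1000), "exceeds")
  # per-IES mode keeps one boundary per IES
  hmI <- topNHeatmap(tbl, list(mut = s), g, n = 3, perIes = TRUE)
  ids <- sub(":.*", "", rownames(hmI$mut))
  expect_equal(anyDuplicated(ids), 0L)
})
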