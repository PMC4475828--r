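test_that("degenerate spec yields exactly the dominant haplotype", {
  ref <- testReference()
  sp <- ecotypeSpec("E1", c(60, 300), nHfs = 1, nLfs = 0)
  h <- generateHaplotypes(sp, ref, seed = 1)
  expect_equal(nrow(h), 1L)
  expect_equal(h$class, "dominant")
})

test_that("HFS pairwise Hamming distances are within-distance or twice it", {
  ref <- testReference()
  sp <- ecotypeSpec("E1", c(60, 300), nHfs = 3, nLfs = 0)
  for (seed in 1:5) {
    h <- generateHaplotypes(sp, ref, withinDistance = 2, seed = seed)
    d <- outer(h$sequence, h$sequence, Vectorize(hammingDist))
    expect_setequal(unique(d[upper.tri(d)]), c(2, 4))
  }
})

test_that("ecotype separation bounds the minimum between-ecotype distance", {
  ref <- testReference()
  specs <- threeEcotypeSpecs(nHfs = 3, nLfs = 2)[1:2]
  h <- communityHaplotypes(specs, ref, withinDistance = 2, separation = 5,
                           seed = 3)
  d <- outer(h$sequence, h$sequence, Vectorize(hammingDist))
  between <- d[h$ecotype == "E1", h$ecotype == "E2"]
  within <- c(d[h$ecotype == "E1", h$ecotype == "E1"],
              d[h$ecotype == "E2", h$ecotype == "E2"])
  expect_gte(min(between), 10)
  expect_gt(min(between), max(within))
})

test_that("a too-short reference is refused", {
  sp <- ecotypeSpec("E1", c(60, 300), nHfs = 5, nLfs = 5)
  expect_error(generateHaplotypes(sp, "ACGTACG", seed = 1),
               "reference shorter")
})

test_that("community abundances form a normalized Gaussian niche response", {
  specs <- threeEcotypeSpecs()
  grid <- habitatGrid(seq(56, 68, by = 1), seq(100, 700, by = 100))
  cg <- simulateCommunity(specs, grid)
  ab <- trueAbundance(cg)
  expect_true(all(abs(colSums(ab) - 1) < 1e-9))
  expect_true(all(ab >= 0))
  # abundance equals the Gaussian product kernel, renormalized per sample,
  # and each ecotype's kernel peaks at the grid point nearest its centre
  kernel <- vapply(specs, function(sp) {
    sp@weight * exp(
      -(grid$temperature_C - sp@nicheCenter[1])^2 / (2 * sp@nicheBreadth[1]^2) -
       (grid$depth_um - sp@nicheCenter[2])^2 / (2 * sp@nicheBreadth[2]^2))
  }, numeric(nrow(grid)))
  expect_equal(unname(ab), unname(t(kernel / rowSums(kernel))),
               tolerance = 1e-12)
  for (i in seq_along(specs)) {
    ctr <- specs[[i]]@nicheCenter
    sdv <- specs[[i]]@nicheBreadth
    zscore <- ((grid$temperature_C - ctr[1]) / sdv[1])^2 +
              ((grid$depth_um - ctr[2]) / sdv[2])^2
    expect_equal(which.max(kernel[, i]), which.min(zscore))
  }
})

test_that("one ecotype fills every sample; symmetric pair splits midway", {
  one <- simulateCommunity(list(ecotypeSpec("E", c(60, 300))),
                           habitatGrid(c(58, 60, 62), c(200, 400)))
  expect_true(all(abs(trueAbundance(one) - 1) < 1e-12))
  pair <- list(ecotypeSpec("A", c(60, 300)), ecotypeSpec("B", c(65, 300)))
  cg <- simulateCommunity(pair, habitatGrid(62.5, 300))
  expect_equal(unname(trueAbundance(cg)[, 1]), c(0.5, 0.5))
  expect_error(simulateCommunity(pair, habitatGrid(numeric(), numeric())),
               "empty")
})

test_that("reads equal haplotypes when the error model is off", {
  ref <- testReference()
  specs <- threeEcotypeSpecs()
  haps <- communityHaplotypes(specs, ref, seed = 5)
  cg <- simulateCommunity(specs, habitatGrid(c(60, 65), 400))
  sim <- simulateReads(cg, haps, 200, errorModel(0, 0), seed = 9)
  expect_true(all(unlist(sim$reads) == sim$truth$sequence_true))
  expect_equal(unname(lengths(sim$reads)), c(200, 200))
})

test_that("fraction of error-free reads matches the closed-form expectation", {
  ref <- testReference(7)
  hap <- ref
  runs <- length(rle(strsplit(hap, "", fixed = TRUE)[[1]])$lengths)
  spec <- list(ecotypeSpec("E", c(60, 300), nHfs = 1, nLfs = 0,
                           dominant = hap))
  cg <- simulateCommunity(spec, habitatGrid(60, 300))
  haps <- communityHaplotypes(spec, ref, seed = 1)
  n <- 10000
  sim <- simulateReads(cg, haps, n, errorModel(pIns = 0.01, pDel = 0),
                       seed = 11)
  pExp <- (1 - 0.01)^runs
  obs <- mean(unlist(sim$reads) == hap)
  expect_lt(abs(obs - pExp), 3 * sqrt(pExp * (1 - pExp) / n))
})

test_that("multinomial sampling respects planted ecotype abundances", {
  ref <- testReference()
  specs <- list(ecotypeSpec("A", c(60, 300), weight = 4, nHfs = 2, nLfs = 1),
                ecotypeSpec("B", c(60, 300), weight = 1, nHfs = 2, nLfs = 1))
  haps <- communityHaplotypes(specs, ref, seed = 2)
  cg <- simulateCommunity(specs, habitatGrid(60, 300))
  expect_equal(unname(trueAbundance(cg)[, 1]), c(0.8, 0.2))
  sim <- simulateReads(cg, haps, 1000, errorModel(0, 0), seed = 4)
  nA <- sum(sim$truth$ecotype == "A")
  expect_lt(abs(nA - 800), 3 * sqrt(1000 * 0.8 * 0.2))
})

test_that("seeded read simulation is reproducible byte for byte", {
  ref <- testReference()
  specs <- threeEcotypeSpecs()
  haps <- communityHaplotypes(specs, ref, seed = 5)
  cg <- simulateCommunity(specs, habitatGrid(c(60, 65), 400))
  s1 <- simulateReads(cg, haps, 100, errorModel(0.02, 0.01), seed = 77)
  s2 <- simulateReads(cg, haps, 100, errorModel(0.02, 0.01), seed = 77)
  expect_identical(s1$reads, s2$reads)
  d <- withr::local_tempdir()
  writeSimulatedReads(s1, cg, file.path(d, "a"))
  writeSimulatedReads(s2, cg, file.path(d, "b"))
  fa <- list.files(file.path(d, "a"), pattern = "fasta$", full.names = TRUE)
  fb <- list.files(file.path(d, "b"), pattern = "fasta$", full.names = TRUE)
  expect_identical(lapply(fa, readLines), lapply(fb, readLines))
})

test_that("diel simulator reproduces phase structure and bookkeeping", {
  prof <- data.frame(pe = c("P1", "P2"), peakHour = c(8, 12),
                     amplitude = c(0.9, 0.9))
  tp <- seq(0, 22, by = 2)
  ds <- simulateDielTranscripts(prof, tp, depth = 5000, seed = 3)
  counts <- dielCounts(ds)
  # earlier peak: P1's maximum share precedes P2's
  share <- sweep(counts, 2, colSums(counts), "/")
  expect_lt(as.numeric(colnames(counts)[which.max(share["P1", ])]),
            as.numeric(colnames(counts)[which.max(share["P2", ])]))
  # equal constant activities split evenly
  flat <- simulateDielTranscripts(
    data.frame(pe = c("P1", "P2"), peakHour = 0, amplitude = 0),
    tp, depth = 10000, seed = 4)
  shares <- dielCounts(flat)["P1", ] / colSums(dielCounts(flat))
  expect_true(all(abs(shares - 0.5) < 3 * sqrt(0.25 / 10000)))
  # missing timepoints are omitted, exactly
  miss <- simulateDielTranscripts(prof, tp, 100, missing = c(4, 6), seed = 1)
  expect_false(any(c("4", "6") %in% colnames(dielCounts(miss))))
  expect_setequal(miss@missing, c("4", "6"))
})
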