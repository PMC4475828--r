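test_that("identity and reverse-complement reads align as expected", {
  ref <- "ATGGCAAGTTGGACCTAGGA"
  al <- bestOrientationAlignment(ref, ref)
  expect_equal(al$orientation, "forward")
  expect_equal(al$score, 2 * nchar(ref))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref)))
  al2 <- bestOrientationAlignment(rc, ref)
  expect_equal(al2$orientation, "reverse-complement")
  expect_equal(al2$score, 2 * nchar(ref))
  expect_equal(unname(gsub("-", "", al2$alignedRead)), ref)
})

test_that("excision removes the planted extra base and trims to reference", {
  ref <- "ATGGCAAGTTGG"
  al <- bestOrientationAlignment("ATGGCAAAGTTGG", ref)
  ex <- exciseFrameshiftBases(al)
  expect_equal(ex$status, "passed")
  expect_equal(ex$sequence, ref)
  expect_equal(ex$nExcised, 1L)
  # identical read: nothing excised
  ex0 <- exciseFrameshiftBases(bestOrientationAlignment(ref, ref))
  expect_equal(ex0$nExcised, 0L)
  expect_equal(ex0$sequence, ref)
  # a deletion leaves a gap relative to the reference: rejected
  exd <- exciseFrameshiftBases(bestOrientationAlignment("ATGGCAGTTGG", ref))
  expect_equal(exd$status, "rejected")
  expect_equal(exd$reason, "gap")
})

test_that("alignment scores match an exhaustive dynamic-programming oracle", {
  set.seed(31)
  scoring <- alignmentScoring()
  for (trial in 1:40) {
    L <- sample(8:20, 1)
    ref <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    chars <- strsplit(ref, "", fixed = TRUE)[[1]]
    kind <- sample(c("ins", "del", "none"), 1)
    read <- switch(kind,
      ins = {
        p <- sample(L, 1)
        paste(append(chars, chars[p], after = p), collapse = "")
      },
      del = paste(chars[-sample(L, 1)], collapse = ""),
      none = ref)
    al <- bestOrientationAlignment(read, ref, scoring)
    expect_equal(al$score, nwOracle(read, ref), info = paste(kind, read, ref))
    # an inserted base makes exactly one reference gap
    if (kind == "ins")
      expect_equal(lengths(regmatches(al$alignedRef,
                                      gregexpr("-", al$alignedRef))), 1L)
  }
})

test_that("batch cleaning conserves counts and recovers planted truth", {
  ref <- testReference()
  specs <- threeEcotypeSpecs()
  haps <- communityHaplotypes(specs, ref, seed = 5)
  cg <- simulateCommunity(specs, habitatGrid(c(60, 63, 65), 400))
  # error-free reads pass untouched
  s0 <- simulateReads(cg, haps, 100, errorModel(0, 0), seed = 1)
  cl0 <- cleanReads(s0$reads[[1]], ref)
  expect_equal(cl0$report$n_passed, 100L)
  expect_equal(sum(cl0$details$n_excised), 0L)
  # insertion-only corruption: everything passes and equals its source
  si <- simulateReads(cg, haps, 400, errorModel(pIns = 0.02, pDel = 0),
                      seed = 2)
  raw <- unlist(unname(si$reads))
  cli <- cleanReads(raw, ref)
  expect_equal(cli$report$n_passed, length(raw))
  truth <- setNames(si$truth$sequence_true, si$truth$read_id)
  expect_true(all(cli$cleaned == truth[names(cli$cleaned)]))
  corrupted <- names(raw)[raw != truth[names(raw)]]
  expect_true(all(cli$details$n_excised[match(corrupted, cli$details$id)] >= 1))
  # deletion-only corruption: every corrupted read is rejected as "gap"
  sd <- simulateReads(cg, haps, 300, errorModel(pIns = 0, pDel = 0.02),
                      seed = 3)
  rawd <- unlist(unname(sd$reads))
  truthd <- setNames(sd$truth$sequence_true, sd$truth$read_id)
  cld <- cleanReads(rawd, ref)
  corr <- rawd != truthd[names(rawd)]
  expect_true(all(cld$details$reason[corr] == "gap"))
  rep <- cld$report
  expect_equal(rep$n_input,
               rep$n_passed + rep$n_rejected_gap + rep$n_rejected_quality)
})

test_that("cleaning is orientation invariant", {
  ref <- testReference()
  hap <- testReference(5)
  chars <- strsplit(hap, "", fixed = TRUE)[[1]]
  read <- paste(append(chars, chars[100], after = 100), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  a <- cleanReads(c(x = read), ref)
  b <- cleanReads(c(x = rc), ref)
  expect_equal(unname(a$cleaned), unname(b$cleaned))
})

test_that("quality rejections: non-IUPAC letters and short reads", {
  ref <- testReference()
  bad <- c(weird = "ACGTXXACGT", short = substr(ref, 1, 100),
           ok = ref)
  cl <- cleanReads(bad, ref)
  expect_equal(cl$report$n_rejected_quality, 2L)
  expect_equal(cl$details$reason[1:2], c("quality", "quality"))
  expect_equal(cl$report$n_passed, 1L)
})

test_that("empty input produces an empty result with a zeroed report", {
  cl <- cleanReads(character(), testReference())
  expect_equal(cl$report$n_input, 0L)
  expect_length(cl$cleaned, 0)
})

test_that("cDNA windowing trims passed reads to the requested segment", {
  ref <- testReference()
  cl <- cleanReads(c(a = ref), ref, cdnaWindow = c(10, 256))
  expect_equal(nchar(cl$cleaned[["a"]]), 247L)
  expect_equal(cl$cleaned[["a"]], substr(ref, 10, 256))
})
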