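test_that("Jukes-Cantor distances follow the closed form", {
  expect_equal(correctedDistances(c(a = "AAAA", b = "AAAA"))["a", "b"], 0)
  # p = 0.1 over 100 sites
  s1 <- strrep("ACGT", 25)
  ch <- strsplit(s1, "", fixed = TRUE)[[1]]
  ch[seq(1, 37, 4)] <- "T"   # 10 substitutions (A -> T)
  s2 <- paste(ch, collapse = "")
  d <- correctedDistances(c(a = s1, b = s2))["a", "b"]
  expect_equal(d, -0.75 * log(1 - 0.4 / 3), tolerance = 1e-10)
  # saturation is an error
  expect_error(correctedDistances(c(a = strrep("A", 100),
                                    b = strrep("C", 100))), "saturat")
  # symmetry and zero diagonal on randomly mutated sequences
  set.seed(2)
  base <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  seqs <- replicate(10, {
    ch <- base
    at <- sample(60, 8)
    ch[at] <- sample(c("A", "C", "G", "T"), 8, replace = TRUE)
    paste(ch, collapse = "")
  })
  names(seqs) <- paste0("t", 1:10)
  m <- correctedDistances(seqs)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
})

test_that("neighbor joining recovers cherries and additive topologies", {
  dm <- matrix(c(0, 0.2, 0.2, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  tr <- njTree(dm)
  expect_setequal(tr$tip.label, c("a", "b"))
  expect_equal(sort(tr$edge.length), c(0.1, 0.1))
  # additive 4-taxon matrix from a known topology ((a,b),(c,d))
  ed <- c(a = 2, b = 3, c = 4, d = 5, internal = 6)
  dm4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dm4["a", "b"] <- dm4["b", "a"] <- ed["a"] + ed["b"]
  dm4["c", "d"] <- dm4["d", "c"] <- ed["c"] + ed["d"]
  for (x in c("a", "b")) for (y in c("c", "d"))
    dm4[x, y] <- dm4[y, x] <- ed[x] + ed[y] + ed["internal"]
  tr4 <- njTree(dm4)
  # brute-force least-squares over the 3 unrooted 4-taxon topologies
  split4 <- function(pair) {
    others <- setdiff(letters[1:4], pair)
    sum((dm4[pair[1], pair[2]] + dm4[others[1], others[2]]) -
        pmin(dm4[pair[1], others[1]] + dm4[pair[2], others[2]],
             dm4[pair[1], others[2]] + dm4[pair[2], others[1]]))
  }
  best <- which.min(c(ab = split4(c("a", "b")), ac = split4(c("a", "c")),
                      ad = split4(c("a", "d"))))
  expect_equal(names(best), "ab")
  expect_true(ape::is.monophyletic(tr4, c("a", "b")) ||
              ape::is.monophyletic(tr4, c("c", "d")))
  # label order does not change the topology
  perm <- sample(4)
  tr4b <- njTree(dm4[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(tr4), ape::unroot(tr4b)), 0,
               ignore_attr = TRUE)
  expect_error(njTree(matrix(0, 1, 1)), "at least 2")
})

test_that("bin curves count complete-linkage clusters along the ladder", {
  # all identical: a single bin at every criterion
  dm0 <- matrix(0, 4, 4)
  expect_true(all(binCurve(dm0)$bins == 1))
  # two clusters: within 0.001, between 0.05
  dm <- matrix(0.05, 6, 6)
  dm[1:3, 1:3] <- 0.001; dm[4:6, 4:6] <- 0.001
  diag(dm) <- 0
  bc <- binCurve(dm, criteria = c(0.99, 0.94))
  expect_equal(bc$bins, c(2L, 1L))
  # monotone non-increasing along any ladder, on random matrices
  set.seed(6)
  for (i in 1:10) {
    x <- matrix(runif(49, 0, 0.2), 7, 7)
    x <- (x + t(x)) / 2; diag(x) <- 0
    expect_true(all(diff(binCurve(x)$bins) <= 0))
  }
  # joint rescaling of distances and ladder leaves the curve unchanged
  bc1 <- binCurve(dm, criteria = 1 - c(0.002, 0.01, 0.06))
  bc2 <- binCurve(dm * 2, criteria = 1 - 2 * c(0.002, 0.01, 0.06))
  expect_equal(bc1$bins, bc2$bins)
})

test_that("the coalescent simulator honours limits and determinism", {
  one <- simulateSES(1, 1, 1, 1, nLineages = 1, maxDepth = 10,
                     seqLen = 324, seed = 1)
  expect_true(all(one$bins == 1))
  a <- simulateSES(0.5, 2, 3, 0.5, 9, 12, 324, seed = 42)
  b <- simulateSES(0.5, 2, 3, 0.5, 9, 12, 324, seed = 42)
  expect_identical(a$bins, b$bins)
  # strong periodic selection collapses within-ecotype diversity: the
  # bin count at moderately strict criteria approaches npop
  set.seed(7)
  bins <- replicate(60, simulateSES(0, sigma = 60, npop = 3, drift = 0.2,
                                    nLineages = 9, maxDepth = 40,
                                    seqLen = 324)$bins[4])
  expect_lt(abs(mean(bins) - 3), 0.5)
})

test_that("with one ecotype and no selection the model is a drift coalescent", {
  # independent oracle: Kingman coalescent with Poisson mutations
  kingmanCurve <- function(n, drift, maxDepth, L) {
    m <- numeric(n); lin <- seq_len(n); t <- 0
    D <- matrix(0, n, n)
    while (length(unique(lin)) > 1) {
      ids <- unique(lin); k <- length(ids)
      dt <- rexp(1, drift * k * (k - 1) / 2)
      dt <- min(dt, maxDepth - t)
      m <- m + rpois(k, dt)[match(lin, ids)]
      t <- t + dt
      pick <- if (t >= maxDepth) ids else sample(ids, 2)
      for (a in seq_len(length(pick) - 1)) for (b in (a + 1):length(pick)) {
        ta <- which(lin == pick[a]); tb <- which(lin == pick[b])
        D[ta, tb] <- outer(m[ta], m[tb], `+`); D[tb, ta] <- t(D[ta, tb])
      }
      lin[lin %in% pick] <- pick[1]
      if (t >= maxDepth) break
    }
    djc <- -0.75 * log(1 - (4 / 3) * pmin(D / L, 0.7499)); diag(djc) <- 0
    binCurve(djc, seqLen = L)$bins
  }
  set.seed(30)
  reps <- 300
  ours <- rowMeans(replicate(reps,
    simulateSES(0, 0, 1, 0.4, 8, 25, 324)$bins))
  theirs <- rowMeans(replicate(reps, kingmanCurve(8, 0.4, 25, 324)))
  expect_lt(max(abs(ours - theirs)), 0.35)
})

test_that("event caps guard non-terminating configurations", {
  expect_error(simulateSES(0, 0, 2, 1, 6, maxDepth = Inf, seqLen = 324,
                           seed = 1, maxEvents = 3), "cap exceeded")
})

test_that("model fitting recovers a planted single population", {
  ok <- 0
  for (s in 1:5) {
    obs <- simulateSES(0, 1, 1, 0.3, 8, 15, 324, seed = 500 + s)
    fit <- fitSES(obs, config = demarcConfig(), seed = s)
    ok <- ok + (fit@npop == 1 && 1 %in% fit@ciNpop)
  }
  expect_gte(ok, 4)
})

test_that("impossible observed curves yield a no-fit error", {
  fake <- structure(list(criteria = identityLadder(), n = 6,
                         bins = rep(6L, 21), meanDist = 0.7, maxDist = 0.7,
                         seqLen = 324), class = "BinCurve")
  cfg <- demarcConfig(nReplicates = 10, slack = 0, maxMiss = 0)
  expect_error(fitSES(fake, config = cfg, seed = 1), "no fit")
})

test_that("demarcation partitions are total, disjoint and clade-shaped", {
  ref <- testReference()
  specs <- threeEcotypeSpecs(nHfs = 3, nLfs = 0)
  haps <- communityHaplotypes(specs, ref, seed = 4)
  seqs <- setNames(haps$sequence, haps$haplotype_id)
  tree <- njTree(correctedDistances(seqs))
  fine <- demarcate(tree, seqs, "fine", seed = 11)
  cons <- demarcate(tree, seqs, "conservative", seed = 11)
  # totality and disjointness are enforced by the class validity; check
  # coverage of the leaf set and the nesting of fine inside conservative
  expect_setequal(names(peAssignments(fine)), tree$tip.label)
  expect_setequal(names(peAssignments(cons)), tree$tip.label)
  expect_true(all(vapply(fine@clades, function(cl)
    length(unique(peAssignments(cons)[cl])) == 1, logical(1))))
  expect_lte(nPE(cons), nPE(fine))
  # every PE is a clade of the tree
  for (cl in fine@clades) {
    if (length(cl) > 1) expect_true(ape::is.monophyletic(tree, cl))
  }
  # determinism under the seed
  fine2 <- demarcate(tree, seqs, "fine", seed = 11)
  expect_identical(peAssignments(fine), peAssignments(fine2))
})

test_that("a star-like clade of near-identical variants is one PE", {
  ref <- testReference()
  sp <- ecotypeSpec("S", c(60, 300), nHfs = 4, nLfs = 0)
  h <- generateHaplotypes(sp, ref, seed = 2)
  seqs <- setNames(h$sequence, h$haplotype_id)
  tree <- njTree(correctedDistances(seqs))
  expect_equal(nPE(demarcate(tree, seqs, "fine", seed = 3)), 1L)
  expect_equal(nPE(demarcate(tree, seqs, "conservative", seed = 3)), 1L)
})
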