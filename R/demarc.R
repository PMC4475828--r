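#' Jukes-Cantor corrected pairwise distances
#'
#' Pairwise corrected distances (substitutions/site) among equal-length,
#' reference-framed sequences: d = -(3/4) ln(1 - (4/3) p) for the observed
#' proportion p of differing sites. Saturated pairs (p >= 0.75) are an
#' error.
#'
#' @param seqs named character vector of equal-length sequences.
#' @return symmetric numeric matrix with zero diagonal, labelled by
#'   sequence names.
#' @examples
#' correctedDistances(c(a = "AAAA", b = "AAAT"))
#' @export
correctedDistances <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must share a common length")
  if (is.null(names(seqs))) names(seqs) <- sprintf("t%d", seq_along(seqs))
  chars <- do.call(rbind, strsplit(tolower(seqs), "", fixed = TRUE))
  rownames(chars) <- names(seqs)
  d <- ape::dist.dna(ape::as.DNAbin(chars), model = "JC69",
                     pairwise.deletion = FALSE)
  m <- as.matrix(d)
  if (any(!is.finite(m)))
    stop("saturated distances (p >= 0.75); JC69 correction undefined")
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (Saitou-Nei Q criterion) with negative branch
#' lengths clamped to zero, rooted at the midpoint for demarcation
#' traversal.
#'
#' @param dm symmetric distance matrix with labels (>= 2 taxa).
#' @return an [ape::phylo] rooted tree whose leaves are the matrix labels.
#' @export
njTree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2) stop("need at least 2 taxa")
  if (n == 2) {
    tr <- ape::read.tree(text = sprintf("(%s:%.10f,%s:%.10f);",
      rownames(dm)[1], dm[1, 2] / 2, rownames(dm)[2], dm[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(as.dist(dm))
  tr$edge.length[tr$edge.length < 0] <- 0
  phangorn::midpoint(tr)
}

#' Ladder of sequence-identity criteria
#'
#' Default demarcation ladder: strict identity (1.0) followed by criteria
#' spaced `step * sortingFactor` apart. The sorting factor widens the
#' ladder spacing (default 1.5x).
#'
#' @param step base spacing between criteria (default 0.005).
#' @param sortingFactor multiplier on the spacing (default 1.5).
#' @param nCriteria number of criteria below 1.0 (default 20).
#' @return decreasing numeric vector of identity fractions, starting at 1.
#' @export
identityLadder <- function(step = 0.005, sortingFactor = 1.5,
                           nCriteria = 20L) {
  c(1, 1 - step * sortingFactor * seq_len(nCriteria))
}

#' Bin a distance matrix over an identity-criterion ladder
#'
#' For each identity criterion c, counts the number of complete-linkage
#' clusters of the sequences at distance threshold (1 - c). Bin counts are
#' non-increasing as the criterion loosens: n distinct variants at
#' criterion 1.0, one bin at criterion 0.
#'
#' @param dm distance matrix (substitutions/site), e.g. from
#'   [correctedDistances()].
#' @param criteria decreasing vector of identity fractions
#'   (default [identityLadder()]).
#' @param seqLen sequence length in nucleotides, carried for downstream
#'   model fitting (optional).
#' @return object of class `BinCurve`: list with `criteria`, `bins`, `n`
#'   (number of sequences), `meanDist`, `maxDist`, `seqLen`.
#' @export
binCurve <- function(dm, criteria = identityLadder(), seqLen = NULL) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n == 1) {
    bins <- rep(1L, length(criteria))
  } else {
    # clusters at threshold h = n - (complete-linkage merges at height <= h)
    hts <- stats::hclust(as.dist(dm), method = "complete")$height
    bins <- n - findInterval(pmax(1 - criteria, 0), sort(hts))
  }
  off <- dm[upper.tri(dm)]
  structure(list(criteria = criteria, bins = bins, n = n,
                 meanDist = if (length(off)) mean(off) else 0,
                 maxDist = if (length(off)) max(off) else 0,
                 seqLen = seqLen),
            class = "BinCurve")
}

#' @export
print.BinCurve <- function(x, ...) {
  cat(sprintf("BinCurve over %d sequences (%d criteria): bins %s\n",
              x$n, length(x$criteria), paste(x$bins, collapse = " ")))
  invisible(x)
}

#' Simulate sequence diversity under the Stable Ecotype Model
#'
#' Backward-in-time coalescent of `nLineages` sampled lineages distributed
#' over `npop` ecotypes, on a clock measured in expected nucleotide
#' substitutions per sequence. Three event types compete:
#' \itemize{
#'   \item ecotype formation (rate `omega` per substitution per lineage):
#'     looking backward, one occupied ecotype merges into another (the
#'     forward-time budding of a new ecotype);
#'   \item periodic selection (rate `sigma` per substitution per occupied
#'     ecotype): a selective sweep coalesces all but one lineage of the
#'     affected ecotype (all its sampled lineages merge into one);
#'   \item drift (rate `drift` per pair of lineages within an ecotype):
#'     one within-ecotype pair coalesces.
#' }
#' Mutations accrue on each branch as Poisson events (one per expected
#' substitution). `maxDepth` is the ecotype divergence depth: lineages
#' still belonging to distinct ecotypes are star-joined there, while a
#' single remaining ecotype keeps coalescing on its own clock (with a
#' distant 50 x `maxDepth` hard stop). Pairwise tip distances
#' (mutations/site, Jukes-Cantor corrected) are binned over the same
#' identity ladder used for observed data.
#'
#' @param omega ecotype formation rate (events per substitution).
#' @param sigma periodic selection rate (events per substitution).
#' @param npop number of ecotypes at sampling time (>= 1).
#' @param drift within-ecotype pairwise coalescence intensity.
#' @param nLineages number of sampled lineages (tips).
#' @param maxDepth root depth in expected substitutions per sequence
#'   (controls between-ecotype divergence when omega is small).
#' @param seqLen sequence length (nt) used to convert mutation counts to
#'   per-site distances.
#' @param criteria identity ladder (default [identityLadder()]).
#' @param seed optional integer seed.
#' @param maxEvents guard against non-terminating parameter combinations.
#' @return a `BinCurve` (see [binCurve()]); the realized tip distance
#'   matrix is attached as attribute `"distances"`.
#' @examples
#' simulateSES(0.5, 1, npop = 2, drift = 0.5, nLineages = 6,
#'             maxDepth = 20, seqLen = 324, seed = 1)
#' @export
simulateSES <- function(omega, sigma, npop, drift, nLineages, maxDepth,
                        seqLen, criteria = identityLadder(), seed = NULL,
                        maxEvents = 1e5) {
  stopifnot(omega >= 0, sigma >= 0, npop >= 1, drift >= 0, nLineages >= 1)
  withSeed(seed, {
    if (nLineages == 1) {
      dm <- matrix(0, 1, 1)
      return(binCurve(dm, criteria, seqLen = seqLen))
    }
    D <- ses_simulate_cpp(omega, sigma, as.integer(npop), drift,
                          as.integer(nLineages), maxDepth,
                          as.integer(maxEvents))
    p <- pmin(D / seqLen, 0.7499)
    djc <- -0.75 * log(1 - (4 / 3) * p)
    diag(djc) <- 0
    bc <- binCurve(djc, criteria, seqLen = seqLen)
    attr(bc, "distances") <- djc
    bc
  })
}

#' Configuration knobs for Stable Ecotype Model fitting and demarcation
#'
#' @param omegaGrid candidate ecotype formation rates.
#' @param sigmaGrid candidate periodic selection rates.
#' @param driftGrid candidate drift intensities; NULL derives a log-spaced
#'   grid by moment matching the observed mean pairwise distance.
#' @param npopMax largest candidate number of ecotypes (capped at the
#'   number of sequences).
#' @param nReplicates coalescent replicates per candidate parameter set.
#' @param slack allowed bin-count deviation at each criterion for a
#'   replicate to count as matching (default 0: bin counts must agree
#'   exactly — the one-versus-two-bins distinction is precisely the
#'   demarcation question, so a bin of slack would erase the signal).
#' @param maxMiss number of criteria allowed to exceed `slack` before a
#'   replicate stops matching (default 3; absorbs the one-criterion jitter
#'   of each curve transition under Poisson mutation noise).
#' @param parsimony fraction of the maximum likelihood within which the
#'   smallest npop is preferred as the ML solution (default 0.8). Bin
#'   curves of tight clades are equally consistent with one ecotype or
#'   several micro-ecotypes; the parsimonious reading resolves such
#'   plateaus toward fewer ecotypes.
#' @param criteria identity ladder (default [identityLadder()]).
#' @param maxEvents event cap per replicate.
#' @return list of configuration values.
#' @export
demarcConfig <- function(omegaGrid = c(0.3, 1.5), sigmaGrid = c(0.3, 1, 3),
                         driftGrid = NULL, npopMax = 6L, nReplicates = 150L,
                         slack = 0L, maxMiss = 3L, parsimony = 0.8,
                         criteria = identityLadder(), maxEvents = 1e5) {
  list(omegaGrid = omegaGrid, sigmaGrid = sigmaGrid, driftGrid = driftGrid,
       npopMax = as.integer(npopMax), nReplicates = as.integer(nReplicates),
       slack = as.integer(slack), maxMiss = as.integer(maxMiss),
       parsimony = parsimony, criteria = criteria, maxEvents = maxEvents)
}

#' Fit Stable Ecotype Model parameters to an observed bin curve
#'
#' Simulation-based approximate likelihood: for each candidate
#' (omega, sigma, npop, drift) on the grid, the likelihood is the fraction
#' of coalescent replicates ([simulateSES()]) whose bin curve matches the
#' observed curve within `slack` bins at all but at most `maxMiss`
#' criteria. The reported npop is the smallest whose profile likelihood is
#' within the `parsimony` fraction of the grid maximum; the npop
#' confidence set contains all npop whose profile likelihood is within a
#' factor exp(-2) of the maximum (a likelihood-ratio cutoff of 2
#' log-units).
#'
#' @param observed a `BinCurve` from [binCurve()] (must carry `seqLen`).
#' @param nLineages number of sampled lineages (defaults to `observed$n`).
#' @param config list from [demarcConfig()].
#' @param seed optional integer seed.
#' @return a [DemarcationFit-class].
#' @export
fitSES <- function(observed, nLineages = observed$n,
                   config = demarcConfig(), seed = NULL) {
  stopifnot(inherits(observed, "BinCurve"))
  L <- observed$seqLen
  if (is.null(L)) stop("observed BinCurve must carry seqLen")
  withSeed(seed, {
    meanD <- max(observed$meanDist, 1 / L)
    maxD <- max(observed$maxDist, 2 / L)
    driftGrid <- config$driftGrid
    if (is.null(driftGrid))
      driftGrid <- 2 / (L * meanD * c(1, 1 / 3, 1 / 9, 1 / 27))
    maxDepth <- maxD * L / 2
    grid <- expand.grid(npop = seq_len(min(config$npopMax, nLineages)),
                        omega = config$omegaGrid, sigma = config$sigmaGrid,
                        drift = driftGrid, KEEP.OUT.ATTRS = FALSE)
    grid <- grid[order(grid$npop), , drop = FALSE]
    if (!identical(config$criteria, observed$criteria))
      stop("config criteria must match the observed curve's ladder")
    lik <- ses_likelihood_cpp(
      as.matrix(grid[, c("omega", "sigma", "npop", "drift")]),
      as.integer(nLineages), maxDepth, L,
      pmax(1 - observed$criteria, 0), as.integer(observed$bins),
      as.integer(config$slack), as.integer(config$maxMiss),
      as.integer(config$nReplicates), as.integer(config$maxEvents))
    if (all(lik == 0)) stop("no fit; widen tolerance")
    prof <- tapply(lik, grid$npop, max)
    # parsimony: smallest npop whose profile likelihood is within the
    # configured fraction of the maximum
    mlNpop <- as.integer(names(prof)[prof >= max(lik) * config$parsimony][1])
    best <- which(grid$npop == mlNpop & lik == prof[as.character(mlNpop)])[1]
    ci <- as.integer(names(prof)[prof >= max(lik) * exp(-2)])
    new("DemarcationFit",
        omega = grid$omega[best], sigma = grid$sigma[best],
        npop = mlNpop, drift = grid$drift[best],
        ciNpop = sort(unique(c(ci, mlNpop))),
        likelihood = lik[best],
        surface = data.frame(grid, likelihood = lik))
  })
}

#' Demarcate putative ecotypes on a tree
#'
#' Traverses the rooted tree from the root. For each internal node, the
#' Stable Ecotype Model is fitted ([fitSES()]) to the bin curve of that
#' node's clade. The clade is accepted as a single putative ecotype when
#' the number-of-ecotypes estimate is compatible with 1 — in
#' `"conservative"` mode when the confidence set contains 1 (the most
#' inclusive grouping), in `"fine"` mode when the maximum-likelihood
#' estimate itself equals 1. Rejected clades recurse into their children;
#' single leaves are PEs. Because ML npop = 1 implies 1 is in the
#' confidence set, every fine-scale PE nests within a conservative PE.
#'
#' @param tree rooted tree from [njTree()] whose tips are variant ids.
#' @param sequences named character vector of the tip sequences.
#' @param mode `"conservative"` or `"fine"`.
#' @param config list from [demarcConfig()].
#' @param seed integer seed (per-node seeds are derived from it).
#' @return a [PEPartition-class]. A node whose fit fails is split into its
#'   children with a warning.
#' @export
demarcate <- function(tree, sequences, mode = c("conservative", "fine"),
                      config = demarcConfig(), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(tree$tip.label %in% names(sequences)))
  L <- nchar(sequences[[1]])
  dm <- correctedDistances(sequences[tree$tip.label])
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  childrenOf <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  tipsUnder <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(childrenOf(node), tipsUnder))
  }
  clades <- list()
  recurse <- function(node) {
    tipIdx <- tipsUnder(node)
    labels <- tree$tip.label[tipIdx]
    if (length(labels) == 1L) {
      clades[[length(clades) + 1L]] <<- labels
      return(invisible())
    }
    sub <- dm[labels, labels, drop = FALSE]
    obs <- binCurve(sub, criteria = config$criteria, seqLen = L)
    fit <- tryCatch(
      fitSES(obs, config = config, seed = deriveSeed(seed, node)),
      error = function(e) NULL)
    accept <- if (is.null(fit)) {
      warning(sprintf("unresolved fit at node %d; clade split", node))
      FALSE
    } else if (mode == "conservative") 1L %in% fit@ciNpop else fit@npop == 1L
    if (accept) {
      clades[[length(clades) + 1L]] <<- labels
    } else {
      for (ch in childrenOf(node)) recurse(ch)
    }
    invisible()
  }
  recurse(root)
  names(clades) <- sprintf("PE%02d", seq_along(clades))
  assignment <- setNames(rep(names(clades), lengths(clades)),
                         unlist(clades, use.names = FALSE))
  new("PEPartition", mode = mode, assignment = assignment, clades = clades)
}
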