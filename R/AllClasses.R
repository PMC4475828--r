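#' @import methods
#' @importFrom stats setNames
NULL

#' Ecotype specification
#'
#' Describes one planted ecotype for the synthetic community generator: its
#' Gaussian niche over the temperature x depth habitat grid, its overall
#' weight in the community, and the number of high-frequency (HFS) and
#' low-frequency (LFS) haplotypes carried besides the dominant variant.
#'
#' @slot id single character label.
#' @slot nicheCenter numeric length 2: (temperature degC, depth um).
#' @slot nicheBreadth numeric length 2: niche s.d. (sigma_T degC, sigma_z um),
#'   both strictly positive.
#' @slot weight positive real, relative community weight.
#' @slot nHfs integer >= 1, number of high-frequency haplotypes including the
#'   dominant variant.
#' @slot nLfs integer >= 0, number of low-frequency haplotypes.
#' @slot dominant nucleotide string of the dominant haplotype, or "" to have
#'   it generated from the reference.
#' @seealso [ecotypeSpec()], [generateHaplotypes()], [simulateCommunity()]
#' @exportClass EcotypeSpec
setClass("EcotypeSpec",
  representation(
    id = "character",
    nicheCenter = "numeric",
    nicheBreadth = "numeric",
    weight = "numeric",
    nHfs = "integer",
    nLfs = "integer",
    dominant = "character"
  )
)

setValidity("EcotypeSpec", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty label")
  if (length(object@nicheCenter) != 2L)
    msg <- c(msg, "'nicheCenter' must be (temperature, depth)")
  if (length(object@nicheBreadth) != 2L || any(object@nicheBreadth <= 0))
    msg <- c(msg, "'nicheBreadth' must be two strictly positive values")
  if (length(object@weight) != 1L || object@weight <= 0)
    msg <- c(msg, "'weight' must be a single positive real")
  if (object@nHfs < 1L) msg <- c(msg, "'nHfs' must be >= 1")
  if (object@nLfs < 0L) msg <- c(msg, "'nLfs' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an EcotypeSpec
#'
#' @param id ecotype label.
#' @param nicheCenter numeric length 2, niche optimum as
#'   (temperature degC, depth um).
#' @param nicheBreadth numeric length 2, Gaussian niche s.d. per axis.
#' @param weight relative community weight (positive).
#' @param nHfs number of high-frequency haplotypes (>= 1, includes dominant).
#' @param nLfs number of low-frequency haplotypes (>= 0).
#' @param dominant optional dominant haplotype sequence; "" to derive it
#'   from the reference during haplotype generation.
#' @return An [EcotypeSpec-class] object.
#' @examples
#' ecotypeSpec("A1", c(60, 400), c(2.5, 200), nHfs = 3, nLfs = 4)
#' @export
ecotypeSpec <- function(id, nicheCenter, nicheBreadth = c(2.5, 200),
                        weight = 1, nHfs = 3L, nLfs = 2L, dominant = "") {
  new("EcotypeSpec",
    id = as.character(id), nicheCenter = as.numeric(nicheCenter),
    nicheBreadth = as.numeric(nicheBreadth), weight = as.numeric(weight),
    nHfs = as.integer(nHfs), nLfs = as.integer(nLfs),
    dominant = as.character(dominant))
}

setMethod("show", "EcotypeSpec", function(object) {
  cat(sprintf(
    "EcotypeSpec '%s': niche (%g degC, %g um), sd (%g, %g), weight %g, %d HFS + %d LFS\n",
    object@id, object@nicheCenter[1], object@nicheCenter[2],
    object@nicheBreadth[1], object@nicheBreadth[2], object@weight,
    object@nHfs, object@nLfs))
})

#' Homopolymer error model
#'
#' Pyrosequencing-style indel model: each maximal run of identical bases of
#' length L independently suffers at most one event per read — an insertion
#' of one extra copy of the run base with probability `pIns * L^runLengthExponent`,
#' or a deletion of one base with probability `pDel * L^runLengthExponent`.
#' With both rates zero, reads equal their source haplotypes.
#'
#' @slot pIns per-run insertion probability in [0, 1).
#' @slot pDel per-run deletion probability in [0, 1).
#' @slot runLengthExponent exponent scaling event probability with run length
#'   (0 = no scaling).
#' @seealso [errorModel()], [simulateReads()]
#' @exportClass ErrorModel
setClass("ErrorModel",
  representation(pIns = "numeric", pDel = "numeric",
                 runLengthExponent = "numeric")
)

setValidity("ErrorModel", function(object) {
  if (object@pIns < 0 || object@pIns >= 1) return("'pIns' must be in [0, 1)")
  if (object@pDel < 0 || object@pDel >= 1) return("'pDel' must be in [0, 1)")
  TRUE
})

#' Construct a homopolymer ErrorModel
#'
#' @param pIns per-homopolymer-run insertion probability.
#' @param pDel per-run deletion probability.
#' @param runLengthExponent run-length scaling exponent (default 0: all runs
#'   equally error-prone).
#' @return An [ErrorModel-class] object.
#' @examples
#' errorModel(pIns = 0.01)         # insertion-only corruption
#' errorModel(0, 0)                # error-free sequencing
#' @export
errorModel <- function(pIns = 0.01, pDel = 0.005, runLengthExponent = 0) {
  new("ErrorModel", pIns = as.numeric(pIns), pDel = as.numeric(pDel),
      runLengthExponent = as.numeric(runLengthExponent))
}

setMethod("show", "ErrorModel", function(object) {
  cat(sprintf("ErrorModel: pIns %g, pDel %g per run (L^%g scaling)\n",
              object@pIns, object@pDel, object@runLengthExponent))
})

#' Synthetic community over a habitat grid
#'
#' True (planted) relative abundance of each ecotype in each sample of a
#' temperature x depth x time design. Rows are ecotypes, columns samples;
#' each column sums to 1.
#'
#' @slot samples data.frame with columns sample_id, temperature_C, depth_um,
#'   timepoint, condition.
#' @slot abundance matrix ecotype x sample of relative abundances (columns
#'   sum to 1, all entries >= 0).
#' @seealso [simulateCommunity()], [trueAbundance()], [sampleMetadata()]
#' @exportClass CommunityGrid
setClass("CommunityGrid",
  representation(samples = "data.frame", abundance = "matrix")
)

setValidity("CommunityGrid", function(object) {
  msg <- character()
  need <- c("sample_id", "temperature_C", "depth_um", "timepoint", "condition")
  if (!all(need %in% names(object@samples)))
    msg <- c(msg, paste("'samples' must have columns:",
                        paste(need, collapse = ", ")))
  if (ncol(object@abundance) != nrow(object@samples))
    msg <- c(msg, "abundance columns must match sample rows")
  if (any(object@abundance < 0))
    msg <- c(msg, "abundances must be non-negative")
  cs <- colSums(object@abundance)
  if (length(cs) && any(abs(cs - 1) > 1e-9))
    msg <- c(msg, "per-sample abundances must sum to 1 (tol 1e-9)")
  if (length(msg)) msg else TRUE
})

#' @describeIn CommunityGrid-class planted relative abundance matrix
#'   (ecotype x sample).
#' @param object a CommunityGrid.
#' @export
trueAbundance <- function(object) object@abundance

#' @describeIn CommunityGrid-class sample metadata table.
#' @export
sampleMetadata <- function(object) object@samples

setMethod("show", "CommunityGrid", function(object) {
  cat(sprintf("CommunityGrid: %d ecotypes x %d samples (T %g-%g degC, depth %g-%g um)\n",
              nrow(object@abundance), ncol(object@abundance),
              min(object@samples$temperature_C), max(object@samples$temperature_C),
              min(object@samples$depth_um), max(object@samples$depth_um)))
})

#' Variant-by-sample count table
#'
#' Unique cleaned sequences (variants) and their exact per-sample counts.
#' Variants are ordered by descending total count, ties broken
#' lexicographically by sequence, so the table is deterministic.
#'
#' @slot sequences named character vector of unique variant sequences
#'   (names are variant ids).
#' @slot counts integer matrix variant x sample; column sums equal the number
#'   of cleaned reads per sample.
#' @seealso [dereplicateAndCount()], [selectHFS()], [variantCounts()]
#' @exportClass VariantTable
setClass("VariantTable",
  representation(sequences = "character", counts = "matrix")
)

setValidity("VariantTable", function(object) {
  msg <- character()
  if (anyDuplicated(object@sequences))
    msg <- c(msg, "variant sequences must be unique")
  if (nrow(object@counts) != length(object@sequences))
    msg <- c(msg, "counts rows must match sequences")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (!identical(rownames(object@counts), names(object@sequences)))
    msg <- c(msg, "counts rownames must equal variant ids")
  if (length(msg)) msg else TRUE
})

#' @describeIn VariantTable-class variant x sample integer count matrix.
#' @param object a VariantTable.
#' @export
variantCounts <- function(object) object@counts

#' @describeIn VariantTable-class named vector of unique variant sequences.
#' @export
variantSequences <- function(object) object@sequences

#' @describeIn VariantTable-class total count of each variant across all
#'   samples.
#' @export
variantTotals <- function(object) rowSums(object@counts)

setMethod("show", "VariantTable", function(object) {
  cat(sprintf("VariantTable: %d variants x %d samples, %d reads total\n",
              nrow(object@counts), ncol(object@counts), sum(object@counts)))
})

#' Fitted Stable Ecotype Model parameters
#'
#' Maximum (simulation-approximated) likelihood estimate of the ecotype
#' formation rate omega, the periodic selection rate sigma (both in events
#' per nucleotide substitution) and the number of ecotypes npop, with a
#' profile-likelihood confidence set for npop.
#'
#' @slot omega ML ecotype formation rate.
#' @slot sigma ML periodic selection rate.
#' @slot npop ML number of ecotypes (>= 1).
#' @slot drift within-ecotype coalescent (drift) intensity used.
#' @slot ciNpop integer vector: npop values whose profile likelihood is
#'   within a factor exp(-2) of the maximum.
#' @slot likelihood ML likelihood value (fraction of matching replicates).
#' @slot surface data.frame of the evaluated likelihood surface
#'   (omega, sigma, npop, likelihood).
#' @seealso [fitSES()], [demarcate()]
#' @exportClass DemarcationFit
setClass("DemarcationFit",
  representation(omega = "numeric", sigma = "numeric", npop = "integer",
                 drift = "numeric", ciNpop = "integer",
                 likelihood = "numeric", surface = "data.frame")
)

setValidity("DemarcationFit", function(object) {
  msg <- character()
  if (object@npop < 1L) msg <- c(msg, "'npop' must be >= 1")
  if (object@omega < 0 || object@sigma < 0)
    msg <- c(msg, "rates must be non-negative")
  if (!(object@npop %in% object@ciNpop))
    msg <- c(msg, "ML npop must lie inside its confidence set")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DemarcationFit", function(object) {
  cat(sprintf(
    "DemarcationFit: npop = %d (CI {%s}), omega = %g, sigma = %g, L = %g\n",
    object@npop, paste(object@ciNpop, collapse = ","),
    object@omega, object@sigma, object@likelihood))
})

#' Putative-ecotype partition of variants
#'
#' Assignment of sequence variants to putative ecotypes (PEs). Each PE is a
#' clade of the demarcation tree (or a single leaf); the partition is total
#' and disjoint over the tree's leaves.
#'
#' @slot mode "conservative" (clade accepted when the confidence interval
#'   for the number of ecotypes includes 1) or "fine" (accepted when the ML
#'   estimate itself equals 1).
#' @slot assignment named character vector: variant id -> PE id.
#' @slot clades named list: PE id -> character vector of member variant ids.
#' @seealso [demarcate()], [peAssignments()]
#' @exportClass PEPartition
setClass("PEPartition",
  representation(mode = "character", assignment = "character",
                 clades = "list")
)

setValidity("PEPartition", function(object) {
  msg <- character()
  if (!object@mode %in% c("conservative", "fine"))
    msg <- c(msg, "'mode' must be 'conservative' or 'fine'")
  members <- unlist(object@clades, use.names = FALSE)
  if (anyDuplicated(members))
    msg <- c(msg, "PE clades must be disjoint")
  if (!setequal(members, names(object@assignment)))
    msg <- c(msg, "clades must cover exactly the assigned variants")
  if (!all(object@assignment %in% names(object@clades)))
    msg <- c(msg, "every assignment must point at a listed PE")
  if (length(msg)) msg else TRUE
})

#' @describeIn PEPartition-class named vector mapping variant id to PE id.
#' @param object a PEPartition.
#' @export
peAssignments <- function(object) object@assignment

#' @describeIn PEPartition-class number of demarcated PEs.
#' @export
nPE <- function(object) length(object@clades)

#' Diel transcript count series
#'
#' Per-category (PE or gene set) transcript counts over diel timepoints.
#' Timepoints that failed sequencing are carried as a missing mask rather
#' than zero columns; timepoints where every category had zero activity are
#' flagged.
#'
#' @slot counts integer matrix category x timepoint (columns named by
#'   timepoint label, e.g. hour).
#' @slot missing character vector of timepoint labels absent from the series.
#' @slot flagged character vector of retained timepoints whose total
#'   activity was zero.
#' @slot ambiguous integer count of reads discarded as ambiguous during
#'   matching (0 for simulated series).
#' @seealso [simulateDielTranscripts()], [matchTranscripts()],
#'   [normalizeDiel()]
#' @exportClass DielSeries
setClass("DielSeries",
  representation(counts = "matrix", missing = "character",
                 flagged = "character", ambiguous = "integer")
)

setValidity("DielSeries", function(object) {
  msg <- character()
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (is.null(colnames(object@counts)))
    msg <- c(msg, "count columns must be named by timepoint")
  if (any(object@missing %in% colnames(object@counts)))
    msg <- c(msg, "missing timepoints must not appear in counts")
  if (length(msg)) msg else TRUE
})

#' @describeIn DielSeries-class category x timepoint count matrix.
#' @param object a DielSeries.
#' @export
dielCounts <- function(object) object@counts

setMethod("show", "DielSeries", function(object) {
  cat(sprintf("DielSeries: %d categories x %d timepoints (%d missing, %d flagged zero)\n",
              nrow(object@counts), ncol(object@counts),
              length(object@missing), length(object@flagged)))
})

setMethod("show", "PEPartition", function(object) {
  sizes <- lengths(object@clades)
  cat(sprintf("PEPartition (%s): %d PEs over %d variants (sizes: %s)\n",
              object@mode, length(object@clades), length(object@assignment),
              paste(sizes, collapse = ",")))
})
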