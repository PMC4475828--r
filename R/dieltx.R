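#' Assign diel cDNA reads to putative ecotypes by exact match
#'
#' A read counts toward a PE if and only if it is identical, over the
#' shared cDNA window, to one of that PE's variant sequences. Reads whose
#' window matches variants of more than one PE (possible after windowing
#' collapses distinct variants) are discarded as ambiguous and tallied;
#' reads matching no variant are unassigned.
#'
#' @param reads named list: timepoint label -> character vector of cDNA
#'   reads (all of the window length).
#' @param variantWindows named character vector: variant id -> windowed
#'   variant sequence.
#' @param variantPE named character vector: variant id -> PE id.
#' @return a [DielSeries-class] whose rows are PEs (plus none missing);
#'   unassigned and ambiguous tallies are in the `ambiguous` slot and the
#'   `"unassigned"` attribute.
#' @export
matchTranscripts <- function(reads, variantWindows, variantPE) {
  stopifnot(length(variantWindows) == length(variantPE),
            all(names(variantWindows) == names(variantPE)))
  w <- unique(nchar(variantWindows))
  if (length(w) != 1) stop("variant windows must share one length")
  pes <- sort(unique(variantPE))
  counts <- matrix(0L, length(pes), length(reads),
                   dimnames = list(pes, names(reads)))
  ambiguous <- 0L; unassigned <- 0L
  # windowed sequence -> set of PEs carrying it
  seqPE <- split(unname(variantPE), unname(variantWindows))
  seqPE <- lapply(seqPE, unique)
  for (t in names(reads)) {
    r <- reads[[t]]
    if (length(r) && any(nchar(r) != w))
      stop("read length does not match the cDNA window")
    hits <- seqPE[r]
    for (h in hits) {
      if (is.null(h)) unassigned <- unassigned + 1L
      else if (length(h) > 1L) ambiguous <- ambiguous + 1L
      else counts[h, t] <- counts[h, t] + 1L
    }
  }
  out <- new("DielSeries", counts = counts, missing = character(),
             flagged = character(), ambiguous = ambiguous)
  attr(out, "unassigned") <- unassigned
  out
}

#' Recruit short transcript reads to lineage gene sets
#'
#' Ungapped scan of each short read against each gene (both strands): the
#' read is recruited to the lineage of its best-matching gene when the
#' best Hamming distance over all gene windows is at most `maxMismatch`.
#' Reads whose best distance is achieved in more than one lineage are
#' discarded and tallied as ambiguous.
#'
#' @param reads named list: timepoint -> character vector of short reads
#'   (e.g. 50 nt).
#' @param genes named list: lineage -> character vector of gene sequences.
#' @param maxMismatch maximum allowed Hamming distance (default 5).
#' @return list with `counts` (lineage x timepoint), `ambiguous` and
#'   `unrecruited` tallies.
#' @export
recruitReads <- function(reads, genes, maxMismatch = 5L) {
  lineages <- names(genes)
  geneSets <- lapply(genes, function(g)
    Biostrings::DNAStringSet(c(g, as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(g))))))
  counts <- matrix(0L, length(lineages), length(reads),
                   dimnames = list(lineages, names(reads)))
  ambiguous <- 0L; unrecruited <- 0L
  bestDist <- function(read, set) {
    pat <- Biostrings::DNAString(read)
    for (mm in 0:maxMismatch) {
      n <- sum(Biostrings::vcountPattern(pat, set, max.mismatch = mm))
      if (n > 0) return(mm)
    }
    Inf
  }
  for (t in names(reads)) {
    for (r in reads[[t]]) {
      d <- vapply(geneSets, bestDist, numeric(1), read = r)
      if (all(!is.finite(d))) { unrecruited <- unrecruited + 1L; next }
      hit <- which(d == min(d))
      if (length(hit) > 1L) ambiguous <- ambiguous + 1L
      else counts[hit, t] <- counts[hit, t] + 1L
    }
  }
  list(counts = counts, ambiguous = ambiguous, unrecruited = unrecruited)
}

#' Two-stage diel normalization
#'
#' Stage one divides each category's count by the total assigned at that
#' timepoint (relative share); stage two divides each category's shares by
#' their geometric mean over non-missing timepoints, so each category's
#' normalized series has geometric mean 1 and timing patterns are
#' comparable across categories of different overall abundance. Zero
#' counts are replaced by `pseudocount` before the geometric-mean stage.
#'
#' @param series a [DielSeries-class], or a category x timepoint count
#'   matrix.
#' @param pseudocount replacement for zero counts (default 0.5).
#' @return list with `values` (category x timepoint matrix of normalized
#'   values), `shares` (stage-one shares), and `missing`.
#' @examples
#' normalizeDiel(matrix(c(10, 30), 1, 2,
#'                      dimnames = list("A", c("2", "6"))))$values
#' @export
normalizeDiel <- function(series, pseudocount = 0.5) {
  if (is(series, "DielSeries")) {
    counts <- dielCounts(series)
    missing <- series@missing
  } else {
    counts <- as.matrix(series)
    missing <- character()
  }
  if (ncol(counts) == 0) stop("all timepoints missing")
  counts <- counts + (counts == 0) * pseudocount
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("non-positive totals at some timepoints")
  shares <- sweep(counts, 2, totals, "/")
  gm <- exp(rowMeans(log(shares)))
  values <- sweep(shares, 1, gm, "/")
  list(values = values, shares = shares, missing = missing)
}

#' Relative share of each category per timepoint
#'
#' Percent relative abundance per timepoint, with the denominator being
#' the assigned reads only.
#'
#' @param series a [DielSeries-class] or count matrix.
#' @return matrix of percentages (columns sum to 100 where total > 0).
#' @export
dielRelativeAbundance <- function(series) {
  counts <- if (is(series, "DielSeries")) dielCounts(series) else
    as.matrix(series)
  tot <- colSums(counts)
  sweep(counts, 2, ifelse(tot == 0, NA_real_, tot), "/") * 100
}
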